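test_that("expected log-likelihood reduces to the density at zero variance", {
  fams <- list(list(lo_family("poisson"), 3, list()),
               list(lo_family("gaussian"), 0.7, list(phi = 2)),
               list(lo_family("negbin"), 4, list(phi = 0.5)),
               list(lo_family("bernoulli", "probit"), 1, list()))
  for (f in fams) {
    ld <- log_density(f[[1]], f[[2]], 0.4, f[[3]])
    meth <- if (f[[1]]$closed_va) "VA" else "EVA"
    expect_equal(expected_loglik(f[[1]], f[[2]], 0.4, 0, meth, f[[3]]), ld)
    expect_equal(expected_loglik(f[[1]], f[[2]], 0.4, 0, "EVA", f[[3]]), ld)
  }
})

test_that("Poisson VA and EVA differ by the documented lognormal gap", {
  va <- expected_loglik(lo_family("poisson"), 1, 0, 0.1, "VA")
  eva <- expected_loglik(lo_family("poisson"), 1, 0, 0.1, "EVA")
  expect_equal(va, -exp(0.05))
  expect_equal(eva, -1.05)
  expect_equal(abs(va - eva), exp(0.05) - 1.05, tolerance = 1e-12)
  # gaussian identity: the expansion is exact
  for (v in c(0, 0.3, 2)) {
    expect_equal(
      expected_loglik(lo_family("gaussian"), 1.3, 0.2, v, "VA",
                      list(phi = 1.7)),
      expected_loglik(lo_family("gaussian"), 1.3, 0.2, v, "EVA",
                      list(phi = 1.7)))
  }
  expect_error(expected_loglik(lo_family("negbin"), 1, 0, 0.1, "VA",
                               list(phi = 1)), "EVA")
})

test_that("Gaussian KL divergence matches its closed form", {
  expect_equal(kl_gaussian(c(0, 0), diag(2), diag(2)), 0)
  expect_equal(kl_gaussian(0, matrix(0.5), matrix(1)),
               0.5 * (0.5 - 1 - log(0.5)), tolerance = 1e-12)
  expect_equal(kl_gaussian(c(1, 0), diag(2), diag(2)), 0.5)
  expect_gt(kl_gaussian(c(0.3, -1), 0.7 * diag(2), diag(2)), 0)
  expect_error(kl_gaussian(0, matrix(-1), matrix(1)), "positive definite")
})

test_that("with no latent terms the ELBO equals the exact GLM log-likelihood", {
  set.seed(21)
  n <- 30; m <- 4
  X <- data.frame(x1 = rnorm(n))
  Y <- matrix(rpois(n * m, 3), n, m)
  dat <- lo_dataset(Y, X)
  spec <- lo_model_spec("poisson", species_formula = ~ x1)
  fit <- lo_fit(spec, dat, lo_control(seed = 1))
  ll <- sum(sapply(seq_len(m), function(j)
    logLik(glm(Y[, j] ~ x1, data = X, family = poisson()))))
  expect_equal(fit$objective, ll, tolerance = 1e-6)
  cf <- t(sapply(seq_len(m), function(j)
    coef(glm(Y[, j] ~ x1, data = X, family = poisson()))))
  expect_equal(unname(cbind(fit$params$beta0, fit$params$Beta_free)),
               unname(cf), tolerance = 1e-4)
})

test_that("the VA ELBO never exceeds the quadrature marginal likelihood", {
  n <- 3; m <- 2
  for (rep in 1:12) {
    set.seed(300 + rep)
    fam_name <- if (rep %% 2 == 0) "poisson" else "bernoulli"
    fam <- if (fam_name == "poisson") lo_family("poisson") else
      lo_family("bernoulli", "probit")
    b0 <- rnorm(m, 0, 0.5); g <- rnorm(m, 0, 0.7)
    eta <- matrix(b0, n, m, byrow = TRUE) + outer(rnorm(n), g)
    Y <- simulate_response(fam, eta)
    dat <- lo_dataset(Y)
    spec <- lo_model_spec(fam_name, num_lv = 1,
                          link = if (fam_name == "bernoulli") "probit"
                          else NULL)
    model <- latentord:::build_model(spec, dat)
    st <- random_state(model, spec, dat, sd = 0.4)
    bound <- latentord:::elbo_value(model, st, "VA")
    logml <- quadrature_logml(fam, Y, st$params$beta0,
                              as.vector(st$params$Gamma_u))
    expect_lte(bound, logml + 1e-6)
  }
})

test_that("analytic gradients agree with finite differences", {
  set.seed(22)
  n <- 7; m <- 4
  X <- data.frame(x1 = rnorm(n), YEAR = rep(1:7))
  Y <- matrix(rpois(n * m, 2), n, m)
  dat <- lo_dataset(Y, X)
  specs <- list(
    lo_model_spec("poisson", num_lv = 2, species_formula = ~ x1),
    lo_model_spec("negbin", num_lv = 1),
    lo_model_spec("poisson", num_lv_c = 1, lv_formula = ~ x1,
                  randomB = "LV"),
    lo_model_spec("poisson", num_lv = 1, lv_cor = "corAR1(1|YEAR)"))
  for (spec in specs) {
    model <- latentord:::build_model(spec, dat)
    st0 <- latentord:::starting_values(spec, dat, mode = "zero")
    th <- latentord:::state_pack(model, st0)
    set.seed(1); th <- th + rnorm(length(th), 0, 0.1)
    st <- latentord:::state_unpack(model, th)
    ga <- latentord:::elbo_gradient(model, st)
    gn <- latentord:::numeric_gradient(function(t)
      latentord:::elbo_value(model, latentord:::state_unpack(model, t)), th)
    expect_lt(max(abs(ga - gn) / pmax(1, abs(gn))), 1e-5)
  }
})

test_that("starting values behave as documented", {
  set.seed(23)
  sim <- simulate_lv_poisson(n = 80, m = 12, d = 2, seed = 23)
  dat <- lo_dataset(sim$Y)
  spec <- lo_model_spec("poisson", num_lv = 2)
  stz <- starting_values(spec, dat, mode = "zero")
  expect_equal(unname(stz$params$beta0), log(pmax(colMeans(sim$Y), 1e-3)))
  expect_true(all(stz$vstate$U_mean == 0))
  # residual seeding: top-2 SVD of the residual matrix captures most of it
  str <- starting_values(spec, dat, mode = "res")
  expect_false(all(str$vstate$U_mean == 0))
  R <- str$vstate$U_mean %*% t(str$params$Gamma_u)
  expect_gt(sum(svd(R)$d[1:2]^2) / sum(svd(R)$d^2), 0.5)
})

test_that("fitting is deterministic and restarts only improve the objective", {
  set.seed(24)
  sim <- simulate_lv_poisson(n = 30, m = 6, d = 1, seed = 24)
  dat <- lo_dataset(sim$Y)
  spec <- lo_model_spec("poisson", num_lv = 1)
  ctl <- lo_control(seed = 3, maxit = 300)
  f1 <- lo_fit(spec, dat, ctl)
  f2 <- lo_fit(spec, dat, ctl)
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$theta, f2$theta)
  f5 <- lo_fit(spec, dat, lo_control(seed = 3, maxit = 300, n_init = 5))
  expect_gte(max(f5$trace), max(f1$trace) - 1e-8)
  expect_gte(f5$objective, f1$objective - 1e-4)
})

test_that("missing cells drop from the likelihood without changing df", {
  set.seed(25)
  sim <- simulate_lv_poisson(n = 20, m = 5, d = 1, seed = 25)
  Y2 <- sim$Y; Y2[3, 2] <- NA
  d1 <- lo_dataset(sim$Y); d2 <- lo_dataset(Y2)
  spec <- lo_model_spec("poisson", num_lv = 1)
  f1 <- lo_fit(spec, d1, lo_control(seed = 1, maxit = 200))
  f2 <- lo_fit(spec, d2, lo_control(seed = 1, maxit = 200))
  expect_identical(f1$n_obs - 1L, f2$n_obs)
  expect_lte(f2$df, f1$df)
  expect_identical(n_observed(d2), 99L)
})
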