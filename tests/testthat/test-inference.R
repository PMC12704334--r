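test_that("information criteria match the printed concurrent-ordination rows", {
  # n = 87 sites, m = 68 species -> 5916 observed cells
  ic <- ic_from_loglik(-53617.480, 236, 87 * 68)
  expect_equal(round(ic$AIC, 2), 107706.96)
  expect_equal(round(ic$AICc, 2), 107726.66)
  expect_equal(round(ic$BIC, 2), 109284.72)
  rows <- list(
    list(logL = -37289.083, df = 317, AIC = 75212.17, AICc = 75248.18,
         BIC = 77331.44),
    list(logL = -26385.168, df = 396, AIC = 53562.34, AICc = 53619.31,
         BIC = 56209.76),
    list(logL = -8864.225, df = 304, AIC = 18336.45, AICc = 18369.50,
         BIC = 20368.82),
    list(logL = -8483.288, df = 532, AIC = 18030.58, AICc = 18135.93,
         BIC = 21587.22))
  for (r in rows) {
    ic <- ic_from_loglik(r$logL, r$df, 5916)
    expect_equal(round(ic$AIC, 2), r$AIC)
    expect_equal(round(ic$AICc, 2), r$AICc)
    expect_equal(round(ic$BIC, 2), r$BIC)
  }
  expect_warning(ic_from_loglik(-10, 50, 40), "AICc undefined")
})

test_that("information criteria of a fit use the lower bound and df", {
  set.seed(31)
  sim <- simulate_lv_poisson(20, 4, 1, seed = 31)
  fit <- lo_fit(lo_model_spec("poisson", num_lv = 1), lo_dataset(sim$Y),
                lo_control(seed = 1, maxit = 200))
  ic <- information_criteria(fit)
  expect_equal(ic$AIC, -2 * fit$objective + 2 * fit$df)
  expect_equal(AIC(fit), ic$AIC)
  expect_equal(BIC(fit), ic$BIC)
  expect_equal(ic$n_obs, 80)
})

test_that("Wald intervals match the GLM oracle on a latent-free model", {
  set.seed(32)
  n <- 120; m <- 5
  X <- data.frame(x1 = rnorm(n))
  b0 <- rnorm(m, 1, 0.3); b1 <- rnorm(m, 0, 0.4)
  eta <- matrix(b0, n, m, byrow = TRUE) + outer(X$x1, b1)
  Y <- matrix(rpois(n * m, exp(eta)), n, m)
  fit <- lo_fit(lo_model_spec("poisson", species_formula = ~ x1),
                lo_dataset(Y, X), lo_control(seed = 1))
  wt <- wald_intervals(fit, level = 0.95)
  expect_equal(wt$upper - wt$estimate, 1.959964 * wt$SE, tolerance = 1e-6)
  ses <- unlist(lapply(seq_len(m), function(j)
    summary(glm(Y[, j] ~ x1, data = X, family = poisson()))$coef[, 2]))
  glm_se <- c(ses[seq(1, 2 * m, by = 2)], ses[seq(2, 2 * m, by = 2)])
  expect_equal(wt$SE, unname(glm_se), tolerance = 0.05)
  expect_equal(wt$estimate[1:m], fit$params$beta0, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("prediction reproduces fitted values and applies the inverse link", {
  set.seed(33)
  n <- 25; m <- 4
  X <- data.frame(x1 = rnorm(n))
  sim <- simulate_lv_poisson(n, m, 1, seed = 33)
  dat <- lo_dataset(sim$Y, X)
  fit <- lo_fit(lo_model_spec("poisson", num_lv = 1,
                              species_formula = ~ x1),
                dat, lo_control(seed = 1, maxit = 300))
  eta_hat <- predict(fit)
  eta_new <- predict(fit, newdata = data.frame(x1 = X$x1,
                                               row.names = rownames(dat$Y)))
  expect_equal(eta_new, eta_hat, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(predict(fit, type = "response"), exp(eta_hat),
               ignore_attr = TRUE)
  # unseen sites get zero latent contribution; zero covariates give intercepts
  pz <- predict(fit, newdata = data.frame(x1 = 0, row.names = "new1"))
  expect_equal(as.vector(pz), fit$params$beta0, ignore_attr = TRUE)
  expect_error(predict(fit, newdata = data.frame(z = 1)), "x1")
})

test_that("residual diagnostics are calibrated under the true model", {
  set.seed(34)
  sim <- simulate_lv_poisson(n = 200, m = 30, d = 2, seed = 34)
  dat <- lo_dataset(sim$Y)
  fit <- lo_fit(lo_model_spec("poisson", num_lv = 2), dat,
                lo_control(seed = 1, maxit = 1500))
  rd <- residual_diagnostics(fit, seed = 2)
  expect_lt(abs(rd$pooled["mean"]), 0.05)
  expect_gt(rd$pooled["var"], 0.9)
  expect_lt(rd$pooled["var"], 1.1)
  # gaussian residuals are deterministic
  Yg <- matrix(rnorm(60), 20, 3)
  fg <- lo_fit(lo_model_spec("gaussian"), lo_dataset(Yg),
               lo_control(seed = 1))
  r1 <- residual_diagnostics(fg, seed = 1)$residuals
  r2 <- residual_diagnostics(fg, seed = 99)$residuals
  expect_equal(r1, r2)
})

test_that("overdispersion inflates Poisson residual variance", {
  set.seed(35)
  n <- 100; m <- 10
  mu <- 4
  Y <- matrix(rnbinom(n * m, size = 0.6, mu = mu), n, m)  # heavy overdispersion
  fit <- lo_fit(lo_model_spec("poisson"), lo_dataset(Y),
                lo_control(seed = 1))
  rd <- residual_diagnostics(fit, seed = 3)
  expect_gt(rd$pooled["var"], 1.5)
})

test_that("variance partitioning returns normalized, sensible proportions", {
  set.seed(36)
  n <- 400; m <- 6
  X <- data.frame(x1 = rnorm(n))
  b1 <- rep(0.8, m)
  U <- rnorm(n)
  g <- rep(0.8, m)
  eta <- outer(X$x1, b1) + outer(U, g)
  Y <- matrix(rpois(n * m, exp(eta)), n, m)
  fit <- lo_fit(lo_model_spec("poisson", num_lv = 1,
                              species_formula = ~ x1),
                lo_dataset(Y, X), lo_control(seed = 1, maxit = 1500))
  vp <- variance_partitioning(fit)
  expect_equal(unname(rowSums(vp$proportions)), rep(1, m), tolerance = 1e-8)
  expect_true(all(vp$proportions >= 0 & vp$proportions <= 1))
  # two equally strong components split the variance about evenly
  expect_lt(max(abs(colMeans(vp$proportions) - 0.5)), 0.1)
  fit0 <- lo_fit(lo_model_spec("poisson"), lo_dataset(Y, X),
                 lo_control(seed = 1))
  expect_error(variance_partitioning(fit0), "two model components")
})

test_that("environment correlations reflect loading geometry", {
  set.seed(37)
  n <- 150; m <- 4
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  B <- matrix(c(0.8, -0.4), 2, 1)
  G <- matrix(c(1, -1, 0.5, 0.25), m, 1)
  eta <- as.matrix(X) %*% B %*% t(G)
  Y <- matrix(rpois(n * m, exp(eta)), n, m)
  fit <- lo_fit(lo_model_spec("poisson", num_RR = 1,
                              lv_formula = ~ x1 + x2, randomB = "LV"),
                lo_dataset(Y, X), lo_control(seed = 1, maxit = 800))
  C <- environment_correlations(fit)
  expect_equal(unname(diag(C)), rep(1, m))
  expect_gt(min(eigen((C + t(C)) / 2, symmetric = TRUE)$values), -1e-8)
  # gamma_2 = -gamma_1 implies correlation -1; same sign implies +1
  expect_equal(C[1, 2], -1, tolerance = 1e-6)
  expect_equal(C[1, 3], 1, tolerance = 1e-6)
  fit_plain <- lo_fit(lo_model_spec("poisson"), lo_dataset(Y, X),
                      lo_control(seed = 1))
  expect_error(environment_correlations(fit_plain), "random environmental")
})

test_that("Wald intervals attain nominal coverage on latent-free models", {
  hits <- 0; total <- 0
  for (rep in 1:150) {
    set.seed(1000 + rep)
    n <- 60; m <- 3
    X <- data.frame(x1 = rnorm(n))
    b0 <- rnorm(m, 0.8, 0.3); b1 <- rnorm(m, 0, 0.4)
    eta <- matrix(b0, n, m, byrow = TRUE) + outer(X$x1, b1)
    Y <- matrix(rpois(n * m, exp(eta)), n, m)
    fit <- lo_fit(lo_model_spec("poisson", species_formula = ~ x1),
                  lo_dataset(Y, X), lo_control(seed = 1))
    wt <- wald_intervals(fit, level = 0.95)
    truth <- c(b0, b1)
    hits <- hits + sum(wt$lower <= truth & truth <= wt$upper)
    total <- total + length(truth)
  }
  cover <- hits / total
  expect_gte(cover, 0.92)
  expect_lte(cover, 0.98)
})
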