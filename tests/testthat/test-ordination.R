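test_that("ordination preserves the fitted latent contribution", {
  set.seed(41)
  sim <- simulate_lv_poisson(n = 60, m = 10, d = 2, seed = 41)
  fit <- lo_fit(lo_model_spec("poisson", num_lv = 2), lo_dataset(sim$Y),
                lo_control(seed = 1, maxit = 1000))
  ord <- ordination_coordinates(fit)
  R <- ord$rotation
  expect_equal(t(R) %*% R, diag(2), tolerance = 1e-10)
  eta_lv <- fit$vstate$U_mean %*% t(fit$params$Gamma_u)
  eta_rot <- ord$site_scores %*% t(ord$species_loadings)
  expect_equal(eta_rot, eta_lv, tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: largest loading on each axis positive
  for (r in 1:2)
    expect_gt(ord$species_loadings[which.max(abs(ord$species_loadings[, r])),
                                   r], 0)
  # d = 1: rotation is a sign; score-loading products unchanged
  f1 <- lo_fit(lo_model_spec("poisson", num_lv = 1), lo_dataset(sim$Y),
               lo_control(seed = 1, maxit = 500))
  o1 <- ordination_coordinates(f1)
  expect_equal(abs(o1$rotation[1, 1]), 1, tolerance = 1e-10)
  expect_equal(o1$site_scores %*% t(o1$species_loadings),
               f1$vstate$U_mean %*% t(f1$params$Gamma_u),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("constrained scores follow the canonical axes", {
  set.seed(42)
  n <- 100; m <- 6
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  G <- matrix(rnorm(m, 0, 0.6), m, 1)
  eta <- as.matrix(X) %*% matrix(c(1, 0), 2, 1) %*% t(G)
  Y <- matrix(rpois(n * m, exp(eta)), n, m)
  fit <- lo_fit(lo_model_spec("poisson", num_RR = 1, lv_formula = ~ x1 + x2),
                lo_dataset(Y, X), lo_control(seed = 1, maxit = 800))
  ord <- ordination_coordinates(fit)
  # the first covariate drives the single constrained axis
  expect_gt(abs(cor(ord$site_scores[, 1], X$x1)), 0.98)
  expect_false(is.null(ord$arrows))
  expect_error(ordination_coordinates(
    lo_fit(lo_model_spec("poisson"), lo_dataset(Y, X),
           lo_control(seed = 1))), "no latent variables")
})

test_that("score configurations are recovered up to rotation (Procrustes)", {
  errs <- sapply(c(50, 200), function(n) {
    sim <- simulate_lv_poisson(n = n, m = 15, d = 2, seed = 43,
                               gamma_sd = 0.9)
    fit <- lo_fit(lo_model_spec("poisson", num_lv = 2), lo_dataset(sim$Y),
                  lo_control(seed = 1, maxit = 2000))
    ord <- ordination_coordinates(fit)
    pr <- vegan::procrustes(scale(sim$U, scale = FALSE),
                            scale(ord$site_scores, scale = FALSE),
                            symmetric = TRUE)
    pr$ss
  })
  expect_lt(errs[1], 0.25)
  expect_lt(errs[2], 0.25)
  expect_lt(errs[2], errs[1] + 0.05)  # recovery improves with n
})

test_that("prediction regions use the chi-square coverage quantile", {
  set.seed(44)
  sim <- simulate_lv_poisson(n = 40, m = 8, d = 2, seed = 44)
  Y <- sim$Y
  Y[2, ] <- Y[1, ]  # two identical sites
  fit <- lo_fit(lo_model_spec("poisson", num_lv = 2), lo_dataset(Y),
                lo_control(seed = 1, maxit = 1000))
  pr <- prediction_regions(fit, level = 0.95)
  expect_equal(pr$chisq_q[1], qchisq(0.95, 2), tolerance = 1e-12)
  expect_equal(round(pr$chisq_q[1], 3), 5.991)
  iden <- abs(pr$area[1] - pr$area[2]) / pr$area[1]
  expect_lt(iden, 0.05)
  # constrained fits carry no residual latent scores
  X <- data.frame(x1 = rnorm(40))
  fc <- lo_fit(lo_model_spec("poisson", num_RR = 1, lv_formula = ~ x1),
               lo_dataset(Y, X), lo_control(seed = 1, maxit = 300))
  expect_error(prediction_regions(fc), "constrained")
})

test_that("average uncertainty shrinks as species are added", {
  areas <- sapply(c(8, 16), function(m) {
    sim <- simulate_lv_poisson(n = 40, m = m, d = 1, seed = 45)
    fit <- lo_fit(lo_model_spec("poisson", num_lv = 1), lo_dataset(sim$Y),
                  lo_control(seed = 1, maxit = 800))
    st <- list(params = fit$params, vstate = fit$vstate)
    mean(latentord:::eta_moments(fit$model, st)$covs$U$A[, 1, 1])
  })
  expect_lt(areas[2], areas[1])
})
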