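test_that("the generator hits its moments and is reproducible", {
  sc <- lo_scenario(n = 320, m = 32, k = 0, d = 0, family = "poisson",
                    intercept_mean = 0, intercept_sd = 0, seed = 5)
  out <- generate_dataset(sc)
  # all effects zero: cellwise mean 1
  se <- sqrt(1 / length(out$data$Y))
  expect_lt(abs(mean(out$data$Y) - 1), 3 * se)
  out2 <- generate_dataset(sc)
  expect_identical(out$data$Y, out2$data$Y)
  expect_identical(out$params, out2$params)
})

test_that("the kelp-like scenario reaches the target zero fraction", {
  out <- generate_dataset(kelp_like_scenario(seed = 2))
  expect_gte(nrow(out$data$Y) * ncol(out$data$Y), 1e4)
  zf <- mean(out$data$Y == 0)
  expect_gt(zf, 0.85); expect_lt(zf, 0.91)
  expect_true(all(out$data$Y >= 0 & out$data$Y <= 1))
  # nested design labels present: 11 sites, 44 transects
  expect_equal(length(unique(out$data$design$SITE)), 11)
  expect_equal(length(unique(out$data$design$TRANSECT)), 44)
})

test_that("the beetle-like scenario produces overdispersed sparse counts", {
  out <- generate_dataset(beetle_like_scenario(seed = 3))
  Y <- out$data$Y
  expect_equal(dim(Y), c(87, 68))
  expect_equal(ncol(out$data$X), 17)
  expect_true(all(Y == round(Y) & Y >= 0))
  expect_gt(mean(Y == 0), 0.3)  # zero-inflation visible
  disp <- apply(Y, 2, var) / pmax(colMeans(Y), 1e-6)
  expect_gt(median(disp), 1.5)  # overdispersed relative to Poisson
})

test_that("random trees give valid correlation structures", {
  rt <- random_tree(2, seed = 7)
  expect_gte(rt$C[1, 2], 0); expect_lt(rt$C[1, 2], 1)
  rt50 <- random_tree(50, seed = 8)
  expect_equal(unname(diag(rt50$C)), rep(1, 50))
  expect_gt(min(eigen(rt50$C, symmetric = TRUE)$values), 0)
})

test_that("a fit with the true spec recovers the linear predictor", {
  sim <- generate_dataset(lo_scenario(n = 200, m = 30, k = 0, d = 2,
                                      family = "poisson", seed = 11))
  fit <- lo_fit(sim$spec, sim$data, lo_control(seed = 1, maxit = 2500))
  eta_hat <- predict(fit)
  expect_gt(cor(as.vector(sim$eta), as.vector(eta_hat)), 0.9)
})

test_that("fourth-corner interactions are recovered from trait data", {
  sim <- generate_dataset(lo_scenario(n = 300, m = 40, k = 2, d = 0,
                                      q = 2, fourth_sd = 0.5,
                                      beta_sd = 0.3, slope_sd = 0.3,
                                      family = "poisson", seed = 12))
  fit <- lo_fit(sim$spec, sim$data, lo_control(seed = 1, maxit = 2000))
  rmse <- sqrt(mean((fit$params$B_fourth - sim$params$B_fourth)^2))
  expect_lt(rmse, 0.15)
})

test_that("phylogenetic signal orders correctly between high and no signal", {
  hits <- 0
  for (s in 1:10) {
    est <- sapply(c(0.8, 0), function(rho) {
      sim <- generate_dataset(lo_scenario(
        n = 60, m = 15, k = 2, d = 0, family = "poisson", tree = TRUE,
        rho_phylo = rho, slope_sd = 0.7, seed = 500 + s))
      fit <- lo_fit(sim$spec, sim$data,
                    lo_control(seed = 1, maxit = 600))
      fit$params$phylo_rho[1]
    })
    if (est[1] > est[2]) hits <- hits + 1
  }
  expect_gte(hits, 8)
})
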