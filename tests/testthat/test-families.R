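test_that("count log-densities match closed forms and the Poisson limit", {
  pois <- lo_family("poisson")
  expect_equal(log_density(pois, 0, 0), -1)
  zip <- lo_family("zip")
  expect_equal(log_density(zip, 0, log(2), aux = list(pi = 0.3)),
               log(0.3 + 0.7 * exp(-2)))
  expect_equal(log_density(zip, 3, log(2), aux = list(pi = 0.3)),
               log(0.7) + dpois(3, 2, log = TRUE))
  nb <- lo_family("negbin")
  for (y in c(0, 1, 5)) {
    gap <- abs(log_density(nb, y, 0.5, aux = list(phi = 1e-8)) -
                 log_density(pois, y, 0.5))
    expect_lt(gap, 1e-5)
    gap_big <- abs(log_density(nb, y, 0.5, aux = list(phi = 1)) -
                     log_density(pois, y, 0.5))
    expect_gt(gap_big, gap)
  }
})

test_that("ordered beta density has the three-part structure and normalizes", {
  expect_equal(ordered_beta_log_density(0, -1, -1, 4, 5), log(0.5))
  # P(0) + P(1) + integral over (0,1) equals one
  eta <- 0.3; z1 <- -1; z2 <- 4; phi <- 5
  p0 <- exp(ordered_beta_log_density(0, eta, z1, z2, phi))
  p1 <- exp(ordered_beta_log_density(1, eta, z1, z2, phi))
  dens <- function(y) exp(ordered_beta_log_density(y, eta, z1, z2, phi))
  mass <- stats::integrate(Vectorize(dens), 0, 1, rel.tol = 1e-9)$value
  expect_equal(p0 + p1 + mass, 1, tolerance = 1e-6)
  # eta -> -Inf pushes all mass to zero
  expect_equal(exp(ordered_beta_log_density(0, -30, z1, z2, phi)), 1,
               tolerance = 1e-10)
  expect_error(ordered_beta_log_density(0.5, 0, 2, 1, 5), "zeta1 < zeta2")
})

test_that("hurdle beta is a proper two-part model", {
  # zero branch ignores the positive-part predictor
  expect_equal(hurdle_beta_log_density(0, 0.7, -5, 3),
               hurdle_beta_log_density(0, 0.7, 5, 3))
  expect_equal(hurdle_beta_log_density(0, 0.7, 1, 3), plogis(-0.7, log.p = TRUE))
  # P(0) + integral of the positive density equals one
  ep <- 0; epos <- 0.5; phi <- 3
  p0 <- exp(hurdle_beta_log_density(0, ep, epos, phi))
  dens <- function(y) exp(hurdle_beta_log_density(y, ep, epos, phi))
  mass <- stats::integrate(Vectorize(dens), 1e-10, 1 - 1e-10,
                           rel.tol = 1e-9)$value
  expect_equal(p0 + mass, 1, tolerance = 1e-6)
  # presence certain: reduces to a plain beta density
  mu <- plogis(0.5)
  expect_equal(hurdle_beta_log_density(0.3, 50, 0.5, 3),
               dbeta(0.3, mu * 3, (1 - mu) * 3, log = TRUE),
               tolerance = 1e-6)
  expect_error(hurdle_beta_log_density(1, 0, 0, 3), "exact ones")
})

test_that("zero-inflated pmfs sum to one over parameter grids", {
  ys <- 0:300
  for (pi0 in c(0, 0.2, 0.6)) for (eta in c(-1, 0.5, 2)) {
    s_zip <- sum(exp(log_density(lo_family("zip"), ys, rep(eta, length(ys)),
                                 aux = list(pi = pi0))))
    expect_equal(s_zip, 1, tolerance = 1e-6)
    for (phi in c(0.3, 1.5)) {
      s_zinb <- sum(exp(log_density(lo_family("zinb"), ys,
                                    rep(eta, length(ys)),
                                    aux = list(pi = pi0, phi = phi))))
      expect_equal(s_zinb, 1, tolerance = 1e-6)
    }
  }
})

test_that("EVA curvature matches finite differences of the log-density", {
  set.seed(11)
  cases <- list(
    list(fam = lo_family("gaussian"), y = rnorm(5), aux = list(phi = 0.8)),
    list(fam = lo_family("poisson"), y = rpois(5, 3), aux = list()),
    list(fam = lo_family("negbin"), y = rpois(5, 3), aux = list(phi = 0.7)),
    list(fam = lo_family("bernoulli", "logit"), y = rbinom(5, 1, 0.5),
         aux = list()),
    list(fam = lo_family("bernoulli", "probit"), y = rbinom(5, 1, 0.5),
         aux = list()),
    list(fam = lo_family("zip"), y = c(0, 0, 1, 3, 7),
         aux = list(pi = 0.3)),
    list(fam = lo_family("zinb"), y = c(0, 0, 1, 3, 7),
         aux = list(pi = 0.3, phi = 0.6)),
    list(fam = lo_family("beta"), y = rbeta(5, 2, 3), aux = list(phi = 4)),
    list(fam = lo_family("ordered_beta"), y = c(0, 1, 0.2, 0.6, 0.9),
         aux = list(phi = 4, zeta1 = -1, zeta2 = 3)))
  h <- 1e-4
  for (cs in cases) {
    eta <- rnorm(5, 0, 1)
    ana <- eva_curvature(cs$fam, cs$y, eta, cs$aux)
    num <- (log_density(cs$fam, cs$y, eta + h, cs$aux) -
              2 * log_density(cs$fam, cs$y, eta, cs$aux) +
              log_density(cs$fam, cs$y, eta - h, cs$aux)) / h^2
    expect_equal(ana, num, tolerance = 1e-4,
                 label = paste("curvature", cs$fam$name, cs$fam$link))
  }
})

test_that("simulation matches the generative moments and edge cases", {
  expect_true(all(simulate_response(lo_family("zip"),
                                    matrix(1, 10, 10),
                                    aux = list(pi = 1), seed = 1) == 0))
  y <- simulate_response(lo_family("poisson"), matrix(log(4), 400, 250),
                         seed = 2)
  se <- sqrt(4 / length(y))
  expect_lt(abs(mean(y) - 4), 3 * se)
  yo <- simulate_response(lo_family("ordered_beta"), matrix(0, 200, 50),
                          aux = list(phi = 4, zeta1 = 12, zeta2 = 15),
                          seed = 3)
  expect_gt(mean(yo == 0), 0.99)
  # NB variance convention: Var = mu + phi mu^2
  yn <- simulate_response(lo_family("negbin"), matrix(log(5), 500, 200),
                          aux = list(phi = 0.5), seed = 4)
  expect_equal(stats::var(as.vector(yn)), 5 + 0.5 * 25, tolerance = 0.1)
  # reproducibility
  expect_identical(simulate_response(lo_family("poisson"), 1:5 / 2, seed = 9),
                   simulate_response(lo_family("poisson"), 1:5 / 2, seed = 9))
})

test_that("Dunn-Smyth residuals are standard normal under the true model", {
  gf <- lo_family("gaussian")
  y <- c(1.2, -0.4); eta <- c(0.5, 0)
  expect_equal(quantile_residual(gf, y, eta, aux = list(phi = 4), seed = 1),
               (y - eta) / 2)
  set.seed(5)
  eta <- matrix(rnorm(1e4, 0.5, 0.7), 100, 100)
  y <- simulate_response(lo_family("poisson"), eta, seed = 6)
  r <- quantile_residual(lo_family("poisson"), y, eta, seed = 7)
  ks <- suppressWarnings(stats::ks.test(as.vector(r), "pnorm"))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(length(r)))
  # randomized residual falls inside [qnorm(F(y-)), qnorm(F(y))]
  fam <- lo_family("poisson")
  cf <- latentord:::family_cdf(fam, 2, log(2), list())
  for (s in 1:20) {
    r1 <- quantile_residual(fam, 2, log(2), seed = s)
    expect_gte(r1, qnorm(cf$Fm))
    expect_lte(r1, qnorm(cf$F))
  }
})

test_that("unsupported links and out-of-support values are rejected", {
  expect_error(lo_family("poisson", link = "logit"), "does not support")
  expect_error(log_density(lo_family("poisson"), -1, 0), "support")
  expect_error(log_density(lo_family("beta"), 1, 0, list(phi = 2)), "support")
})
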