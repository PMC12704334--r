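# Independent oracles used across the suite.

# Gauss-Hermite nodes/weights via Golub-Welsch (physicists' convention,
# weight exp(-x^2))
gauss_hermite <- function(k) {
  i <- seq_len(k - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# adaptive quadrature log marginal likelihood for a d = 1 latent variable
# model: eta_ij = beta0_j + gamma_j * u_i, u_i ~ N(0,1), independent sites
quadrature_logml <- function(family, Y, beta0, gamma, aux = list(),
                             nodes = 50) {
  gh <- gauss_hermite(nodes)
  n <- nrow(Y)
  total <- 0
  for (i in seq_len(n)) {
    joint <- function(u) {
      sapply(u, function(ui) {
        eta <- beta0 + gamma * ui
        sum(log_density(family, Y[i, ], eta, aux)) + stats::dnorm(ui, log = TRUE)
      })
    }
    opt <- stats::optimize(joint, c(-8, 8), maximum = TRUE)
    mu <- opt$maximum
    h <- 1e-4
    curv <- (joint(mu + h) - 2 * joint(mu) + joint(mu - h)) / h^2
    s <- 1 / sqrt(max(-curv, 1e-4))
    u <- mu + sqrt(2) * s * gh$nodes
    lw <- joint(u) + gh$nodes^2 + log(gh$weights) + log(sqrt(2) * s)
    M <- max(lw)
    total <- total + M + log(sum(exp(lw - M)))
  }
  total
}

# closed-form maximum likelihood of probabilistic PCA (shared residual
# variance), mean profiled out; returns the maximized log-likelihood of the
# n x m data matrix under N(mu, W W' + s2 I) with rank-d W
ppca_logml <- function(Y, d) {
  n <- nrow(Y); m <- ncol(Y)
  S <- stats::cov(Y) * (n - 1) / n
  ev <- eigen(S, symmetric = TRUE)$values
  s2 <- mean(ev[(d + 1):m])
  Cdet <- sum(log(ev[seq_len(d)])) + (m - d) * log(s2)
  trc <- d + sum(ev[(d + 1):m]) / s2
  -n / 2 * (m * log(2 * pi) + Cdet + trc)
}

# random small state for ELBO bound checks: perturbed packed coordinates
random_state <- function(model, spec, data, sd = 0.3) {
  st <- latentord:::starting_values(spec, data, mode = "zero")
  th <- latentord:::state_pack(model, st)
  th <- th + stats::rnorm(length(th), 0, sd)
  latentord:::state_unpack(model, th)
}

simulate_lv_poisson <- function(n, m, d, seed, gamma_sd = 0.7,
                                intercept_sd = 0.5) {
  set.seed(seed)
  U <- matrix(stats::rnorm(n * d), n, d)
  G <- matrix(stats::rnorm(m * d, 0, gamma_sd), m, d)
  G[upper.tri(G)] <- 0
  b0 <- stats::rnorm(m, 1, intercept_sd)
  eta <- matrix(b0, n, m, byrow = TRUE) + U %*% t(G)
  Y <- matrix(stats::rpois(n * m, exp(eta)), n, m)
  list(Y = Y, eta = eta, U = U, G = G, b0 = b0)
}
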