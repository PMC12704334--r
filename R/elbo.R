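#' Expected log-likelihood of one cell under a Gaussian variational density
#'
#' With \eqn{\eta \sim N(\tilde\eta, v)}, method \code{"VA"} returns the
#' exact expectation \eqn{E_q[\log f(y \mid \eta)]} for the families with a
#' closed form: gaussian/identity, poisson/log
#' (\eqn{y\tilde\eta - e^{\tilde\eta + v/2} - \log y!}), and
#' bernoulli/probit (a closed-form bound from the latent-normal augmentation,
#' \eqn{\log\Phi((2y-1)\tilde\eta) - v/2}, exact at \eqn{v = 0}).
#' Method \code{"EVA"} applies the second-order expansion
#' \eqn{\log f(y\mid\tilde\eta) + \frac{1}{2} v \cdot
#' \partial^2_\eta \log f(y\mid\tilde\eta)} and works for every family.
#' Both reduce to the log-density at \eqn{v = 0}.
#'
#' @param family an [lo_family()].
#' @param y observations (vector/matrix).
#' @param eta_mean variational mean of the linear predictor.
#' @param eta_var variational variance (nonnegative), conformable.
#' @param method \code{"VA"} or \code{"EVA"}.
#' @param aux auxiliary parameter list.
#' @return expected log-likelihood values with the shape of \code{y}.
#' @export
expected_loglik <- function(family, y, eta_mean, eta_var, method = c("VA", "EVA"),
                            aux = list()) {
  method <- match.arg(method)
  if (any(eta_var < 0)) stop("variational variances must be nonnegative")
  if (method == "VA") {
    if (!family$closed_va)
      stop("no closed-form VA for family '", family$name, "' with link '",
           family$link, "'; use method = \"EVA\"")
    phi <- expand_aux(aux$phi, y)
    switch(paste(family$name, family$link),
      "gaussian identity" =
        -0.5 * log(2 * pi * phi) - ((y - eta_mean)^2 + eta_var) / (2 * phi),
      "poisson log" =
        y * eta_mean - exp(eta_mean + eta_var / 2) - lgamma(y + 1),
      "bernoulli probit" =
        stats::pnorm((2 * y - 1) * eta_mean, log.p = TRUE) - eta_var / 2)
  } else {
    log_density(family, y, eta_mean, aux) +
      0.5 * eta_var * eva_curvature(family, y, eta_mean, aux)
  }
}

# derivatives of expected_loglik wrt (eta_mean, eta_var); EVA uses analytic
# dlogf plus a central difference on the curvature
expected_loglik_grad <- function(family, y, eta_mean, eta_var, method, aux) {
  if (method == "VA") {
    phi <- expand_aux(aux$phi, y)
    switch(paste(family$name, family$link),
      "gaussian identity" = list(deta = (y - eta_mean) / phi,
                                 dv = -1 / (2 * phi) + 0 * y),
      "poisson log" = {
        W <- exp(eta_mean + eta_var / 2)
        list(deta = y - W, dv = -W / 2)
      },
      "bernoulli probit" = {
        s <- 2 * y - 1
        lam <- exp(stats::dnorm(s * eta_mean, log = TRUE) -
                     stats::pnorm(s * eta_mean, log.p = TRUE))
        list(deta = s * lam, dv = -0.5 + 0 * y)
      })
  } else {
    h <- eva_curvature(family, y, eta_mean, aux)
    step <- 1e-5
    dh <- (eva_curvature(family, y, eta_mean + step, aux) -
             eva_curvature(family, y, eta_mean - step, aux)) / (2 * step)
    list(deta = dlog_density_deta(family, y, eta_mean, aux) +
           0.5 * eta_var * dh,
         dv = h / 2)
  }
}

#' Kullback-Leibler divergence between two zero-prior Gaussians
#'
#' \eqn{KL(N(m, A) \,\|\, N(0, \Sigma)) = \frac{1}{2}[\mathrm{tr}(\Sigma^{-1}A)
#' + m^\top \Sigma^{-1} m - \dim - \log\det A + \log\det \Sigma]}; nonnegative,
#' and zero iff \eqn{m = 0, A = \Sigma}.
#'
#' @param mean variational mean vector \code{m}.
#' @param cov variational covariance \code{A} (matrix, or vector of diagonal
#'   entries).
#' @param prior_cov prior covariance \eqn{\Sigma} (matrix or diagonal vector).
#' @return a nonnegative scalar.
#' @export
kl_gaussian <- function(mean, cov, prior_cov) {
  d <- length(mean)
  if (!is.matrix(cov)) cov <- diag(cov, d)
  if (!is.matrix(prior_cov)) prior_cov <- diag(prior_cov, d)
  ch_p <- tryCatch(chol(prior_cov), error = function(e)
    stop("prior covariance is not positive definite"))
  ch_a <- tryCatch(chol(cov), error = function(e)
    stop("variational covariance is not positive definite"))
  Sinv <- chol2inv(ch_p)
  0.5 * (sum(Sinv * cov) + sum(mean * (Sinv %*% mean)) - d -
           2 * sum(log(diag(ch_a))) + 2 * sum(log(diag(ch_p))))
}

# KL with precomputed prior precision and log-determinant, diagonal q cov
kl_gaussian_diagq <- function(mean, avar, Q, logdet_prior) {
  0.5 * (sum(diag(Q) * avar) + sum(mean * (Q %*% mean)) - length(mean) -
           sum(log(avar)) + logdet_prior)
}

#' Evidence lower bound of a latent-variable community model
#'
#' Sums the expected log-likelihood over observed cells (missing cells drop
#' out) and subtracts the Gaussian KL divergence of every latent block from
#' its prior. This is the objective maximized by [lo_fit()].
#'
#' @param spec an [lo_model_spec()].
#' @param params an [lo_parameter_set()] (or plain list with the same
#'   fields).
#' @param vstate variational state, see [lo_fit()]; a list with means and
#'   covariance factors per latent block.
#' @param data an [lo_dataset()].
#' @param method \code{"VA"} or \code{"EVA"}; defaults to VA when the family
#'   has a closed form.
#' @return the scalar lower bound.
#' @export
elbo <- function(spec, params, vstate, data, method = NULL) {
  model <- build_model(spec, data)
  if (is.null(method)) method <- default_method(spec$family)
  st <- list(params = params, vstate = vstate)
  elbo_value(model, st, method)
}

default_method <- function(family) if (family$closed_va) "VA" else "EVA"
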