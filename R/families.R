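#' Response family for a latent-variable community model
#'
#' Constructs a family object describing the conditional distribution of the
#' response given the linear predictor. Families cover the data types common
#' in community ecology: counts (\code{poisson}, \code{negbin}), zero-inflated
#' counts (\code{zip}, \code{zinb}), presence-absence (\code{bernoulli} with
#' logit or probit link), continuous responses (\code{gaussian}), and percent
#' cover on \code{[0,1]} (\code{beta}, \code{hurdle_beta}, \code{ordered_beta},
#' all with logit link).
#'
#' Auxiliary parameters by family: \code{phi} is the residual variance for
#' \code{gaussian}, the overdispersion for \code{negbin}/\code{zinb} with
#' variance \eqn{\mu + \phi \mu^2} (so \eqn{\phi \to 0} recovers the Poisson),
#' and the beta precision for the cover families; \code{pi} is the
#' zero-inflation probability; \code{zeta1}/\code{zeta2} are the ordered-beta
#' cutoffs (\code{zeta1 < zeta2}).
#'
#' @param name family name, one of \code{"gaussian"}, \code{"poisson"},
#'   \code{"negbin"}, \code{"zip"}, \code{"zinb"}, \code{"bernoulli"},
#'   \code{"beta"}, \code{"hurdle_beta"}, \code{"ordered_beta"}.
#' @param link link function; defaults to the canonical choice for the family
#'   (identity, log, or logit). \code{bernoulli} additionally accepts
#'   \code{"probit"}.
#' @return an object of class \code{"lo_family"}.
#' @export
lo_family <- function(name, link = NULL) {
  name <- match.arg(name, c("gaussian", "poisson", "negbin", "zip", "zinb",
                            "bernoulli", "beta", "hurdle_beta", "ordered_beta"))
  default_link <- switch(name,
    gaussian = "identity",
    poisson = , negbin = , zip = , zinb = "log",
    bernoulli = "logit",
    beta = , hurdle_beta = , ordered_beta = "logit")
  if (is.null(link)) link <- default_link
  ok <- switch(name,
    gaussian = "identity",
    poisson = , negbin = , zip = , zinb = "log",
    bernoulli = c("logit", "probit"),
    beta = , hurdle_beta = , ordered_beta = "logit")
  if (!link %in% ok)
    stop(sprintf("family '%s' does not support link '%s'", name, link))
  aux <- switch(name,
    gaussian = "phi",
    poisson = character(0),
    negbin = "phi",
    zip = "pi",
    zinb = c("phi", "pi"),
    bernoulli = character(0),
    beta = "phi",
    hurdle_beta = "phi",
    ordered_beta = c("phi", "zeta1", "zeta2"))
  closed_va <- (name == "gaussian" && link == "identity") ||
    (name == "poisson") || (name == "bernoulli" && link == "probit")
  structure(list(name = name, link = link, aux = aux, closed_va = closed_va),
            class = "lo_family")
}

#' @export
print.lo_family <- function(x, ...) {
  cat(sprintf("<lo_family> %s (%s link)", x$name, x$link))
  if (length(x$aux)) cat("; aux:", paste(x$aux, collapse = ", "))
  cat("\n")
  invisible(x)
}

# expand an auxiliary parameter to the shape of y: scalars recycle; vectors of
# length ncol(y) are per-species; matrices pass through
expand_aux <- function(a, y) {
  if (is.null(a)) return(NULL)
  if (is.matrix(y)) {
    if (is.matrix(a)) return(a)
    if (length(a) == 1L) return(matrix(a, nrow(y), ncol(y)))
    if (length(a) == ncol(y))
      return(matrix(a, nrow(y), ncol(y), byrow = TRUE))
    stop("auxiliary parameter has length ", length(a),
         " but the response has ", ncol(y), " columns")
  }
  rep_len(a, length(y))
}

mean_from_link <- function(link, eta) {
  switch(link,
    identity = eta,
    log = exp(eta),
    logit = stats::plogis(eta),
    probit = stats::pnorm(eta),
    stop("unknown link ", link))
}

check_support <- function(family, y) {
  yv <- y[is.finite(y)]
  bad <- switch(family$name,
    gaussian = FALSE,
    poisson = , negbin = , zip = , zinb = any(yv < 0 | yv != round(yv)),
    bernoulli = any(!yv %in% c(0, 1)),
    beta = any(yv <= 0 | yv >= 1),
    hurdle_beta = any(yv < 0 | yv >= 1),
    ordered_beta = any(yv < 0 | yv > 1))
  if (bad)
    stop(sprintf("response value outside the support of family '%s'",
                 family$name))
  invisible(TRUE)
}

#' Log-density of a response family
#'
#' Evaluates the log conditional density (or probability mass) of each
#' observation given its linear predictor. Vectorized: \code{y} and \code{eta}
#' may be matrices; per-species auxiliary parameters recycle across rows.
#'
#' Zero-inflated families use the mixture mass function
#' \eqn{P(0) = \pi + (1-\pi) p(0)} and \eqn{P(c) = (1-\pi) p(c)} for
#' \eqn{c \ge 1}, with a Poisson or negative binomial base \eqn{p}.
#'
#' @param family an [lo_family()] object.
#' @param y observations (vector or matrix).
#' @param eta linear predictor, conformable with \code{y}.
#' @param aux named list of auxiliary parameters (see [lo_family()]).
#' @return log-density values with the shape of \code{y}.
#' @export
log_density <- function(family, y, eta, aux = list()) {
  check_support(family, y)
  phi <- expand_aux(aux$phi, y)
  pi0 <- expand_aux(aux$pi, y)
  out <- switch(family$name,
    gaussian = stats::dnorm(y, eta, sqrt(phi), log = TRUE),
    poisson = stats::dpois(y, exp(eta), log = TRUE),
    negbin = stats::dnbinom(y, size = 1 / phi, mu = exp(eta), log = TRUE),
    zip = zi_log_density(y, eta, pi0, phi = NULL, base = "poisson"),
    zinb = zi_log_density(y, eta, pi0, phi = phi, base = "negbin"),
    bernoulli = {
      p <- mean_from_link(family$link, eta)
      ifelse(y > 0.5, log(p), log1p(-p))
    },
    beta = beta_logit_log_density(y, eta, phi),
    hurdle_beta = stop(
      "hurdle_beta carries two linear predictors; use hurdle_beta_log_density()"),
    ordered_beta = ordered_beta_log_density(
      y, eta, expand_aux(aux$zeta1, y), expand_aux(aux$zeta2, y), phi))
  out
}

zi_log_density <- function(y, eta, pi0, phi, base) {
  mu <- exp(eta)
  if (base == "poisson") {
    lp <- stats::dpois(y, mu, log = TRUE)
    lp0 <- -mu
  } else {
    lp <- stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE)
    lp0 <- (1 / phi) * (log(1 / phi) - log(1 / phi + mu))
  }
  out <- log1p(-pi0) + lp
  at0 <- y == 0
  out[at0] <- log(pi0[at0] + exp(log1p(-pi0[at0]) + lp0[at0]))
  out
}

beta_logit_log_density <- function(y, eta, phi) {
  mu <- stats::plogis(eta)
  stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)
}

#' Ordered beta log-density
#'
#' Mixed discrete-continuous distribution on \code{[0,1]} for sparse percent
#' cover: point masses at 0 and 1 controlled by two ordered cutoffs on the
#' same linear predictor as the continuous part,
#' \deqn{P(y=0) = 1 - \mathrm{logistic}(\eta - \zeta_1), \quad
#'       P(y=1) = \mathrm{logistic}(\eta - \zeta_2),}
#' and for \eqn{y \in (0,1)} the density
#' \eqn{[\mathrm{logistic}(\eta-\zeta_1) - \mathrm{logistic}(\eta-\zeta_2)]}
#' times a beta density with mean \eqn{\mathrm{logistic}(\eta)} and precision
#' \eqn{\phi}.
#'
#' @param y values in \code{[0,1]}.
#' @param eta linear predictor.
#' @param zeta1,zeta2 ordered cutoffs, \code{zeta1 < zeta2}.
#' @param phi beta precision, positive.
#' @return log-density values with the shape of \code{y}.
#' @export
ordered_beta_log_density <- function(y, eta, zeta1, zeta2, phi) {
  if (any(zeta1 >= zeta2))
    stop("ordered beta cutoffs must satisfy zeta1 < zeta2")
  if (any(phi <= 0)) stop("beta precision phi must be positive")
  if (any(y < 0 | y > 1)) stop("ordered beta response must lie in [0, 1]")
  y <- y + 0 * eta  # broadcast
  s1 <- stats::plogis(eta - zeta1)
  s2 <- stats::plogis(eta - zeta2)
  out <- log(s1 - s2) + beta_logit_log_density(pmin(pmax(y, 1e-12), 1 - 1e-12),
                                               eta, phi)
  out[y == 0] <- log1p(-s1)[y == 0]
  out[y == 1] <- log(s2)[y == 1]
  out
}

#' Hurdle beta log-density
#'
#' Two-part model for percent cover with exact zeros: a Bernoulli-logit
#' presence process with predictor \code{eta_pres}, and conditional on
#' presence a beta density with mean \code{logistic(eta_pos)} and precision
#' \code{phi}. The hurdle is the sole source of zeros; exact ones are not
#' supported in this two-part variant.
#'
#' @param y values in \code{[0, 1)}.
#' @param eta_pres linear predictor of the presence part.
#' @param eta_pos linear predictor of the positive-cover part.
#' @param phi beta precision, positive.
#' @return log-density values with the shape of \code{y}.
#' @export
hurdle_beta_log_density <- function(y, eta_pres, eta_pos, phi) {
  if (any(phi <= 0)) stop("beta precision phi must be positive")
  if (any(y < 0 | y >= 1))
    stop("hurdle beta (two-part) supports y in [0, 1); exact ones are not allowed")
  y <- y + 0 * eta_pres
  out <- stats::plogis(eta_pres, log.p = TRUE) +
    beta_logit_log_density(pmax(y, 1e-12), eta_pos, phi)
  at0 <- y == 0
  lp0 <- stats::plogis(-eta_pres, log.p = TRUE)
  out[at0] <- (lp0 + 0 * out)[at0]
  out
}

# first derivative of the log-density with respect to eta (analytic),
# used by the EVA gradient
dlog_density_deta <- function(family, y, eta, aux = list()) {
  phi <- expand_aux(aux$phi, y)
  pi0 <- expand_aux(aux$pi, y)
  switch(family$name,
    gaussian = (y - eta) / phi,
    poisson = y - exp(eta),
    negbin = {
      r <- 1 / phi; mu <- exp(eta)
      y - (y + r) * mu / (r + mu)
    },
    bernoulli = {
      if (family$link == "logit") y - stats::plogis(eta)
      else {
        s <- 2 * y - 1
        s * exp(stats::dnorm(s * eta, log = TRUE) -
                  stats::pnorm(s * eta, log.p = TRUE))
      }
    },
    zip = {
      mu <- exp(eta)
      d <- y - mu
      at0 <- y == 0
      w <- (1 - pi0) * exp(-mu)
      A <- pi0 + w
      d[at0] <- (-mu * w / A)[at0]
      d
    },
    zinb = {
      r <- 1 / phi; mu <- exp(eta)
      d <- y - (y + r) * mu / (r + mu)
      at0 <- y == 0
      w <- (1 - pi0) * exp(r * (log(r) - log(r + mu)))
      A <- pi0 + w
      gp <- -r * mu / (r + mu)
      d[at0] <- (w * gp / A)[at0]
      d
    },
    beta = beta_dlog_deta(y, eta, phi),
    ordered_beta = {
      z1 <- expand_aux(aux$zeta1, y); z2 <- expand_aux(aux$zeta2, y)
      s1 <- stats::plogis(eta - z1); s2 <- stats::plogis(eta - z2)
      d1 <- s1 * (1 - s1); d2 <- s2 * (1 - s2)
      yc <- pmin(pmax(y, 1e-12), 1 - 1e-12)
      d <- (d1 - d2) / (s1 - s2) + beta_dlog_deta(yc, eta, phi)
      d[y == 0] <- (-s1)[y == 0]
      d[y == 1] <- (1 - s2)[y == 1]
      d
    },
    stop("no analytic derivative for family ", family$name))
}

beta_dlog_deta <- function(y, eta, phi) {
  mu <- stats::plogis(eta)
  dmu <- phi * (-digamma(mu * phi) + digamma((1 - mu) * phi) +
                  log(y) - log1p(-y))
  dmu * mu * (1 - mu)
}

beta_d2log_deta2 <- function(y, eta, phi) {
  mu <- stats::plogis(eta)
  dmu <- phi * (-digamma(mu * phi) + digamma((1 - mu) * phi) +
                  log(y) - log1p(-y))
  d2mu <- -phi^2 * (trigamma(mu * phi) + trigamma((1 - mu) * phi))
  mp <- mu * (1 - mu)
  d2mu * mp^2 + dmu * mp * (1 - 2 * mu)
}

#' Second derivative of the log-density in the linear predictor
#'
#' Returns \eqn{\partial^2 \log f(y \mid \eta) / \partial \eta^2}, the
#' curvature used by the extended variational approximation, which evaluates
#' the expected log-density as
#' \eqn{\log f(y\mid\tilde\eta) + \frac{1}{2} v \cdot \mathrm{curvature}}.
#' For mixed discrete-continuous families the branch containing the observed
#' value is differentiated.
#'
#' @inheritParams log_density
#' @return curvature values with the shape of \code{y}.
#' @export
eva_curvature <- function(family, y, eta, aux = list()) {
  phi <- expand_aux(aux$phi, y)
  pi0 <- expand_aux(aux$pi, y)
  switch(family$name,
    gaussian = -1 / phi + 0 * eta + 0 * y,
    poisson = -exp(eta) + 0 * y,
    negbin = {
      r <- 1 / phi; mu <- exp(eta)
      -(y + r) * r * mu / (r + mu)^2
    },
    bernoulli = {
      if (family$link == "logit") {
        p <- stats::plogis(eta)
        -p * (1 - p) + 0 * y
      } else {
        s <- 2 * y - 1
        lam <- exp(stats::dnorm(s * eta, log = TRUE) -
                     stats::pnorm(s * eta, log.p = TRUE))
        -lam * (s * eta + lam)
      }
    },
    zip = {
      mu <- exp(eta)
      h <- -mu
      at0 <- y == 0
      w <- (1 - pi0) * exp(-mu)
      A <- pi0 + w
      h0 <- -mu * w / A + mu^2 * w / A - (mu * w / A)^2
      h[at0] <- h0[at0]
      h
    },
    zinb = {
      r <- 1 / phi; mu <- exp(eta)
      h <- -(y + r) * r * mu / (r + mu)^2
      at0 <- y == 0
      w <- (1 - pi0) * exp(r * (log(r) - log(r + mu)))
      A <- pi0 + w
      gp <- -r * mu / (r + mu)
      gpp <- -r^2 * mu / (r + mu)^2
      h0 <- w * (gpp + gp^2) / A - (w * gp / A)^2
      h[at0] <- h0[at0]
      h
    },
    beta = beta_d2log_deta2(y, eta, phi),
    ordered_beta = {
      z1 <- expand_aux(aux$zeta1, y); z2 <- expand_aux(aux$zeta2, y)
      s1 <- stats::plogis(eta - z1); s2 <- stats::plogis(eta - z2)
      d1 <- s1 * (1 - s1); d2 <- s2 * (1 - s2)
      dd1 <- d1 * (1 - 2 * s1); dd2 <- d2 * (1 - 2 * s2)
      S <- s1 - s2
      yc <- pmin(pmax(y, 1e-12), 1 - 1e-12)
      h <- (dd1 - dd2) / S - ((d1 - d2) / S)^2 + beta_d2log_deta2(yc, eta, phi)
      h[y == 0] <- (-d1)[y == 0]
      h[y == 1] <- (-d2)[y == 1]
      h
    },
    hurdle_beta = stop("use the expanded two-part representation for hurdle_beta"))
}

#' Simulate responses from a family
#'
#' Draws one response per cell of \code{eta} with the exact generative
#' structure of [log_density()]; reproducible given \code{seed}.
#'
#' @inheritParams log_density
#' @param seed integer seed; if \code{NULL} the current RNG state is used.
#' @return simulated responses with the shape of \code{eta}.
#' @export
simulate_response <- function(family, eta, aux = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(eta)
  phi <- expand_aux(aux$phi, eta)
  pi0 <- expand_aux(aux$pi, eta)
  out <- switch(family$name,
    gaussian = stats::rnorm(n, eta, sqrt(phi)),
    poisson = stats::rpois(n, exp(eta)),
    negbin = stats::rnbinom(n, size = 1 / phi, mu = exp(eta)),
    zip = ifelse(stats::runif(n) < pi0, 0, stats::rpois(n, exp(eta))),
    zinb = ifelse(stats::runif(n) < pi0, 0,
                  stats::rnbinom(n, size = 1 / phi, mu = exp(eta))),
    bernoulli = as.numeric(stats::runif(n) < mean_from_link(family$link, eta)),
    beta = {
      mu <- stats::plogis(eta)
      stats::rbeta(n, mu * phi, (1 - mu) * phi)
    },
    ordered_beta = {
      z1 <- expand_aux(aux$zeta1, eta); z2 <- expand_aux(aux$zeta2, eta)
      p0 <- 1 - stats::plogis(eta - z1)
      p1 <- stats::plogis(eta - z2)
      u <- stats::runif(n)
      mu <- stats::plogis(eta)
      yb <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
      yb <- pmin(pmax(yb, 1e-12), 1 - 1e-12)
      ifelse(u < p0, 0, ifelse(u > 1 - p1, 1, yb))
    },
    hurdle_beta = stop(
      "simulate hurdle_beta via simulate_hurdle_beta() (two predictors)"))
  if (is.matrix(eta)) out <- matrix(out, nrow(eta), ncol(eta),
                                    dimnames = dimnames(eta))
  out
}

#' @rdname simulate_response
#' @param eta_pres,eta_pos the two hurdle-beta linear predictors.
#' @export
simulate_hurdle_beta <- function(eta_pres, eta_pos, phi, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(eta_pres)
  phi <- expand_aux(phi, eta_pres)
  pres <- stats::runif(n) < stats::plogis(eta_pres)
  mu <- stats::plogis(eta_pos)
  yb <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
  yb <- pmin(pmax(yb, 1e-12), 1 - 1e-9)
  out <- ifelse(pres, yb, 0)
  if (is.matrix(eta_pres)) out <- matrix(out, nrow(eta_pres), ncol(eta_pres))
  out
}

# CDF F(y) and left limit F(y-) per family; both with the shape of y
family_cdf <- function(family, y, eta, aux = list()) {
  phi <- expand_aux(aux$phi, y)
  pi0 <- expand_aux(aux$pi, y)
  switch(family$name,
    gaussian = {
      F <- stats::pnorm(y, eta, sqrt(phi)); list(F = F, Fm = F)
    },
    beta = {
      mu <- stats::plogis(eta)
      F <- stats::pbeta(y, mu * phi, (1 - mu) * phi)
      list(F = F, Fm = F)
    },
    poisson = list(F = stats::ppois(y, exp(eta)),
                   Fm = stats::ppois(y - 1, exp(eta))),
    negbin = list(F = stats::pnbinom(y, size = 1 / phi, mu = exp(eta)),
                  Fm = stats::pnbinom(y - 1, size = 1 / phi, mu = exp(eta))),
    zip = {
      Fb <- stats::ppois(y, exp(eta)); Fbm <- stats::ppois(y - 1, exp(eta))
      list(F = pi0 + (1 - pi0) * Fb,
           Fm = ifelse(y == 0, 0, pi0 + (1 - pi0) * Fbm))
    },
    zinb = {
      Fb <- stats::pnbinom(y, size = 1 / phi, mu = exp(eta))
      Fbm <- stats::pnbinom(y - 1, size = 1 / phi, mu = exp(eta))
      list(F = pi0 + (1 - pi0) * Fb,
           Fm = ifelse(y == 0, 0, pi0 + (1 - pi0) * Fbm))
    },
    bernoulli = {
      p <- mean_from_link(family$link, eta)
      list(F = ifelse(y > 0.5, 1, 1 - p),
           Fm = ifelse(y > 0.5, 1 - p, 0))
    },
    ordered_beta = {
      z1 <- expand_aux(aux$zeta1, y); z2 <- expand_aux(aux$zeta2, y)
      p0 <- 1 - stats::plogis(eta - z1)
      p1 <- stats::plogis(eta - z2)
      pc <- pmax(1 - p0 - p1, 0)
      mu <- stats::plogis(eta)
      yc <- pmin(pmax(y, 1e-12), 1 - 1e-12)
      Fc <- stats::pbeta(yc, mu * phi, (1 - mu) * phi)
      F <- p0 + pc * Fc
      Fm <- F
      F[y == 0] <- p0[y == 0]
      Fm[y == 0] <- 0
      F[y == 1] <- 1
      Fm[y == 1] <- (p0 + pc)[y == 1]
      list(F = F, Fm = Fm)
    },
    stop("no cdf for family ", family$name))
}

#' Randomized quantile (Dunn-Smyth) residuals
#'
#' Computes \eqn{\Phi^{-1}(u)} with \eqn{u} uniform on
#' \eqn{(F(y^-), F(y)]} for discrete or mixed families and \eqn{u = F(y)}
#' for continuous ones. Under a correctly specified model the residuals are
#' standard normal, including for discrete responses.
#'
#' @inheritParams log_density
#' @param seed integer seed for the randomization; \code{NULL} uses the
#'   current RNG state.
#' @return residuals with the shape of \code{y}.
#' @export
quantile_residual <- function(family, y, eta, aux = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cf <- family_cdf(family, y, eta, aux)
  u <- cf$Fm + stats::runif(length(y)) * (cf$F - cf$Fm)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  r <- stats::qnorm(u)
  if (is.matrix(y)) r <- matrix(r, nrow(y), ncol(y), dimnames = dimnames(y))
  r
}
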