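#' Information criteria from a maximized log-likelihood
#'
#' \eqn{AIC = -2\hat\ell + 2\,df}; \eqn{BIC = -2\hat\ell + df \log N};
#' \eqn{AICc = AIC + 2 df (df+1)/(N - df - 1)}, where \eqn{N} is the number
#' of observed response cells (\eqn{n \cdot m} without missingness) and
#' \eqn{\hat\ell} the maximized variational lower bound.
#'
#' @param logL maximized log-likelihood (lower bound) value.
#' @param df number of freely estimated parameters.
#' @param n_obs number of observed response cells.
#' @return a data frame with \code{AIC}, \code{AICc}, \code{BIC},
#'   \code{logL}, \code{df}, \code{n_obs}.
#' @export
ic_from_loglik <- function(logL, df, n_obs) {
  aic <- -2 * logL + 2 * df
  bic <- -2 * logL + df * log(n_obs)
  denom <- n_obs - df - 1
  aicc <- if (denom <= 0) {
    warning("AICc undefined: n_obs - df - 1 <= 0")
    NA_real_
  } else aic + 2 * df * (df + 1) / denom
  data.frame(AIC = aic, AICc = aicc, BIC = bic, logL = logL, df = df,
             n_obs = n_obs)
}

#' Information criteria of a fitted model
#'
#' @param fit an [lo_fit()] object.
#' @return see [ic_from_loglik()].
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "lo_fit"))
  ic_from_loglik(fit$objective, fit$df, fit$n_obs)
}

#' @export
AIC.lo_fit <- function(object, ..., k = 2) {
  -2 * object$objective + k * object$df
}

#' @export
BIC.lo_fit <- function(object, ...) {
  -2 * object$objective + object$df * log(object$n_obs)
}

# names and positions of the fixed-effect coordinates in the packed vector
fixed_parameter_index <- function(model) {
  blocks <- model_blocks(model)
  keep <- c("beta0", "Beta", "beta_common", "B_fourth", "B_canon",
            "row_fixed")
  idx <- integer(0); nms <- character(0); pos <- 0L
  spn <- colnames(model$Y)
  for (bl in blocks) {
    if (bl$name %in% keep) {
      idx <- c(idx, pos + seq_len(bl$len))
      nm <- switch(bl$name,
        beta0 = if (bl$len == 1L) "beta0" else paste0("beta0:", spn),
        Beta = {
          fixed_cols <- setdiff(seq_len(model$k),
                                if (is.null(model$slopes)) integer(0)
                                else model$slopes$cols)
          cn <- colnames(model$design$X)[fixed_cols]
          as.vector(outer(spn, cn, function(a, b) paste0(b, ":", a)))
        },
        beta_common = colnames(model$design$X),
        B_fourth = as.vector(outer(colnames(model$design$X),
                                   colnames(model$design$T), paste, sep = ":")),
        B_canon = {
          lab <- as.vector(outer(colnames(model$design$X_lv),
                                 paste0("LV", seq_len(model$dc)),
                                 paste, sep = ":"))
          keep_free <- as.vector(
            (row(matrix(0, model$k_lv, model$dc)) <= model$dc &
               row(matrix(0, model$k_lv, model$dc)) >
                 col(matrix(0, model$k_lv, model$dc))) |
              row(matrix(0, model$k_lv, model$dc)) > model$dc)
          # match bcanon packing order: leading strictly-lower, then rest
          M <- matrix(lab, model$k_lv, model$dc)
          lead <- row(M) <= model$dc & row(M) > col(M)
          rest <- row(M) > model$dc
          c(M[lead], M[rest])
        },
        row_fixed = colnames(model$design$row_fixed))
      nms <- c(nms, nm)
    }
    pos <- pos + bl$len
  }
  list(idx = idx, names = nms)
}

#' Wald estimates, standard errors and intervals for fixed parameters
#'
#' Computes the observed information of the joint objective (fixed
#' parameters plus variational parameters) at the optimum by finite
#' differences of the analytic gradient, inverts it, and extracts the
#' fixed-parameter block. Intervals are \eqn{\hat\theta \pm
#' z_{(1+level)/2}\,SE}. A singular information matrix falls back to a
#' pseudo-inverse with the affected rows flagged.
#'
#' @param fit an [lo_fit()] object.
#' @param level coverage level, default 0.95.
#' @return data frame with \code{term}, \code{estimate}, \code{SE},
#'   \code{z}, \code{p}, \code{lower}, \code{upper}, \code{flagged}.
#' @export
wald_intervals <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "lo_fit"))
  model <- fit$model
  th <- fit$theta
  gr <- function(t) -elbo_gradient(model, state_unpack(model, t), fit$method)
  H <- stats::optimHess(th, fn = function(t)
    -elbo_value(model, state_unpack(model, t), fit$method), gr = gr)
  H <- (H + t(H)) / 2
  fx <- fixed_parameter_index(model)
  flagged <- FALSE
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V)) {
    warning("singular observed information; using a pseudo-inverse")
    flagged <- TRUE
    V <- MASS::ginv(H)
  }
  se <- sqrt(pmax(diag(V)[fx$idx], 0))
  est <- th[fx$idx]
  z <- est / se
  zq <- stats::qnorm((1 + level) / 2)
  out <- data.frame(term = fx$names, estimate = est, SE = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)),
                    lower = est - zq * se, upper = est + zq * se,
                    flagged = flagged | !is.finite(se) | se == 0,
                    row.names = NULL)
  attr(out, "level") <- level
  out
}

#' Predict linear predictors or response means
#'
#' Latent terms enter at their predicted (variational mean) values for
#' training sites; sites not seen in training get zero latent contributions.
#'
#' @param object an [lo_fit()].
#' @param newdata optional data frame of covariates (with design columns as
#'   needed); default reuses the training data.
#' @param type \code{"link"} for \eqn{\hat\eta} or \code{"response"} for the
#'   family mean.
#' @param ... unused.
#' @return an n_new x m matrix.
#' @export
predict.lo_fit <- function(object, newdata = NULL,
                           type = c("link", "response"), ...) {
  type <- match.arg(type)
  model <- object$model
  st <- list(params = object$params, vstate = object$vstate)
  if (is.null(newdata)) {
    eta <- eta_moments(model, st)$eta
  } else {
    newdata <- as.data.frame(newdata)
    sp <- object$spec
    need <- unique(c(all.vars(sp$species_formula), all.vars(sp$lv_formula)))
    miss <- setdiff(need, colnames(newdata))
    if (length(miss))
      stop("newdata is missing covariate column(s): ",
           paste(miss, collapse = ", "))
    n_new <- nrow(newdata)
    m <- model$m
    p <- object$params
    b0 <- p$beta0
    eta <- matrix(if (length(b0) == 1L) b0 else rep(b0, each = n_new),
                  n_new, m)
    known <- match(rownames(newdata), rownames(object$data$Y))
    if (!is.null(sp$species_formula)) {
      Xn <- stats::model.matrix(sp$species_formula, data = newdata)
      Xn <- Xn[, colnames(Xn) != "(Intercept)", drop = FALSE]
      if (sp$fourth_corner) {
        Beta <- matrix(p$beta_common, m, model$k, byrow = TRUE)
        if (model$q > 0) Beta <- Beta + model$design$T %*% t(p$B_fourth)
        if (!is.null(object$vstate$b_mean))
          Beta[, model$slopes$cols] <- Beta[, model$slopes$cols] +
            object$vstate$b_mean
        eta <- eta + Xn %*% t(Beta)
      } else {
        B <- full_beta(model, p)
        if (!is.null(model$slopes))
          B[, model$slopes$cols] <- B[, model$slopes$cols] +
            object$vstate$b_mean
        eta <- eta + Xn %*% t(B)
      }
    }
    Gam <- full_gamma(model, p)
    if (model$dc > 0) {
      Xlvn <- stats::model.matrix(sp$lv_formula, data = newdata)
      Xlvn <- Xlvn[, colnames(Xlvn) != "(Intercept)", drop = FALSE]
      Uc <- Xlvn %*% b_canon_current(model, st)
      if (sp$num_lv_c > 0) {
        epsn <- matrix(0, n_new, model$dc)
        ok <- !is.na(known)
        if (any(ok)) epsn[ok, ] <- object$vstate$eps_mean[known[ok], ,
                                                          drop = FALSE]
        Uc <- Uc + epsn
      }
      eta <- eta + Uc %*% t(Gam[, seq_len(model$dc), drop = FALSE])
    }
    if (model$d0 > 0 && is.null(model$lv_struct)) {
      Un <- matrix(0, n_new, model$d0)
      ok <- !is.na(known)
      if (any(ok)) Un[ok, ] <- object$vstate$U_mean[known[ok], , drop = FALSE]
      eta <- eta + Un %*% t(Gam[, model$dc + seq_len(model$d0), drop = FALSE])
    }
  }
  if (type == "link") return(eta)
  fam <- object$spec$family
  mu <- mean_from_link(if (fam$name %in% c("zip", "zinb")) "log" else
    fam$link, eta)
  if (fam$name %in% c("zip", "zinb"))
    mu <- sweep(mu, 2, 1 - object$params$pi_zi, "*")
  mu
}

#' Randomized quantile residuals and normality summary for a fit
#'
#' Dunn-Smyth residuals per observed cell, at the fitted mean linear
#' predictors and auxiliary parameters. Standard normal under a correctly
#' specified model. The summary reports pooled mean/variance and a
#' per-species Kolmogorov-Smirnov statistic against N(0,1).
#'
#' @param fit an [lo_fit()].
#' @param seed integer seed for the residual randomization.
#' @return list with \code{residuals} (n x m, NA at unobserved cells) and
#'   \code{summary} (per-species data frame).
#' @export
residual_diagnostics <- function(fit, seed = 1L) {
  stopifnot(inherits(fit, "lo_fit"))
  model <- fit$model
  st <- list(params = fit$params, vstate = fit$vstate)
  eta <- eta_moments(model, st)$eta
  aux <- aux_for_model(model, fit$params)
  set.seed(seed)
  if (!model$hurdle) {
    r <- quantile_residual(model$fam, model$Y, eta, aux)
  } else {
    m0 <- model$m_obs
    Y0 <- fit$data$Y
    p_pres <- stats::plogis(eta[, seq_len(m0), drop = FALSE])
    eta_pos <- eta[, m0 + seq_len(m0), drop = FALSE]
    phi <- expand_aux(aux$phi, Y0)
    mu <- stats::plogis(eta_pos)
    Fb <- stats::pbeta(pmax(Y0, 1e-12), mu * phi, (1 - mu) * phi)
    F <- (1 - p_pres) + p_pres * Fb
    Fm <- F
    F[Y0 == 0] <- (1 - p_pres)[Y0 == 0]
    Fm[Y0 == 0] <- 0
    u <- Fm + stats::runif(length(Y0)) * (F - Fm)
    r <- matrix(stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12)),
                nrow(Y0), ncol(Y0))
  }
  obs_mask <- fit$data$observed_mask
  r[!obs_mask] <- NA
  ks <- vapply(seq_len(ncol(r)), function(j) {
    x <- r[!is.na(r[, j]), j]
    suppressWarnings(stats::ks.test(x, "pnorm")$statistic)
  }, 0)
  summ <- data.frame(species = colnames(fit$data$Y),
                     mean = colMeans(r, na.rm = TRUE),
                     var = apply(r, 2, stats::var, na.rm = TRUE),
                     ks = ks, row.names = NULL)
  list(residuals = r, summary = summ,
       pooled = c(mean = mean(r, na.rm = TRUE),
                  var = stats::var(as.vector(r), na.rm = TRUE)))
}

#' Variance partitioning across model components
#'
#' For each species, the variance over sites of every component's
#' contribution to the linear predictor (covariates at their estimates,
#' random terms at their predicted values), normalized to proportions.
#'
#' @param fit an [lo_fit()].
#' @param group_names optional replacement names for the components.
#' @return object of class \code{"lo_varpart"}: list with
#'   \code{proportions} (m x C matrix, rows sum to 1) and \code{raw}.
#' @export
variance_partitioning <- function(fit, group_names = NULL) {
  stopifnot(inherits(fit, "lo_fit"))
  model <- fit$model
  st <- list(params = fit$params, vstate = fit$vstate)
  p <- fit$params; v <- fit$vstate
  des <- model$design
  n <- model$n; m <- model$m
  comps <- list()
  if (model$k > 0) {
    Beta <- if (model$spec$fourth_corner) {
      B <- matrix(p$beta_common, m, model$k, byrow = TRUE)
      if (model$q > 0) B <- B + des$T %*% t(p$B_fourth)
      B
    } else full_beta(model, p)
    if (!is.null(model$slopes) && !is.null(v$b_mean))
      Beta[, model$slopes$cols] <- Beta[, model$slopes$cols] + v$b_mean
    for (l in seq_len(model$k))
      comps[[colnames(des$X)[l]]] <- outer(des$X[, l], Beta[, l])
  }
  Gam <- full_gamma(model, p)
  st_mom <- eta_moments(model, st)
  if (!is.null(st_mom$U)) {
    for (r in seq_len(ncol(st_mom$U)))
      comps[[paste0("LV", r)]] <- outer(st_mom$U[, r], Gam[, r])
  }
  if (model$p_row > 0)
    comps[["row (fixed)"]] <-
      matrix(as.vector(des$row_fixed %*% p$row_fixed), n, m)
  for (g in seq_len(model$n_row_blocks))
    comps[[paste0("row ", des$row_random[[g]]$name)]] <-
      matrix(as.vector(des$row_random[[g]]$Z %*% v$row[[g]]$mean), n, m)
  if (length(comps) < 2)
    stop("variance partitioning needs at least two model components")
  V <- vapply(comps, function(M) apply(M, 2, stats::var), numeric(m))
  tot <- rowSums(V)
  degen <- tot <= 0
  if (any(degen)) {
    warning("species with zero total variance get uniform proportions: ",
            paste(colnames(fit$data$Y)[degen], collapse = ", "))
    V[degen, ] <- 1
    tot[degen] <- ncol(V)
  }
  P <- V / tot
  rownames(P) <- colnames(model$Y)
  if (!is.null(group_names)) {
    if (length(group_names) != ncol(P))
      stop("group_names must have length ", ncol(P))
    colnames(P) <- group_names
  }
  structure(list(proportions = P, raw = V), class = "lo_varpart")
}

#' @export
print.lo_varpart <- function(x, ...) {
  cat("<lo_varpart> mean proportion per component:\n")
  print(round(colMeans(x$proportions), 3))
  invisible(x)
}

#' @export
plot.lo_varpart <- function(x, ...) {
  graphics::barplot(t(x$proportions), col = grDevices::hcl.colors(
    ncol(x$proportions), "TealRose"), border = NA,
    legend.text = colnames(x$proportions), las = 2, ...)
  invisible(x)
}

#' Species correlations induced by random environmental effects
#'
#' The covariance between species of the environment-driven random part of
#' the linear predictor (random canonical coefficients or species random
#' slopes), evaluated over the empirical covariate distribution, returned
#' as a correlation matrix.
#'
#' @param fit an [lo_fit()] with \code{randomB != "none"} or species random
#'   slopes.
#' @return an m x m correlation matrix (symmetric PSD, unit diagonal).
#' @export
environment_correlations <- function(fit) {
  stopifnot(inherits(fit, "lo_fit"))
  model <- fit$model
  v <- fit$vstate
  R <- NULL
  if (model$dc > 0 && fit$spec$randomB != "none") {
    U <- model$design$X_lv %*% v$Bv_mean
    R <- U %*% t(full_gamma(model, fit$params)[, seq_len(model$dc),
                                               drop = FALSE])
  } else if (!is.null(model$slopes)) {
    R <- model$slopes$X_r %*% t(v$b_mean)
  } else {
    stop("no random environmental terms in this model")
  }
  Q <- stats::cov(R)
  sd <- sqrt(pmax(diag(Q), 1e-12))
  C <- Q / outer(sd, sd)
  diag(C) <- 1
  dimnames(C) <- list(colnames(model$Y), colnames(model$Y))
  C
}
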