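#' Ordination coordinates from a fitted model
#'
#' Extracts site scores and species loadings: variational means of
#' \eqn{u_i} for unconstrained fits, \eqn{B^\top x_i} for constrained fits,
#' and \eqn{B^\top x_i + \hat\epsilon_i} for concurrent fits. Coordinates
#' are rotated to the principal axes of the fitted latent contribution
#' (orthogonal rotation, so \eqn{\hat\eta} is unchanged), with the sign
#' convention that the largest-magnitude loading on each axis is positive.
#' For constrained/concurrent fits the rows of the canonical coefficient
#' matrix become biplot arrows; an arrow is flagged significant when the
#' Wald interval of both its rotated coordinates excludes zero.
#'
#' @param fit an [lo_fit()] with at least one latent dimension.
#' @param scaling \code{"sites"} (scores carry the singular values),
#'   \code{"species"}, or \code{"symmetric"}.
#' @param arrows_sig if \code{TRUE}, compute Wald intervals for the
#'   canonical coefficients to flag significant arrows (slower).
#' @param level coverage for the significance flags.
#' @return object of class \code{"lo_ordination"}: \code{site_scores}
#'   (n x d), \code{species_loadings} (m x d), \code{arrows} (k_lv x d or
#'   NULL), \code{rotation} (orthogonal d x d), \code{scaling}.
#' @export
ordination_coordinates <- function(fit, scaling = c("sites", "species",
                                                    "symmetric"),
                                   arrows_sig = FALSE, level = 0.95) {
  scaling <- match.arg(scaling)
  model <- fit$model
  d <- model$d
  if (d == 0) stop("the fit has no latent variables to ordinate")
  st <- list(params = fit$params, vstate = fit$vstate)
  S <- eta_moments(model, st)$U
  L <- full_gamma(model, fit$params)
  sv <- svd(S)
  R <- sv$v  # orthogonal principal-axis rotation
  Sr <- S %*% R
  Lr <- L %*% R
  # sign convention: largest |loading| positive per axis
  for (r in seq_len(d)) {
    s <- sign(Lr[which.max(abs(Lr[, r])), r])
    if (s < 0) { Lr[, r] <- -Lr[, r]; Sr[, r] <- -Sr[, r]; R[, r] <- -R[, r] }
  }
  if (scaling != "sites") {
    sdv <- apply(Sr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    if (scaling == "species") {
      Sr <- sweep(Sr, 2, sdv, "/"); Lr <- sweep(Lr, 2, sdv, "*")
    } else {
      Sr <- sweep(Sr, 2, sqrt(sdv), "/"); Lr <- sweep(Lr, 2, sqrt(sdv), "*")
    }
  }
  arrows <- NULL
  if (model$dc > 0) {
    B <- b_canon_current(model, st)
    Br <- B %*% R[seq_len(model$dc), seq_len(model$dc), drop = FALSE]
    # max-norm matching: longest arrow spans the score cloud
    len <- sqrt(rowSums(Br^2))
    if (max(len) > 0)
      Br <- Br * max(sqrt(rowSums(Sr[, seq_len(model$dc), drop = FALSE]^2))) /
        max(len)
    sig <- rep(NA, nrow(Br))
    if (arrows_sig && fit$spec$randomB == "none") {
      wt <- wald_intervals(fit, level = level)
      wb <- wt[grepl(":LV", wt$term), ]
      if (nrow(wb)) {
        M <- matrix(0, model$k_lv, model$dc)
        lead <- row(M) <= model$dc & row(M) > col(M)
        rest <- row(M) > model$dc
        excl <- matrix(NA, model$k_lv, model$dc)
        vals <- wb$lower > 0 | wb$upper < 0
        excl[lead] <- vals[seq_len(sum(lead))]
        excl[rest] <- vals[sum(lead) + seq_len(sum(rest))]
        sig <- apply(excl, 1, function(z) all(z[!is.na(z)]) && any(!is.na(z)))
      }
    }
    arrows <- cbind(Br, significant = sig)
    rownames(arrows) <- colnames(model$design$X_lv)
  }
  structure(list(site_scores = Sr, species_loadings = Lr, arrows = arrows,
                 rotation = R, scaling = scaling,
                 kind = if (fit$spec$num_lv_c > 0) "concurrent"
                 else if (fit$spec$num_RR > 0) "constrained"
                 else "unconstrained"),
            class = "lo_ordination")
}

#' @export
print.lo_ordination <- function(x, ...) {
  cat(sprintf("<lo_ordination> %s, %d sites x %d axes (%s scaling)\n",
              x$kind, nrow(x$site_scores), ncol(x$site_scores), x$scaling))
  invisible(x)
}

#' Ordination plot (sites, species, biplot arrows)
#'
#' @param x an \code{"lo_ordination"}.
#' @param species show species loadings.
#' @param arrows show canonical-coefficient arrows when present.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lo_ordination <- function(x, species = TRUE, arrows = TRUE, ...) {
  S <- x$site_scores
  graphics::plot(S[, 1], S[, 2], pch = 16, col = "grey40",
                 xlab = "Axis 1", ylab = "Axis 2", ...)
  if (species)
    graphics::text(x$species_loadings[, 1], x$species_loadings[, 2],
                   labels = seq_len(nrow(x$species_loadings)), col = "blue",
                   cex = 0.7)
  if (arrows && !is.null(x$arrows)) {
    sig <- x$arrows[, "significant"]
    col <- ifelse(is.na(sig) | !sig, "salmon", "darkred")
    graphics::arrows(0, 0, x$arrows[, 1], x$arrows[, 2], length = 0.08,
                     col = col)
    graphics::text(x$arrows[, 1] * 1.05, x$arrows[, 2] * 1.05,
                   rownames(x$arrows), col = col, cex = 0.7)
  }
  invisible(x)
}

#' Prediction (uncertainty) regions for ordination scores
#'
#' Per-site ellipses from the rotated variational covariance of the
#' residual latent scores, at the stated coverage: the ellipse is
#' \eqn{\{z : (z-\hat u_i)^\top A_i^{-1} (z-\hat u_i) \le \chi^2_d(level)\}}.
#'
#' @param fit an [lo_fit()] with unconstrained or informed latent variables.
#' @param level coverage, default 0.95.
#' @return data frame with one row per site: center coordinates, the
#'   covariance entries, the chi-square quantile, and the ellipse area.
#' @export
prediction_regions <- function(fit, level = 0.95) {
  model <- fit$model
  if (model$d0 == 0 && fit$spec$num_lv_c == 0)
    stop("prediction regions need residual latent variables ",
         "(unconstrained or informed); constrained fits have none")
  if (!is.null(model$lv_struct))
    stop("prediction regions are per-site; structured latent variables ",
         "share scores across sites")
  st <- list(params = fit$params, vstate = fit$vstate)
  mom <- eta_moments(model, st)
  d <- model$d
  q <- stats::qchisq(level, df = d)
  # residual covariance per site: informed residual and/or unconstrained
  A <- array(0, c(model$n, d, d))
  if (fit$spec$num_lv_c > 0)
    A[, seq_len(model$dc), seq_len(model$dc)] <- mom$covs$eps$A
  if (model$d0 > 0)
    A[, model$dc + seq_len(model$d0), model$dc + seq_len(model$d0)] <-
      mom$covs$U$A
  ord <- ordination_coordinates(fit)
  R <- ord$rotation
  out <- data.frame(site = rownames(fit$data$Y))
  centers <- ord$site_scores
  areas <- numeric(model$n)
  covs <- matrix(0, model$n, d * d)
  for (i in seq_len(model$n)) {
    Ai <- t(R) %*% matrix(A[i, , ], d, d) %*% R
    covs[i, ] <- as.vector(Ai)
    areas[i] <- pi * q * sqrt(max(det(Ai), 0))^(2 / d) *
      if (d == 2) 1 else NA
  }
  out <- cbind(out, center = centers, chisq_q = q, area = areas, cov = covs)
  attr(out, "level") <- level
  out
}
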