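#' Control settings for model fitting
#'
#' @param method \code{"VA"} (closed-form Gaussian variational bound, for
#'   gaussian/identity, poisson/log, bernoulli/probit) or \code{"EVA"}
#'   (second-order extended approximation, any family). Default picks VA
#'   when available.
#' @param n_init number of short jittered restarts before the final
#'   optimization; the best restart (by objective, tie-broken by gradient
#'   norm) seeds the long run.
#' @param maxit maximum iterations of the final optimization.
#' @param init_maxit iterations for each short restart run.
#' @param reltol relative objective-change convergence tolerance.
#' @param grad_tol gradient max-norm reported against convergence.
#' @param seed integer seed controlling starts and jitter.
#' @param optimizer \code{"L-BFGS-B"} or \code{"BFGS"}.
#' @param start \code{"res"} (GLM + residual SVD seeding) or \code{"zero"}.
#' @param jitter_sd standard deviation of the restart jitter applied to
#'   latent-related coordinates.
#' @param trace print optimizer progress.
#' @return a list of class \code{"lo_control"}.
#' @export
lo_control <- function(method = NULL, n_init = 1L, maxit = 2000L,
                       init_maxit = 50L, reltol = 1e-8, grad_tol = 1e-3,
                       seed = 1L, optimizer = c("L-BFGS-B", "BFGS"),
                       start = c("res", "zero"), jitter_sd = 0.1,
                       trace = FALSE) {
  structure(list(method = method, n_init = n_init, maxit = maxit,
                 init_maxit = init_maxit, reltol = reltol,
                 grad_tol = grad_tol, seed = seed,
                 optimizer = match.arg(optimizer), start = match.arg(start),
                 jitter_sd = jitter_sd, trace = trace),
            class = "lo_control")
}

#' Starting values for a latent-variable community model
#'
#' Mode \code{"zero"} sets every latent-related quantity to zero and the
#' intercepts to link-transformed species means. Mode \code{"res"}
#' additionally fits independent per-species GLMs and seeds loadings and
#' site scores from a truncated SVD of the Pearson residual matrix; species
#' whose GLM fails fall back to the zero start with a warning.
#'
#' @param spec an [lo_model_spec()].
#' @param data an [lo_dataset()].
#' @param mode \code{"res"} or \code{"zero"}.
#' @return a list with \code{params} and \code{vstate} (see [lo_fit()]).
#' @export
starting_values <- function(spec, data, mode = c("res", "zero")) {
  mode <- match.arg(mode)
  model <- build_model(spec, data)
  st <- zero_start(model)
  if (mode == "res") st <- residual_seed(model, st)
  st
}

link_transform <- function(fam, mu) {
  switch(fam$link,
    identity = mu,
    log = log(pmax(mu, 1e-3)),
    logit = stats::qlogis(pmin(pmax(mu, 0.02), 0.98)),
    probit = stats::qnorm(pmin(pmax(mu, 0.02), 0.98)))
}

zero_start <- function(model) {
  sp <- model$spec; n <- model$n; m <- model$m
  Ybar <- colSums(model$Y * model$mask) / pmax(colSums(model$mask), 1)
  fam0 <- if (model$hurdle) lo_family("beta") else model$fam
  b0 <- link_transform(fam0, Ybar)
  if (model$hurdle) {
    pres <- seq_len(model$m_obs)
    b0[pres] <- stats::qlogis(pmin(pmax(Ybar[pres], 0.02), 0.98))
  }
  p <- list(beta0 = if (sp$beta0com) mean(b0) else b0)
  kf <- model$k - if (is.null(model$slopes)) 0L else model$slopes$k_r
  if (model$k > 0) {
    if (sp$fourth_corner) {
      p$beta_common <- numeric(model$k)
      if (model$q > 0) p$B_fourth <- matrix(0, model$k, model$q)
    } else if (kf > 0) p$Beta_free <- matrix(0, m, kf)
  }
  if (model$dc > 0) {
    if (sp$randomB == "none") {
      B <- matrix(0, model$k_lv, model$dc)
      for (r in seq_len(model$dc)) B[r, r] <- 1
      p$B_canon <- B
    } else {
      p$randB_var <- rep(0.25, switch(sp$randomB, LV = model$dc,
                                      P = model$dc + model$k_lv, single = 1L))
    }
    G <- matrix(0, m, model$dc)
    for (r in seq_len(min(model$dc, m))) G[r, r] <- 0.1
    p$Gamma_c <- G
    if (sp$num_lv_c > 0) p$sigma2_lv <- rep(1, model$dc)
  }
  if (model$d0 > 0) {
    G <- matrix(0, m, model$d0)
    for (r in seq_len(min(model$d0, m))) G[r, r] <- 0.1
    p$Gamma_u <- G
  }
  if (isTRUE(sp$quadratic)) p$D_quad <- matrix(0.05, m, model$d)
  if (has_phi(model$fam)) p$phi <- rep(
    if (model$fam$name == "gaussian")
      max(mean(apply(model$Y, 2, stats::var, na.rm = TRUE)), 1e-2) else 1,
    model$n_phi)
  if (has_pi(model$fam)) p$pi_zi <- rep(0.1, model$m_obs)
  if (model$fam$name == "ordered_beta") {
    p$zeta2 <- 3
    p$zeta_gap <- rep(log(3), if (sp$zeta_struc == "species")
      model$m_obs else 1L)
  }
  if (model$p_row > 0) p$row_fixed <- numeric(model$p_row)
  for (g in seq_len(model$n_row_blocks)) {
    p[[paste0("row_var_", g)]] <- 0.25
    if (model$design$row_random[[g]]$kind != "iid")
      p[[paste0("row_cor_", g)]] <- 0.3
  }
  if (!is.null(model$lv_struct)) p$rho_lv <- rep(0.3, model$d0)
  if (!is.null(model$slopes)) {
    p$slope_var <- rep(0.25, model$slopes$k_r)
    if (!is.null(model$slopes$phylo))
      p$phylo_rho <- rep(0.3, if (model$slopes$phylo$rho_struct == "term")
        model$slopes$k_r else 1L)
  }
  v <- list(row = list())
  sd0 <- 0.3
  if (model$d0 > 0) {
    if (is.null(model$lv_struct)) {
      v$U_mean <- matrix(0, n, model$d0)
      v$U_L <- init_ltri_vec(n, model$d0, sd0)
    } else {
      Tn <- length(model$lv_struct$levels)
      v$Us_mean <- matrix(0, Tn, model$d0)
      v$Us_L <- replicate(model$d0, init_ltri_single(Tn, sd0),
                          simplify = FALSE)
    }
  }
  if (sp$num_lv_c > 0) {
    v$eps_mean <- matrix(0, n, model$dc)
    v$eps_L <- init_ltri_vec(n, model$dc, sd0)
  }
  if (model$dc > 0 && sp$randomB != "none") {
    v$Bv_mean <- matrix(0, model$k_lv, model$dc)
    v$Bv_sd <- matrix(0.2, model$k_lv, model$dc)
  }
  for (g in seq_len(model$n_row_blocks)) {
    blk <- model$design$row_random[[g]]
    G <- length(blk$levels)
    v$row[[g]] <- if (blk$kind == "iid")
      list(mean = numeric(G), sd = rep(sd0, G))
    else list(mean = numeric(G), L = diag(sd0, G))
  }
  if (!is.null(model$slopes)) {
    v$b_mean <- matrix(0, m, model$slopes$k_r)
    v$b_sd <- matrix(0.2, m, model$slopes$k_r)
  }
  list(params = p, vstate = v)
}

init_ltri_vec <- function(n, d, sd0) {
  nl <- lower_tri_count(d)
  Lm <- matrix(0, n, nl)
  Lm[, diag_positions(d)] <- log(sd0)
  as.vector(Lm)
}
init_ltri_single <- function(Tn, sd0) {
  L <- diag(sd0, Tn)
  vec_from_ltri(L)
}

glm_family_for <- function(fam) {
  switch(fam$name,
    poisson = , negbin = , zip = , zinb = stats::poisson(),
    bernoulli = stats::binomial(link = fam$link),
    gaussian = stats::gaussian(),
    NULL)
}

residual_seed <- function(model, st) {
  des <- model$design
  gf <- glm_family_for(model$fam)
  n <- model$n; m <- model$m
  R <- matrix(0, n, m)
  SL <- matrix(0, m, model$k)  # per-species GLM slopes
  Xf <- des$X
  for (j in seq_len(m)) {
    obs <- model$mask[, j]
    yj <- model$Y[obs, j]
    ok <- FALSE
    if (!is.null(gf)) {
      fit <- tryCatch({
        dfj <- if (is.null(Xf)) data.frame(y = yj) else
          data.frame(y = yj, Xf[obs, , drop = FALSE], check.names = FALSE)
        suppressWarnings(stats::glm(y ~ ., data = dfj, family = gf))
      }, error = function(e) NULL)
      if (!is.null(fit) && all(is.finite(stats::coef(fit)))) {
        cf <- stats::coef(fit)
        st$params$beta0[j] <- if (model$spec$beta0com)
          st$params$beta0[j] else cf[1]
        if (model$k > 0) {
          sl <- cf[-1][seq_len(model$k)]
          SL[j, ] <- ifelse(is.finite(sl), pmin(pmax(sl, -5), 5), 0)
        }
        if (!model$spec$fourth_corner && !is.null(st$params$Beta_free) &&
            is.null(model$slopes))
          st$params$Beta_free[j, ] <- SL[j, seq_len(ncol(st$params$Beta_free))]
        R[obs, j] <- stats::residuals(fit, type = "pearson")
        ok <- TRUE
      }
    }
    if (!ok) {
      mu <- mean(yj)
      R[obs, j] <- (yj - mu) / sqrt(stats::var(yj) + 1e-8)
    }
  }
  if (model$spec$fourth_corner && model$k > 0) {
    # regress species slopes on traits: community effects, fourth-corner
    # matrix, residual random slopes
    Tm <- des$T
    for (l in seq_len(model$k)) {
      if (!is.null(Tm)) {
        cf <- stats::coef(stats::lm(SL[, l] ~ Tm))
        cf[!is.finite(cf)] <- 0
        st$params$beta_common[l] <- cf[1]
        st$params$B_fourth[l, ] <- cf[-1]
        res <- SL[, l] - cf[1] - as.vector(Tm %*% cf[-1])
      } else {
        st$params$beta_common[l] <- mean(SL[, l])
        res <- SL[, l] - mean(SL[, l])
      }
      if (!is.null(st$vstate$b_mean)) st$vstate$b_mean[, l] <- res
      if (!is.null(st$params$slope_var))
        st$params$slope_var[l] <- max(stats::var(res), 0.05)
    }
  } else if (!is.null(model$slopes)) {
    st$vstate$b_mean <- SL[, model$slopes$cols, drop = FALSE]
    st$params$slope_var <- pmax(apply(st$vstate$b_mean, 2, stats::var), 0.05)
    fixed_cols <- setdiff(seq_len(model$k), model$slopes$cols)
    if (length(fixed_cols) && !is.null(st$params$Beta_free))
      st$params$Beta_free <- SL[, fixed_cols, drop = FALSE]
  }
  R[!is.finite(R)] <- 0
  R <- pmin(pmax(R, -10), 10)
  d_seed <- model$d0
  if (d_seed > 0 && is.null(model$lv_struct)) {
    sv <- svd(R, nu = d_seed, nv = d_seed)
    U0 <- sv$u * sqrt(n)
    G0 <- sv$v %*% diag(sv$d[seq_len(d_seed)] / sqrt(n), d_seed)
    st$vstate$U_mean <- U0
    G0[upper.tri(G0)] <- 0
    st$params$Gamma_u <- G0
  }
  st
}

#' Fit a latent-variable community model by variational approximation
#'
#' Maximizes the evidence lower bound ([elbo()]) jointly over model
#' parameters and the Gaussian variational state with a quasi-Newton
#' optimizer and analytic gradients. With \code{n_init > 1}, several short
#' jittered runs are compared (objective value, then gradient magnitude)
#' and the best seeds the final optimization. Deterministic given
#' \code{control$seed}.
#'
#' @param spec an [lo_model_spec()].
#' @param data an [lo_dataset()].
#' @param control an [lo_control()].
#' @return an object of class \code{"lo_fit"} with elements \code{spec},
#'   \code{params}, \code{vstate}, \code{objective} (final lower bound),
#'   \code{grad_norm}, \code{df}, \code{n_obs}, \code{trace} (per-restart
#'   objectives), \code{converged}.
#' @export
lo_fit <- function(spec, data, control = lo_control()) {
  model <- build_model(spec, data, method = control$method)
  method <- model$method
  st0 <- starting_values(spec, data, mode = control$start)
  theta0 <- state_pack(model, st0)
  negf <- function(th) {
    val <- tryCatch(-elbo_value(model, state_unpack(model, th), method),
                    error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }
  negg <- function(th) {
    g <- tryCatch(-elbo_gradient(model, state_unpack(model, th), method),
                  error = function(e) rep(0, length(th)))
    g[!is.finite(g)] <- 0
    pmin(pmax(g, -1e6), 1e6)
  }
  latent_idx <- latent_coordinate_index(model)
  runs <- list()
  n_init <- max(1L, control$n_init)
  for (r in seq_len(n_init)) {
    set.seed(control$seed + r - 1L)
    th <- theta0
    if (r > 1L)
      th[latent_idx] <- th[latent_idx] +
        stats::rnorm(length(latent_idx), 0, control$jitter_sd)
    o <- try_optim(th, negf, negg, control, maxit = control$init_maxit)
    runs[[r]] <- o
  }
  vals <- vapply(runs, function(o) o$value, 0)
  if (all(!is.finite(vals) | vals >= 1e10))
    stop("all restarts diverged; restart objectives: ",
         paste(signif(vals, 6), collapse = ", "))
  gnorms <- vapply(runs, function(o) max(abs(negg(o$par))), 0)
  score <- rank(vals) + 0.5 * rank(gnorms)
  best <- which.min(score)
  # final optimization: repeated quasi-Newton rounds until the gradient
  # norm or the relative objective change meets tolerance
  o <- try_optim(runs[[best]]$par, negf, negg, control,
                 maxit = control$maxit)
  for (round in seq_len(7)) {
    gn_now <- max(abs(negg(o$par)))
    if (is.finite(gn_now) && gn_now < control$grad_tol) break
    o2 <- try_optim(o$par, negf, negg, control, maxit = control$maxit)
    improved <- (o$value - o2$value) > control$reltol * (abs(o$value) + 1)
    if (o2$value <= o$value) o <- o2
    if (!improved) break
  }
  if (!is.finite(o$value) || o$value >= 1e10)
    stop("non-finite objective at the optimum; trace: ",
         paste(signif(vals, 6), collapse = ", "))
  st <- state_unpack(model, o$par)
  gn <- max(abs(negg(o$par)))
  fit <- structure(list(
    spec = spec, data = data, model = model, method = method,
    params = st$params, vstate = st$vstate, theta = o$par,
    objective = -o$value, grad_norm = gn,
    n_obs = sum(model$mask),
    df = count_free_parameters(spec, model$n, model$m_obs,
                               design = model$design),
    trace = -vals, control = control,
    converged = is.finite(gn) && gn < max(control$grad_tol, 1e-2) * 100),
    class = "lo_fit")
  fit
}

try_optim <- function(th, negf, negg, control, maxit) {
  ctl <- if (control$optimizer == "L-BFGS-B")
    list(maxit = maxit, factr = control$reltol / .Machine$double.eps,
         lmm = 25L, trace = if (control$trace) 1L else 0L)
  else list(maxit = maxit, reltol = control$reltol,
            trace = if (control$trace) 1L else 0L)
  o <- tryCatch(
    stats::optim(th, negf, negg, method = control$optimizer, control = ctl),
    error = function(e) NULL)
  if (is.null(o)) o <- list(par = th, value = negf(th), convergence = 99L)
  o
}

latent_coordinate_index <- function(model) {
  blocks <- model_blocks(model)
  latent <- c("Gamma_c", "Gamma_u", "B_canon", "U_mean", "U_L", "Us_mean",
              "Us_L", "eps_mean", "eps_L", "Bv_mean", "Bv_lsd", "b_mean",
              "b_lsd")
  idx <- integer(0); pos <- 0L
  for (bl in blocks) {
    if (bl$name %in% latent || startsWith(bl$name, "row_mean_"))
      idx <- c(idx, pos + seq_len(bl$len))
    pos <- pos + bl$len
  }
  idx
}

#' @export
print.lo_fit <- function(x, ...) {
  cat(sprintf("<lo_fit> %s (%s, %s)\n", x$spec$family$name,
              x$spec$family$link, x$method))
  cat(sprintf("  %d sites x %d species, %d observed cells\n",
              x$model$n, x$model$m_obs, x$n_obs))
  cat(sprintf("  lower bound: %.4f  (df = %d, |grad| = %.2e)\n",
              x$objective, x$df, x$grad_norm))
  invisible(x)
}

#' @export
logLik.lo_fit <- function(object, ...) {
  structure(object$objective, df = object$df, nobs = object$n_obs,
            class = "logLik")
}
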