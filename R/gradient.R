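# Analytic gradient of the ELBO in the packed parameterization.
#
# The chain splits at the per-cell moments (eta_mean, eta_var): the family
# supplies dE/deta and dE/dv (closed form under VA; analytic first
# derivative plus a differenced curvature under EVA), and everything
# upstream is linear algebra. Scalar structural parameters that enter only
# through KL terms (variances, correlation and signal parameters) use exact
# central differences on the cheap KL component; auxiliary family
# parameters use vectorized central differences on the cell term, two
# matrix evaluations per block.

elbo_gradient <- function(model, st, method = model$method) {
  if (isTRUE(model$spec$quadratic))
    return(numeric_gradient(function(th)
      elbo_value(model, state_unpack(model, th), method),
      state_pack(model, st)))
  sp <- model$spec; p <- st$params; v <- st$vstate
  des <- model$design
  n <- model$n; m <- model$m
  mom <- eta_moments(model, st)
  cg <- cell_grad(model, st, mom$eta, mom$v, method)
  Gm <- cg$deta; Gv <- cg$dv
  Gam <- mom$Gam
  out <- list()

  out$beta0 <- if (sp$beta0com) sum(Gm) else colSums(Gm)
  if (model$k > 0) {
    if (sp$fourth_corner) {
      out$beta_common <- as.vector(t(des$X) %*% rowSums(Gm))
      if (model$q > 0)
        out$B_fourth <- as.vector(t(des$X) %*% Gm %*% des$T)
    } else {
      fixed_cols <- setdiff(seq_len(model$k),
                            if (is.null(model$slopes)) integer(0)
                            else model$slopes$cols)
      if (length(fixed_cols))
        out$Beta <- as.vector(t(Gm) %*% des$X[, fixed_cols, drop = FALSE])
    }
  }
  if (model$dc > 0) {
    Gam_c <- Gam[, seq_len(model$dc), drop = FALSE]
    if (sp$randomB == "none") {
      GB <- t(des$X_lv) %*% Gm %*% Gam_c
      out$B_canon <- pack_bcanon_grad(GB, model$dc)
    } else {
      out$randB_var <- kl_fd(model, st, "randB_var", length(p$randB_var))
    }
    # loadings on constrained dims
    GG <- t(Gm) %*% mom$U[, seq_len(model$dc), drop = FALSE]
    if (sp$num_lv_c > 0) {
      A <- mom$covs$eps$A
      for (r in seq_len(model$dc)) for (s in seq_len(model$dc))
        GG[, r] <- GG[, r] + 2 * as.vector(t(Gv) %*% A[, r, s]) * Gam_c[, s]
    }
    if (sp$randomB != "none") {
      XA <- (des$X_lv^2) %*% (v$Bv_sd^2)
      for (r in seq_len(model$dc))
        GG[, r] <- GG[, r] + 2 * Gam_c[, r] * as.vector(t(Gv) %*% XA[, r])
    }
    out$Gamma_c <- vec_from_gamma(GG)
    if (sp$num_lv_c > 0)
      out$sigma2_lv <- kl_fd(model, st, "sigma2_lv", model$dc)
  }
  if (model$d0 > 0) {
    off <- model$dc
    Gam_u <- Gam[, off + seq_len(model$d0), drop = FALSE]
    GG <- t(Gm) %*% mom$U[, off + seq_len(model$d0), drop = FALSE]
    if (is.null(model$lv_struct)) {
      A <- mom$covs$U$A
      for (r in seq_len(model$d0)) for (s in seq_len(model$d0))
        GG[, r] <- GG[, r] + 2 * as.vector(t(Gv) %*% A[, r, s]) * Gam_u[, s]
    } else {
      Z <- model$lv_struct$Z
      for (r in seq_len(model$d0)) {
        avar <- rowSums(mom$covs$Us[[r]]^2)
        GG[, r] <- GG[, r] +
          2 * Gam_u[, r] * as.vector(t(Gv) %*% (Z %*% avar))
      }
    }
    out$Gamma_u <- vec_from_gamma(GG)
  }
  if (has_phi(model$fam)) out$phi <- aux_fd(model, st, mom, method, "phi")
  if (has_pi(model$fam)) out$pi <- aux_fd(model, st, mom, method, "pi")
  if (model$fam$name == "ordered_beta") {
    out$zeta2 <- aux_fd(model, st, mom, method, "zeta2")
    out$zeta_gap <- aux_fd(model, st, mom, method, "zeta_gap")
  }
  if (model$p_row > 0)
    out$row_fixed <- as.vector(t(des$row_fixed) %*% rowSums(Gm))
  for (g in seq_len(model$n_row_blocks)) {
    out[[paste0("row_var_", g)]] <- kl_fd(model, st, paste0("row_var_", g), 1L)
    if (des$row_random[[g]]$kind != "iid")
      out[[paste0("row_cor_", g)]] <- kl_fd(model, st, paste0("row_cor_", g), 1L)
  }
  if (!is.null(model$lv_struct))
    out$rho_lv <- kl_fd(model, st, "rho_lv", model$d0)
  if (!is.null(model$slopes)) {
    out$slope_var <- kl_fd(model, st, "slope_var", model$slopes$k_r)
    if (!is.null(model$slopes$phylo))
      out$phylo_rho <- kl_fd(model, st, "phylo_rho", length(p$phylo_rho))
  }

  # ---- variational blocks ----
  if (model$d0 > 0 && is.null(model$lv_struct)) {
    off <- model$dc
    Gam_u <- Gam[, off + seq_len(model$d0), drop = FALSE]
    out$U_mean <- as.vector(Gm %*% Gam_u - v$U_mean)
    out$U_L <- factor_grad_sites(model, Gv, Gam_u, mom$covs$U,
                                 prior_diag = rep(1, model$d0))
  }
  if (model$d0 > 0 && !is.null(model$lv_struct)) {
    Z <- model$lv_struct$Z
    Tn <- length(model$lv_struct$levels)
    pos <- model$lv_struct$positions
    off <- model$dc
    gm <- matrix(0, Tn, model$d0)
    gl <- vector("list", model$d0)
    for (r in seq_len(model$d0)) {
      rho <- p$rho_lv[r]
      Sig <- outer(pos, pos, function(a, b) rho^abs(a - b))
      Sinv <- solve(Sig)
      mr <- v$Us_mean[, r]
      gm[, r] <- as.vector(t(Z) %*% (Gm %*% Gam[, off + r])) - Sinv %*% mr
      L <- mom$covs$Us[[r]]
      GA <- diag(as.vector(t(Z) %*% (Gv %*% (Gam[, off + r]^2))), Tn) -
        0.5 * Sinv + 0.5 * chol2inv(chol(tcrossprod(L)))
      GL <- 2 * GA %*% L
      diag(GL) <- diag(GL) * diag(L)
      gl[[r]] <- GL[lower.tri(GL, diag = TRUE)]
    }
    out$Us_mean <- as.vector(gm)
    out$Us_L <- unlist(gl)
  }
  if (sp$num_lv_c > 0) {
    Gam_c <- Gam[, seq_len(model$dc), drop = FALSE]
    out$eps_mean <- as.vector(Gm %*% Gam_c -
                                sweep(v$eps_mean, 2, p$sigma2_lv, "/"))
    out$eps_L <- factor_grad_sites(model, Gv, Gam_c, mom$covs$eps,
                                   prior_diag = p$sigma2_lv)
  }
  if (model$dc > 0 && sp$randomB != "none") {
    Gam_c <- Gam[, seq_len(model$dc), drop = FALSE]
    pv <- randB_prior_var(model, p)
    out$Bv_mean <- as.vector(t(des$X_lv) %*% Gm %*% Gam_c - v$Bv_mean / pv)
    a <- v$Bv_sd^2
    dEda <- t(des$X_lv^2) %*% Gv %*% (Gam_c^2)
    dKda <- 0.5 * (1 / pv - 1 / a)
    out$Bv_lsd <- as.vector((dEda - dKda) * 2 * a)
  }
  for (g in seq_len(model$n_row_blocks)) {
    blk <- des$row_random[[g]]
    pr <- row_prior_matrix(model, p, g)
    rb <- v$row[[g]]
    rsG <- rowSums(Gm); rsV <- rowSums(Gv)
    if (!is.null(pr$diag)) {
      out[[paste0("row_mean_", g)]] <-
        as.vector(t(blk$Z) %*% rsG) - rb$mean / pr$diag
      a <- rb$sd^2
      dEda <- as.vector(t(blk$Z) %*% rsV)
      out[[paste0("row_lsd_", g)]] <-
        (dEda - 0.5 * (1 / pr$diag - 1 / a)) * 2 * a
    } else {
      Sinv <- chol2inv(chol(pr$full))
      out[[paste0("row_mean_", g)]] <-
        as.vector(t(blk$Z) %*% rsG) - as.vector(Sinv %*% rb$mean)
      L <- rb$L
      GA <- diag(as.vector(t(blk$Z) %*% rsV), nrow(L)) -
        0.5 * Sinv + 0.5 * chol2inv(chol(tcrossprod(L)))
      GL <- 2 * GA %*% L
      diag(GL) <- diag(GL) * diag(L)
      out[[paste0("row_L_", g)]] <- GL[lower.tri(GL, diag = TRUE)]
    }
  }
  if (!is.null(model$slopes)) {
    Xr <- model$slopes$X_r
    gb <- t(Gm) %*% Xr
    ga <- t(Gv) %*% (Xr^2)
    a <- v$b_sd^2
    for (l in seq_len(model$slopes$k_r)) {
      pr <- slope_prior(model, p, l)
      if (!is.null(pr$diag)) {
        gb[, l] <- gb[, l] - v$b_mean[, l] / pr$diag
        ga[, l] <- ga[, l] - 0.5 * (1 / pr$diag - 1 / a[, l])
      } else {
        gb[, l] <- gb[, l] - as.vector(pr$Q %*% v$b_mean[, l])
        ga[, l] <- ga[, l] - 0.5 * (diag(pr$Q) - 1 / a[, l])
      }
    }
    out$b_mean <- as.vector(gb)
    out$b_lsd <- as.vector(ga * 2 * a)
  }

  assemble_gradient(model, out)
}

# per-site triangular-factor gradient for iid latent blocks
factor_grad_sites <- function(model, Gv, Gam_part, sc, prior_diag) {
  n <- model$n
  d <- ncol(Gam_part)
  nl <- lower_tri_count(d)
  S <- array(0, c(n, d, d))
  for (r in seq_len(d)) for (s in seq_len(d))
    S[, r, s] <- as.vector(Gv %*% (Gam_part[, r] * Gam_part[, s]))
  Gl <- matrix(0, n, nl)
  Pinv <- diag(1 / prior_diag, d)
  tri <- which(lower.tri(diag(d), diag = TRUE))
  for (i in seq_len(n)) {
    L <- matrix(sc$L[i, , ], d, d)
    A <- matrix(sc$A[i, , ], d, d)
    GA <- matrix(S[i, , ], d, d) - 0.5 * Pinv +
      0.5 * chol2inv(chol(A))
    GL <- 2 * GA %*% L
    diag(GL) <- diag(GL) * diag(L)
    Gl[i, ] <- GL[tri]
  }
  as.vector(Gl)
}

pack_bcanon_grad <- function(GB, d) {
  lead <- row(GB) <= d & row(GB) > col(GB)
  rest <- row(GB) > d
  c(GB[lead], GB[rest])
}

# central difference of the total KL in the raw coordinates of one block
kl_fd <- function(model, st, block, len, step = 1e-6) {
  base_p <- st$params
  g <- numeric(len)
  for (i in seq_len(len)) {
    for (sgn in c(1, -1)) {
      p2 <- perturb_raw(model, base_p, block, i, sgn * step)
      st2 <- st; st2$params <- p2
      val <- kl_total(model, st2)
      if (sgn > 0) up <- val else dn <- val
    }
    g[i] <- -(up - dn) / (2 * step)  # objective subtracts KL
  }
  g
}

perturb_raw <- function(model, p, block, i, d) {
  if (block == "sigma2_lv") p$sigma2_lv[i] <- p$sigma2_lv[i] * exp(d)
  else if (block == "rho_lv") p$rho_lv[i] <- tanh(atanh(p$rho_lv[i]) + d)
  else if (block == "slope_var") p$slope_var[i] <- p$slope_var[i] * exp(d)
  else if (block == "phylo_rho")
    p$phylo_rho[i] <- stats::plogis(stats::qlogis(p$phylo_rho[i]) + d)
  else if (block == "randB_var") p$randB_var[i] <- p$randB_var[i] * exp(d)
  else if (startsWith(block, "row_var_")) p[[block]] <- p[[block]] * exp(d)
  else if (startsWith(block, "row_cor_")) p[[block]] <- p[[block]] + d
  else stop("internal: cannot perturb block ", block)
  p
}

# vectorized central difference of the summed cell term in one auxiliary
# block's raw coordinates; per-species blocks need two matrix evaluations
aux_fd <- function(model, st, mom, method, block, step = 1e-6) {
  eval_term <- function(p2) {
    st2 <- st; st2$params <- p2
    E <- cell_expected_loglik(model, st2, mom$eta, mom$v, method)
    E[!model$mask] <- 0
    E
  }
  p <- st$params
  if (block == "phi") {
    p_up <- p; p_up$phi <- p$phi * exp(step)
    p_dn <- p; p_dn$phi <- p$phi * exp(-step)
    per_sp <- colSums(eval_term(p_up) - eval_term(p_dn)) / (2 * step)
    if (model$hurdle) per_sp <- per_sp[model$m_obs + seq_len(model$m_obs)]
    as.vector(tapply(per_sp, model$disp_idx, sum))
  } else if (block == "pi") {
    raw <- stats::qlogis(p$pi_zi)
    p_up <- p; p_up$pi_zi <- stats::plogis(raw + step)
    p_dn <- p; p_dn$pi_zi <- stats::plogis(raw - step)
    colSums(eval_term(p_up) - eval_term(p_dn)) / (2 * step)
  } else if (block == "zeta2") {
    p_up <- p; p_up$zeta2 <- p$zeta2 + step
    p_dn <- p; p_dn$zeta2 <- p$zeta2 - step
    sum(eval_term(p_up) - eval_term(p_dn)) / (2 * step)
  } else if (block == "zeta_gap") {
    p_up <- p; p_up$zeta_gap <- p$zeta_gap + step
    p_dn <- p; p_dn$zeta_gap <- p$zeta_gap - step
    d <- colSums(eval_term(p_up) - eval_term(p_dn)) / (2 * step)
    if (length(p$zeta_gap) == 1L) sum(d) else d
  } else stop("internal: unknown aux block ", block)
}

assemble_gradient <- function(model, out) {
  blocks <- model_blocks(model)
  g <- numeric(0)
  for (bl in blocks) {
    nm <- bl$name
    key <- if (nm == "Beta") "Beta" else nm
    val <- out[[key]]
    if (is.null(val)) stop("internal: missing gradient block ", nm)
    if (length(val) != bl$len)
      stop("internal: gradient block ", nm, " has length ", length(val),
           " expected ", bl$len)
    g <- c(g, as.numeric(val))
  }
  g
}

numeric_gradient <- function(fn, theta, step = 1e-6) {
  g <- numeric(length(theta))
  for (i in seq_along(theta)) {
    tp <- theta; tp[i] <- tp[i] + step
    tm <- theta; tm[i] <- tm[i] - step
    g[i] <- (fn(tp) - fn(tm)) / (2 * step)
  }
  g
}
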