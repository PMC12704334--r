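# Internal model representation, state packing, ELBO and gradient.
#
# The variational family is Gaussian with block structure: per-site means and
# lower-triangular covariance factors for unconstrained/informed latent
# variables, one triangular factor of size T per latent dimension for
# structured (e.g. AR1) latent variables, per-level means with diagonal
# (iid prior) or triangular (correlated prior) factors for random row
# effects, and diagonal factors for species random slopes and random
# canonical coefficients.

build_model <- function(spec, data, method = NULL) {
  design <- parse_model(spec, data)
  fam <- spec$family
  hurdle <- fam$name == "hurdle_beta"
  Y <- data$Y
  mask <- design$observed_mask
  n <- nrow(Y); m_obs <- ncol(Y)
  if (hurdle) {
    # two-part expansion: presence columns then positive-cover columns
    Ypres <- (Y > 0) * 1
    Ypos <- Y
    mask_pos <- mask & !is.na(Y) & Y > 0
    Y <- cbind(Ypres, Ypos)
    mask <- cbind(mask, mask_pos)
    design$observed_mask <- mask
  }
  m <- ncol(Y)
  k <- if (is.null(design$X)) 0L else ncol(design$X)
  k_lv <- if (is.null(design$X_lv)) 0L else ncol(design$X_lv)
  q <- if (is.null(design$T)) 0L else ncol(design$T)
  dc <- spec$num_RR + spec$num_lv_c
  d0 <- spec$num_lv
  if (isTRUE(spec$quadratic) && (!is.null(design$lv_groups)))
    stop("quadratic latent terms are not supported with structured latent variables")
  slopes <- NULL
  if (spec$fourth_corner || !is.null(spec$random_slopes)) {
    cols <- if (spec$fourth_corner && is.null(spec$random_slopes))
      seq_len(k) else match(spec$random_slopes, colnames(design$X))
    if (anyNA(cols))
      stop("random_slopes name covariates absent from the design: ",
           paste(spec$random_slopes[is.na(cols)], collapse = ", "))
    phylo <- NULL
    if (!is.null(spec$phylo)) {
      if (is.null(data$tree)) stop("phylogenetic random slopes need a tree")
      tc <- tree_to_correlation(data$tree, species = colnames(data$Y))
      ord <- order_by_root_distance(tc$tree)
      phylo <- list(C = tc$C[colnames(data$Y), colnames(data$Y)],
                    D = tc$D[colnames(data$Y), colnames(data$Y)],
                    nn = min(spec$phylo$nn, m_obs - 1L),
                    ordering = match(tc$tree$tip.label[ord], colnames(data$Y)),
                    rho_struct = spec$phylo$rho_struct)
    }
    slopes <- list(cols = cols, k_r = length(cols),
                   X_r = design$X[, cols, drop = FALSE], phylo = phylo)
    if (hurdle) stop("random slopes are not supported for the hurdle family")
  }
  disp_idx <- spec$disp_groups %||% seq_len(if (hurdle) m_obs else m)
  if (hurdle) disp_idx <- disp_idx  # phi applies to the positive part only
  n_phi <- length(unique(disp_idx))
  if (is.null(method)) method <- default_method(fam)
  if (hurdle) method <- "EVA"
  list(spec = spec, design = design, Y = Y, mask = mask, n = n, m = m,
       m_obs = m_obs, hurdle = hurdle, k = k, k_lv = k_lv, q = q,
       dc = dc, d0 = d0, d = dc + d0, fam = fam, method = method,
       lv_cor_ok = if (!is.null(design$lv_groups) &&
                       design$lv_groups$kind != "corAR1")
         stop("only corAR1 structures are supported for lv_cor") else TRUE,
       slopes = slopes, disp_idx = as.integer(factor(disp_idx)),
       n_phi = n_phi,
       lv_struct = design$lv_groups,
       n_row_blocks = length(design$row_random),
       p_row = if (is.null(design$row_fixed)) 0L else ncol(design$row_fixed))
}

has_phi <- function(fam) fam$name %in%
  c("gaussian", "negbin", "zinb", "beta", "hurdle_beta", "ordered_beta")
has_pi <- function(fam) fam$name %in% c("zip", "zinb")

# ---- block list and packing ----------------------------------------------

lower_tri_count <- function(d) d * (d + 1) / 2

model_blocks <- function(model) {
  sp <- model$spec; b <- list()
  add <- function(name, len) b[[length(b) + 1]] <<- list(name = name, len = len)
  m <- model$m; n <- model$n
  add("beta0", if (sp$beta0com) 1L else m)
  if (model$k > 0) {
    if (sp$fourth_corner) {
      add("beta_common", model$k)
      if (model$q > 0) add("B_fourth", model$k * model$q)
    } else {
      kf <- model$k - if (is.null(model$slopes)) 0L else model$slopes$k_r
      if (kf > 0) add("Beta", m * kf)
    }
  }
  if (model$dc > 0) {
    if (sp$randomB == "none")
      add("B_canon", model$k_lv * model$dc - lower_tri_count(model$dc))
    else
      add("randB_var", switch(sp$randomB, LV = model$dc,
                              P = model$dc + model$k_lv, single = 1L))
    add("Gamma_c", m * model$dc - model$dc * (model$dc - 1) / 2)
    if (sp$num_lv_c > 0) add("sigma2_lv", model$dc)
  }
  if (model$d0 > 0) add("Gamma_u", m * model$d0 - model$d0 * (model$d0 - 1) / 2)
  if (isTRUE(sp$quadratic)) add("D_quad", m * model$d)
  if (has_phi(model$fam)) add("phi", model$n_phi)
  if (has_pi(model$fam)) add("pi", model$m_obs)
  if (model$fam$name == "ordered_beta") {
    add("zeta2", 1L)
    add("zeta_gap", if (sp$zeta_struc == "species") model$m_obs else 1L)
  }
  if (model$p_row > 0) add("row_fixed", model$p_row)
  for (g in seq_len(model$n_row_blocks)) {
    blk <- model$design$row_random[[g]]
    add(paste0("row_var_", g), 1L)
    if (blk$kind != "iid") add(paste0("row_cor_", g), 1L)
  }
  if (!is.null(model$lv_struct)) add("rho_lv", model$d0)
  if (!is.null(model$slopes)) {
    add("slope_var", model$slopes$k_r)
    if (!is.null(model$slopes$phylo))
      add("phylo_rho", if (model$slopes$phylo$rho_struct == "term")
        model$slopes$k_r else 1L)
  }
  # variational blocks
  if (model$d0 > 0) {
    if (is.null(model$lv_struct)) {
      add("U_mean", n * model$d0)
      add("U_L", n * lower_tri_count(model$d0))
    } else {
      T <- length(model$lv_struct$levels)
      add("Us_mean", T * model$d0)
      add("Us_L", model$d0 * lower_tri_count(T))
    }
  }
  if (sp$num_lv_c > 0) {
    add("eps_mean", n * model$dc)
    add("eps_L", n * lower_tri_count(model$dc))
  }
  if (model$dc > 0 && sp$randomB != "none") {
    add("Bv_mean", model$k_lv * model$dc)
    add("Bv_lsd", model$k_lv * model$dc)
  }
  for (g in seq_len(model$n_row_blocks)) {
    blk <- model$design$row_random[[g]]
    G <- length(blk$levels)
    add(paste0("row_mean_", g), G)
    if (blk$kind == "iid") add(paste0("row_lsd_", g), G)
    else add(paste0("row_L_", g), lower_tri_count(G))
  }
  if (!is.null(model$slopes)) {
    add("b_mean", m * model$slopes$k_r)
    add("b_lsd", m * model$slopes$k_r)
  }
  b
}

n_free_parameters <- function(model) sum(vapply(model_blocks(model),
                                                `[[`, 0, "len"))

# lower-triangular matrix (incl diagonal) from packed vector, log-diagonal
ltri_from_vec <- function(v, d) {
  L <- matrix(0, d, d)
  L[lower.tri(L, diag = TRUE)] <- v
  diag(L) <- exp(diag(L))
  L
}
vec_from_ltri <- function(L) {
  d <- nrow(L)
  M <- L
  diag(M) <- log(diag(L))
  M[lower.tri(M, diag = TRUE)]
}

# loading matrix with zero upper triangle from packed free entries
gamma_from_vec <- function(v, m, d) {
  G <- matrix(0, m, d)
  free <- which(row(G) >= col(G))
  G[free] <- v
  G
}
vec_from_gamma <- function(G) G[row(G) >= col(G)]

# canonical coefficients: leading d x d block unit-lower-triangular
bcanon_from_vec <- function(v, k_lv, d) {
  B <- matrix(0, k_lv, d)
  lead <- row(B) <= d & row(B) > col(B)
  rest <- row(B) > d
  nl <- sum(lead)
  B[lead] <- v[seq_len(nl)]
  B[rest] <- v[nl + seq_len(sum(rest))]
  for (r in seq_len(d)) B[r, r] <- 1
  B
}
vec_from_bcanon <- function(B, d) {
  lead <- row(B) <= d & row(B) > col(B)
  rest <- row(B) > d
  c(B[lead], B[rest])
}

state_unpack <- function(model, theta) {
  blocks <- model_blocks(model)
  pos <- 0L
  take <- function(len) {
    out <- theta[pos + seq_len(len)]
    pos <<- pos + len
    out
  }
  p <- list(); v <- list(row = list())
  sp <- model$spec; m <- model$m; n <- model$n
  for (bl in blocks) {
    x <- take(bl$len)
    nm <- bl$name
    if (nm == "beta0") p$beta0 <- x
    else if (nm == "Beta") {
      kf <- bl$len / m
      p$Beta_free <- matrix(x, m, kf)
    } else if (nm == "beta_common") p$beta_common <- x
    else if (nm == "B_fourth") p$B_fourth <- matrix(x, model$k, model$q)
    else if (nm == "B_canon") p$B_canon <- bcanon_from_vec(x, model$k_lv, model$dc)
    else if (nm == "randB_var") p$randB_var <- exp(x)
    else if (nm == "Gamma_c") p$Gamma_c <- gamma_from_vec(x, m, model$dc)
    else if (nm == "Gamma_u") p$Gamma_u <- gamma_from_vec(x, m, model$d0)
    else if (nm == "sigma2_lv") p$sigma2_lv <- exp(x)
    else if (nm == "D_quad") p$D_quad <- matrix(exp(x), m, model$d)
    else if (nm == "phi") p$phi <- exp(x)
    else if (nm == "pi") p$pi_zi <- stats::plogis(x)
    else if (nm == "zeta2") p$zeta2 <- x
    else if (nm == "zeta_gap") p$zeta_gap <- x
    else if (nm == "row_fixed") p$row_fixed <- x
    else if (startsWith(nm, "row_var_")) p[[nm]] <- exp(x)
    else if (startsWith(nm, "row_cor_")) p[[nm]] <- x  # raw; interpreted per kind
    else if (nm == "rho_lv") p$rho_lv <- tanh(x)
    else if (nm == "slope_var") p$slope_var <- exp(x)
    else if (nm == "phylo_rho") p$phylo_rho <- stats::plogis(x)
    else if (nm == "U_mean") v$U_mean <- matrix(x, n, model$d0)
    else if (nm == "U_L") v$U_L <- x  # n x ltri, expanded on demand
    else if (nm == "Us_mean") v$Us_mean <-
        matrix(x, length(model$lv_struct$levels), model$d0)
    else if (nm == "Us_L") v$Us_L <- split(x, rep(seq_len(model$d0),
        each = bl$len / model$d0))
    else if (nm == "eps_mean") v$eps_mean <- matrix(x, n, model$dc)
    else if (nm == "eps_L") v$eps_L <- x
    else if (nm == "Bv_mean") v$Bv_mean <- matrix(x, model$k_lv, model$dc)
    else if (nm == "Bv_lsd") v$Bv_sd <- matrix(exp(x), model$k_lv, model$dc)
    else if (startsWith(nm, "row_mean_")) {
      g <- as.integer(sub("row_mean_", "", nm))
      v$row[[g]] <- list(mean = x)
    } else if (startsWith(nm, "row_lsd_")) {
      g <- as.integer(sub("row_lsd_", "", nm))
      v$row[[g]]$sd <- exp(x)
    } else if (startsWith(nm, "row_L_")) {
      g <- as.integer(sub("row_L_", "", nm))
      G <- length(model$design$row_random[[g]]$levels)
      v$row[[g]]$L <- ltri_from_vec(x, G)
    } else if (nm == "b_mean") v$b_mean <- matrix(x, m, model$slopes$k_r)
    else if (nm == "b_lsd") v$b_sd <- matrix(exp(x), m, model$slopes$k_r)
    else stop("internal: unknown block ", nm)
  }
  list(params = p, vstate = v)
}

state_pack <- function(model, st) {
  blocks <- model_blocks(model)
  p <- st$params; v <- st$vstate
  out <- numeric(0)
  for (bl in blocks) {
    nm <- bl$name
    x <- if (nm == "beta0") p$beta0
    else if (nm == "Beta") as.vector(p$Beta_free)
    else if (nm == "beta_common") p$beta_common
    else if (nm == "B_fourth") as.vector(p$B_fourth)
    else if (nm == "B_canon") vec_from_bcanon(p$B_canon, model$dc)
    else if (nm == "randB_var") log(p$randB_var)
    else if (nm == "Gamma_c") vec_from_gamma(p$Gamma_c)
    else if (nm == "Gamma_u") vec_from_gamma(p$Gamma_u)
    else if (nm == "sigma2_lv") log(p$sigma2_lv)
    else if (nm == "D_quad") log(as.vector(p$D_quad))
    else if (nm == "phi") log(p$phi)
    else if (nm == "pi") stats::qlogis(p$pi_zi)
    else if (nm == "zeta2") p$zeta2
    else if (nm == "zeta_gap") p$zeta_gap
    else if (nm == "row_fixed") p$row_fixed
    else if (startsWith(nm, "row_var_")) log(p[[nm]])
    else if (startsWith(nm, "row_cor_")) p[[nm]]
    else if (nm == "rho_lv") atanh(p$rho_lv)
    else if (nm == "slope_var") log(p$slope_var)
    else if (nm == "phylo_rho") stats::qlogis(p$phylo_rho)
    else if (nm == "U_mean") as.vector(v$U_mean)
    else if (nm == "U_L") v$U_L
    else if (nm == "Us_mean") as.vector(v$Us_mean)
    else if (nm == "Us_L") unlist(v$Us_L, use.names = FALSE)
    else if (nm == "eps_mean") as.vector(v$eps_mean)
    else if (nm == "eps_L") v$eps_L
    else if (nm == "Bv_mean") as.vector(v$Bv_mean)
    else if (nm == "Bv_lsd") log(as.vector(v$Bv_sd))
    else if (startsWith(nm, "row_mean_"))
      v$row[[as.integer(sub("row_mean_", "", nm))]]$mean
    else if (startsWith(nm, "row_lsd_"))
      log(v$row[[as.integer(sub("row_lsd_", "", nm))]]$sd)
    else if (startsWith(nm, "row_L_"))
      vec_from_ltri(v$row[[as.integer(sub("row_L_", "", nm))]]$L)
    else if (nm == "b_mean") as.vector(v$b_mean)
    else if (nm == "b_lsd") log(as.vector(v$b_sd))
    else stop("internal: unknown block ", nm)
    if (length(x) != bl$len)
      stop("internal: block ", nm, " has length ", length(x),
           " but expected ", bl$len)
    out <- c(out, as.numeric(x))
  }
  unname(out)
}

# ---- derived quantities ---------------------------------------------------

# site-level covariance arrays A[i,,] from packed triangular factors
site_cov_array <- function(Lvec, n, d) {
  nl <- lower_tri_count(d)
  Lm <- matrix(Lvec, n, nl)
  A <- array(0, c(n, d, d))
  Ls <- array(0, c(n, d, d))
  idx <- which(lower.tri(diag(d), diag = TRUE))
  for (t in seq_along(idx)) {
    rc <- arrayInd(idx[t], c(d, d))
    val <- Lm[, t]
    if (rc[1] == rc[2]) val <- exp(val)
    Ls[, rc[1], rc[2]] <- val
  }
  for (r in seq_len(d)) for (s in seq_len(d)) {
    acc <- 0
    for (t in seq_len(d)) acc <- acc + Ls[, r, t] * Ls[, s, t]
    A[, r, s] <- acc
  }
  list(A = A, L = Ls)
}

aux_for_model <- function(model, p) {
  aux <- list()
  if (has_phi(model$fam)) {
    phi_sp <- p$phi[model$disp_idx]
    if (model$hurdle) aux$phi <- phi_sp  # applied to the positive part
    else aux$phi <- phi_sp
  }
  if (has_pi(model$fam)) aux$pi <- p$pi_zi
  if (model$fam$name == "ordered_beta") {
    aux$zeta2 <- p$zeta2
    z1 <- p$zeta2 - exp(p$zeta_gap)
    aux$zeta1 <- if (length(z1) == 1L) rep(z1, model$m) else z1
  }
  aux
}

# full loading matrix m x d, constrained columns first
full_gamma <- function(model, p) {
  G <- NULL
  if (model$dc > 0) G <- p$Gamma_c
  if (model$d0 > 0) G <- cbind(G, p$Gamma_u)
  G
}

# species coefficient matrix on the fixed (non-random-slope) covariates
full_beta <- function(model, p) {
  if (model$k == 0) return(NULL)
  if (model$spec$fourth_corner) return(NULL)  # handled separately
  B <- matrix(0, model$m, model$k)
  fixed_cols <- setdiff(seq_len(model$k),
                        if (is.null(model$slopes)) integer(0) else model$slopes$cols)
  if (length(fixed_cols) && !is.null(p$Beta_free)) B[, fixed_cols] <- p$Beta_free
  B
}

b_canon_current <- function(model, st) {
  if (model$dc == 0) return(NULL)
  if (model$spec$randomB == "none") st$params$B_canon else st$vstate$Bv_mean
}

# mean linear predictor and total variational variance per cell
eta_moments <- function(model, st) {
  sp <- model$spec; p <- st$params; v <- st$vstate
  n <- model$n; m <- model$m
  des <- model$design
  eta <- matrix(if (length(p$beta0) == 1L) p$beta0 else rep(p$beta0, each = n),
                n, m)
  vv <- matrix(0, n, m)
  if (model$p_row > 0) eta <- eta + as.vector(des$row_fixed %*% p$row_fixed)
  for (g in seq_len(model$n_row_blocks)) {
    blk <- des$row_random[[g]]
    eta <- eta + as.vector(blk$Z %*% v$row[[g]]$mean)
    avar <- if (!is.null(v$row[[g]]$L)) rowSums(v$row[[g]]$L^2) else
      v$row[[g]]$sd^2
    vv <- vv + as.vector(blk$Z %*% avar)
  }
  if (model$k > 0) {
    if (sp$fourth_corner) {
      Beta <- matrix(p$beta_common, m, model$k, byrow = TRUE)
      if (model$q > 0) Beta <- Beta + des$T %*% t(p$B_fourth)
      eta <- eta + des$X %*% t(Beta)
    } else {
      B <- full_beta(model, p)
      if (!is.null(B)) eta <- eta + des$X %*% t(B)
    }
    if (!is.null(model$slopes)) {
      Xr <- model$slopes$X_r
      eta <- eta + Xr %*% t(v$b_mean)
      vv <- vv + (Xr^2) %*% t(v$b_sd^2)
    }
  }
  Gam <- full_gamma(model, p)
  U <- NULL; covs <- list()
  if (model$dc > 0) {
    Bc <- b_canon_current(model, st)
    Uc <- des$X_lv %*% Bc
    if (sp$num_lv_c > 0) Uc <- Uc + v$eps_mean
    U <- Uc
    if (sp$num_lv_c > 0) {
      sc <- site_cov_array(v$eps_L, n, model$dc)
      covs$eps <- sc
      for (r in seq_len(model$dc)) for (s in seq_len(model$dc))
        vv <- vv + outer(sc$A[, r, s], Gam[, r] * Gam[, s])
    }
    if (sp$randomB != "none") {
      # q(B) diagonal: Var(x' B_col) = sum_l x_l^2 a_lr
      XA <- (des$X_lv^2) %*% (v$Bv_sd^2)  # n x dc
      for (r in seq_len(model$dc))
        vv <- vv + outer(XA[, r], Gam[, r]^2)
    }
  }
  if (model$d0 > 0) {
    off <- model$dc
    if (is.null(model$lv_struct)) {
      U <- cbind(U, v$U_mean)
      sc <- site_cov_array(v$U_L, n, model$d0)
      covs$U <- sc
      for (r in seq_len(model$d0)) for (s in seq_len(model$d0))
        vv <- vv + outer(sc$A[, r, s], Gam[, off + r] * Gam[, off + s])
    } else {
      Z <- model$lv_struct$Z
      U <- cbind(U, Z %*% v$Us_mean)
      Tn <- length(model$lv_struct$levels)
      Ls <- lapply(v$Us_L, ltri_from_vec, d = Tn)
      covs$Us <- Ls
      for (r in seq_len(model$d0)) {
        avar <- rowSums(Ls[[r]]^2)
        vv <- vv + outer(as.vector(Z %*% avar), Gam[, off + r]^2)
      }
    }
  }
  if (!is.null(U)) {
    eta <- eta + U %*% t(Gam)
    if (isTRUE(sp$quadratic)) {
      # E[u' D u] = sum_l D_l (m_l^2 + A_ll); Var via the delta expansion
      Avar <- matrix(0, n, model$d)
      if (model$dc > 0 && sp$num_lv_c > 0)
        for (r in seq_len(model$dc)) Avar[, r] <- covs$eps$A[, r, r]
      if (model$d0 > 0 && is.null(model$lv_struct))
        for (r in seq_len(model$d0))
          Avar[, model$dc + r] <- covs$U$A[, r, r]
      eta <- eta - (U^2 + Avar) %*% t(p$D_quad)
      # Var(gamma'u - u'Du) with gamma_tilde = gamma - 2 D m (per cell)
      vq <- matrix(0, n, m)
      for (r in seq_len(model$d)) {
        gt <- outer(-2 * U[, r], p$D_quad[, r]) +
          matrix(Gam[, r], n, m, byrow = TRUE)
        vq <- vq + gt^2 * Avar[, r] +
          2 * (Avar[, r]^2) * matrix(p$D_quad[, r]^2, n, m, byrow = TRUE)
      }
      vv <- vq  # diagonal-covariance approximation for quadratic models
    }
  }
  list(eta = eta, v = vv, U = U, covs = covs, Gam = Gam)
}

# ---- KL terms -------------------------------------------------------------

row_prior_matrix <- function(model, p, g) {
  blk <- model$design$row_random[[g]]
  s2 <- p[[paste0("row_var_", g)]]
  G <- length(blk$levels)
  if (blk$kind == "iid") return(list(diag = rep(s2, G)))
  raw <- p[[paste0("row_cor_", g)]]
  R <- switch(blk$kind,
    corAR1 = {
      rho <- tanh(raw)
      outer(blk$positions, blk$positions, function(a, b) rho^abs(a - b))
    },
    corCS = {
      lo <- -1 / (G - 1)
      rho <- lo + (1 - lo) * stats::plogis(raw)
      M <- matrix(rho, G, G); diag(M) <- 1; M
    },
    corExp = {
      D <- coord_dist(blk$coords)
      exp(-D / exp(raw))
    },
    corMatern = {
      D <- coord_dist(blk$coords)
      matern_correlation(D, exp(raw), 1.5)
    })
  list(full = s2 * R)
}

slope_prior <- function(model, p, l) {
  m_obs <- model$m
  s2 <- p$slope_var[l]
  ph <- model$slopes$phylo
  if (is.null(ph)) return(list(diag = rep(s2, m_obs)))
  rho <- if (ph$rho_struct == "term") p$phylo_rho[l] else p$phylo_rho[1]
  Sig <- phylo_covariance(ph$C, rho, s2)
  nnf <- nn_precision_approx(Sig, ordering = ph$ordering, nn = ph$nn, D = ph$D)
  list(Q = nn_precision_matrix(nnf), logdet = -nnf$logdet_Q)
}

kl_total <- function(model, st) {
  sp <- model$spec; p <- st$params; v <- st$vstate
  kl <- 0
  if (model$d0 > 0 && is.null(model$lv_struct)) {
    sc <- site_cov_array(v$U_L, model$n, model$d0)
    Lm <- matrix(v$U_L, model$n, lower_tri_count(model$d0))
    ldet <- 2 * rowSums(Lm[, diag_positions(model$d0), drop = FALSE])
    trA <- 0
    for (r in seq_len(model$d0)) trA <- trA + sc$A[, r, r]
    kl <- kl + 0.5 * sum(trA + rowSums(v$U_mean^2) - model$d0 - ldet)
  }
  if (model$d0 > 0 && !is.null(model$lv_struct)) {
    Tn <- length(model$lv_struct$levels)
    pos <- model$lv_struct$positions
    for (r in seq_len(model$d0)) {
      L <- ltri_from_vec(v$Us_L[[r]], Tn)
      rho <- p$rho_lv[r]
      Sig <- outer(pos, pos, function(a, b) rho^abs(a - b))
      kl <- kl + kl_gaussian(v$Us_mean[, r], tcrossprod(L), Sig)
    }
  }
  if (sp$num_lv_c > 0) {
    sc <- site_cov_array(v$eps_L, model$n, model$dc)
    Lm <- matrix(v$eps_L, model$n, lower_tri_count(model$dc))
    ldet <- 2 * rowSums(Lm[, diag_positions(model$dc), drop = FALSE])
    s2 <- p$sigma2_lv
    trA <- 0
    for (r in seq_len(model$dc)) trA <- trA + sc$A[, r, r] / s2[r]
    kl <- kl + 0.5 * sum(trA + rowSums(sweep(v$eps_mean^2, 2, s2, "/")) -
                           model$dc - ldet + sum(log(s2)))
  }
  if (model$dc > 0 && sp$randomB != "none") {
    pv <- randB_prior_var(model, p)  # k_lv x dc matrix of prior variances
    a <- v$Bv_sd^2
    kl <- kl + 0.5 * sum(a / pv + v$Bv_mean^2 / pv - 1 - log(a) + log(pv))
  }
  for (g in seq_len(model$n_row_blocks)) {
    pr <- row_prior_matrix(model, p, g)
    rb <- v$row[[g]]
    if (!is.null(pr$diag)) {
      a <- rb$sd^2
      kl <- kl + 0.5 * sum(a / pr$diag + rb$mean^2 / pr$diag - 1 -
                             log(a) + log(pr$diag))
    } else {
      kl <- kl + kl_gaussian(rb$mean, tcrossprod(rb$L), pr$full)
    }
  }
  if (!is.null(model$slopes)) {
    for (l in seq_len(model$slopes$k_r)) {
      pr <- slope_prior(model, p, l)
      a <- v$b_sd[, l]^2
      if (!is.null(pr$diag)) {
        kl <- kl + 0.5 * sum(a / pr$diag + v$b_mean[, l]^2 / pr$diag - 1 -
                               log(a) + log(pr$diag))
      } else {
        kl <- kl + kl_gaussian_diagq(v$b_mean[, l], a, pr$Q, pr$logdet)
      }
    }
  }
  kl
}

diag_positions <- function(d) {
  M <- matrix(seq_len(d * d), d, d)
  idx <- M[lower.tri(M, diag = TRUE)]
  match(M[cbind(seq_len(d), seq_len(d))], idx)
}

randB_prior_var <- function(model, p) {
  k_lv <- model$k_lv; dc <- model$dc
  switch(model$spec$randomB,
    LV = matrix(p$randB_var, k_lv, dc, byrow = TRUE),
    single = matrix(p$randB_var, k_lv, dc),
    P = outer(p$randB_var[dc + seq_len(k_lv)], p$randB_var[seq_len(dc)]))
}

# ---- objective ------------------------------------------------------------

elbo_value <- function(model, st, method = model$method) {
  mom <- eta_moments(model, st)
  E <- cell_expected_loglik(model, st, mom$eta, mom$v, method)
  sum(E[model$mask]) - kl_total(model, st)
}

cell_expected_loglik <- function(model, st, eta, vv, method) {
  aux <- aux_for_model(model, st$params)
  if (!model$hurdle)
    return(expected_loglik(model$fam, model$Y, eta, vv, method, aux))
  m0 <- model$m_obs
  pres <- seq_len(m0); pos <- m0 + pres
  E <- matrix(0, model$n, model$m)
  famp <- lo_family("bernoulli", "logit")
  famb <- lo_family("beta", "logit")
  E[, pres] <- expected_loglik(famp, model$Y[, pres], eta[, pres],
                               vv[, pres], "EVA", list())
  ypos <- model$Y[, pos]
  ypos[!model$mask[, pos]] <- 0.5  # placeholder; masked out of the sum
  E[, pos] <- expected_loglik(famb, ypos, eta[, pos], vv[, pos], "EVA",
                              list(phi = aux$phi))
  E
}

cell_grad <- function(model, st, eta, vv, method) {
  aux <- aux_for_model(model, st$params)
  if (!model$hurdle) {
    g <- expected_loglik_grad(model$fam, model$Y, eta, vv, method, aux)
  } else {
    m0 <- model$m_obs
    pres <- seq_len(m0); pos <- m0 + pres
    famp <- lo_family("bernoulli", "logit")
    famb <- lo_family("beta", "logit")
    g1 <- expected_loglik_grad(famp, model$Y[, pres], eta[, pres],
                               vv[, pres], "EVA", list())
    ypos <- model$Y[, pos]
    ypos[!model$mask[, pos]] <- 0.5
    g2 <- expected_loglik_grad(famb, ypos, eta[, pos], vv[, pos], "EVA",
                               list(phi = aux$phi))
    g <- list(deta = cbind(g1$deta, g2$deta), dv = cbind(g1$dv, g2$dv))
  }
  g$deta[!model$mask] <- 0
  g$dv[!model$mask] <- 0
  g
}
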