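#' Model specification for a latent-variable community model
#'
#' Collects everything that defines a GLLVM: the response family, the numbers
#' of unconstrained (\code{num_lv}), constrained (\code{num_RR}) and informed
#' (\code{num_lv_c}) latent variables, the three formula slots (full-rank
#' covariates, reduced-rank covariates, row effects), and optional structure:
#' quadratic latent terms, random canonical coefficients (\code{randomB}),
#' correlated latent variables (\code{lv_cor}), trait-based fourth-corner
#' terms, species random slopes, and phylogenetic settings.
#'
#' Constrained latent variables are fully determined by the reduced-rank
#' covariates, \eqn{u_i = B^\top x_i}; informed latent variables add a
#' residual, \eqn{u_i = B^\top x_i + \epsilon_i} (concurrent ordination);
#' unconstrained latent variables are free site scores.
#'
#' @param family an [lo_family()] or a family name string.
#' @param num_lv,num_RR,num_lv_c nonnegative latent-variable counts.
#' @param species_formula full-rank covariate formula (RHS only), e.g.
#'   \code{~ pH + moisture}.
#' @param lv_formula reduced-rank covariate formula for constrained/informed
#'   latent variables.
#' @param row_formula row-effect formula; supports fixed terms, random
#'   intercepts \code{(1|G)}, nesting \code{(1|A/B)}, and correlation
#'   wrappers \code{corAR1(1|G)}, \code{corCS(1|G)}, \code{corExp(1|G)},
#'   \code{corMatern(1|G)}.
#' @param quadratic if \code{TRUE}, adds species-specific negative quadratic
#'   latent terms (unimodal responses).
#' @param randomB \code{"none"}, \code{"LV"} (one variance per latent
#'   dimension), \code{"P"} (additional per-covariate variances), or
#'   \code{"single"} (one shared variance) for random canonical coefficients.
#' @param lv_cor optional correlation structure for the latent variables: a
#'   string like \code{"corAR1(1|YEAR)"} referring to a design column.
#' @param fourth_corner if \code{TRUE}, species covariate responses are
#'   modelled as \eqn{\beta_j = \beta_e + B_{et} t_j + b_j} using the trait
#'   table.
#' @param random_slopes character vector of covariate names whose
#'   species-specific effects \eqn{b_j} are random (implied for fourth-corner
#'   models; required for phylogenetic models).
#' @param phylo optional list \code{list(rho_struct = "term"|"single",
#'   nn = 10)} activating phylogenetically structured random slopes.
#' @param disp_groups optional integer vector mapping species to shared
#'   dispersion groups.
#' @param zeta_struc \code{"common"} or \code{"species"} ordered-beta cutoff
#'   structure (species-specific lower cutoff, common upper cutoff).
#' @param beta0com if \code{TRUE}, one intercept shared by all species.
#' @param link optional link override passed to [lo_family()].
#' @return an object of class \code{"lo_model_spec"}.
#' @export
lo_model_spec <- function(family, num_lv = 0L, num_RR = 0L, num_lv_c = 0L,
                          species_formula = NULL, lv_formula = NULL,
                          row_formula = NULL, quadratic = FALSE,
                          randomB = c("none", "LV", "P", "single"),
                          lv_cor = NULL, fourth_corner = FALSE,
                          random_slopes = NULL, phylo = NULL,
                          disp_groups = NULL,
                          zeta_struc = c("common", "species"),
                          beta0com = FALSE, link = NULL) {
  if (is.character(family)) family <- lo_family(family, link = link)
  randomB <- match.arg(randomB)
  zeta_struc <- match.arg(zeta_struc)
  if (num_lv < 0 || num_RR < 0 || num_lv_c < 0)
    stop("latent variable counts must be nonnegative")
  if (num_RR > 0 && num_lv_c > 0)
    stop("use either constrained (num_RR) or informed (num_lv_c) latent variables")
  if ((num_RR + num_lv_c) > 0 && is.null(lv_formula))
    stop("constrained/informed latent variables need an lv_formula")
  if (randomB != "none" && num_RR + num_lv_c == 0)
    stop("randomB requires constrained or informed latent variables")
  if (zeta_struc == "species" && family$name != "ordered_beta")
    stop("zeta_struc applies only to the ordered_beta family")
  if (!is.null(phylo)) {
    phylo$rho_struct <- match.arg(phylo$rho_struct %||% "single",
                                  c("single", "term"))
    phylo$nn <- phylo$nn %||% 10L
  }
  structure(list(family = family, num_lv = as.integer(num_lv),
                 num_RR = as.integer(num_RR), num_lv_c = as.integer(num_lv_c),
                 species_formula = species_formula, lv_formula = lv_formula,
                 row_formula = row_formula, quadratic = quadratic,
                 randomB = randomB, lv_cor = lv_cor,
                 fourth_corner = fourth_corner,
                 random_slopes = random_slopes, phylo = phylo,
                 disp_groups = disp_groups, zeta_struc = zeta_struc,
                 beta0com = beta0com),
            class = "lo_model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lo_model_spec <- function(x, ...) {
  cat(sprintf("<lo_model_spec> family %s (%s)\n", x$family$name,
              x$family$link))
  cat(sprintf("  latent variables: %d unconstrained, %d constrained, %d informed%s\n",
              x$num_lv, x$num_RR, x$num_lv_c,
              if (x$quadratic) " (quadratic)" else ""))
  if (!is.null(x$species_formula))
    cat("  covariates:", deparse(x$species_formula), "\n")
  if (!is.null(x$lv_formula))
    cat("  lv covariates:", deparse(x$lv_formula),
        if (x$randomB != "none") sprintf("(randomB = %s)", x$randomB) else "",
        "\n")
  if (!is.null(x$row_formula))
    cat("  row effects:", deparse(x$row_formula), "\n")
  invisible(x)
}

total_lv <- function(spec) spec$num_lv + spec$num_RR + spec$num_lv_c

# ---- formula parsing ------------------------------------------------------

# parse one row-effect formula into fixed terms plus random blocks;
# random blocks may be wrapped in correlation structures
parse_row_formula <- function(formula, design, coords = NULL) {
  if (is.null(formula)) return(list(fixed = NULL, random = list()))
  tl <- attr(stats::terms(formula), "term.labels")
  fixed_terms <- character(0)
  random <- list()
  for (lab in tl) {
    lab2 <- gsub("\\s+", " ", lab)
    cw <- regmatches(lab2, regexec(
      "^(corAR1|corCS|corExp|corMatern)\\((.+)\\)$", lab2))[[1]]
    kind <- "iid"
    inner <- lab2
    if (length(cw)) {
      kind <- cw[2]
      inner <- cw[3]
    }
    if (grepl("\\|", inner)) {
      parts <- strsplit(inner, "\\|")[[1]]
      lhs <- trimws(parts[1]); rhs <- trimws(parts[2])
      if (lhs != "1")
        stop("unsupported random term '", lab,
             "': only random intercepts '(1|group)' are supported")
      groups <- trimws(strsplit(rhs, "/")[[1]])
      miss <- setdiff(groups, colnames(design))
      if (length(miss))
        stop("group label(s) not found among design columns: ",
             paste(miss, collapse = ", "))
      if (length(groups) > 1 && kind != "iid")
        stop("correlation structures cannot wrap nested groupings")
      # nesting a/b expands to a plus a:b
      labels <- Reduce(function(acc, g) c(acc, paste(c(acc[length(acc)], g),
                                                     collapse = ":")),
                       groups[-1], groups[1])
      for (gl in labels) {
        cols <- strsplit(gl, ":")[[1]]
        fac <- interaction(design[cols], drop = TRUE, lex.order = TRUE)
        random[[length(random) + 1]] <- list(
          name = gl, kind = kind, factor = fac,
          levels = levels(fac))
      }
    } else if (kind != "iid") {
      stop("correlation wrappers must contain a random term '(1|group)': ", lab)
    } else {
      fixed_terms <- c(fixed_terms, lab2)
    }
  }
  fixed <- NULL
  if (length(fixed_terms)) {
    ff <- stats::reformulate(fixed_terms, intercept = FALSE)
    fixed <- stats::model.matrix(ff, data = design)
  }
  for (i in seq_along(random)) {
    b <- random[[i]]
    Z <- stats::model.matrix(~ 0 + b$factor)
    colnames(Z) <- b$levels
    random[[i]]$Z <- Z
    if (b$kind %in% c("corExp", "corMatern")) {
      if (is.null(coords))
        stop("spatial correlation structure '", b$kind,
             "' needs coordinates for the group levels")
      random[[i]]$coords <- coords
    }
    if (b$kind == "corAR1") {
      lv <- suppressWarnings(as.numeric(b$levels))
      random[[i]]$positions <- if (any(is.na(lv))) seq_along(b$levels) else lv
    }
  }
  list(fixed = fixed, random = random)
}

validate_formula_dialect <- function(formula) {
  if (is.null(formula)) return(invisible(TRUE))
  tl <- attr(stats::terms(formula), "term.labels")
  bad <- tl[grepl("\\|", tl)]
  if (length(bad))
    stop("random-effect syntax is not supported in this formula slot: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Parse model formulas against a dataset into design matrices
#'
#' Validates the specification and constructs the numeric design matrices:
#' full-rank covariates \code{X}, reduced-rank covariates \code{X_lv}, trait
#' matrix \code{T}, fixed and random row-effect blocks, and the observation
#' mask. Categorical covariates expand to treatment-contrast indicators with
#' the first level as reference; nesting \code{A/B} in row formulas expands
#' to blocks for \code{A} and \code{A:B}.
#'
#' @param spec an [lo_model_spec()].
#' @param data an [lo_dataset()].
#' @return a list of class \code{"lo_design"} with elements \code{X},
#'   \code{X_lv}, \code{T}, \code{row_fixed}, \code{row_random},
#'   \code{lv_groups}, \code{observed_mask}.
#' @export
parse_model <- function(spec, data) {
  stopifnot(inherits(spec, "lo_model_spec"), inherits(data, "lo_dataset"))
  check_support(spec$family, data$Y[data$observed_mask])
  Xdf <- data$X
  X <- NULL
  if (!is.null(spec$species_formula)) {
    validate_formula_dialect(spec$species_formula)
    if (is.null(Xdf)) stop("species_formula given but the dataset has no covariates")
    X <- stats::model.matrix(spec$species_formula, data = Xdf)
    X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  }
  X_lv <- NULL
  if (!is.null(spec$lv_formula)) {
    validate_formula_dialect(spec$lv_formula)
    if (is.null(Xdf)) stop("lv_formula given but the dataset has no covariates")
    X_lv <- stats::model.matrix(spec$lv_formula, data = Xdf)
    X_lv <- X_lv[, colnames(X_lv) != "(Intercept)", drop = FALSE]
    if (spec$num_RR + spec$num_lv_c > ncol(X_lv))
      stop("number of constrained/informed latent variables exceeds the ",
           "number of reduced-rank covariates")
  }
  design_df <- data$design %||% Xdf
  row <- parse_row_formula(spec$row_formula, design_df, data$coords)
  lv_groups <- NULL
  if (!is.null(spec$lv_cor)) {
    f <- stats::as.formula(paste("~", spec$lv_cor))
    pr <- parse_row_formula(f, design_df, data$coords)
    if (length(pr$random) != 1)
      stop("lv_cor must name exactly one correlation-wrapped grouping")
    lv_groups <- pr$random[[1]]
  }
  Tm <- NULL
  if (spec$fourth_corner || !is.null(spec$phylo)) {
    if (spec$fourth_corner) {
      if (is.null(data$traits)) stop("fourth-corner model needs a trait table")
      Tm <- stats::model.matrix(~ ., data = data$traits)
      Tm <- Tm[, colnames(Tm) != "(Intercept)", drop = FALSE]
    }
  }
  structure(list(X = X, X_lv = X_lv, T = Tm, row_fixed = row$fixed,
                 row_random = row$random, lv_groups = lv_groups,
                 observed_mask = data$observed_mask),
            class = "lo_design")
}

# ---- reduced-rank coefficients and the linear predictor -------------------

#' Reduced-rank (canonical) coefficient expansion
#'
#' Given canonical coefficients \code{B} (k x d) and species loadings
#' \code{Gamma} (m x d), returns the implied m x k species coefficient matrix
#' with row \eqn{j} equal to \eqn{(B \gamma_j)^\top}; its rank is at most d.
#'
#' @param B_canon k x d canonical coefficient matrix.
#' @param Gamma m x d loading matrix.
#' @return an m x k coefficient matrix of rank at most d.
#' @export
reduced_rank_coefficients <- function(B_canon, Gamma) {
  B_canon <- as.matrix(B_canon); Gamma <- as.matrix(Gamma)
  if (ncol(B_canon) != ncol(Gamma))
    stop("B_canon and Gamma must share the latent dimension d")
  Gamma %*% t(B_canon)
}

#' Assemble the linear predictor of a latent-variable community model
#'
#' Computes \eqn{\eta_{ij} = \alpha_i + \beta_{0j} + x_i^\top \beta_j +
#' u_i^\top \gamma_j - u_i^\top D_j u_i} (quadratic term only when the spec
#' asks for it). Latent variables are taken from \code{latents}:
#' unconstrained scores \code{U}, concurrent residuals \code{eps} (so that
#' \eqn{u_i = B^\top x_i + \epsilon_i}), row-effect values per random block,
#' and species random slopes \code{b}.
#'
#' @param spec an [lo_model_spec()].
#' @param params parameter list (see [lo_parameter_set()]).
#' @param design an \code{"lo_design"} from [parse_model()].
#' @param latents list with (as required) \code{U} (n x num_lv),
#'   \code{eps} (n x d_c), \code{row} (list of level-value vectors),
#'   \code{b} (m x k random slopes).
#' @return an n x m matrix of linear predictors.
#' @export
linear_predictor <- function(spec, params, design, latents = list()) {
  n <- nrow(design$observed_mask); m <- ncol(design$observed_mask)
  beta0 <- params$beta0
  if (length(beta0) == 1L) beta0 <- rep(beta0, m)
  eta <- matrix(beta0, n, m, byrow = TRUE)
  if (!is.null(design$row_fixed) && !is.null(params$row_fixed))
    eta <- eta + as.vector(design$row_fixed %*% params$row_fixed)
  if (length(design$row_random)) {
    if (is.null(latents$row))
      stop("model has random row effects but no row latent values supplied")
    for (g in seq_along(design$row_random))
      eta <- eta + as.vector(design$row_random[[g]]$Z %*% latents$row[[g]])
  }
  if (!is.null(design$X)) {
    Beta <- species_coefficients(spec, params, design, latents)
    eta <- eta + design$X %*% t(Beta)
  }
  U <- latent_scores(spec, params, design, latents)
  if (!is.null(U)) {
    eta <- eta + U %*% t(params$Gamma)
    if (isTRUE(spec$quadratic)) {
      if (is.null(params$D_quad))
        stop("quadratic model needs nonnegative quadratic coefficients D_quad")
      eta <- eta - (U^2) %*% t(params$D_quad)
    }
  }
  eta
}

# m x k species coefficient matrix, including fourth-corner structure
species_coefficients <- function(spec, params, design, latents = list()) {
  m <- ncol(design$observed_mask); k <- ncol(design$X)
  if (spec$fourth_corner) {
    Beta <- matrix(params$beta_common, m, k, byrow = TRUE)
    if (!is.null(params$B_fourth) && !is.null(design$T))
      Beta <- Beta + design$T %*% t(params$B_fourth)
    if (!is.null(latents$b)) Beta <- Beta + latents$b
    Beta
  } else if (!is.null(spec$random_slopes) && !is.null(latents$b)) {
    Beta <- params$Beta %||% matrix(0, m, k)
    Beta + latents$b
  } else {
    params$Beta
  }
}

# n x d matrix of latent variable values (NULL if the model has none)
latent_scores <- function(spec, params, design, latents = list()) {
  cols <- list()
  dc <- spec$num_RR + spec$num_lv_c
  if (dc > 0) {
    Uc <- design$X_lv %*% params$B_canon
    if (spec$num_lv_c > 0) {
      if (is.null(latents$eps))
        stop("concurrent ordination needs residual latent values 'eps'")
      Uc <- Uc + latents$eps
    }
    cols$constrained <- Uc
  }
  if (spec$num_lv > 0) {
    if (!is.null(design$lv_groups)) {
      if (is.null(latents$U))
        stop("structured latent variables need group-level scores 'U'")
      cols$free <- design$lv_groups$Z %*% latents$U
    } else {
      if (is.null(latents$U))
        stop("unconstrained latent variables need site scores 'U'")
      cols$free <- latents$U
    }
  }
  if (!length(cols)) return(NULL)
  do.call(cbind, cols)
}

#' Parameter set constructor
#'
#' A light container for all estimable quantities of the model; unused slots
#' stay \code{NULL}. See the fields of the returned list.
#'
#' @param beta0 species intercepts (length m, or 1 if shared).
#' @param Beta m x k species covariate coefficients.
#' @param beta_common length-k community-level effects (fourth corner).
#' @param B_fourth k x q fourth-corner interaction matrix.
#' @param B_canon k_lv x d canonical coefficients.
#' @param Gamma m x d species loadings.
#' @param D_quad m x d nonnegative quadratic coefficients.
#' @param sigma2_lv length-d residual variances of informed latent variables.
#' @param phi dispersion parameters (per species or per dispersion group).
#' @param pi_zi zero-inflation probabilities in \code{[0,1]}.
#' @param zeta1,zeta2 ordered-beta cutoffs, \code{zeta1 < zeta2}.
#' @param row_fixed fixed row-effect coefficients.
#' @param row_var random row-effect variances (one per block).
#' @param row_cor correlation parameters of structured row blocks.
#' @param Sigma_b covariance of species random slopes (diagonal as variances).
#' @param rho_lv AR1 parameters of structured latent variables.
#' @param rho_phylo phylogenetic signal(s) in \code{[0,1]}.
#' @param sigma2_phylo per-covariate phylogenetic scales.
#' @return a list of class \code{"lo_parameter_set"}.
#' @export
lo_parameter_set <- function(beta0 = NULL, Beta = NULL, beta_common = NULL,
                             B_fourth = NULL, B_canon = NULL, Gamma = NULL,
                             D_quad = NULL, sigma2_lv = NULL, phi = NULL,
                             pi_zi = NULL, zeta1 = NULL, zeta2 = NULL,
                             row_fixed = NULL, row_var = NULL, row_cor = NULL,
                             Sigma_b = NULL, rho_lv = NULL, rho_phylo = NULL,
                             sigma2_phylo = NULL) {
  out <- list(beta0 = beta0, Beta = Beta, beta_common = beta_common,
              B_fourth = B_fourth, B_canon = B_canon, Gamma = Gamma,
              D_quad = D_quad, sigma2_lv = sigma2_lv, phi = phi,
              pi_zi = pi_zi, zeta1 = zeta1, zeta2 = zeta2,
              row_fixed = row_fixed, row_var = row_var, row_cor = row_cor,
              Sigma_b = Sigma_b, rho_lv = rho_lv, rho_phylo = rho_phylo,
              sigma2_phylo = sigma2_phylo)
  if (!is.null(out$D_quad) && any(out$D_quad < 0))
    stop("quadratic coefficients must be nonnegative")
  if (!is.null(out$pi_zi) && any(out$pi_zi < 0 | out$pi_zi > 1))
    stop("zero-inflation probabilities must lie in [0,1]")
  if (!is.null(out$phi) && any(out$phi <= 0))
    stop("dispersion parameters must be positive")
  class(out) <- "lo_parameter_set"
  out
}

# ---- free-parameter accounting -------------------------------------------

# auxiliary parameter vectors per species: 0 for poisson/bernoulli,
# 1 for gaussian/negbin/zip/beta, 2 for zinb
n_aux_vectors <- function(family) {
  switch(family$name,
    poisson = , bernoulli = 0L,
    gaussian = , negbin = , zip = , beta = , hurdle_beta = 1L,
    zinb = 2L,
    ordered_beta = 1L)
}

#' Count freely estimated parameters
#'
#' Returns the degrees of freedom of a model: the number of freely estimated
#' parameters after identifiability constraints. For a full-rank multivariate
#' GLM this is \eqn{m (k + 1)} (plus auxiliaries). For constrained or
#' concurrent ordination with d latent dimensions and k reduced-rank
#' covariates, the latent part contributes \eqn{k d + d m - d(d-1)}: the
#' canonical coefficients carry \eqn{d(d+1)/2} normalization constraints
#' (upper triangle including the diagonal of the leading d x d block), the
#' loadings carry \eqn{d(d-1)/2} (upper triangle zero), and the d residual
#' variances of informed latent variables are free, which nets out to the
#' \eqn{-d(d-1)} constraint total. Unconstrained latent variables contribute
#' \eqn{d_0 m - d_0(d_0-1)/2}.
#'
#' @param spec an [lo_model_spec()].
#' @param n number of sites.
#' @param m number of species.
#' @param k number of full-rank covariate columns (defaults from the spec's
#'   formula when a design is supplied).
#' @param k_lv number of reduced-rank covariate columns.
#' @param q number of trait columns (fourth-corner models).
#' @param design optional \code{"lo_design"}; when given, \code{k},
#'   \code{k_lv}, \code{q} and row-effect dimensions are taken from it.
#' @return integer degrees of freedom.
#' @export
count_free_parameters <- function(spec, n, m, k = 0L, k_lv = 0L, q = 0L,
                                  design = NULL) {
  if (!is.null(design)) {
    k <- if (is.null(design$X)) 0L else ncol(design$X)
    k_lv <- if (is.null(design$X_lv)) 0L else ncol(design$X_lv)
    q <- if (is.null(design$T)) 0L else ncol(design$T)
  }
  fam <- spec$family
  df <- if (spec$beta0com) 1L else m
  # auxiliary parameters
  s <- n_aux_vectors(fam)
  n_phi <- if (!is.null(spec$disp_groups)) length(unique(spec$disp_groups)) else m
  if (fam$name %in% c("gaussian", "negbin", "beta", "hurdle_beta",
                      "ordered_beta")) df <- df + n_phi
  if (fam$name == "zip") df <- df + m
  if (fam$name == "zinb") df <- df + n_phi + m
  if (fam$name == "ordered_beta")
    df <- df + if (spec$zeta_struc == "species") m + 1L else 2L
  # full-rank covariate part
  if (k > 0) {
    if (spec$fourth_corner) {
      df <- df + k + k * q  # community effects + fourth-corner matrix
      if (!is.null(spec$phylo)) {
        df <- df + k  # per-covariate phylo scales sigma_l^2
        df <- df + if (spec$phylo$rho_struct == "term") k else 1L
      } else if (!is.null(spec$random_slopes) || spec$fourth_corner) {
        df <- df + k  # diagonal random-slope variances
      }
    } else if (!is.null(spec$random_slopes)) {
      nr <- length(spec$random_slopes)
      df <- df + (k - nr) * m  # fixed coefficients for the remaining covariates
      df <- df + nr            # random-slope means are predicted, variances counted
      if (!is.null(spec$phylo)) {
        df <- df + if (spec$phylo$rho_struct == "term") nr else 1L
      }
    } else {
      df <- df + k * m
    }
  }
  # constrained / informed latent part
  d_c <- spec$num_RR + spec$num_lv_c
  if (d_c > 0) {
    if (spec$randomB == "none") {
      df <- df + k_lv * d_c - d_c * (d_c + 1L) / 2L
    } else {
      df <- df + switch(spec$randomB, LV = d_c, P = d_c + k_lv, single = 1L)
    }
    df <- df + m * d_c - d_c * (d_c - 1L) / 2L  # loadings, upper tri zero
    if (spec$num_lv_c > 0 && spec$randomB == "none")
      df <- df + d_c  # residual LV variances
  }
  # unconstrained latent part
  if (spec$num_lv > 0) {
    d0 <- spec$num_lv
    df <- df + m * d0 - d0 * (d0 - 1L) / 2L
    if (!is.null(spec$lv_cor)) df <- df + d0  # one correlation per LV
  }
  if (isTRUE(spec$quadratic)) df <- df + m * total_lv(spec)
  # row effects: fixed columns, plus one variance (and possibly one
  # correlation parameter) per random block
  if (!is.null(spec$row_formula)) {
    if (!is.null(design)) {
      if (!is.null(design$row_fixed)) df <- df + ncol(design$row_fixed)
      for (b in design$row_random)
        df <- df + 1L + if (b$kind != "iid") 1L else 0L
    } else {
      df <- df + row_formula_df(spec$row_formula)
    }
  }
  as.integer(round(df))
}

# spec-only fallback: one column per fixed term label, one variance
# (plus one correlation parameter) per random block
row_formula_df <- function(formula) {
  tl <- attr(stats::terms(formula), "term.labels")
  nr <- 0L
  for (lab in tl) {
    if (grepl("\\|", lab)) {
      inner <- sub("^(corAR1|corCS|corExp|corMatern)\\((.+)\\)$", "\\2", lab)
      rhs <- trimws(strsplit(inner, "\\|")[[1]][2])
      nblocks <- length(strsplit(rhs, "/")[[1]])
      has_cor <- grepl("^(corAR1|corCS|corExp|corMatern)\\(", lab)
      nr <- nr + nblocks + if (has_cor) 1L else 0L
    } else {
      nr <- nr + 1L
    }
  }
  nr
}
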