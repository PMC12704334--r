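#' Scenario description for the community-data simulator
#'
#' Defines a generative latent-variable community model: dimensions, family
#' with auxiliaries, effect scales, an optional nested sampling design with
#' AR1 temporal structure, a target zero fraction for sparse cover data,
#' and optional phylogeny settings.
#'
#' @param n,m,k,d sites, species, covariates, latent dimensions.
#' @param family family name (see [lo_family()]); \code{link} optional.
#' @param beta_sd scale of species covariate coefficients.
#' @param gamma_sd scale of species loadings.
#' @param intercept_mean,intercept_sd species intercept distribution.
#' @param phi dispersion (family-specific; see [lo_family()]).
#' @param pi_zi zero-inflation probability for zip/zinb.
#' @param q number of traits (0 disables the fourth-corner term).
#' @param fourth_sd scale of fourth-corner interaction entries.
#' @param design optional list \code{list(sites, transects, years,
#'   rho)}: a nested site/transect design observed over years, with random
#'   site and transect intercepts and AR1 latent variables over years.
#' @param row_sd standard deviations (site, transect) of the nested random
#'   row effects.
#' @param zero_target expected zero fraction for the ordered-beta family;
#'   the lower cutoff is tuned by bisection against the Monte-Carlo zero
#'   rate.
#' @param x_cor pairwise correlation between covariates (multicollinearity
#'   knob).
#' @param tree logical: draw a random phylogeny and phylogenetically
#'   structured random slopes.
#' @param rho_phylo phylogenetic signal used when \code{tree = TRUE}.
#' @param slope_sd scale (sd) of species random slopes.
#' @param seed integer seed.
#' @return a list of class \code{"lo_scenario"}.
#' @export
lo_scenario <- function(n = 100, m = 20, k = 2, d = 2, family = "poisson",
                        link = NULL, beta_sd = 0.5, gamma_sd = 0.7,
                        intercept_mean = 0, intercept_sd = 0.5, phi = 1,
                        pi_zi = 0.2, q = 0, fourth_sd = 0.5,
                        design = NULL, row_sd = c(0.5, 0.3),
                        zero_target = NULL, x_cor = 0, tree = FALSE,
                        rho_phylo = 0.8, slope_sd = 0.4, seed = 1L) {
  stopifnot(n > 0, m > 0, k >= 0, d >= 0)
  if (!is.null(zero_target) && (zero_target < 0 || zero_target >= 1))
    stop("zero_target must lie in [0, 1)")
  structure(as.list(environment()), class = "lo_scenario")
}

#' Generate a synthetic community dataset with known truth
#'
#' Draws covariates (standard normal, optionally correlated), latent
#' variables from their declared structure (AR1 over years under a nested
#' design), random row effects, species random slopes (phylogenetically
#' structured when a tree is requested), assembles the linear predictor,
#' and simulates responses through the family's generative model. Fully
#' reproducible given the scenario seed.
#'
#' @param scenario an [lo_scenario()].
#' @return list with \code{data} (an [lo_dataset()]), \code{params} (true
#'   parameter values), \code{latents} (true latent values), \code{eta}
#'   (true linear predictor), and \code{spec} (a matching [lo_model_spec()]).
#' @export
generate_dataset <- function(scenario) {
  sc <- scenario
  set.seed(sc$seed)
  nested <- !is.null(sc$design)
  if (nested) {
    ns <- sc$design$sites; nt <- sc$design$transects; ny <- sc$design$years
    layout <- expand.grid(TRANSECT = seq_len(nt), YEAR = seq_len(ny) - 1L)
    layout$SITE <- ((layout$TRANSECT - 1L) %% ns) + 1L
    n <- nrow(layout)
  } else {
    n <- sc$n
  }
  m <- sc$m; k <- sc$k; d <- sc$d
  X <- NULL
  if (k > 0) {
    X <- matrix(stats::rnorm(n * k), n, k)
    if (sc$x_cor != 0) {
      R <- matrix(sc$x_cor, k, k); diag(R) <- 1
      X <- X %*% chol(R)
    }
    colnames(X) <- paste0("x", seq_len(k))
  }
  beta0 <- stats::rnorm(m, sc$intercept_mean, sc$intercept_sd)
  fam <- lo_family(sc$family, sc$link)
  eta <- matrix(beta0, n, m, byrow = TRUE)
  latents <- list()
  params <- list(beta0 = beta0)
  traits <- NULL
  if (k > 0) {
    if (sc$q > 0) {
      traits <- matrix(stats::rnorm(m * sc$q), m, sc$q,
                       dimnames = list(NULL, paste0("t", seq_len(sc$q))))
      beta_common <- stats::rnorm(k, 0, sc$beta_sd)
      B_fourth <- matrix(stats::rnorm(k * sc$q, 0, sc$fourth_sd), k, sc$q)
      b <- matrix(stats::rnorm(m * k, 0, sc$slope_sd), m, k)
      Beta <- matrix(beta_common, m, k, byrow = TRUE) +
        traits %*% t(B_fourth) + b
      params$beta_common <- beta_common
      params$B_fourth <- B_fourth
      latents$b <- b
    } else if (isTRUE(sc$tree)) {
      rt <- random_tree(m, seed = sc$seed + 1L)
      b <- matrix(0, m, k)
      for (l in seq_len(k)) {
        Sig <- phylo_covariance(rt$C, sc$rho_phylo, sc$slope_sd^2)
        b[, l] <- as.vector(t(chol(Sig)) %*% stats::rnorm(m))
      }
      Beta <- b
      latents$b <- b
      params$rho_phylo <- sc$rho_phylo
      params$tree <- rt$tree
    } else {
      Beta <- matrix(stats::rnorm(m * k, 0, sc$beta_sd), m, k)
    }
    params$Beta <- Beta
    eta <- eta + X %*% t(Beta)
  }
  row_labels <- NULL
  if (nested) {
    a_site <- stats::rnorm(sc$design$sites, 0, sc$row_sd[1])
    a_tran <- stats::rnorm(sc$design$transects, 0, sc$row_sd[2])
    eta <- eta + a_site[layout$SITE] + a_tran[layout$TRANSECT]
    latents$row <- list(site = a_site, transect = a_tran)
    row_labels <- data.frame(SITE = factor(layout$SITE),
                             TRANSECT = factor(layout$TRANSECT),
                             YEAR = layout$YEAR)
  }
  if (d > 0) {
    Gamma <- matrix(stats::rnorm(m * d, 0, sc$gamma_sd), m, d)
    Gamma[upper.tri(Gamma)] <- 0
    params$Gamma <- Gamma
    if (nested && !is.null(sc$design$rho)) {
      ny <- sc$design$years
      Uy <- matrix(0, ny, d)
      for (r in seq_len(d)) {
        S <- outer(0:(ny - 1), 0:(ny - 1),
                   function(a, b) sc$design$rho^abs(a - b))
        Uy[, r] <- as.vector(t(chol(S)) %*% stats::rnorm(ny))
      }
      U <- Uy[layout$YEAR + 1L, , drop = FALSE]
      latents$U_year <- Uy
      params$rho_lv <- rep(sc$design$rho, d)
    } else {
      U <- matrix(stats::rnorm(n * d), n, d)
    }
    latents$U <- U
    eta <- eta + U %*% t(Gamma)
  }
  aux <- list()
  if (has_phi(fam)) aux$phi <- sc$phi
  if (has_pi(fam)) aux$pi <- sc$pi_zi
  if (fam$name == "ordered_beta") {
    z2 <- 6
    z1 <- if (!is.null(sc$zero_target))
      tune_zeta1(eta, z2, sc$phi, sc$zero_target) else 0
    aux$zeta1 <- z1; aux$zeta2 <- z2
    params$zeta1 <- z1; params$zeta2 <- z2
  }
  params$aux <- aux
  Y <- if (fam$name == "hurdle_beta")
    simulate_hurdle_beta(eta, eta, sc$phi) else
      simulate_response(fam, eta, aux)
  dimnames(Y) <- list(paste0("site", seq_len(n)), paste0("sp", seq_len(m)))
  if (!is.null(traits)) rownames(traits) <- colnames(Y)
  dat <- lo_dataset(Y, X = X, traits = traits, design = row_labels,
                    tree = params$tree)
  spec <- scenario_spec(sc)
  list(data = dat, params = params, latents = latents, eta = eta,
       spec = spec)
}

# bisection on the ordered-beta lower cutoff against the zero rate
tune_zeta1 <- function(eta, zeta2, phi, target, tol = 0.002) {
  zero_rate <- function(z1) mean(1 - stats::plogis(eta - z1))
  lo <- min(eta) - 20; hi <- zeta2 - 1e-3
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    if (zero_rate(mid) < target) lo <- mid else hi <- mid
    if (abs(zero_rate(mid) - target) < tol) break
  }
  (lo + hi) / 2
}

scenario_spec <- function(sc) {
  nested <- !is.null(sc$design)
  lo_model_spec(
    sc$family, link = sc$link,
    num_lv = sc$d,
    species_formula = if (sc$k > 0)
      stats::reformulate(paste0("x", seq_len(sc$k))) else NULL,
    row_formula = if (nested) ~ (1 | SITE) + (1 | TRANSECT) else NULL,
    lv_cor = if (nested && !is.null(sc$design$rho) && sc$d > 0)
      "corAR1(1|YEAR)" else NULL,
    fourth_corner = sc$q > 0,
    random_slopes = if (sc$k > 0 && isTRUE(sc$tree))
      paste0("x", seq_len(sc$k)) else NULL,
    phylo = if (isTRUE(sc$tree)) list(rho_struct = "single", nn = 10) else NULL)
}

#' Beetle-like scenario: overdispersed, zero-inflated counts, many covariates
#'
#' Emulates the structure of a ground-beetle community survey: 87 sites,
#' 68 species, 17 scaled environmental covariates, zero-inflated negative
#' binomial counts.
#'
#' @param seed integer seed.
#' @param family count family, default \code{"zinb"}.
#' @return an [lo_scenario()].
#' @export
beetle_like_scenario <- function(seed = 1L, family = "zinb") {
  lo_scenario(n = 87, m = 68, k = 17, d = 2, family = family,
              beta_sd = 0.3, gamma_sd = 0.8, intercept_mean = 0.5,
              intercept_sd = 1, phi = 1, pi_zi = 0.25, seed = seed)
}

#' Kelp-like scenario: sparse percent cover under a nested design
#'
#' Emulates a kelp-forest monitoring design: 44 transects nested in 11
#' sites observed over 21 years, ordered-beta percent cover with the lower
#' cutoff tuned so that about 88 percent of records are zeros, and AR1
#' latent variables over years.
#'
#' @param seed integer seed.
#' @param m number of species (default 30, scaled down from the full
#'   community for tractable fitting).
#' @return an [lo_scenario()].
#' @export
kelp_like_scenario <- function(seed = 1L, m = 30) {
  lo_scenario(m = m, k = 2, d = 2, family = "ordered_beta", phi = 4,
              beta_sd = 0.2, gamma_sd = 0.6, intercept_mean = -1,
              intercept_sd = 0.7,
              design = list(sites = 11, transects = 44, years = 21,
                            rho = 0.9),
              zero_target = 0.88, seed = seed)
}

#' Random phylogeny with correlation and distance matrices
#'
#' @param m number of tips (species), at least 2.
#' @param seed integer seed.
#' @return list with \code{tree}, \code{C} (Brownian correlation), \code{D}
#'   (cophenetic distance).
#' @export
random_tree <- function(m, seed = 1L) {
  stopifnot(m >= 2)
  set.seed(seed)
  tree <- ape::rtree(m, tip.label = paste0("sp", seq_len(m)))
  tc <- tree_to_correlation(tree)
  ord <- paste0("sp", seq_len(m))
  list(tree = tc$tree, C = tc$C[ord, ord], D = tc$D[ord, ord])
}
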