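#' Correlation structure for latent variables, row effects, or species
#'
#' Describes a parametric correlation structure over ordered levels (time),
#' coordinates (space), or a phylogeny. Used as the prior correlation of
#' structured latent variables and random row effects.
#'
#' @param kind one of \code{"AR1"}, \code{"CS"}, \code{"Exp"},
#'   \code{"Matern"}, \code{"phylo"}.
#' @param params named list of parameters: \code{rho} for AR1/CS and the
#'   phylogenetic signal, \code{range} (and optionally \code{smoothness},
#'   default 1.5) for Exp/Matern, \code{sigma2} for the phylo scale.
#' @param index for AR1/CS: an ordered vector of level positions (e.g. years
#'   0..20; unequal spacing maps AR1 to \eqn{\rho^{\Delta t}}); for Exp/Matern:
#'   a matrix of coordinates (rows = levels); for phylo: species ordering.
#' @param nn neighbour count for the phylogenetic nearest-neighbour
#'   approximation.
#' @return an object of class \code{"lo_corstruct"}.
#' @export
lo_corstruct <- function(kind, params = list(), index = NULL, nn = NULL) {
  kind <- match.arg(kind, c("AR1", "CS", "Exp", "Matern", "phylo"))
  structure(list(kind = kind, params = params, index = index, nn = nn),
            class = "lo_corstruct")
}

#' Build a positive-definite correlation matrix from a structure
#'
#' AR1 gives the Toeplitz matrix \eqn{[\rho^{|t_i - t_j|}]}; CS has unit
#' diagonal and \eqn{\rho} off-diagonal; Exp gives
#' \eqn{\exp(-d_{ij}/\mathrm{range})}; Matern uses the standard Matérn
#' correlation at the stated smoothness (default 1.5). All have unit diagonal.
#'
#' @param struct an [lo_corstruct()] object (not \code{kind = "phylo"};
#'   phylogenetic covariances are built by [phylo_covariance()]).
#' @return a T x T positive-definite correlation matrix.
#' @export
build_correlation <- function(struct) {
  stopifnot(inherits(struct, "lo_corstruct"))
  p <- struct$params
  switch(struct$kind,
    AR1 = {
      t <- struct$index
      if (is.null(t)) stop("AR1 needs ordered level positions in 'index'")
      rho <- p$rho
      if (abs(rho) >= 1) stop("AR1 rho must lie in (-1, 1)")
      outer(t, t, function(a, b) rho^abs(a - b))
    },
    CS = {
      t <- struct$index
      if (is.null(t)) stop("CS needs the level set in 'index'")
      T <- length(t)
      rho <- p$rho
      if (rho >= 1 || rho <= -1 / (T - 1))
        stop("CS rho must lie in (-1/(T-1), 1)")
      M <- matrix(rho, T, T); diag(M) <- 1
      M
    },
    Exp = {
      D <- coord_dist(struct$index)
      if (p$range <= 0) stop("Exp range must be positive")
      exp(-D / p$range)
    },
    Matern = {
      D <- coord_dist(struct$index)
      if (p$range <= 0) stop("Matern range must be positive")
      nu <- if (is.null(p$smoothness)) 1.5 else p$smoothness
      matern_correlation(D, p$range, nu)
    },
    stop("build_correlation does not handle kind '", struct$kind,
         "'; use phylo_covariance()"))
}

coord_dist <- function(coords) {
  if (is.null(coords)) stop("spatial structures need coordinates in 'index'")
  coords <- as.matrix(coords)
  as.matrix(stats::dist(coords))
}

matern_correlation <- function(D, range, nu) {
  x <- sqrt(2 * nu) * D / range
  out <- if (nu == 0.5) {
    exp(-x)
  } else if (nu == 1.5) {
    (1 + x) * exp(-x)
  } else if (nu == 2.5) {
    (1 + x + x^2 / 3) * exp(-x)
  } else {
    M <- 2^(1 - nu) / gamma(nu) * x^nu * besselK(x, nu)
    M[x == 0] <- 1
    M
  }
  out[D == 0] <- 1
  out
}

#' Phylogenetic random-effect covariance
#'
#' For a covariate with phylogenetic signal \eqn{\rho \in [0,1]} and scale
#' \eqn{\sigma^2 > 0}, the species random slopes have covariance
#' \deqn{\sigma^2 [ C \rho + (1 - \rho) I ],}
#' interpolating between independence (\eqn{\rho = 0}) and the full
#' Brownian-motion correlation \eqn{C} (\eqn{\rho = 1}).
#'
#' @param C m x m phylogenetic correlation matrix, unit diagonal.
#' @param rho phylogenetic signal in \code{[0, 1]}.
#' @param sigma2 positive scale.
#' @return an m x m covariance matrix.
#' @export
phylo_covariance <- function(C, rho, sigma2) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (rho < 0 || rho > 1) stop("phylogenetic signal rho must lie in [0, 1]")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  sigma2 * (rho * C + (1 - rho) * diag(nrow(C)))
}

#' Correlation and distance matrices from a phylogeny
#'
#' Computes the Brownian-motion correlation matrix (shared branch length to
#' the root, scaled to unit diagonal) and the cophenetic distance matrix of a
#' tree. A taxonomic classification table can be supplied instead of a tree;
#' it is converted to a tree with unit-length edges per rank via
#' [taxonomy_to_tree()].
#'
#' @param tree an [ape::phylo] tree with uniquely labelled tips, or a
#'   data frame of taxonomic ranks (rows = species, ordered coarse to fine,
#'   with species labels as row names).
#' @param species optional character vector of species that must be present;
#'   mismatches raise an error listing the missing names.
#' @return a list with \code{C} (correlation), \code{D} (cophenetic
#'   distance), and \code{tree}.
#' @export
tree_to_correlation <- function(tree, species = NULL) {
  if (is.data.frame(tree)) tree <- taxonomy_to_tree(tree)
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object or taxonomy table")
  if (anyDuplicated(tree$tip.label)) stop("tree tips must be uniquely labelled")
  if (!is.null(species)) {
    miss <- setdiff(species, tree$tip.label)
    if (length(miss))
      stop("species missing from the tree: ", paste(miss, collapse = ", "))
    tree <- ape::keep.tip(tree, species)
  }
  V <- ape::vcv(tree)
  C <- stats::cov2cor(V)
  D <- ape::cophenetic.phylo(tree)
  ord <- tree$tip.label
  list(C = C[ord, ord], D = D[ord, ord], tree = tree)
}

#' Convert a taxonomic classification to a tree with unit rank edges
#'
#' Each taxonomic rank contributes one unit of branch length, so species
#' sharing finer ranks are more strongly correlated under Brownian motion.
#'
#' @param tax data frame of ranks (columns ordered coarse to fine); row names
#'   are the species labels.
#' @return an [ape::phylo] tree.
#' @export
taxonomy_to_tree <- function(tax) {
  stopifnot(is.data.frame(tax), nrow(tax) >= 2)
  sp <- rownames(tax)
  if (is.null(sp)) stop("taxonomy table needs species row names")
  # build(rows, depth) returns a newick subtree whose root edge is the unit
  # edge of rank depth-1; a singleton tip absorbs all remaining rank units
  # plus one tip unit, keeping tips equidistant from the root
  build <- function(rows, depth) {
    if (length(rows) == 1L)
      return(paste0(sp[rows], ":", ncol(tax) - depth + 3))
    if (depth > ncol(tax))
      return(paste0("(", paste0(sp[rows], ":1", collapse = ","), "):1"))
    groups <- split(rows, as.character(tax[rows, depth]))
    subs <- vapply(groups, function(g) build(g, depth + 1), character(1))
    if (length(subs) == 1L) {
      # a rank with a single group: merge its unit into the child edge
      len <- as.numeric(sub("^.*:([0-9.]+)$", "\\1", subs))
      return(sub(":[0-9.]+$", paste0(":", len + 1), subs))
    }
    paste0("(", paste(subs, collapse = ","), "):1")
  }
  txt <- build(seq_len(nrow(tax)), 1L)
  if (!startsWith(txt, "(")) txt <- paste0("(", txt, ")")
  tr <- ape::read.tree(text = paste0(txt, ";"))
  tr
}

#' Nearest-neighbour sparse approximation to an inverse covariance
#'
#' Vecchia-style approximation: under the given species ordering, each
#' variable conditions on at most \code{nn} of its predecessors (the most
#' correlated ones, or nearest by \code{D} if supplied). The implied
#' precision is \eqn{Q = (I - B)^\top D_c^{-1} (I - B)} with strictly
#' lower-triangular conditioning weights \code{B} and conditional variances
#' \code{d}. With \code{nn = m - 1} the factorization is exact and
#' \eqn{Q = C^{-1}}.
#'
#' @param C m x m positive-definite covariance/correlation matrix.
#' @param ordering permutation of \code{1:m} (e.g. species ordered by
#'   distance from the root); default identity.
#' @param nn neighbour count, \code{1 <= nn <= m - 1}.
#' @param D optional distance matrix used to pick neighbours.
#' @return an object of class \code{"lo_nnfactor"} with elements \code{B},
#'   \code{d}, \code{ordering}, \code{logdet_Q}, and the implied precision
#'   accessible via [nn_precision_matrix()].
#' @export
nn_precision_approx <- function(C, ordering = seq_len(nrow(C)), nn, D = NULL) {
  m <- nrow(C)
  if (nn < 1 || nn > m - 1) stop("nn must lie in [1, m-1]")
  if (length(ordering) != m || anyDuplicated(ordering))
    stop("ordering must be a permutation of 1:m")
  Co <- C[ordering, ordering, drop = FALSE]
  Do <- if (!is.null(D)) D[ordering, ordering, drop = FALSE] else NULL
  B <- matrix(0, m, m)
  d <- numeric(m)
  d[1] <- Co[1, 1]
  for (i in seq_len(m)[-1]) {
    prev <- seq_len(i - 1)
    if (length(prev) > nn) {
      score <- if (is.null(Do)) -abs(Co[i, prev]) else Do[i, prev]
      prev <- prev[order(score)[seq_len(nn)]]
    }
    b <- solve(Co[prev, prev, drop = FALSE], Co[prev, i])
    B[i, prev] <- b
    d[i] <- Co[i, i] - sum(Co[i, prev] * b)
  }
  structure(list(B = B, d = d, ordering = ordering,
                 logdet_Q = -sum(log(d)), m = m),
            class = "lo_nnfactor")
}

#' Dense precision matrix implied by a nearest-neighbour factor
#'
#' @param x an \code{"lo_nnfactor"} from [nn_precision_approx()].
#' @param original_order if \code{TRUE} (default) the precision is permuted
#'   back to the input ordering of \code{C}.
#' @return an m x m precision matrix.
#' @export
nn_precision_matrix <- function(x, original_order = TRUE) {
  A <- diag(x$m) - x$B
  Q <- t(A) %*% (A / x$d)
  if (original_order) {
    inv <- order(x$ordering)
    Q <- Q[inv, inv]
  }
  Q
}

#' Kullback-Leibler divergence of a nearest-neighbour approximation
#'
#' KL divergence from the approximating Gaussian \eqn{N(0, Q^{-1})} to the
#' exact \eqn{N(0, C)}; zero when \code{nn = m - 1}.
#'
#' @param x an \code{"lo_nnfactor"}.
#' @param C the exact covariance the factor approximates.
#' @return a nonnegative scalar.
#' @export
nn_kl_divergence <- function(x, C) {
  m <- x$m
  Q <- nn_precision_matrix(x, original_order = TRUE)
  Cinv_logdet <- determinant(C, logarithm = TRUE)$modulus
  Sigma1 <- solve(Q)
  0.5 * (sum(diag(solve(C, Sigma1))) - m +
           as.numeric(Cinv_logdet) - (-x$logdet_Q))
}

#' Order species by distance from the root of a tree
#'
#' @param tree an [ape::phylo] tree.
#' @return an integer permutation of the tips (increasing root distance).
#' @export
order_by_root_distance <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  order(depth)
}
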