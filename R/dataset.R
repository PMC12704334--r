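#' Community dataset: responses, covariates, traits, design, tree
#'
#' The unit consumed by [lo_fit()] and produced by [generate_dataset()].
#' Responses are a sites x species matrix; covariates a sites x k table;
#' traits an optional species x q table; \code{design} holds study-design
#' label columns (site/transect/year); \code{observed_mask} marks non-missing
#' cells (missing-at-random cells are simply dropped from the likelihood).
#'
#' @param Y n x m response matrix with unique row (site) and column (species)
#'   names (assigned if absent).
#' @param X optional n x k covariate data frame or matrix.
#' @param traits optional m x q trait table (rows align with species).
#' @param design optional data frame of design label columns (n rows).
#' @param coords optional coordinate matrix (n rows, or one per design level).
#' @param tree optional [ape::phylo] tree over the species.
#' @param observed_mask optional n x m logical; defaults to \code{!is.na(Y)}.
#' @return an object of class \code{"lo_dataset"}.
#' @export
lo_dataset <- function(Y, X = NULL, traits = NULL, design = NULL,
                       coords = NULL, tree = NULL, observed_mask = NULL) {
  Y <- as.matrix(Y)
  if (is.null(rownames(Y))) rownames(Y) <- paste0("site", seq_len(nrow(Y)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("sp", seq_len(ncol(Y)))
  if (anyDuplicated(rownames(Y)) || anyDuplicated(colnames(Y)))
    stop("site and species identifiers must be unique")
  if (is.null(observed_mask)) observed_mask <- !is.na(Y)
  observed_mask <- observed_mask & !is.na(Y)
  if (any(colSums(observed_mask) == 0))
    stop("every species needs at least one observed cell; offenders: ",
         paste(colnames(Y)[colSums(observed_mask) == 0], collapse = ", "))
  if (any(rowSums(observed_mask) == 0))
    stop("every site needs at least one observed cell; offenders: ",
         paste(rownames(Y)[rowSums(observed_mask) == 0], collapse = ", "))
  if (!is.null(X)) {
    X <- as.data.frame(X)
    if (nrow(X) != nrow(Y)) stop("X rows must align with Y rows")
    rownames(X) <- rownames(Y)
  }
  if (!is.null(traits)) {
    traits <- as.data.frame(traits)
    if (nrow(traits) != ncol(Y)) stop("trait rows must align with Y columns")
    if (!is.null(rownames(traits)) && all(colnames(Y) %in% rownames(traits)))
      traits <- traits[colnames(Y), , drop = FALSE]
    else rownames(traits) <- colnames(Y)
  }
  if (!is.null(design)) {
    design <- as.data.frame(design)
    if (nrow(design) != nrow(Y)) stop("design rows must align with Y rows")
  }
  structure(list(Y = Y, X = X, traits = traits, design = design,
                 coords = coords, tree = tree, observed_mask = observed_mask),
            class = "lo_dataset")
}

#' @export
print.lo_dataset <- function(x, ...) {
  cat(sprintf("<lo_dataset> %d sites x %d species; %d covariates%s%s\n",
              nrow(x$Y), ncol(x$Y),
              if (is.null(x$X)) 0L else ncol(x$X),
              if (is.null(x$traits)) "" else
                sprintf("; %d traits", ncol(x$traits)),
              if (is.null(x$tree)) "" else "; tree attached"))
  zf <- mean(x$Y[x$observed_mask] == 0, na.rm = TRUE)
  cat(sprintf("  observed cells: %d (%.1f%% zeros)\n",
              sum(x$observed_mask), 100 * zf))
  invisible(x)
}

#' Number of observed response cells
#' @param data an [lo_dataset()].
#' @return integer count of cells entering the likelihood.
#' @export
n_observed <- function(data) sum(data$observed_mask)
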