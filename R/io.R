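#' Read a community dataset from delimited text files
#'
#' The response file holds the sites x species matrix with site identifiers
#' in the first column and species names in the header; covariate, trait,
#' and design files follow the same convention (first column = identifier).
#' The delimiter is auto-detected among comma and tab. Empty response cells
#' become masked (missing-at-random) entries.
#'
#' @param response path of the response matrix file.
#' @param covariates optional covariate table path.
#' @param traits optional trait table path (first column = species).
#' @param design optional design-label table path.
#' @param tree optional newick tree path.
#' @param scale_covariates center and scale numeric covariates.
#' @param percent_scale \code{"unit"} if cover is already on \code{[0,1]},
#'   \code{"percent"} to divide by 100.
#' @return an [lo_dataset()].
#' @export
load_dataset <- function(response, covariates = NULL, traits = NULL,
                         design = NULL, tree = NULL,
                         scale_covariates = FALSE,
                         percent_scale = c("unit", "percent")) {
  percent_scale <- match.arg(percent_scale)
  Ydf <- read_delim_auto(response)
  ids <- as.character(Ydf[[1]])
  Y <- as.matrix(Ydf[, -1, drop = FALSE])
  if (!is.numeric(Y)) {
    bad <- which(!vapply(Ydf[-1], is.numeric, TRUE))
    stop("non-numeric response column(s): ",
         paste(colnames(Ydf)[-1][bad], collapse = ", "))
  }
  rownames(Y) <- ids
  if (percent_scale == "percent") Y <- Y / 100
  X <- NULL
  if (!is.null(covariates)) {
    Xdf <- read_delim_auto(covariates)
    xid <- as.character(Xdf[[1]])
    if (!identical(sort(xid), sort(ids)))
      stop("covariate site identifiers do not align with the response; ",
           "offenders: ",
           paste(c(setdiff(xid, ids), setdiff(ids, xid)), collapse = ", "))
    X <- Xdf[match(ids, xid), -1, drop = FALSE]
    rownames(X) <- ids
    if (scale_covariates) {
      num <- vapply(X, is.numeric, TRUE)
      X[num] <- lapply(X[num], function(z) as.numeric(scale(z)))
    }
  }
  Tr <- NULL
  if (!is.null(traits)) {
    Tdf <- read_delim_auto(traits)
    tid <- as.character(Tdf[[1]])
    miss <- setdiff(tid, colnames(Y))
    extra <- setdiff(colnames(Y), tid)
    if (length(miss) || length(extra))
      stop("trait species do not align with the response; offenders: ",
           paste(c(miss, extra), collapse = ", "))
    Tr <- Tdf[match(colnames(Y), tid), -1, drop = FALSE]
    rownames(Tr) <- colnames(Y)
  }
  Dd <- NULL
  if (!is.null(design)) {
    Ddf <- read_delim_auto(design)
    did <- as.character(Ddf[[1]])
    if (!identical(sort(did), sort(ids)))
      stop("design site identifiers do not align with the response")
    Dd <- Ddf[match(ids, did), -1, drop = FALSE]
  }
  tr <- if (!is.null(tree)) ape::read.tree(tree) else NULL
  lo_dataset(Y, X = X, traits = Tr, design = Dd, tree = tr)
}

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >=
             lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write a community dataset as delimited text files
#'
#' Inverse of [load_dataset()]: writes \code{response.csv},
#' \code{covariates.csv}, \code{traits.csv}, \code{design.csv},
#' \code{tree.nwk} as present, into \code{dir}.
#'
#' @param data an [lo_dataset()].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of written paths.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(M, name, rn = "id") {
    p <- file.path(dir, paste0(name, ".csv"))
    df <- data.frame(rownames(M) %||% seq_len(nrow(M)), M,
                     check.names = FALSE)
    colnames(df)[1] <- rn
    utils::write.table(df, p, sep = ",", row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  Yout <- data$Y
  Yout[!data$observed_mask] <- NA
  wr(Yout, "response", "site")
  if (!is.null(data$X)) wr(data$X, "covariates", "site")
  if (!is.null(data$traits)) wr(data$traits, "traits", "species")
  if (!is.null(data$design)) {
    D <- data$design; rownames(D) <- rownames(data$Y)
    wr(D, "design", "site")
  }
  if (!is.null(data$tree)) {
    p <- file.path(dir, "tree.nwk")
    ape::write.tree(data$tree, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Express a model specification as a JSON-compatible configuration
#'
#' @param spec an [lo_model_spec()].
#' @return a named list mirroring the specification fields.
#' @export
spec_to_config <- function(spec) {
  list(family = spec$family$name, link = spec$family$link,
       num_lv = spec$num_lv, num_RR = spec$num_RR,
       num_lv_c = spec$num_lv_c,
       quadratic = spec$quadratic,
       species_formula = if (!is.null(spec$species_formula))
         deparse1(spec$species_formula) else NULL,
       lv_formula = if (!is.null(spec$lv_formula))
         deparse1(spec$lv_formula) else NULL,
       row_formula = if (!is.null(spec$row_formula))
         deparse1(spec$row_formula) else NULL,
       randomB = spec$randomB, lv_cor = spec$lv_cor,
       fourth_corner = spec$fourth_corner,
       random_slopes = spec$random_slopes,
       phylo = spec$phylo, disp_groups = spec$disp_groups,
       zeta_struc = spec$zeta_struc, beta0com = spec$beta0com)
}

#' Build a model specification from a configuration list or JSON file
#'
#' @param config a named list (as from [spec_to_config()]) or a path to a
#'   JSON file holding one.
#' @return an [lo_model_spec()].
#' @export
config_to_spec <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  ff <- function(x) if (is.null(x) || !nzchar(x)) NULL else stats::as.formula(x)
  lo_model_spec(
    family = config$family, link = config$link,
    num_lv = config$num_lv %||% 0L, num_RR = config$num_RR %||% 0L,
    num_lv_c = config$num_lv_c %||% 0L,
    species_formula = ff(config$species_formula),
    lv_formula = ff(config$lv_formula),
    row_formula = ff(config$row_formula),
    quadratic = isTRUE(config$quadratic),
    randomB = config$randomB %||% "none",
    lv_cor = config$lv_cor,
    fourth_corner = isTRUE(config$fourth_corner),
    random_slopes = config$random_slopes,
    phylo = config$phylo, disp_groups = config$disp_groups,
    zeta_struc = config$zeta_struc %||% "common",
    beta0com = isTRUE(config$beta0com))
}

#' Save and load a fitted model as a single JSON archive
#'
#' The archive stores the specification, the packed parameter vector, the
#' dataset, and fit diagnostics as plain text, so a fit can be shipped and
#' reloaded without re-optimization.
#'
#' @param fit an [lo_fit()].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
save_fit_archive <- function(fit, path) {
  dat <- fit$data
  arch <- list(
    spec = spec_to_config(fit$spec),
    theta = fit$theta,
    method = fit$method,
    objective = fit$objective, grad_norm = fit$grad_norm,
    df = fit$df, n_obs = fit$n_obs, trace = fit$trace,
    data = list(Y = as.data.frame(ifelse(dat$observed_mask, dat$Y, NA)),
                sites = rownames(dat$Y), species = colnames(dat$Y),
                X = dat$X, traits = dat$traits, design = dat$design,
                tree = if (!is.null(dat$tree))
                  ape::write.tree(dat$tree) else NULL))
  jsonlite::write_json(arch, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname save_fit_archive
#' @export
load_fit_archive <- function(path) {
  arch <- jsonlite::read_json(path, simplifyVector = TRUE)
  Y <- as.matrix(arch$data$Y)
  dimnames(Y) <- list(arch$data$sites, arch$data$species)
  dat <- lo_dataset(Y,
                    X = arch$data$X, traits = arch$data$traits,
                    design = arch$data$design,
                    tree = if (!is.null(arch$data$tree))
                      ape::read.tree(text = arch$data$tree) else NULL)
  spec <- config_to_spec(arch$spec)
  model <- build_model(spec, dat, method = arch$method)
  st <- state_unpack(model, arch$theta)
  structure(list(spec = spec, data = dat, model = model,
                 method = arch$method, params = st$params,
                 vstate = st$vstate, theta = arch$theta,
                 objective = arch$objective, grad_norm = arch$grad_norm,
                 n_obs = arch$n_obs, df = arch$df, trace = arch$trace,
                 control = NULL, converged = NA), class = "lo_fit")
}
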