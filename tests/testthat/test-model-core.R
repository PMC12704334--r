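make_design_data <- function(n_sites = 11, n_tran = 4, n_years = 2,
                             seed = 1) {
  set.seed(seed)
  df <- expand.grid(SITE = paste0("s", seq_len(n_sites)),
                    TRANSECT = paste0("t", seq_len(n_tran)),
                    YEAR = seq_len(n_years))
  n <- nrow(df)
  X <- data.frame(df, x1 = rnorm(n), x2 = rnorm(n))
  Y <- matrix(rpois(n * 5, 2), n, 5)
  lo_dataset(Y, X)
}

test_that("row-effect formulas parse nesting and correlation wrappers", {
  dat <- make_design_data()
  spec <- lo_model_spec("poisson",
                        row_formula = ~ (1 | SITE / TRANSECT) + YEAR)
  des <- parse_model(spec, dat)
  expect_length(des$row_random, 2)
  expect_equal(length(des$row_random[[1]]$levels), 11)
  expect_equal(length(des$row_random[[2]]$levels), 44)
  expect_equal(colnames(des$row_fixed), "YEAR")

  dat21 <- local({
    set.seed(2)
    df <- data.frame(YEAR = rep(0:20, each = 2), x1 = rnorm(42))
    lo_dataset(matrix(rpois(42 * 3, 2), 42, 3), df)
  })
  spec2 <- lo_model_spec("poisson", num_lv = 2, lv_cor = "corAR1(1|YEAR)")
  des2 <- parse_model(spec2, dat21)
  expect_equal(des2$lv_groups$kind, "corAR1")
  expect_length(des2$lv_groups$levels, 21)

  spec3 <- lo_model_spec("poisson", num_lv = 2)
  des3 <- parse_model(spec3, dat)
  expect_null(des3$X_lv)

  expect_error(parse_model(
    lo_model_spec("poisson", row_formula = ~ (x1 | SITE)), dat),
    "random intercepts")
  expect_error(parse_model(
    lo_model_spec("poisson", row_formula = ~ (1 | NOPE)), dat), "NOPE")
  expect_error(parse_model(
    lo_model_spec("poisson", species_formula = ~ (1 | SITE)), dat),
    "not supported")
})

test_that("reduced-rank coefficients have rank at most d", {
  set.seed(3)
  B <- matrix(rnorm(10), 5, 2)
  G <- matrix(rnorm(16), 8, 2)
  M <- reduced_rank_coefficients(B, G)
  expect_equal(dim(M), c(8, 5))
  expect_equal(M[3, ], as.vector(B %*% G[3, ]))
  sv <- svd(M)$d
  expect_lt(sv[3] / sv[1], 1e-8)
  expect_equal(reduced_rank_coefficients(matrix(0, 5, 2), G),
               matrix(0, 8, 5))
  # d = k with invertible B represents any target exactly
  Bf <- matrix(rnorm(9), 3, 3)
  target <- matrix(rnorm(12), 4, 3)
  Gf <- target %*% t(solve(Bf))
  expect_equal(reduced_rank_coefficients(Bf, Gf), target, tolerance = 1e-10)
  expect_error(reduced_rank_coefficients(matrix(0, 5, 2), matrix(0, 8, 3)),
               "latent dimension")
})

test_that("linear predictor assembles all terms and is unimodal when quadratic", {
  set.seed(4)
  n <- 12; m <- 4
  dat <- lo_dataset(matrix(rpois(n * m, 2), n, m),
                    data.frame(x1 = rnorm(n), x2 = rnorm(n)))
  spec <- lo_model_spec("poisson", num_lv = 2, species_formula = ~ x1 + x2)
  des <- parse_model(spec, dat)
  p0 <- list(beta0 = rep(0, m), Beta = matrix(0, m, 2),
             Gamma = matrix(0, m, 2))
  eta0 <- linear_predictor(spec, p0, des,
                           latents = list(U = matrix(0, n, 2)))
  expect_equal(eta0, matrix(0, n, m), ignore_attr = TRUE)

  # constrained model depends on X only through B'X
  specc <- lo_model_spec("poisson", num_RR = 1, lv_formula = ~ x1 + x2)
  desc <- parse_model(specc, dat)
  B <- matrix(c(1, -2), 2, 1)
  G <- matrix(rnorm(m), m, 1)
  pc <- list(beta0 = rep(0, m), B_canon = B, Gamma = G)
  etac <- linear_predictor(specc, pc, desc)
  u <- desc$X_lv %*% B
  expect_equal(etac, u %*% t(G), ignore_attr = TRUE)

  # quadratic response has an interior maximum in u
  specq <- lo_model_spec("poisson", num_lv = 1, quadratic = TRUE)
  desq <- parse_model(specq, dat)
  Dq <- matrix(0.5, m, 1)
  Gq <- matrix(1, m, 1)
  grid <- seq(-4, 4, length.out = 161)
  vals <- sapply(grid, function(u) {
    linear_predictor(specq,
                     list(beta0 = rep(0, m), Gamma = Gq, D_quad = Dq),
                     desq, latents = list(U = matrix(u, n, 1)))[1, 1]
  })
  imax <- which.max(vals)
  expect_gt(imax, 1); expect_lt(imax, length(grid))
  expect_equal(grid[imax], 1, tolerance = 0.1)  # optimum at gamma/(2D)
})

test_that("free-parameter counts reproduce the concurrent-ordination table", {
  df_cells <- expand.grid(fam = c("poisson", "zip", "negbin", "zinb"),
                          d = 2:4, stringsAsFactors = FALSE)
  expected <- c(poisson = NA)
  truth <- matrix(c(236, 304, 304, 372,
                    317, 385, 385, 453,
                    396, 464, 464, 532), nrow = 4)
  rownames(truth) <- c("poisson", "zip", "negbin", "zinb")
  for (d in 2:4) for (fam in rownames(truth)) {
    spec <- lo_model_spec(fam, num_lv_c = d, lv_formula = ~ x)
    expect_identical(count_free_parameters(spec, 87, 68, k_lv = 17),
                     as.integer(truth[fam, d - 1]),
                     label = paste(fam, "d =", d))
  }
  glm_spec <- lo_model_spec("poisson", species_formula = ~ x)
  expect_identical(count_free_parameters(glm_spec, 87, 68, k = 17), 1224L)
})

test_that("randomB df differences equal variance-parameter count differences", {
  base <- function(rb) count_free_parameters(
    lo_model_spec("poisson", num_RR = 2, lv_formula = ~ x, randomB = rb),
    50, 20, k_lv = 5)
  expect_identical(base("P") - base("LV"), 5L)       # extra per-covariate
  expect_identical(base("LV") - base("single"), 1L)  # per-LV vs shared
})

test_that("spec invariants are enforced", {
  expect_error(lo_model_spec("poisson", randomB = "LV"), "randomB")
  expect_error(lo_model_spec("poisson", num_RR = 1), "lv_formula")
  expect_error(lo_model_spec("poisson", zeta_struc = "species"),
               "ordered_beta")
  dat <- make_design_data()
  spec <- lo_model_spec("poisson", num_RR = 3, lv_formula = ~ x1 + x2)
  expect_error(parse_model(spec, dat), "exceeds")
})

test_that("model configurations round-trip through the JSON dialect", {
  spec <- lo_model_spec("zinb", num_lv_c = 2, lv_formula = ~ x1 + x2,
                        row_formula = ~ (1 | SITE), randomB = "P",
                        beta0com = TRUE)
  cfg <- spec_to_config(spec)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, null = "null")
  spec2 <- config_to_spec(path)
  expect_equal(spec_to_config(spec2), cfg)
})
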