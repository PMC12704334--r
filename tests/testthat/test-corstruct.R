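test_that("correlation builders produce the stated matrices", {
  ar0 <- build_correlation(lo_corstruct("AR1", list(rho = 0), index = 1:4))
  expect_equal(ar0, diag(4))
  ar <- build_correlation(lo_corstruct("AR1", list(rho = 0.9), index = 1:3))
  expect_equal(ar, matrix(c(1, .9, .81, .9, 1, .9, .81, .9, 1), 3))
  ar21 <- build_correlation(lo_corstruct("AR1", list(rho = 0.99),
                                         index = 0:20))
  expect_gt(min(eigen(ar21, symmetric = TRUE)$values), 0)
  # unequal spacing maps to rho^dt
  aru <- build_correlation(lo_corstruct("AR1", list(rho = 0.5),
                                        index = c(0, 2)))
  expect_equal(aru[1, 2], 0.25)
  cs <- build_correlation(lo_corstruct("CS", list(rho = 0.3), index = 1:5))
  expect_equal(unname(diag(cs)), rep(1, 5))
  expect_equal(cs[1, 2], 0.3)
  expect_error(build_correlation(lo_corstruct("CS", list(rho = -0.5),
                                              index = 1:3)), "rho")
  co <- cbind(runif(6), runif(6))
  ex <- build_correlation(lo_corstruct("Exp", list(range = 0.7), index = co))
  ma <- build_correlation(lo_corstruct("Matern", list(range = 0.7),
                                       index = co))
  for (M in list(ex, ma)) {
    expect_equal(unname(diag(M)), rep(1, 6))
    expect_gt(min(eigen(M, symmetric = TRUE)$values), -1e-10)
  }
  expect_error(build_correlation(lo_corstruct("AR1", list(rho = 1.2),
                                              index = 1:3)), "rho")
})

test_that("phylogenetic covariance interpolates between independence and C", {
  C <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(phylo_covariance(C, 0, 2), 2 * diag(2))
  expect_equal(phylo_covariance(C, 1, 2), 2 * C)
  expect_equal(phylo_covariance(C, 0.4, 2),
               matrix(c(2, 0.4, 0.4, 2), 2))
  # linear in sigma2, continuous in rho
  expect_equal(phylo_covariance(C, 0.3, 6), 3 * phylo_covariance(C, 0.3, 2))
  rhos <- seq(0, 1, by = 0.1)
  offd <- sapply(rhos, function(r) phylo_covariance(C, r, 1)[1, 2])
  expect_equal(offd, 0.5 * rhos)
  expect_error(phylo_covariance(C, 1.4, 1), "rho")
})

test_that("trees map to Brownian correlations and cophenetic distances", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1);")
  tc <- tree_to_correlation(star)
  expect_equal(tc$C, diag(3), ignore_attr = TRUE)
  two <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  tc2 <- tree_to_correlation(two)
  expect_equal(tc2$C["a", "b"], 0.5)  # half the root path is shared
  expect_equal(tc2$D["a", "b"], 2)
  set.seed(8)
  tr <- ape::rtree(20)
  tc3 <- tree_to_correlation(tr)
  expect_gt(min(eigen(tc3$C, symmetric = TRUE)$values), 0)
  expect_error(tree_to_correlation(two, species = c("a", "zz")), "zz")
})

test_that("taxonomy converts to a unit-edge tree", {
  tax <- data.frame(class = c("A", "A", "A", "B"),
                    genus = c("g1", "g1", "g2", "g3"),
                    row.names = c("sp1", "sp2", "sp3", "sp4"))
  tr <- taxonomy_to_tree(tax)
  tc <- tree_to_correlation(tr)
  expect_setequal(tr$tip.label, rownames(tax))
  # same genus shares more history than same class only
  expect_gt(tc$C["sp1", "sp2"], tc$C["sp1", "sp3"])
  expect_gt(tc$C["sp1", "sp3"], tc$C["sp1", "sp4"])
})

test_that("nearest-neighbour factorization is exact at nn = m - 1", {
  expect_equal(nn_precision_matrix(nn_precision_approx(diag(5), nn = 2)),
               diag(5))
  set.seed(9)
  rt <- random_tree(12, seed = 9)
  f <- nn_precision_approx(rt$C, nn = 11)
  expect_equal(nn_precision_matrix(f), solve(rt$C), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(nn_kl_divergence(f, rt$C), 1e-10)
  expect_error(nn_precision_approx(rt$C, nn = 0), "nn")
})

test_that("nearest-neighbour KL error decreases with more neighbours", {
  kls <- sapply(1:20, function(s) {
    rt <- random_tree(30, seed = 100 + s)
    ord <- order_by_root_distance(rt$tree)
    sapply(c(2, 10), function(nn)
      nn_kl_divergence(nn_precision_approx(rt$C, ordering = ord, nn = nn,
                                           D = rt$D), rt$C))
  })
  expect_lt(mean(kls[2, ]), mean(kls[1, ]))  # nn = 10 better than nn = 2
})
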