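test_that("panel correlations match the published associations", {
  cc <- correlation_matrix(agt_panel())
  expect_equal(cc$r["AGP", "AVI"], 0.96, tolerance = 0.01 / 0.96)
  expect_equal(cc$r["SL", "RL"], 0.72, tolerance = 0.02 / 0.72)
  expect_true(all(diag(cc$r) == 1))
  expect_true(isSymmetric(cc$r))
  expect_true(all(abs(cc$r) <= 1 + 1e-12))
  expect_equal(cc$stars["AGP", "AVI"], "***")
  # correlation matrix is positive semidefinite to numerical tolerance
  expect_gte(min(eigen(cc$r, symmetric = TRUE)$values), -1e-10)
})

test_that("constant traits yield flagged undefined correlations", {
  panel <- agt_panel()[1:10, ]
  panel$SL <- 5
  expect_warning(cc <- correlation_matrix(panel, c("AGP", "AVI", "SL")),
                 "constant")
  expect_true(all(is.na(cc$r["SL", ])))
  expect_false(anyNA(cc$r["AGP", "AVI"]))
})

test_that("correlation-matrix PCA reproduces the published leading axis", {
  p <- trait_pca(agt_panel())
  expect_equal(p$eigenvalues[1], 4.69, tolerance = 0.05 / 4.69)
  expect_equal(p$variance_pct[1], 33.53, tolerance = 0.5 / 33.53)
  expect_equal(sum(p$eigenvalues), 14)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  # cos2 columns sum to the eigenvalues, rows to one
  expect_equal(unname(colSums(p$cos2)), p$eigenvalues, tolerance = 1e-9)
  expect_equal(unname(rowSums(p$cos2)), rep(1, 14), tolerance = 1e-9)
  # the vigor index is the strongest contributor to the first axis
  expect_equal(names(which.max(p$cos2[, 1])), "AVI")
  expect_equal(unname(p$cos2["AVI", 1]), 0.89, tolerance = 0.02)
})

test_that("PCA handles rank deficiency and is row-order invariant", {
  set.seed(5)
  d <- data.frame(genotype = paste0("g", 1:30), SL = rnorm(30, 20, 5))
  d$RL <- 2 * d$SL + 3   # perfectly correlated pair
  p <- trait_pca(d, c("SL", "RL"))
  expect_equal(p$eigenvalues, c(2, 0), tolerance = 1e-12)

  panel <- agt_panel()
  p1 <- trait_pca(panel)
  p2 <- trait_pca(panel[sample(nrow(panel)), ])
  expect_equal(p2$eigenvalues, p1$eigenvalues, tolerance = 1e-12)
  expect_equal(p2$cos2, p1$cos2, tolerance = 1e-9)

  const <- panel; const$KB <- 1
  expect_error(trait_pca(const), "KB")
})

test_that("Gower distance follows the range-normalized mean difference", {
  d <- data.frame(genotype = c("a", "b", "c"),
                  SL = c(0, 5, 10), RL = c(2, 2, 2))
  expect_warning(g <- gower_distance(d, c("SL", "RL")), "zero-range")
  m <- as.matrix(g)
  expect_equal(m["a", "c"], 1)
  expect_equal(m["a", "b"], 0.5)
  expect_equal(diag(m), c(a = 0, b = 0, c = 0))

  # identical genotypes at distance zero; full-range opposites at one
  d2 <- data.frame(genotype = c("x", "y", "z"),
                   SL = c(3, 3, 10), RL = c(1, 1, 4))
  m2 <- as.matrix(gower_distance(d2, c("SL", "RL")))
  expect_equal(m2["x", "y"], 0)
  d3 <- agt_panel()
  rng <- vapply(trait_codes(), function(tr) range(d3[[tr]]), numeric(2))
  extremes <- cbind(data.frame(genotype = c("lo", "hi")),
                    as.data.frame(rng))
  expect_equal(as.numeric(gower_distance(extremes)), 1)
})

test_that("Gower distance is invariant to affine trait rescaling and
           matches the reference implementation", {
  panel <- agt_panel()[1:25, ]
  g1 <- gower_distance(panel, c("AGP", "SL", "RL", "HSW"))
  rescaled <- panel
  rescaled$SL <- 100 * rescaled$SL - 7
  rescaled$HSW <- 0.3 * rescaled$HSW + 2
  g2 <- gower_distance(rescaled, c("AGP", "SL", "RL", "HSW"))
  expect_equal(as.numeric(g2), as.numeric(g1), tolerance = 1e-12)

  skip_if_not_installed("cluster")
  ref <- cluster::daisy(panel[c("AGP", "SL", "RL", "HSW")],
                        metric = "gower")
  expect_equal(as.numeric(g1), as.numeric(ref), tolerance = 1e-10)
})

test_that("Ward.D2 recovers well-separated structure and is monotone", {
  set.seed(8)
  blob <- function(center, n) {
    data.frame(SL = rnorm(n, center, 0.5), RL = rnorm(n, center, 0.5))
  }
  d <- rbind(blob(0, 15), blob(50, 15))
  d$genotype <- paste0("g", 1:30)
  dist_ <- gower_distance(d, c("SL", "RL"))
  cl <- ward_d2_cluster(dist_, k = 2)
  truth <- rep(1:2, each = 15)
  tab <- table(cl$assignments, truth)
  expect_equal(sort(as.vector(tab)), c(0L, 0L, 15L, 15L))
  expect_false(is.unsorted(cl$tree$height))

  # k = n puts every genotype alone; k > n is an error
  cl_n <- ward_d2_cluster(dist_, k = 30)
  expect_equal(length(unique(cl_n$assignments)), 30L)
  expect_error(ward_d2_cluster(dist_, k = 31), "k must lie")

  # assignments at k are nested refinements of assignments at k - 1
  panel <- agt_panel()
  dp <- gower_distance(panel)
  for (k in c(3, 6)) {
    fine <- ward_d2_cluster(dp, k)$assignments
    coarse <- ward_d2_cluster(dp, k - 1)$assignments
    expect_true(all(tapply(coarse, fine,
                           function(v) length(unique(v))) == 1L))
  }
})

test_that("the most submergence-tolerant landraces co-cluster", {
  panel <- agt_panel()
  cl <- ward_d2_cluster(gower_distance(panel, ag_traits()), k = 6)
  stars <- cl$assignments[c("Karuthakar", "Poovan samba", "Mattaikar",
                            "Edakkal")]
  expect_equal(length(unique(stars)), 1L)
})

test_that("cluster profiles summarise within/between distances", {
  # two tight, far-apart clusters of identical points
  d <- data.frame(genotype = paste0("g", 1:6),
                  SL = c(1, 1, 1, 9, 9, 9), RL = c(2, 2, 2, 8, 8, 8))
  dist_ <- gower_distance(d, c("SL", "RL"))
  assign_ <- setNames(rep(1:2, each = 3), d$genotype)
  prof <- cluster_profile(assign_, d, traits = NULL, distances = dist_)
  expect_equal(unname(prof$within), c(0, 0))
  m <- as.matrix(dist_)
  expect_equal(prof$between["1", "2"], mean(m[1:3, 4:6]))

  # published cluster-IV membership: mean germination of the four stars
  panel <- agt_panel()
  iv <- c("Karuthakar", "Poovan samba", "Mattaikar", "Edakkal")
  assignments <- setNames(ifelse(panel$genotype %in% iv, "IV", "rest"),
                          panel$genotype)
  prof2 <- cluster_profile(assignments, panel, traits = "AGP")
  s <- prof2$summary
  expect_equal(s$mean[s$group == "IV"], 97.50, tolerance = 1e-3)

  # singleton clusters are flagged with zero within-distance
  assign_s <- setNames(c(1, 2, 2, 2, 2, 2), d$genotype)
  prof3 <- cluster_profile(assign_s, d, distances = dist_)
  expect_match(paste(prof3$flags, collapse = " "), "singleton")
  expect_equal(unname(prof3$within["1"]), 0)
})

test_that("dendrograms export as Newick with merge-height branch lengths", {
  panel <- agt_panel()[1:12, ]
  cl <- ward_d2_cluster(gower_distance(panel), k = 3)
  nwk <- cluster_newick(cl)
  expect_match(nwk, "^\\(.*\\);$")
  tree <- ape::read.tree(text = nwk)
  expect_equal(sort(tree$tip.label),
               sort(gsub(" ", "_", panel$genotype)))
})
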