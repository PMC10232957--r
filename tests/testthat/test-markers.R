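test_that("PIC follows the closed forms", {
  expect_equal(pic(1), 0)
  p2 <- c(0.61, 0.39)
  expect_equal(pic(p2), 1 - sum(p2^2) - 2 * 0.61^2 * 0.39^2)
  expect_equal(pic(p2), 0.3626, tolerance = 1e-4)
  expect_equal(pic(rep(0.25, 4)), 0.703125)
  expect_equal(pic(p2, method = "expected_het"), 1 - sum(p2^2))
  expect_error(pic(c(0.5, 0.6)), "sum to 1")
})

test_that("PIC is bounded by expected heterozygosity and maximized at
           equal frequencies", {
  set.seed(4)
  for (na in 2:4) {
    for (i in 1:50) {
      p <- as.numeric(rmultinom(1, 1000, rep(1, na))) / 1000
      p <- p[p > 0]
      he <- 1 - sum(p^2)
      expect_lte(pic(p), he)
      expect_lte(pic(p), pic(rep(1 / na, na)) + 1e-12)
    }
    # grid search confirms the equifrequent maximum
    if (na == 2) {
      grid <- seq(0.01, 0.99, by = 0.01)
      vals <- vapply(grid, function(q) pic(c(q, 1 - q)), 1.0)
      expect_equal(grid[which.max(vals)], 0.5)
    }
  }
})

test_that("allele statistics count alleles and flag monomorphic loci", {
  calls <- matrix(c("A", "B", "A", "B",
                    "A", "A", "A", "A",
                    "A", "B", "C", NA),
                  nrow = 4,
                  dimnames = list(paste0("g", 1:4), c("L1", "L2", "L3")))
  st <- allele_stats(agt_markers(calls))
  expect_equal(st$Na, c(2L, 1L, 3L))
  expect_equal(st$MAF, c(0.5, 1.0, 1 / 3))
  expect_equal(st$PIC[2], 0)
  expect_true(st$monomorphic[2])
  expect_equal(st$missing_rate, c(0, 0, 0.25))

  calls_empty <- cbind(calls, L4 = NA_character_)
  mk <- suppressWarnings(agt_markers(calls_empty))
  expect_warning(st2 <- allele_stats(mk), "all-missing")
  expect_false("L4" %in% st2$locus)
})

test_that("marker distances follow their definitions", {
  calls <- matrix(c("A", "A",
                    "B", "B",
                    "A", "C",
                    "A", "B",
                    "D", "E"),
                  nrow = 2,
                  dimnames = list(c("x", "y"),
                                  c("L1", "L2", "L3", "L4", "L5")))
  mk <- agt_markers(calls)
  # 3 of 5 loci mismatch
  expect_equal(as.numeric(genetic_distance(mk, "mismatch")), 3)
  expect_equal(as.numeric(genetic_distance(mk, "shared_allele")), 3 / 5)
  # band-counting oracle: each genotype carries 5 bands, 2 shared
  expect_equal(as.numeric(genetic_distance(mk, "nei_li")),
               1 - 2 * 2 / (5 + 5))

  same <- agt_markers(matrix("A", 2, 3,
                             dimnames = list(c("u", "v"), c("a", "b", "c"))))
  for (metric in c("nei_li", "shared_allele", "mismatch")) {
    expect_equal(as.numeric(genetic_distance(same, metric)), 0)
  }
  disjoint <- agt_markers(matrix(c("A", "B", "C", "D"), 2, 2,
                                 dimnames = list(c("u", "v"),
                                                 c("L1", "L2"))))
  expect_equal(as.numeric(genetic_distance(disjoint, "nei_li")), 1)

  # pair with no co-scored locus
  nocommon <- agt_markers(matrix(c("A", NA, NA, "B"), 2, 2,
                                 dimnames = list(c("u", "v"),
                                                 c("L1", "L2"))))
  expect_warning(d <- genetic_distance(nocommon, "mismatch"),
                 "no co-scored")
  expect_true(is.na(as.numeric(d)))
})

test_that("single-marker ANOVA matches a sums-of-squares oracle", {
  calls <- matrix(rep(c("A", "B"), each = 3), ncol = 1,
                  dimnames = list(paste0("g", 1:6), "M1"))
  mk <- agt_markers(calls)
  rec <- data.frame(genotype = paste0("g", 1:6),
                    SL = c(1, 2, 3, 5, 6, 7))
  res <- single_marker_analysis(mk, rec, traits = "SL")
  y <- rec$SL; cl <- calls[, 1]
  ssb <- sum(tapply(y, cl, length) * (tapply(y, cl, mean) - mean(y))^2)
  sst <- sum((y - mean(y))^2)
  fstat <- (ssb / 1) / ((sst - ssb) / 4)
  expect_equal(res$r2, 100 * ssb / sst)
  expect_equal(res$f, fstat)
  expect_equal(res$p, pf(fstat, 1, 4, lower.tail = FALSE))
  # for a biallelic marker, R2 is the squared point-biserial correlation
  expect_equal(res$r2, 100 * cor(y, as.numeric(cl == "B"))^2)
})

test_that("degenerate marker-trait combinations are skipped with reasons", {
  calls <- matrix(c("A", "A", "A", "A", "A", "B",
                    "A", "B", "A", "B", "A", "B"), ncol = 2,
                  dimnames = list(paste0("g", 1:6), c("mono", "ok")))
  mk <- agt_markers(calls)
  rec <- data.frame(genotype = paste0("g", 1:6),
                    SL = c(4, 4, 4, 4, 4, 4),
                    RL = c(1, 5, 2, 6, 1, 7))
  res <- single_marker_analysis(mk, rec, traits = c("SL", "RL"))
  sk <- attr(res, "skipped")
  expect_true(any(sk$marker == "mono"))   # single usable class
  expect_true(any(sk$trait == "SL" & sk$reason == "constant trait"))
  expect_equal(nrow(res), 1L)             # only ok x RL tested

  # a marker explaining the trait exactly
  rec2 <- data.frame(genotype = paste0("g", 1:6),
                     RL = ifelse(calls[, "ok"] == "A", 2, 9))
  res2 <- single_marker_analysis(mk, rec2, traits = "RL")
  row_ok <- res2[res2$marker == "ok", ]
  expect_equal(row_ok$r2, 100)
  expect_lt(row_ok$p, 1e-10)
})

test_that("genotype labels are normalized before matching tables", {
  calls <- matrix(c("A", "B", "A", "B"), ncol = 1,
                  dimnames = list(c("'FR13 A'", " karuthakar ",
                                    "IR42", "Co 43"), "M1"))
  mk <- agt_markers(calls)
  rec <- data.frame(genotype = c("FR13 A", "Karuthakar", "ir42", "CO 43"),
                    SL = c(1, 2, 8, 9))
  res <- single_marker_analysis(mk, rec, traits = "SL")
  expect_equal(res$n, 4L)
})
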