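test_that("trial reader infers the design and rejects bad schemas", {
  df <- toy_trial_df(c(50, 52, 48, 55, 53, 51), g = 1, s = 2, r = 3,
                     trait = "AGP")
  path <- tmp_table(df)
  tr <- read_trial_table(path)
  expect_s3_class(tr, "agt_trial")
  expect_equal(tr$design, list(g = 1L, s = 2L, r = 3L))

  df_bad <- df; names(df_bad)[6] <- "result"
  expect_error(read_trial_table(tmp_table(df_bad)), "missing column")

  df_chr <- df; df_chr$value <- as.character(df_chr$value)
  df_chr$value[3] <- "n/a"
  expect_error(read_trial_table(tmp_table(df_chr)), "row 3")
})

test_that("out-of-range and unknown trait values are rejected", {
  df <- toy_trial_df(c(90, 105, 80), g = 1, r = 3, trait = "AGP")
  expect_error(read_trial_table(tmp_table(df)), "AGP outside \\[0,100\\]")
  df2 <- toy_trial_df(c(1, 2, 3), g = 1, r = 3, trait = "XYZ")
  expect_error(read_trial_table(tmp_table(df2)), "unknown trait")
  df3 <- toy_trial_df(c(-1, 2, 3), g = 1, r = 3, trait = "SL")
  expect_error(read_trial_table(tmp_table(df3)), "SL outside")
})

test_that("trial write/read round-trip is lossless, for both delimiters", {
  tr <- simulate_trial(g = 6, s = 2, r = 3, seed = 11)
  for (sep in c(",", "\t")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_trial_table(tr, path, sep = sep)
    back <- read_trial_table(path)
    expect_equal(back$observations, tr$observations, tolerance = 1e-12)
    expect_equal(back$design, tr$design)
  }
})

test_that("the packaged panel loads with the published structure", {
  panel <- agt_panel()
  expect_equal(nrow(panel), 119L)
  expect_true(all(trait_codes() %in% names(panel)))
  karu <- panel[panel$genotype == "Karuthakar", ]
  expect_equal(karu$AGP, 100.00)
  expect_equal(karu$AVI, 4206)
  expect_equal(karu$SL, 33.53)
  expect_equal(karu$RL, 8.53)
  expect_equal(karu$grain_type, "Long-bold")
  samba <- panel[panel$genotype == "Samba massanam", ]
  expect_equal(samba$AGP, 10.00)
  expect_equal(samba$AVI, 150)
  expect_equal(samba$SL, 5.14)
  expect_equal(as.integer(table(panel$grain_type)[
    c("Long-bold", "Long-slender", "Medium-slender", "Short-bold")]),
    c(63L, 24L, 13L, 19L))
  # grain-dimension ratio is consistent with its components (printed rounding)
  expect_true(all(abs(panel$LBR - panel$KL / panel$KB) < 0.15))
})

test_that("genotype-mean reader rejects duplicates and missing cells", {
  panel <- agt_panel()
  dup <- rbind(panel, panel[1, ])
  expect_error(read_genotype_means(tmp_table(dup)), "duplicate genotype")
  hole <- panel
  hole$SL[5] <- NA
  expect_error(read_genotype_means(tmp_table(hole)),
               "missing SL value for genotype")
})

test_that("marker reader builds allele inventories and handles missing", {
  df <- data.frame(genotype = c("g1", "g2", "g3"),
                   L1 = c("A", "B", "A"), L2 = c("A", "A", "-"))
  mk <- read_marker_scores(tmp_table(df))
  expect_equal(vapply(mk$alleles, length, 1L), c(L1 = 2L, L2 = 1L))
  expect_true(is.na(mk$calls["g3", "L2"]))
  expect_equal(unname(mk$missing_rate), c(0, 1 / 3))

  empty <- data.frame(genotype = c("g1", "g2"), L1 = c("A", "B"),
                      L2 = c("-", "-"))
  expect_warning(read_marker_scores(tmp_table(empty)),
                 "monomorphic-undetermined")
})

test_that("marker write/read round-trips bit-exactly", {
  mk <- simulate_markers(list(L1 = c(0.6, 0.4), L2 = c(0.5, 0.3, 0.2)),
                         n = 25, missing_rate = 0.1, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_marker_scores(mk, path)
  back <- read_marker_scores(path)
  expect_identical(back$calls, mk$calls)
  expect_identical(back$alleles, mk$alleles)
})

test_that("validate_trial reports balance gaps and range violations", {
  tr <- simulate_trial(g = 4, s = 2, r = 3, seed = 5)
  rep_ok <- validate_trial(tr)
  expect_true(rep_ok$pass)
  expect_null(rep_ok$missing_cells)

  # drop one replicate cell
  obs <- tr$observations
  drop <- with(obs, genotype == "G002" & season == "S1" & replicate == 2)
  tr_gap <- agt_trial(obs[!drop, ], check = FALSE)
  rep_gap <- validate_trial(tr_gap)
  expect_false(rep_gap$pass)
  expect_equal(rep_gap$missing_cells$genotype, "G002")
  expect_equal(rep_gap$missing_cells$season, "S1")
  expect_equal(rep_gap$missing_cells$replicate, 2)

  # negative shoot length slips in only when construction checks are off
  obs2 <- toy_trial_df(c(10, -2, 12, 11, 10, 9), g = 2, r = 3, trait = "SL")
  rep_neg <- validate_trial(agt_trial(obs2, check = FALSE))
  expect_false(rep_neg$pass)
  expect_equal(rep_neg$range_violations$value, -2)
})
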