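# Independent brute-force oracles used to cross-check the implementation.

# RCBD sums of squares by direct summation over cells (single season).
# d: data frame with genotype, replicate, value.
oracle_rcbd_ss <- function(d) {
  grand <- mean(d$value)
  gm <- tapply(d$value, d$genotype, mean)
  rm_ <- tapply(d$value, d$replicate, mean)
  r <- length(rm_); g <- length(gm)
  ss_g <- r * sum((gm - grand)^2)
  ss_r <- g * sum((rm_ - grand)^2)
  ss_tot <- sum((d$value - grand)^2)
  list(ss_g = ss_g, ss_r = ss_r, ss_e = ss_tot - ss_g - ss_r,
       ss_tot = ss_tot,
       df = c(g = g - 1, r = r - 1, e = (g - 1) * (r - 1)))
}

# Pooled (two-way with blocks nested in season) sums of squares by direct
# summation, balanced case.
oracle_pooled_ss <- function(d) {
  grand <- mean(d$value)
  g_lv <- unique(d$genotype); s_lv <- unique(d$season)
  r_lv <- unique(d$replicate)
  g <- length(g_lv); s <- length(s_lv); r <- length(r_lv)
  gm <- tapply(d$value, d$genotype, mean)
  sm <- tapply(d$value, d$season, mean)
  gsm <- tapply(d$value, list(d$genotype, d$season), mean)
  srm <- tapply(d$value, list(d$season, d$replicate), mean)
  ss_g <- s * r * sum((gm - grand)^2)
  ss_s <- g * r * sum((sm - grand)^2)
  ss_gs <- r * sum((gsm - outer(gm, sm, "+") + grand)^2)
  ss_sr <- g * sum((sweep(srm, 1, sm))^2)
  ss_tot <- sum((d$value - grand)^2)
  list(ss_g = ss_g, ss_s = ss_s, ss_gs = ss_gs, ss_sr = ss_sr,
       ss_e = ss_tot - ss_g - ss_s - ss_gs - ss_sr, ss_tot = ss_tot,
       df = c(g = g - 1, s = s - 1, gs = (g - 1) * (s - 1),
              sr = s * (r - 1), e = s * (g - 1) * (r - 1)))
}

# Recursive all-pairs Newman-Keuls oracle: tests the widest range first and
# recurses into sub-ranges only where the enclosing range is significant.
# Returns the logical non-significance matrix over means sorted descending.
oracle_snk_nonsig <- function(means, n, mse, dfe, alpha = 0.05) {
  k <- length(means)
  nonsig <- matrix(FALSE, k, k); diag(nonsig) <- TRUE
  mark_all <- function(i, j) {
    for (a in i:j) for (b in i:j) nonsig[a, b] <<- TRUE
  }
  test_range <- function(i, j) {
    if (j <= i) return(invisible())
    span <- j - i + 1
    crit <- qtukey(1 - alpha, span, dfe) *
      sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
    if ((means[i] - means[j]) < crit) {
      mark_all(i, j)
    } else {
      test_range(i, j - 1)
      test_range(i + 1, j)
    }
  }
  test_range(1, k)
  nonsig
}

# shared-letter relation of a letter display
share_matrix <- function(letters_vec) {
  k <- length(letters_vec)
  chars <- strsplit(letters_vec, "")
  outer(seq_len(k), seq_len(k), Vectorize(function(i, j) {
    length(intersect(chars[[i]], chars[[j]])) > 0
  }))
}

# write a small delimited file and return its path
tmp_table <- function(df, sep = ",") {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# tiny balanced long-format trial data frame
toy_trial_df <- function(values, g, s = 1, r, trait = "RI",
                         treatment = "submerged") {
  grid <- expand.grid(replicate = seq_len(r), season = sprintf("S%d", 1:s),
                      genotype = sprintf("G%d", seq_len(g)),
                      stringsAsFactors = FALSE)
  data.frame(genotype = grid$genotype, season = grid$season,
             replicate = grid$replicate, treatment = treatment,
             trait = trait, value = values, stringsAsFactors = FALSE)
}
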