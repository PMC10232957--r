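#' Simulate a multi-environment screening trial
#'
#' Draws observations from the additive model
#' \deqn{y_{ijk} = \mu + g_i + s_j + (gs)_{ij} + b_{k(j)} + e_{ijk}}
#' with independent normal genotype, season, genotype-by-season, block
#' (replicate within season) and residual effects of the stated variances.
#' Season main effects are drawn with variance \code{sigma2_s}. The
#' defaults emulate the packaged screening panel's design: 119 genotypes,
#' 2 seasons, 3 replicates.
#'
#' @param mu Grand mean.
#' @param sigma2_g,sigma2_ge,sigma2_b,sigma2_e,sigma2_s Variance components
#'   (all >= 0).
#' @param g,s,r Numbers of genotypes, seasons and replicates.
#' @param trait Registered trait code attached to the observations
#'   (default \code{"RI"}, the one unbounded trait, so simulated values
#'   never violate range checks).
#' @param treatment Treatment label attached to the observations.
#' @param seed Optional RNG seed; a given seed reproduces the dataset
#'   bit-exactly.
#' @return An [agt_trial()] object. The true effects are attached as
#'   attribute \code{truth}.
#' @examples
#' tr <- simulate_trial(g = 10, seed = 1)
#' tr$design
#' @export
simulate_trial <- function(mu = 50, sigma2_g = 100, sigma2_ge = 30,
                           sigma2_b = 10, sigma2_e = 25, sigma2_s = 0,
                           g = 119, s = 2, r = 3, trait = "RI",
                           treatment = "submerged", seed = NULL) {
  stopifnot(sigma2_g >= 0, sigma2_ge >= 0, sigma2_b >= 0, sigma2_e >= 0,
            sigma2_s >= 0, g >= 1, s >= 1, r >= 1)
  if (!trait %in% trait_codes()) stop("unknown trait code: ", trait)
  if (!is.null(seed)) set.seed(seed)

  genos <- sprintf("G%03d", seq_len(g))
  seasons <- sprintf("S%d", seq_len(s))
  eff_g <- stats::rnorm(g, 0, sqrt(sigma2_g))
  eff_s <- stats::rnorm(s, 0, sqrt(sigma2_s))
  eff_gs <- matrix(stats::rnorm(g * s, 0, sqrt(sigma2_ge)), g, s)
  eff_b <- matrix(stats::rnorm(s * r, 0, sqrt(sigma2_b)), s, r)

  grid <- expand.grid(replicate = seq_len(r), season = seq_len(s),
                      genotype = seq_len(g))
  value <- mu + eff_g[grid$genotype] + eff_s[grid$season] +
    eff_gs[cbind(grid$genotype, grid$season)] +
    eff_b[cbind(grid$season, grid$replicate)] +
    stats::rnorm(nrow(grid), 0, sqrt(sigma2_e))

  obs <- data.frame(
    genotype = genos[grid$genotype],
    season = seasons[grid$season],
    replicate = grid$replicate,
    treatment = treatment,
    trait = trait,
    value = value,
    stringsAsFactors = FALSE
  )
  out <- agt_trial(obs, check = FALSE)
  attr(out, "truth") <- list(mu = mu, sigma2_g = sigma2_g,
                             sigma2_ge = sigma2_ge, sigma2_b = sigma2_b,
                             sigma2_e = sigma2_e, sigma2_s = sigma2_s,
                             effects_g = stats::setNames(eff_g, genos))
  out
}

#' Simulate binomial germination counts
#'
#' Emulates the germination assay: per genotype, season and replicate, the
#' number of emerged seedlings is Binomial(seeds_per_rep, p_i); the
#' replicate AGP is 100 x emerged / seeds_per_rep, and the pooled AGP is the
#' mean over all replicates and seasons, so pooled values lie on the
#' lattice {100 k / (seeds_per_rep x r x s)}.
#'
#' @param p Vector of per-genotype emergence probabilities in [0, 1]
#'   (names become genotype labels).
#' @param seeds_per_rep Seeds sown per replicate (default 5).
#' @param r,s Replicates and seasons.
#' @param seed Optional RNG seed.
#' @return List with \code{replicates} (long data frame: genotype, season,
#'   replicate, emerged, agp) and \code{pooled} (named vector of pooled
#'   AGP per genotype).
#' @export
simulate_germination <- function(p, seeds_per_rep = 5, r = 3, s = 2,
                                 seed = NULL) {
  stopifnot(all(p >= 0 & p <= 1), seeds_per_rep >= 1, r >= 1, s >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- length(p)
  genos <- if (!is.null(names(p))) names(p) else sprintf("G%03d", seq_len(g))
  grid <- expand.grid(replicate = seq_len(r), season = sprintf("S%d", 1:s),
                      genotype = seq_len(g), stringsAsFactors = FALSE)
  emerged <- stats::rbinom(nrow(grid), seeds_per_rep, p[grid$genotype])
  reps <- data.frame(
    genotype = genos[grid$genotype],
    season = grid$season,
    replicate = grid$replicate,
    emerged = emerged,
    agp = 100 * emerged / seeds_per_rep,
    stringsAsFactors = FALSE
  )
  pooled_tab <- tapply(reps$agp, reps$genotype, mean)[genos]
  list(replicates = reps,
       pooled = stats::setNames(as.numeric(pooled_tab), genos))
}

#' Simulate a multi-allelic marker panel
#'
#' Calls are drawn i.i.d. per genotype and locus from the given allele
#' frequencies (one call per genotype: inbred panel scored from bands);
#' a fraction of entries is then masked as missing.
#'
#' @param freqs Named list of per-locus allele frequency vectors (each
#'   summing to 1; allele names taken from vector names, or A, B, C, ...).
#' @param n Number of genotypes.
#' @param missing_rate Proportion of calls masked as missing.
#' @param seed Optional RNG seed.
#' @return An [agt_markers()] dataset.
#' @examples
#' simulate_markers(list(L1 = c(0.61, 0.39), L2 = c(0.5, 0.3, 0.2)),
#'                  n = 10, seed = 42)
#' @export
simulate_markers <- function(freqs, n, missing_rate = 0, seed = NULL) {
  stopifnot(is.list(freqs), n >= 1, missing_rate >= 0, missing_rate < 1)
  for (f in freqs) {
    if (abs(sum(f) - 1) > 1e-8) stop("each frequency vector must sum to 1")
  }
  if (is.null(names(freqs))) names(freqs) <- sprintf("L%02d",
                                                     seq_along(freqs))
  if (!is.null(seed)) set.seed(seed)
  genos <- sprintf("G%03d", seq_len(n))
  calls <- vapply(freqs, function(f) {
    alleles <- if (!is.null(names(f))) names(f) else LETTERS[seq_along(f)]
    sample(alleles, n, replace = TRUE, prob = f)
  }, character(n))
  calls <- matrix(calls, nrow = n,
                  dimnames = list(genos, names(freqs)))
  if (missing_rate > 0) {
    mask <- stats::runif(length(calls)) < missing_rate
    calls[mask] <- NA_character_
  }
  agt_markers(calls)
}

#' Recovery experiment for the variance-component estimators
#'
#' Repeatedly simulates trials with known variance components, re-estimates
#' them with [anova_pooled()] (or [anova_rcbd()] when s = 1) and summarises
#' bias, RMSE and +/- 2 SE coverage per component, along with the mean of
#' the downstream GCV and broad-sense heritability.
#'
#' @param n_sim Number of simulated trials (>= 2).
#' @param mu,sigma2_g,sigma2_ge,sigma2_b,sigma2_e,g,s,r Design and truth;
#'   see [simulate_trial()].
#' @param seed Optional seed controlling the whole experiment.
#' @param truncate Clamp negative estimates at zero before summarising.
#' @return Object of class \code{agt_recovery}: list with \code{summary}
#'   (data frame: parameter, truth, mean, bias, rmse, se, covered),
#'   \code{downstream} (mean GCV and h2bs) and \code{estimates} (n_sim x
#'   parameter matrix).
#' @export
recovery_experiment <- function(n_sim, mu = 50, sigma2_g = 100,
                                sigma2_ge = 30, sigma2_b = 10,
                                sigma2_e = 25, g = 100, s = 2, r = 3,
                                seed = NULL, truncate = TRUE) {
  stopifnot(n_sim >= 2)
  if (!is.null(seed)) set.seed(seed)
  est <- matrix(NA_real_, n_sim, 5,
                dimnames = list(NULL, c("sigma2_g", "sigma2_ge", "sigma2_e",
                                        "gcv", "h2bs")))
  for (i in seq_len(n_sim)) {
    tr <- simulate_trial(mu = mu, sigma2_g = sigma2_g, sigma2_ge = sigma2_ge,
                         sigma2_b = sigma2_b, sigma2_e = sigma2_e,
                         g = g, s = s, r = r)
    fit <- if (s >= 2) anova_pooled(tr, "RI", truncate = truncate)
           else anova_rcbd(tr, "RI", truncate = truncate)
    cmp <- fit$components
    vp <- variability_parameters(cmp, mean = mu, basis = "plot")
    est[i, ] <- c(cmp$sigma2_g,
                  if (is.finite(cmp$sigma2_ge)) cmp$sigma2_ge else NA,
                  cmp$sigma2_e, vp$gcv, vp$h2bs)
  }
  truth <- c(sigma2_g = sigma2_g, sigma2_ge = if (s >= 2) sigma2_ge else NA,
             sigma2_e = sigma2_e)
  summ <- do.call(rbind, lapply(names(truth), function(pn) {
    x <- est[, pn]
    if (all(is.na(x))) return(NULL)
    m <- mean(x); se <- stats::sd(x) / sqrt(n_sim)
    data.frame(parameter = pn, truth = truth[[pn]], mean = m,
               bias = m - truth[[pn]],
               rmse = sqrt(mean((x - truth[[pn]])^2)), se = se,
               covered = abs(m - truth[[pn]]) <= 2 * se,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ,
                 downstream = colMeans(est[, c("gcv", "h2bs")]),
                 estimates = est,
                 design = list(g = g, s = s, r = r, n_sim = n_sim)),
            class = "agt_recovery")
}

#' @export
print.agt_recovery <- function(x, ...) {
  d <- x$design
  cat(sprintf("Recovery experiment: %d simulations of g=%d, s=%d, r=%d\n",
              d$n_sim, d$g, d$s, d$r))
  s <- x$summary
  s[-1] <- lapply(s[-1], function(v) if (is.numeric(v)) signif(v, 5) else v)
  print(s, row.names = FALSE)
  cat(sprintf("Downstream means: GCV %.2f%%, h2bs %.2f%%\n",
              x$downstream["gcv"], x$downstream["h2bs"]))
  invisible(x)
}

#' Convenience preset: simulate a full screening panel
#'
#' Generates a 119-genotype x 2-season x 3-replicate trial for all ten
#' seedling traits, with variance magnitudes loosely matching a landrace
#' screening panel (large genotypic variance for AGP/AVI/SL, small for the
#' weights), plus a binomial germination layer for AGP. Intended for
#' end-to-end demonstration runs.
#'
#' @param seed RNG seed.
#' @return An [agt_trial()] object containing all simulated traits.
#' @export
demo_panel <- function(seed = 42) {
  set.seed(seed)
  spec <- list(
    # trait, mu, s2g, s2ge, s2e (orders of magnitude of a real panel)
    AVI = c(1950, 6e6, 1e6, 3e5),
    SL = c(22.8, 225, 100, 15),
    RL = c(6.9, 26, 17, 2),
    RI = c(3.1, 280, 100, 15),
    SRR = c(3.9, 13, 12, 8),
    NOL = c(1.9, 0.5, 0.4, 0.1),
    NOR = c(6.2, 17, 6, 1.5),
    FW = c(0.15, 0.024, 0.019, 0.01),
    DW = c(0.09, 0.011, 0.007, 0.003)
  )
  pieces <- lapply(names(spec), function(tr) {
    v <- spec[[tr]]
    sim <- simulate_trial(mu = v[1], sigma2_g = v[2], sigma2_ge = v[3],
                          sigma2_b = v[4] / 10, sigma2_e = v[4],
                          g = 119, s = 2, r = 3, trait = "RI")
    obs <- sim$observations
    obs$trait <- tr
    # clamp at zero for the non-negative traits so the panel is readable
    if (tr != "RI") obs$value <- pmax(obs$value, 0)
    obs
  })
  p_emerge <- stats::runif(119, 0.1, 1)
  germ <- simulate_germination(p_emerge, seeds_per_rep = 5, r = 3, s = 2)
  agp <- germ$replicates
  agp_obs <- data.frame(genotype = sprintf("G%03d",
                                           match(agp$genotype,
                                                 unique(agp$genotype))),
                        season = agp$season, replicate = agp$replicate,
                        treatment = "submerged", trait = "AGP",
                        value = agp$agp, stringsAsFactors = FALSE)
  agp_obs$genotype <- agp$genotype
  agt_trial(rbind(do.call(rbind, pieces), agp_obs), check = TRUE)
}
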