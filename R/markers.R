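#' Polymorphic information content
#'
#' Botstein form (default), the convention of standard marker-analysis
#' software for inbred panels:
#' \deqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2.}
#' The simpler expected-heterozygosity form \eqn{1 - \sum_i p_i^2} is
#' available via \code{method = "expected_het"}.
#'
#' @param p Vector of allele frequencies (must sum to 1).
#' @param method \code{"botstein"} (default) or \code{"expected_het"}.
#' @return PIC value in [0, 1).
#' @examples
#' pic(c(0.61, 0.39))          # 0.3626
#' pic(rep(0.25, 4))           # 0.703125
#' @export
pic <- function(p, method = c("botstein", "expected_het")) {
  method <- match.arg(method)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("allele frequencies must be non-negative and sum to 1")
  }
  he <- 1 - sum(p^2)
  if (method == "expected_het") return(he)
  p2 <- p^2
  he - (sum(p2)^2 - sum(p2^2))   # (sum p^2)^2 - sum p^4 = sum_{i<j} 2 p_i^2 p_j^2
}

#' Per-locus allele statistics
#'
#' Allele frequencies over non-missing calls, allele count (Na), major
#' allele frequency (MAF) and PIC for every locus of a marker dataset.
#' Monomorphic loci get PIC 0 and are flagged; all-missing loci are
#' excluded with a warning.
#'
#' @param markers An [agt_markers()] dataset.
#' @param method PIC formula, see [pic()].
#' @return Data frame of class \code{agt_locus_stats} with columns
#'   \code{locus}, \code{n_scored}, \code{missing_rate}, \code{Na},
#'   \code{MAF}, \code{PIC}, \code{monomorphic}; the per-locus frequency
#'   vectors are attached as attribute \code{frequencies}.
#' @examples
#' m <- simulate_markers(list(L1 = c(A = 0.6, B = 0.4)), n = 50, seed = 1)
#' allele_stats(m)
#' @export
allele_stats <- function(markers, method = c("botstein", "expected_het")) {
  method <- match.arg(method)
  stopifnot(inherits(markers, "agt_markers"))
  calls <- markers$calls
  scored <- colSums(!is.na(calls))
  if (any(scored == 0)) {
    warning("excluding all-missing locus/loci: ",
            paste(colnames(calls)[scored == 0], collapse = ", "))
    calls <- calls[, scored > 0, drop = FALSE]
    scored <- scored[scored > 0]
  }
  freqs <- lapply(seq_len(ncol(calls)), function(j) {
    tab <- table(calls[, j])
    sort(tab / sum(tab), decreasing = TRUE)
  })
  names(freqs) <- colnames(calls)
  out <- data.frame(
    locus = colnames(calls),
    n_scored = as.integer(scored),
    missing_rate = 1 - scored / nrow(calls),
    Na = vapply(freqs, length, 1L),
    MAF = vapply(freqs, function(f) unname(f[1]), 1.0),
    PIC = vapply(freqs, function(f) pic(as.numeric(f), method), 1.0),
    stringsAsFactors = FALSE
  )
  out$monomorphic <- out$Na == 1L
  rownames(out) <- NULL
  structure(out, class = c("agt_locus_stats", "data.frame"),
            frequencies = freqs, method = method)
}

#' Marker-based genetic distances between genotypes
#'
#' Three dissimilarities over single-call (inbred) marker profiles:
#' \describe{
#'   \item{nei_li}{\eqn{1 - 2 n_{shared}/(n_x + n_y)} on band
#'     presence/absence, where each allele at each locus is one band and a
#'     genotype carries the band of its call.}
#'   \item{shared_allele}{1 minus the proportion of co-scored loci with the
#'     same allele call.}
#'   \item{mismatch}{Unnormalized count of co-scored loci with differing
#'     calls.}
#' }
#' Pairs with no co-scored locus get \code{NA} and a warning.
#'
#' @param markers An [agt_markers()] dataset with at least two genotypes.
#' @param metric One of \code{"nei_li"}, \code{"shared_allele"},
#'   \code{"mismatch"}.
#' @return A \code{stats::dist} with attribute \code{metric}.
#' @export
genetic_distance <- function(markers,
                             metric = c("nei_li", "shared_allele",
                                        "mismatch")) {
  metric <- match.arg(metric)
  stopifnot(inherits(markers, "agt_markers"))
  calls <- markers$calls
  n <- nrow(calls)
  if (n < 2) stop("need at least 2 genotypes")
  D <- matrix(0, n, n, dimnames = list(rownames(calls), rownames(calls)))
  any_uncoscored <- FALSE
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      co <- !is.na(calls[i, ]) & !is.na(calls[j, ])
      if (!any(co)) {
        D[i, j] <- D[j, i] <- NA
        any_uncoscored <- TRUE
        next
      }
      same <- calls[i, co] == calls[j, co]
      d <- switch(metric,
        nei_li = {
          nx <- sum(co); ny <- sum(co)      # one band per co-scored locus
          1 - 2 * sum(same) / (nx + ny)
        },
        shared_allele = 1 - mean(same),
        mismatch = sum(!same)
      )
      D[i, j] <- D[j, i] <- d
    }
  }
  if (any_uncoscored) {
    warning("genotype pair(s) with no co-scored locus: distance set to NA")
  }
  d <- stats::as.dist(D)
  attr(d, "metric") <- metric
  d
}

#' Single-marker trait association
#'
#' One-way ANOVA of each trait over the allele classes of each marker
#' (single-factor single-marker analysis). Reports the F-test p-value, the
#' percent of trait variance explained
#' \eqn{R^2 = 100 \, SS_{marker}/SS_{total}}, and both the raw p-values and
#' Benjamini-Hochberg adjusted ones across the marker x trait grid.
#' Genotype labels are case/whitespace-normalized before matching the
#' marker and phenotype tables.
#'
#' @param markers An [agt_markers()] dataset.
#' @param records Genotype-mean data frame.
#' @param traits Trait codes to test (default: all registered traits
#'   present).
#' @param alpha Significance threshold for the \code{significant} flag.
#' @param min_class_size Minimum genotypes per allele class for the class
#'   to enter the ANOVA (default 2).
#' @return Data frame of class \code{agt_mta}: one row per tested
#'   marker x trait with \code{marker}, \code{trait}, \code{n},
#'   \code{n_classes}, \code{f}, \code{p}, \code{r2}, \code{p_bh},
#'   \code{significant}; skipped combinations are listed in attribute
#'   \code{skipped} with reasons.
#' @export
single_marker_analysis <- function(markers, records, traits = NULL,
                                   alpha = 0.05, min_class_size = 2L) {
  stopifnot(inherits(markers, "agt_markers"))
  if (is.null(traits)) traits <- intersect(trait_codes(), names(records))
  key_m <- normalize_genotype(rownames(markers$calls))
  key_p <- normalize_genotype(records$genotype)
  common <- intersect(key_m, key_p)
  if (length(common) < 4) stop("fewer than 4 genotypes shared between files")
  calls <- markers$calls[match(common, key_m), , drop = FALSE]
  phen <- records[match(common, key_p), , drop = FALSE]

  rows <- list(); skipped <- list()
  for (locus in colnames(calls)) {
    for (tr in traits) {
      cl <- calls[, locus]
      y <- phen[[tr]]
      ok <- !is.na(cl) & !is.na(y)
      cl <- cl[ok]; y <- y[ok]
      keep_classes <- names(which(table(cl) >= min_class_size))
      sel <- cl %in% keep_classes
      cl <- cl[sel]; y <- y[sel]
      if (length(unique(cl)) < 2) {
        skipped[[length(skipped) + 1]] <-
          data.frame(marker = locus, trait = tr,
                     reason = "fewer than 2 usable allele classes")
        next
      }
      if (stats::sd(y) == 0) {
        skipped[[length(skipped) + 1]] <-
          data.frame(marker = locus, trait = tr, reason = "constant trait")
        next
      }
      fit <- stats::aov(y ~ factor(cl))
      sm <- summary(fit)[[1]]
      ssb <- sm[["Sum Sq"]][1]; sse <- sm[["Sum Sq"]][2]
      rows[[length(rows) + 1]] <- data.frame(
        marker = locus, trait = tr, n = length(y),
        n_classes = length(unique(cl)),
        f = sm[["F value"]][1], p = sm[["Pr(>F)"]][1],
        r2 = 100 * ssb / (ssb + sse),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker = character(0), trait = character(0), n = integer(0),
               n_classes = integer(0), f = numeric(0), p = numeric(0),
               r2 = numeric(0))
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  structure(out, class = c("agt_mta", "data.frame"),
            skipped = if (length(skipped)) do.call(rbind, skipped),
            alpha = alpha)
}

#' @export
print.agt_mta <- function(x, ...) {
  cat(sprintf("Single-marker associations: %d tested, %d significant at alpha = %g (raw p)\n",
              nrow(x), sum(x$significant), attr(x, "alpha")))
  df <- as.data.frame(x)
  df$f <- signif(df$f, 4); df$p <- signif(df$p, 3)
  df$r2 <- signif(df$r2, 4); df$p_bh <- signif(df$p_bh, 3)
  print(utils::head(df[order(df$p), ], 10), row.names = FALSE)
  sk <- attr(x, "skipped")
  if (!is.null(sk)) cat(sprintf("(%d combination(s) skipped)\n", nrow(sk)))
  invisible(x)
}
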