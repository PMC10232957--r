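#' Newman-Keuls (SNK) multiple-range comparison with compact letters
#'
#' Groups are ranked by mean (descending) and compared with the stepwise
#' studentized-range test: a pair of means separated by p ranks is declared
#' different when their difference exceeds
#' \eqn{q_{\alpha, p, df_e} \sqrt{ MS_e/2 \, (1/n_i + 1/n_j) }}
#' (a Tukey-Kramer style standard error, so unequal group sizes are
#' handled); whenever a spanning range is non-significant, all ranges nested
#' inside it are declared non-significant without further testing (the
#' standard protection of the Newman-Keuls procedure). The compact letter
#' display marks the maximal runs of mutually indistinguishable groups.
#'
#' The error mean square is taken from the one-way ANOVA across the groups
#' (experimental unit = the values supplied, typically genotype means).
#'
#' @param values_by_group Named list of numeric vectors, one per group.
#' @param alpha Familywise significance level (default 0.05).
#' @return Object of class \code{agt_snk}: data frame with \code{group},
#'   \code{n}, \code{mean}, \code{sd}, \code{letters}, ordered by descending
#'   mean. Groups sharing any letter are not significantly different at
#'   \code{alpha}. Attributes carry \code{mse}, \code{df_error},
#'   \code{alpha} and a \code{flags} character vector (degenerate cases).
#' @examples
#' snk_letters(list(a = c(10, 11, 12), b = c(10.2, 11.1, 12.3),
#'                  c = c(30, 31, 32)))
#' @export
snk_letters <- function(values_by_group, alpha = 0.05) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 1,
            alpha > 0, alpha < 1)
  if (is.null(names(values_by_group)) ||
      any(!nzchar(names(values_by_group)))) {
    stop("values_by_group must be a fully named list")
  }
  flags <- character(0)

  n <- vapply(values_by_group, length, 1L)
  means <- vapply(values_by_group, mean, 1.0)
  sds <- vapply(values_by_group, stats::sd, 1.0)

  # singleton groups contribute no within-group df; they are reported but
  # excluded from the range tests
  usable <- n >= 2L
  if (any(!usable)) {
    flags <- c(flags, paste0("singleton group(s) excluded from letters: ",
                             paste(names(values_by_group)[!usable],
                                   collapse = ", ")))
  }

  ord <- order(means, decreasing = TRUE)
  out <- data.frame(group = names(values_by_group)[ord], n = n[ord],
                    mean = means[ord], sd = sds[ord],
                    letters = NA_character_, stringsAsFactors = FALSE)

  idx <- which(usable[ord])          # positions (in ranked order) tested
  kk <- length(idx)
  if (kk >= 1) {
    dfe <- sum(out$n[idx] - 1L)
    mse <- if (dfe > 0)
      sum((out$n[idx] - 1L) * out$sd[idx]^2, na.rm = TRUE) / dfe
    else 0
    if (kk == 1L) {
      out$letters[idx] <- "a"
    } else if (mse <= 0 || dfe == 0) {
      # zero within-group variance: equal means share, unequal differ
      flags <- c(flags, "zero within-group variance; letters from exact ties")
      nonsig <- outer(out$mean[idx], out$mean[idx],
                      function(a, b) abs(a - b) < 1e-12)
      out$letters[idx] <- letters_from_nonsig(nonsig)
    } else {
      nonsig <- snk_nonsig_matrix(out$mean[idx], out$n[idx], mse, dfe, alpha)
      out$letters[idx] <- letters_from_nonsig(nonsig)
    }
  } else {
    dfe <- 0; mse <- NA_real_
  }

  structure(out, class = c("agt_snk", "data.frame"),
            mse = mse, df_error = dfe, alpha = alpha, flags = flags)
}

# internal: stepwise SNK over means already sorted in descending order;
# returns logical matrix nonsig[i, j] (TRUE = not significantly different)
snk_nonsig_matrix <- function(means, n, mse, dfe, alpha) {
  k <- length(means)
  nonsig <- diag(TRUE, k)
  # test ranges from widest to narrowest; inherit non-significance inward
  declared_nonsig <- matrix(FALSE, k, k)
  for (span in k:2) {
    for (i in 1:(k - span + 1)) {
      j <- i + span - 1
      if (declared_nonsig[i, j]) next
      qcrit <- stats::qtukey(1 - alpha, span, dfe)
      se <- sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
      if ((means[i] - means[j]) < qcrit * se) {
        # whole range homogeneous: mark every nested pair non-significant
        for (a in i:j) for (b in a:j) declared_nonsig[a, b] <- TRUE
      }
    }
  }
  for (i in 1:k) for (j in i:k) {
    nonsig[i, j] <- nonsig[j, i] <- declared_nonsig[i, j] || i == j
  }
  nonsig
}

# internal: compact letter display for a non-significance structure that is
# contiguous in rank order (range tests): maximal homogeneous intervals
letters_from_nonsig <- function(nonsig) {
  k <- nrow(nonsig)
  # candidate intervals [i, j] entirely non-significant
  homog <- function(i, j) all(nonsig[i:j, i:j])
  intervals <- list()
  for (i in 1:k) {
    j <- i
    while (j < k && homog(i, j + 1)) j <- j + 1
    intervals[[length(intervals) + 1]] <- c(i, j)
  }
  # keep maximal intervals only
  keep <- vapply(seq_along(intervals), function(a) {
    ia <- intervals[[a]]
    !any(vapply(seq_along(intervals), function(b) {
      ib <- intervals[[b]]
      a != b && ib[1] <= ia[1] && ia[2] <= ib[2] &&
        (ib[1] < ia[1] || ib[2] > ia[2])
    }, TRUE))
  }, TRUE)
  intervals <- unique(intervals[keep])
  lab <- rep("", k)
  for (m in seq_along(intervals)) {
    rng <- intervals[[m]]
    lab[rng[1]:rng[2]] <- paste0(lab[rng[1]:rng[2]], letters[m])
  }
  lab
}

#' @export
print.agt_snk <- function(x, ...) {
  cat(sprintf("Newman-Keuls comparison (alpha = %g, MSe = %.4g, df = %d)\n",
              attr(x, "alpha"), attr(x, "mse"), attr(x, "df_error")))
  df <- as.data.frame(x)
  df$mean <- signif(df$mean, 6)
  df$sd <- signif(df$sd, 4)
  print(df, row.names = FALSE)
  fl <- attr(x, "flags")
  if (length(fl)) cat("Flags:", paste(fl, collapse = "; "), "\n")
  invisible(x)
}

#' Grouped trait summaries with SNK letters
#'
#' For each requested trait, summarises a scored genotype panel by a
#' grouping column (tolerance class, grain type, cluster, ...) as
#' n / mean / sd per group plus the Newman-Keuls compact letter display
#' across groups (experimental unit = genotype).
#'
#' @param records Data frame of genotype records carrying the grouping
#'   column (e.g. the output of [score_panel()]).
#' @param by Name of the grouping column.
#' @param traits Trait codes to summarise (default: all registered traits
#'   present in \code{records}).
#' @param alpha Significance level for the letter display.
#' @return Data frame of class \code{agt_group_summary} with columns
#'   \code{trait}, \code{group}, \code{n}, \code{mean}, \code{sd},
#'   \code{letters} (groups ordered by descending mean within trait).
#' @examples
#' scored <- score_panel(agt_panel())
#' head(group_summary(scored, by = "tolerance_class", traits = "AGP"))
#' @export
group_summary <- function(records, by, traits = NULL, alpha = 0.05) {
  if (!by %in% names(records)) stop("grouping column not found: ", by)
  if (any(is.na(records[[by]]))) {
    stop("grouping labels must be present on every record")
  }
  if (is.null(traits)) traits <- intersect(trait_codes(), names(records))
  missing_tr <- setdiff(traits, names(records))
  if (length(missing_tr)) {
    stop("trait column(s) not found: ", paste(missing_tr, collapse = ", "))
  }
  out <- do.call(rbind, lapply(traits, function(tr) {
    vals <- split(records[[tr]], records[[by]], drop = TRUE)
    snk <- snk_letters(vals, alpha = alpha)
    cbind(trait = tr, as.data.frame(snk), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("agt_group_summary", "data.frame"), by = by,
            alpha = alpha)
}
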