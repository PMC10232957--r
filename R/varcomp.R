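#' Variance components from a screening trial
#'
#' Method-of-moments estimation from the expected mean squares of the
#' randomized-complete-block ANOVA: per season,
#' \eqn{\sigma^2_e = MS_{error}} and
#' \eqn{\sigma^2_g = (MS_{genotype} - MS_{error})/r};
#' pooled over seasons,
#' \eqn{\sigma^2_{ge} = (MS_{g\times s} - MS_{error})/r} and
#' \eqn{\sigma^2_g = (MS_{genotype} - MS_{g\times s})/(r s)}, with the
#' genotype F ratio tested against the genotype-by-season mean square.
#' Negative estimates are clamped at zero and flagged (raw values are kept
#' in the returned table's attributes).
#'
#' @param trial An [agt_trial()] object with a balanced layout for the
#'   requested trait.
#' @param trait Registered trait code to analyse.
#' @param season Season label (single-season analysis); defaults to the only
#'   season present.
#' @param treatment Treatment stratum analysed (default \code{"submerged"};
#'   used only if that treatment is present).
#' @param truncate Clamp negative variance components at zero (default).
#' @return Object of class \code{agt_anova}: list with the ANOVA
#'   \code{table} (source, df, ss, ms, f, p, stars) and \code{components}
#'   (class \code{agt_varcomp}: sigma2_g, sigma2_ge, sigma2_e, r, s,
#'   truncated flags, raw estimates).
#' @seealso [anova_pooled()], [variability_parameters()]
#' @export
anova_rcbd <- function(trial, trait, season = NULL,
                       treatment = "submerged", truncate = TRUE) {
  d <- trial_slice(trial, trait, treatment)
  if (is.null(season)) {
    if (length(unique(d$season)) > 1L) {
      stop("multiple seasons present; give `season` or use anova_pooled()")
    }
    season <- d$season[1]
  }
  d <- d[d$season == season, ]
  if (!nrow(d)) stop("no observations for season ", season)
  check_balance(d, within_season = TRUE)
  g <- length(unique(d$genotype))
  r <- length(unique(d$replicate))
  if (g < 2) stop("need at least 2 genotypes")
  if (r < 2) stop("need at least 2 replicates (error MS undefined at r = 1)")

  fit <- stats::aov(value ~ genotype + replicate,
                    data = transform(d, genotype = factor(genotype),
                                     replicate = factor(replicate)))
  ss <- summary(fit)[[1]][["Sum Sq"]]
  df <- summary(fit)[[1]][["Df"]]
  names(ss) <- names(df) <- trimws(rownames(summary(fit)[[1]]))
  if (max(d$value) == min(d$value)) ss[] <- 0   # exact zeros, not QR noise
  ms <- ss / df

  mse <- ms[["Residuals"]]
  f_g <- if (mse > 0) ms[["genotype"]] / mse else NA_real_
  p_g <- if (is.finite(f_g))
    stats::pf(f_g, df[["genotype"]], df[["Residuals"]], lower.tail = FALSE)
  else NA_real_
  f_r <- if (mse > 0) ms[["replicate"]] / mse else NA_real_
  p_r <- if (is.finite(f_r))
    stats::pf(f_r, df[["replicate"]], df[["Residuals"]], lower.tail = FALSE)
  else NA_real_

  tab <- data.frame(
    source = c("genotype", "replicate", "error"),
    df = c(df[["genotype"]], df[["replicate"]], df[["Residuals"]]),
    ss = c(ss[["genotype"]], ss[["replicate"]], ss[["Residuals"]]),
    ms = c(ms[["genotype"]], ms[["replicate"]], mse),
    f = c(f_g, f_r, NA),
    p = c(p_g, p_r, NA),
    stringsAsFactors = FALSE
  )
  tab$stars <- p_stars(tab$p)

  raw_g <- (ms[["genotype"]] - mse) / r
  comp <- new_varcomp(sigma2_g = raw_g, sigma2_ge = NA_real_,
                      sigma2_e = mse, r = r, s = 1L, truncate = truncate)
  structure(list(table = tab, components = comp, trait = trait,
                 season = season, pooled = FALSE),
            class = "agt_anova")
}

#' Pooled-over-seasons ANOVA and variance components
#'
#' @inheritParams anova_rcbd
#' @return See [anova_rcbd()]; the pooled table carries sources genotype,
#'   season, replicate-within-season, genotype x season and pooled error,
#'   and the components include \code{sigma2_ge}.
#' @export
anova_pooled <- function(trial, trait, treatment = "submerged",
                         truncate = TRUE) {
  d <- trial_slice(trial, trait, treatment)
  s <- length(unique(d$season))
  if (s < 2) stop("single season present; use anova_rcbd()")
  check_balance(d, within_season = TRUE)
  g <- length(unique(d$genotype))
  r <- length(unique(d$replicate))
  if (g < 2) stop("need at least 2 genotypes")
  if (r < 2) stop("need at least 2 replicates")

  dd <- transform(d, genotype = factor(genotype), season = factor(season),
                  replicate = factor(replicate))
  fit <- stats::aov(value ~ genotype + season + season:replicate +
                      genotype:season, data = dd)
  sm <- summary(fit)[[1]]
  key <- gsub(" ", "", rownames(sm))
  ss <- stats::setNames(sm[["Sum Sq"]], key)
  df <- stats::setNames(sm[["Df"]], key)
  if (max(d$value) == min(d$value)) ss[] <- 0   # exact zeros, not QR noise
  ms <- ss / df

  mse <- ms[["Residuals"]]
  ms_gs <- ms[["genotype:season"]]
  # genotype tested against G x S; G x S and blocks against pooled error
  rows <- list(
    genotype = c(ms[["genotype"]], ms_gs),
    season = c(ms[["season"]], mse),
    `replicate_within_season` = c(ms[["season:replicate"]], mse),
    `genotype_x_season` = c(ms_gs, mse)
  )
  dfe <- df[["Residuals"]]
  dfd <- c(df[["genotype:season"]], dfe, dfe, dfe)
  src <- c("genotype", "season", "season:replicate", "genotype:season")
  f <- p <- numeric(4)
  for (i in seq_along(rows)) {
    denom <- rows[[i]][2]
    f[i] <- if (denom > 0) rows[[i]][1] / denom else NA_real_
    p[i] <- if (is.finite(f[i]))
      stats::pf(f[i], df[[src[i]]], dfd[i], lower.tail = FALSE)
    else NA_real_
  }

  tab <- data.frame(
    source = c(names(rows), "error"),
    df = c(df[src], dfe),
    ss = c(ss[src], ss[["Residuals"]]),
    ms = c(ms[src], mse),
    f = c(f, NA),
    p = c(p, NA),
    stringsAsFactors = FALSE
  )
  tab$stars <- p_stars(tab$p)

  raw_ge <- (ms_gs - mse) / r
  raw_g <- (ms[["genotype"]] - ms_gs) / (r * s)
  comp <- new_varcomp(sigma2_g = raw_g, sigma2_ge = raw_ge, sigma2_e = mse,
                      r = r, s = s, truncate = truncate)
  structure(list(table = tab, components = comp, trait = trait,
                 season = NULL, pooled = TRUE),
            class = "agt_anova")
}

# internal: one trait x treatment slice of the long table
trial_slice <- function(trial, trait, treatment) {
  stopifnot(inherits(trial, "agt_trial"))
  obs <- trial$observations
  if (treatment %in% obs$treatment) obs <- obs[obs$treatment == treatment, ]
  d <- obs[obs$trait == trait, ]
  if (!nrow(d)) stop("no observations for trait ", trait)
  d
}

# internal: require exactly one observation per design cell
check_balance <- function(d, within_season = TRUE) {
  cells <- table(d$genotype, d$season, d$replicate)
  if (any(cells != 1L)) {
    idx <- which(cells != 1L, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "unbalanced design: genotype %s, season %s, replicate %s has %d observation(s)",
      dimnames(cells)[[1]][idx[1]], dimnames(cells)[[2]][idx[2]],
      dimnames(cells)[[3]][idx[3]],
      cells[idx[1], idx[2], idx[3]]))
  }
  invisible(TRUE)
}

# internal
new_varcomp <- function(sigma2_g, sigma2_ge, sigma2_e, r, s, truncate) {
  raw <- c(g = sigma2_g, ge = sigma2_ge, e = sigma2_e)
  truncated <- c(g = FALSE, ge = FALSE)
  if (truncate) {
    if (is.finite(sigma2_g) && sigma2_g < 0) {
      sigma2_g <- 0; truncated["g"] <- TRUE
    }
    if (is.finite(sigma2_ge) && sigma2_ge < 0) {
      sigma2_ge <- 0; truncated["ge"] <- TRUE
    }
  }
  structure(list(sigma2_g = sigma2_g, sigma2_ge = sigma2_ge,
                 sigma2_e = sigma2_e, r = r, s = s,
                 truncated = truncated, raw = raw),
            class = "agt_varcomp")
}

# internal: significance codes, ** at 0.01 as in the screening report
p_stars <- function(p) {
  ifelse(is.na(p), "",
  ifelse(p < 0.001, "***",
  ifelse(p < 0.01, "**",
  ifelse(p < 0.05, "*", ""))))
}

#' @export
print.agt_varcomp <- function(x, ...) {
  cat(sprintf("Variance components (r = %d, s = %d):\n", x$r, x$s))
  cat(sprintf("  sigma2_g  = %.4f%s\n", x$sigma2_g,
              if (x$truncated["g"]) " (truncated at 0)" else ""))
  if (is.finite(x$sigma2_ge)) {
    cat(sprintf("  sigma2_ge = %.4f%s\n", x$sigma2_ge,
                if (x$truncated["ge"]) " (truncated at 0)" else ""))
  }
  cat(sprintf("  sigma2_e  = %.4f\n", x$sigma2_e))
  invisible(x)
}

#' @export
print.agt_anova <- function(x, ...) {
  cat(sprintf("%s ANOVA for %s%s\n",
              if (x$pooled) "Pooled" else "RCBD", x$trait,
              if (!is.null(x$season)) paste0(" (season ", x$season, ")")
              else ""))
  tab <- x$table
  tab$ss <- signif(tab$ss, 6)
  tab$ms <- signif(tab$ms, 6)
  tab$f <- signif(tab$f, 4)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  print(x$components)
  invisible(x)
}
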