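#' Genetic variability parameters
#'
#' Computes the standard germplasm-screening variability statistics from
#' variance components and the trait grand mean:
#' \deqn{GCV = 100 \sqrt{\sigma^2_g}/\bar{x}, \quad
#'       PCV = 100 \sqrt{\sigma^2_p}/\bar{x}, \quad
#'       h^2_{bs} = 100 \, \sigma^2_g/\sigma^2_p,}
#' genetic advance \eqn{GA = k (h^2_{bs}/100) \sigma_g} (the
#' \code{"genotypic"} variant, default) or
#' \eqn{k (h^2_{bs}/100) \sigma_p} (the textbook \code{"phenotypic"}
#' variant), \eqn{GAM = 100 GA/\bar{x}}, and
#' \eqn{SED = \sqrt{2\sigma^2_e/r}}.
#'
#' The phenotypic variance \eqn{\sigma^2_p} depends on the chosen basis:
#' \code{plot} uses \eqn{\sigma^2_g + \sigma^2_{ge} + \sigma^2_e};
#' \code{entry_mean} uses
#' \eqn{\sigma^2_g + \sigma^2_{ge}/s + \sigma^2_e/(rs)};
#' \code{single_env} uses \eqn{\sigma^2_g + \sigma^2_e}. The default
#' (\code{auto}) picks \code{single_env} for single-season components and
#' \code{plot} otherwise.
#'
#' @param components An \code{agt_varcomp} object (from [anova_rcbd()] or
#'   [anova_pooled()]), or a list with \code{sigma2_g}, \code{sigma2_ge}
#'   (may be \code{NA}), \code{sigma2_e}, \code{r}, \code{s}.
#' @param mean Trait grand mean (> 0).
#' @param k Selection differential; 2.06 corresponds to selecting the top 5%.
#' @param basis Phenotypic-variance basis (see Details).
#' @param ga_basis Which standard deviation multiplies the heritability in
#'   GA: \code{"genotypic"} (default) or \code{"phenotypic"}.
#' @return Object of class \code{agt_variability}: list with \code{gcv},
#'   \code{pcv}, \code{h2bs}, \code{ga}, \code{gam}, \code{sed}, \code{mean},
#'   \code{k}, \code{basis}, \code{ga_basis} and the variances used.
#' @seealso [variability_from_cv()], [categorize_variability()]
#' @export
variability_parameters <- function(components, mean, k = 2.06,
                                   basis = c("auto", "plot", "entry_mean",
                                             "single_env"),
                                   ga_basis = c("genotypic", "phenotypic")) {
  basis <- match.arg(basis)
  ga_basis <- match.arg(ga_basis)
  if (!is.finite(mean) || mean <= 0) stop("mean must be positive")
  s2g <- components$sigma2_g
  s2ge <- components$sigma2_ge
  s2e <- components$sigma2_e
  r <- components$r
  s <- components$s
  if (is.null(s2ge) || !is.finite(s2ge)) s2ge <- NA_real_
  if (any(c(s2g, s2e) < 0, na.rm = TRUE)) {
    stop("variance components must be non-negative")
  }
  if (basis == "auto") {
    basis <- if (is.na(s2ge) || s <= 1) "single_env" else "plot"
  }
  ge <- if (is.na(s2ge)) 0 else s2ge
  s2p <- switch(basis,
                plot = s2g + ge + s2e,
                entry_mean = s2g + ge / s + s2e / (r * s),
                single_env = s2g + s2e)

  gcv <- 100 * sqrt(s2g) / mean
  pcv <- 100 * sqrt(s2p) / mean
  h2 <- if (s2p > 0) 100 * s2g / s2p else NA_real_
  sd_sel <- if (ga_basis == "genotypic") sqrt(s2g) else sqrt(s2p)
  ga <- if (is.na(h2)) 0 else k * (h2 / 100) * sd_sel
  gam <- 100 * ga / mean
  sed <- sqrt(2 * s2e / r)

  structure(list(gcv = gcv, pcv = pcv, h2bs = h2, ga = ga, gam = gam,
                 sed = sed, mean = mean, k = k, basis = basis,
                 ga_basis = ga_basis, sigma2_g = s2g, sigma2_p = s2p,
                 sigma2_e = s2e, h2_undefined = is.na(h2)),
            class = "agt_variability")
}

#' Variability parameters from published coefficients of variation
#'
#' Reconstructs the genotypic and phenotypic standard deviations from
#' printed GCV/PCV/mean triples (\eqn{\sigma_g = GCV \cdot \bar{x}/100},
#' \eqn{\sigma_p = PCV \cdot \bar{x}/100}) and derives heritability, genetic
#' advance and GAM from them. Useful for internal-consistency checks of
#' published variability tables.
#'
#' @param gcv,pcv Coefficients of variation in percent (vectorized).
#' @param mean Trait grand mean(s).
#' @param k Selection differential.
#' @param ga_basis See [variability_parameters()].
#' @return Data frame with \code{gcv}, \code{pcv}, \code{mean},
#'   \code{h2bs}, \code{ga}, \code{gam}.
#' @examples
#' variability_from_cv(50.00, 55.20, 59.80)  # h2bs 82.04, GA 50.54
#' @export
variability_from_cv <- function(gcv, pcv, mean, k = 2.06,
                                ga_basis = c("genotypic", "phenotypic")) {
  ga_basis <- match.arg(ga_basis)
  stopifnot(all(pcv > 0), all(mean > 0), all(gcv >= 0))
  sigma_g <- gcv * mean / 100
  sigma_p <- pcv * mean / 100
  h2 <- 100 * (gcv / pcv)^2
  sd_sel <- if (ga_basis == "genotypic") sigma_g else sigma_p
  ga <- k * (h2 / 100) * sd_sel
  gam <- 100 * ga / mean
  data.frame(gcv = gcv, pcv = pcv, mean = mean, h2bs = h2, ga = ga,
             gam = gam)
}

#' Categorical labels for variability parameters
#'
#' Conventional cutoffs used in germplasm-screening reports:
#' GCV/PCV and GAM: < 10 low, 10--20 moderate, > 20 high;
#' heritability: < 30 low, 30--60 moderate, > 60 high.
#'
#' @param params An \code{agt_variability} object or list with \code{gcv},
#'   \code{pcv}, \code{h2bs}, \code{gam}.
#' @return Named character vector with labels for gcv, pcv, h2bs, gam.
#' @export
categorize_variability <- function(params) {
  cv_cat <- function(x) ifelse(x < 10, "low",
                               ifelse(x <= 20, "moderate", "high"))
  h2_cat <- function(x) ifelse(x < 30, "low",
                               ifelse(x <= 60, "moderate", "high"))
  c(gcv = cv_cat(params$gcv), pcv = cv_cat(params$pcv),
    h2bs = h2_cat(params$h2bs), gam = cv_cat(params$gam))
}

#' @export
print.agt_variability <- function(x, ...) {
  cat(sprintf(
    "Variability parameters (mean %.4g, k = %.2f, basis %s, GA on sigma_%s):\n",
    x$mean, x$k, x$basis, if (x$ga_basis == "genotypic") "g" else "p"))
  cat(sprintf("  GCV %.2f%%  PCV %.2f%%  h2bs %.2f%%  GA %.4g  GAM %.2f%%  SED %.4g\n",
              x$gcv, x$pcv, x$h2bs, x$ga, x$gam, x$sed))
  invisible(x)
}
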