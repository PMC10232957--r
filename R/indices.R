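#' Anaerobic vigor index
#'
#' AVI = AGP x (shoot length + root length), measured on the submerged
#' seedlings. The %.cm product is treated as a dimensionless vigor score.
#'
#' @param agp Anaerobic germination percentage, in [0, 100].
#' @param shoot_length,root_length Seedling lengths (cm), non-negative.
#' @return Numeric index (vectorized).
#' @examples
#' anaerobic_vigor_index(100, 33.53, 8.53)  # 4206
#' @export
anaerobic_vigor_index <- function(agp, shoot_length, root_length) {
  if (any(agp < 0 | agp > 100)) stop("agp must lie in [0, 100]")
  if (any(shoot_length < 0) || any(root_length < 0)) {
    stop("lengths must be non-negative")
  }
  agp * (shoot_length + root_length)
}

#' Response index
#'
#' RI = shoot length under submergence minus shoot length under control.
#' Positive values indicate submergence-stimulated shoot elongation (the
#' escape strategy); negative values indicate shoot reduction under hypoxia.
#'
#' @param shoot_submerged,shoot_control Shoot lengths (cm), non-negative.
#' @return Signed difference in cm (vectorized).
#' @export
response_index <- function(shoot_submerged, shoot_control) {
  if (any(shoot_submerged < 0) || any(shoot_control < 0)) {
    stop("shoot lengths must be non-negative")
  }
  shoot_submerged - shoot_control
}

#' Tolerance classification from germination percentage
#'
#' Partition of AGP into four submergence-tolerance categories:
#' AGP >= 90 tolerant; 70 < AGP < 90 moderately tolerant;
#' 40 < AGP <= 70 moderately susceptible; AGP <= 40 susceptible.
#' The published integer bands (71--89, 41--70) leave fractional AGP values
#' unassigned; the half-open intervals above make the partition total while
#' reproducing the published class counts on the packaged panel.
#'
#' @param agp Anaerobic germination percentage, in [0, 100] (vectorized).
#' @return Ordered factor with levels \code{susceptible} <
#'   \code{moderately_susceptible} < \code{moderately_tolerant} <
#'   \code{tolerant}.
#' @export
classify_tolerance <- function(agp) {
  if (any(!is.finite(agp)) || any(agp < 0 | agp > 100)) {
    stop("agp must lie in [0, 100]")
  }
  lev <- c("susceptible", "moderately_susceptible", "moderately_tolerant",
           "tolerant")
  out <- ifelse(agp >= 90, "tolerant",
         ifelse(agp > 70, "moderately_tolerant",
         ifelse(agp > 40, "moderately_susceptible", "susceptible")))
  factor(out, levels = lev, ordered = TRUE)
}

#' Grain-type classification rule
#'
#' Kernel dimension thresholds for the five standard market grain types.
#' Defaults: kernels >= 6 mm are "long"; length-to-breadth ratio >= 3 is
#' "slender"; short kernels with LBR in [2.5, 3) are "medium-slender".
#' Because short-slender accessions are rare in typical panels, they are by
#' default reported merged into the short-bold group
#' (\code{merge_short_slender}).
#'
#' @param long_threshold Kernel length (mm) at or above which a grain is long.
#' @param slender_threshold LBR at or above which a grain is slender.
#' @param medium_slender_lbr_floor Lower LBR bound of the medium-slender band.
#' @param merge_short_slender Report short-slender as short-bold.
#' @return A list of class \code{grain_type_rule}.
#' @export
grain_type_rule <- function(long_threshold = 6.0, slender_threshold = 3.0,
                            medium_slender_lbr_floor = 2.5,
                            merge_short_slender = TRUE) {
  if (!(medium_slender_lbr_floor > 0 &&
        medium_slender_lbr_floor < slender_threshold)) {
    stop("need 0 < medium_slender_lbr_floor < slender_threshold")
  }
  structure(list(long_threshold = long_threshold,
                 slender_threshold = slender_threshold,
                 medium_slender_lbr_floor = medium_slender_lbr_floor,
                 merge_short_slender = merge_short_slender),
            class = "grain_type_rule")
}

#' Classify grain type from kernel dimensions
#'
#' @param kernel_length Kernel length in mm (> 0).
#' @param lbr Length-to-breadth ratio (> 0).
#' @param rule A [grain_type_rule()].
#' @return Factor with levels \code{Long-slender}, \code{Long-bold},
#'   \code{Medium-slender}, \code{Short-slender}, \code{Short-bold}
#'   (\code{Short-slender} absent when the merge flag is on).
#' @examples
#' classify_grain_type(6.4, 2.91)  # Long-bold
#' @export
classify_grain_type <- function(kernel_length, lbr,
                                rule = grain_type_rule()) {
  if (any(kernel_length <= 0) || any(lbr <= 0)) {
    stop("kernel_length and lbr must be positive")
  }
  long <- kernel_length >= rule$long_threshold
  slender <- lbr >= rule$slender_threshold
  medium <- !long & !slender & lbr >= rule$medium_slender_lbr_floor
  out <- ifelse(long & slender, "Long-slender",
         ifelse(long, "Long-bold",
         ifelse(slender, "Short-slender",
         ifelse(medium, "Medium-slender", "Short-bold"))))
  if (rule$merge_short_slender) out[out == "Short-slender"] <- "Short-bold"
  lev <- c("Long-bold", "Long-slender", "Medium-slender", "Short-slender",
           "Short-bold")
  if (rule$merge_short_slender) lev <- setdiff(lev, "Short-slender")
  factor(out, levels = lev)
}

#' Score a genotype panel
#'
#' Annotates each genotype-mean record with its tolerance class (from AGP)
#' and, when kernel dimensions are present, the rule-derived grain type, and
#' tallies the class counts.
#'
#' @param records Genotype-mean data frame as returned by
#'   [read_genotype_means()] or [agt_panel()].
#' @param rule A [grain_type_rule()] for the kernel classification.
#' @return The input data frame with added columns \code{tolerance_class}
#'   and \code{grain_type_rule}, of class \code{agt_scored}; class counts are
#'   attached as attributes \code{tolerance_counts} and
#'   \code{grain_type_counts}.
#' @examples
#' scored <- score_panel(agt_panel())
#' attr(scored, "tolerance_counts")
#' @export
score_panel <- function(records, rule = grain_type_rule()) {
  if (nrow(records) == 0) {
    records$tolerance_class <- factor(character(0))
    records$grain_type_rule <- factor(character(0))
    return(structure(records, class = c("agt_scored", "data.frame"),
                     tolerance_counts = table(factor(character(0))),
                     grain_type_counts = table(factor(character(0)))))
  }
  if (!"AGP" %in% names(records)) stop("records must carry an AGP column")
  records$tolerance_class <- classify_tolerance(records$AGP)
  if (all(c("KL", "LBR") %in% names(records))) {
    records$grain_type_rule <- classify_grain_type(records$KL, records$LBR,
                                                   rule)
  }
  structure(records, class = c("agt_scored", "data.frame"),
            tolerance_counts = table(records$tolerance_class),
            grain_type_counts = if (!is.null(records$grain_type_rule))
              table(records$grain_type_rule))
}

#' @export
print.agt_scored <- function(x, ...) {
  cat(sprintf("Scored panel: %d genotype(s)\n", nrow(x)))
  tc <- attr(x, "tolerance_counts")
  if (!is.null(tc)) {
    cat("Tolerance classes:\n")
    print(tc)
  }
  gc <- attr(x, "grain_type_counts")
  if (!is.null(gc)) {
    cat("Rule-derived grain types:\n")
    print(gc)
  }
  invisible(x)
}
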