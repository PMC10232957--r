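#' Canonical trait registry for anaerobic-germination screening
#'
#' The screening panel records fourteen traits per genotype: germination and
#' vigor under submergence (AGP, AVI), seedling growth (SL, RL, RI, SRR, NOL,
#' NOR, FW, DW) and kernel morphology (KL, KB, LBR, HSW). All readers and
#' analysis functions accept only these codes.
#'
#' @return A data frame with one row per trait: \code{code}, \code{unit},
#'   \code{label}, \code{higher_is_better}, and the permissible range
#'   (\code{min}, \code{max}; \code{-Inf}/\code{Inf} where unbounded).
#' @examples
#' trait_registry()
#' @export
trait_registry <- function() {
  data.frame(
    code = c("AGP", "AVI", "SL", "RL", "RI", "SRR", "NOL",
             "NOR", "FW", "DW", "KL", "KB", "LBR", "HSW"),
    unit = c("%", "index", "cm", "cm", "cm", "ratio", "count",
             "count", "g", "g", "mm", "mm", "ratio", "g"),
    label = c("anaerobic germination percentage", "anaerobic vigor index",
              "shoot length", "root length", "response index",
              "shoot-to-root ratio", "number of leaves", "number of roots",
              "fresh weight", "dry weight", "kernel length", "kernel breadth",
              "length-to-breadth ratio", "hundred-seed weight"),
    higher_is_better = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
                         TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    min = c(0, 0, 0, 0, -Inf, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    max = c(100, Inf, Inf, Inf, Inf, Inf, Inf, Inf, Inf, Inf, Inf, Inf,
            Inf, Inf),
    stringsAsFactors = FALSE
  )
}

#' @rdname trait_registry
#' @export
trait_codes <- function() trait_registry()$code

# Trait subset used for the anaerobic-germination-potential analyses
# (everything measured on the submerged seedlings, excluding kernel traits).
#' Trait presets
#'
#' \code{ag_traits()} returns the anaerobic-germination-potential trait
#' subset (AGP, AVI, SL, RL, RI, SRR, NOL, NOR, FW, DW); \code{trait_codes()}
#' returns all fourteen.
#' @export
ag_traits <- function() {
  c("AGP", "AVI", "SL", "RL", "RI", "SRR", "NOL", "NOR", "FW", "DW")
}

# internal: range check, returns character vector of violations (empty if ok)
check_trait_range <- function(trait, value) {
  reg <- trait_registry()
  i <- match(trait, reg$code)
  bad <- !is.na(i) & is.finite(value) &
    (value < reg$min[i] | value > reg$max[i])
  which(bad)
}

# internal: genotype labels are matched across phenotype and marker files
# after case and whitespace normalization
normalize_genotype <- function(x) {
  x <- gsub("[‘’'\"]", "", x)
  x <- gsub("\\s+", " ", trimws(x))
  tolower(x)
}
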