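#' Construct a trial dataset from long-format observations
#'
#' A screening trial is stored in long (tidy) format so unbalanced designs
#' remain representable; balance is validated, never assumed. Each row is one
#' cup/plot measurement: genotype x season x replicate x treatment x trait.
#'
#' @param observations Data frame with columns \code{genotype},
#'   \code{season}, \code{replicate} (positive integer), \code{treatment}
#'   (\code{"submerged"} or \code{"control"}), \code{trait} (a registered
#'   trait code) and numeric \code{value}.
#' @param check If \code{TRUE} (default), reject out-of-range trait values at
#'   construction; with \code{FALSE} the object is built anyway and
#'   [validate_trial()] will report the violations.
#' @return An object of class \code{agt_trial}: a list with
#'   \code{observations} and the inferred \code{design} (g genotypes,
#'   s seasons, r replicates).
#' @seealso [read_trial_table()], [validate_trial()], [simulate_trial()]
#' @export
agt_trial <- function(observations, check = TRUE) {
  required <- c("genotype", "season", "replicate", "treatment", "trait",
                "value")
  missing_cols <- setdiff(required, names(observations))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  obs <- observations[required]
  obs$genotype <- as.character(obs$genotype)
  obs$season <- as.character(obs$season)
  obs$treatment <- as.character(obs$treatment)
  obs$trait <- as.character(obs$trait)

  bad_trt <- setdiff(unique(obs$treatment), c("submerged", "control"))
  if (length(bad_trt)) {
    stop("unknown treatment level(s): ", paste(bad_trt, collapse = ", "))
  }
  bad_trait <- setdiff(unique(obs$trait), trait_codes())
  if (length(bad_trait)) {
    stop("unknown trait code(s): ", paste(bad_trait, collapse = ", "))
  }
  if (!is.numeric(obs$value) || any(!is.finite(obs$value))) {
    stop("all trait values must be finite numbers")
  }
  if (any(obs$replicate != round(obs$replicate)) || any(obs$replicate < 1)) {
    stop("replicate must be a positive integer")
  }
  if (check) {
    for (tr in unique(obs$trait)) {
      sel <- obs$trait == tr
      bad <- check_trait_range(obs$trait[sel], obs$value[sel])
      if (length(bad)) {
        rng <- trait_registry()[trait_registry()$code == tr, ]
        stop(sprintf("%s outside [%s,%s]: %d offending value(s), first %g",
                     tr, rng$min, rng$max, length(bad),
                     obs$value[sel][bad[1]]))
      }
    }
  }

  structure(list(
    observations = obs,
    design = list(g = length(unique(obs$genotype)),
                  s = length(unique(obs$season)),
                  r = max(obs$replicate))
  ), class = "agt_trial")
}

#' @export
print.agt_trial <- function(x, ...) {
  d <- x$design
  cat(sprintf(
    "Screening trial: %d genotype(s) x %d season(s) x %d replicate(s); %d observations, traits: %s\n",
    d$g, d$s, d$r, nrow(x$observations),
    paste(sort(unique(x$observations$trait)), collapse = ", ")))
  invisible(x)
}

# internal: sniff delimiter from the header line
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a long-format trial table
#'
#' @param path Path to a delimited text file with header columns
#'   \code{genotype}, \code{season}, \code{replicate}, \code{treatment},
#'   \code{trait}, \code{value}.
#' @param sep Field delimiter; by default auto-detected (TAB if the header
#'   contains one, comma otherwise).
#' @return An [agt_trial()] object.
#' @export
read_trial_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character")
  required <- c("genotype", "season", "replicate", "treatment", "trait",
                "value")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  value <- suppressWarnings(as.numeric(raw$value))
  if (anyNA(value)) {
    bad <- which(is.na(value))[1]
    stop(sprintf("non-numeric value %s at data row %d",
                 dQuote(raw$value[bad]), bad))
  }
  raw$value <- value
  rep_num <- suppressWarnings(as.integer(raw$replicate))
  if (anyNA(rep_num)) stop("non-integer replicate label")
  raw$replicate <- rep_num
  agt_trial(raw)
}

#' Write a trial dataset back to delimited text
#'
#' Inverse of [read_trial_table()]; the write/read round trip is lossless.
#' @param trial An [agt_trial()] object.
#' @param path Output path.
#' @param sep Field delimiter (default comma).
#' @export
write_trial_table <- function(trial, path, sep = ",") {
  stopifnot(inherits(trial, "agt_trial"))
  utils::write.table(trial$observations, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a genotype-mean table
#'
#' One row per genotype: pooled means for the 14 registered traits plus an
#' optional \code{grain_type} column. Duplicate genotype labels and missing
#' trait cells are errors (the downstream analyses assume complete means).
#'
#' @param path Path to a delimited text file.
#' @param sep Field delimiter; auto-detected by default.
#' @return A data frame with \code{genotype}, the 14 trait columns and, if
#'   present, \code{grain_type}.
#' @export
read_genotype_means <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- detect_sep(path)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (!"genotype" %in% names(d)) stop("schema error: missing column genotype")
  missing_tr <- setdiff(trait_codes(), names(d))
  if (length(missing_tr)) {
    stop("schema error: missing trait column(s) ",
         paste(missing_tr, collapse = ", "))
  }
  dup <- d$genotype[duplicated(normalize_genotype(d$genotype))]
  if (length(dup)) {
    stop("duplicate genotype label(s): ", paste(unique(dup), collapse = ", "))
  }
  for (tr in trait_codes()) {
    if (!is.numeric(d[[tr]])) d[[tr]] <- suppressWarnings(as.numeric(d[[tr]]))
    if (anyNA(d[[tr]])) {
      g <- d$genotype[which(is.na(d[[tr]]))[1]]
      stop(sprintf("missing %s value for genotype %s", tr, dQuote(g)))
    }
    bad <- check_trait_range(rep(tr, nrow(d)), d[[tr]])
    if (length(bad)) {
      stop(sprintf("%s outside permissible range for genotype %s",
                   tr, dQuote(d$genotype[bad[1]])))
    }
  }
  keep <- c("genotype", trait_codes(),
            intersect("grain_type", names(d)))
  d[keep]
}

#' The packaged 119-genotype screening panel
#'
#' Pooled genotype means (two seasons, three replicates, five seeds per
#' replicate) for 115 south-Indian rice landraces and four check varieties
#' screened under 15 days of submergence, with the published grain-type
#' label for each genotype.
#'
#' @return Data frame of 119 genotypes x 14 traits + \code{grain_type}.
#' @examples
#' panel <- agt_panel()
#' nrow(panel)
#' @export
agt_panel <- function() {
  read_genotype_means(system.file("extdata", "genotype_means_table4.csv",
                                  package = "agtscreen", mustWork = TRUE))
}

#' Published genetic variability parameters for the packaged panel
#'
#' Per-trait grand mean, GCV, PCV, broad-sense heritability, genetic advance,
#' genetic advance as percent of mean and standard error of difference, as
#' published for the packaged screening panel. Used as reference inputs when
#' checking the variability formulas against one another.
#'
#' @return Data frame with one row per trait.
#' @export
variability_reference <- function() {
  utils::read.csv(system.file("extdata", "variability_reference.csv",
                              package = "agtscreen", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Read a marker score matrix
#'
#' Matrix layout: first column \code{genotype}, remaining columns one per
#' locus; cells hold allele identifiers (band-size classes) or the missing
#' token \code{"-"} (empty cells are also treated as missing).
#'
#' @param path Path to a delimited text file.
#' @param sep Field delimiter; auto-detected by default.
#' @param missing_token Cell value marking a missing call (besides "").
#' @return An object of class \code{agt_markers}: list with \code{calls}
#'   (character matrix, genotypes x loci, \code{NA} = missing),
#'   \code{alleles} (per-locus allele inventory) and \code{missing_rate}
#'   (per-locus fraction of missing calls).
#' @export
read_marker_scores <- function(path, sep = NULL, missing_token = "-") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- detect_sep(path)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, colClasses = "character")
  if (!"genotype" %in% names(d)) stop("schema error: missing column genotype")
  loci <- setdiff(names(d), "genotype")
  if (!length(loci)) stop("no locus columns found")
  calls <- as.matrix(d[loci])
  rownames(calls) <- d$genotype
  calls[calls == missing_token | calls == ""] <- NA_character_
  agt_markers(calls)
}

#' Construct a marker dataset from a call matrix
#'
#' @param calls Character matrix of allele calls, genotypes in rows (row
#'   names), loci in columns (column names); \code{NA} marks missing calls.
#' @return \code{agt_markers} object; see [read_marker_scores()].
#' @export
agt_markers <- function(calls) {
  stopifnot(is.matrix(calls), !is.null(rownames(calls)),
            !is.null(colnames(calls)))
  mode(calls) <- "character"
  alleles <- lapply(seq_len(ncol(calls)), function(j) {
    sort(unique(calls[!is.na(calls[, j]), j]))
  })
  names(alleles) <- colnames(calls)
  empty <- names(alleles)[vapply(alleles, length, 1L) == 0L]
  if (length(empty)) {
    warning("locus with all calls missing (monomorphic-undetermined): ",
            paste(empty, collapse = ", "))
  }
  structure(list(
    calls = calls,
    alleles = alleles,
    missing_rate = colMeans(is.na(calls))
  ), class = "agt_markers")
}

#' @export
print.agt_markers <- function(x, ...) {
  cat(sprintf("Marker dataset: %d genotypes x %d loci (Na: %s)\n",
              nrow(x$calls), ncol(x$calls),
              paste(vapply(x$alleles, length, 1L), collapse = ", ")))
  invisible(x)
}

#' Write a marker score matrix
#'
#' Inverse of [read_marker_scores()]; the round trip is bit-exact.
#' @param markers \code{agt_markers} object.
#' @param path Output path.
#' @param sep Field delimiter.
#' @param missing_token Token written for missing calls.
#' @export
write_marker_scores <- function(markers, path, sep = ",",
                                missing_token = "-") {
  stopifnot(inherits(markers, "agt_markers"))
  m <- markers$calls
  m[is.na(m)] <- missing_token
  d <- data.frame(genotype = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a trial dataset
#'
#' Report-only check of design balance (every genotype x season x replicate
#' cell present once per trait and treatment), trait value ranges and
#' per-trait coverage.
#'
#' @param trial An [agt_trial()] object.
#' @return Object of class \code{agt_validation}: list with \code{pass},
#'   \code{missing_cells}, \code{range_violations} and \code{coverage}.
#' @export
validate_trial <- function(trial) {
  stopifnot(inherits(trial, "agt_trial"))
  obs <- trial$observations
  genos <- unique(obs$genotype)
  seasons <- unique(obs$season)
  reps <- seq_len(trial$design$r)

  missing_cells <- NULL
  for (trt in unique(obs$treatment)) {
    for (tr in unique(obs$trait[obs$treatment == trt])) {
      sub <- obs[obs$treatment == trt & obs$trait == tr, ]
      full <- expand.grid(genotype = genos, season = seasons,
                          replicate = reps, stringsAsFactors = FALSE)
      key_have <- paste(sub$genotype, sub$season, sub$replicate)
      key_full <- paste(full$genotype, full$season, full$replicate)
      gap <- full[!(key_full %in% key_have), , drop = FALSE]
      if (nrow(gap)) {
        gap$treatment <- trt
        gap$trait <- tr
        missing_cells <- rbind(missing_cells, gap)
      }
    }
  }

  viol <- NULL
  for (tr in unique(obs$trait)) {
    sel <- which(obs$trait == tr)
    bad <- check_trait_range(obs$trait[sel], obs$value[sel])
    if (length(bad)) viol <- rbind(viol, obs[sel[bad], ])
  }

  coverage <- as.data.frame(table(trait = obs$trait, treatment = obs$treatment),
                            stringsAsFactors = FALSE)
  names(coverage)[3] <- "n_obs"

  structure(list(
    pass = is.null(missing_cells) && is.null(viol),
    missing_cells = missing_cells,
    range_violations = viol,
    coverage = coverage
  ), class = "agt_validation")
}

#' @export
print.agt_validation <- function(x, ...) {
  cat("Trial validation:", if (x$pass) "PASS" else "FAIL", "\n")
  if (!is.null(x$missing_cells)) {
    cat(sprintf("  %d missing design cell(s), first: genotype %s season %s replicate %s\n",
                nrow(x$missing_cells), x$missing_cells$genotype[1],
                x$missing_cells$season[1], x$missing_cells$replicate[1]))
  }
  if (!is.null(x$range_violations)) {
    cat(sprintf("  %d range violation(s)\n", nrow(x$range_violations)))
  }
  invisible(x)
}
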