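#' Pearson correlation matrix with significance
#'
#' Pairwise Pearson correlations over genotypes with two-sided t-test
#' p-values and the usual star codes (* 0.05, ** 0.01, *** 0.001).
#'
#' @param records Genotype-mean data frame.
#' @param traits Trait codes to correlate (default: all registered traits
#'   present).
#' @return Object of class \code{agt_corr}: list with matrices \code{r},
#'   \code{p}, \code{stars}, the sample size \code{n} and a character
#'   vector \code{constant} naming any zero-variance traits (their
#'   correlations are \code{NA}).
#' @examples
#' cc <- correlation_matrix(agt_panel(), c("AGP", "AVI", "SL", "RL"))
#' round(cc$r, 2)
#' @export
correlation_matrix <- function(records, traits = NULL) {
  if (is.null(traits)) traits <- intersect(trait_codes(), names(records))
  X <- as.matrix(records[traits])
  n <- nrow(X)
  if (n < 3) stop("need at least 3 genotypes")
  sds <- apply(X, 2, stats::sd)
  constant <- colnames(X)[sds == 0]
  if (length(constant)) {
    warning("constant trait(s), correlations undefined: ",
            paste(constant, collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(X))
  r[constant, ] <- NA; r[, constant] <- NA
  diag(r) <- ifelse(colnames(X) %in% constant, NA, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA
  stars <- matrix(p_stars(p), nrow(p), dimnames = dimnames(r))
  structure(list(r = r, p = p, stars = stars, n = n, constant = constant),
            class = "agt_corr")
}

#' @export
print.agt_corr <- function(x, ...) {
  cat(sprintf("Pearson correlations over %d genotypes\n", x$n))
  m <- matrix(paste0(formatC(x$r, digits = 2, format = "f"), x$stars),
              nrow(x$r), dimnames = dimnames(x$r))
  m[upper.tri(m)] <- ""
  diag(m) <- "1"
  print(m, quote = FALSE)
  invisible(x)
}

#' Correlation-matrix principal component analysis
#'
#' Traits are standardized (mean 0, variance 1, population divisor n) and
#' the correlation matrix is eigen-decomposed. The squared correlation of
#' each trait with each component (its cos2) is
#' \eqn{cos^2_{kj} = e_{kj}^2 \lambda_j}; each cos2 column sums to its
#' eigenvalue and each trait's row over all components sums to 1.
#'
#' @param records Genotype-mean data frame.
#' @param traits Trait codes to include (default: all registered traits
#'   present).
#' @return Object of class \code{agt_pca}: list with \code{eigenvalues},
#'   \code{variance_pct}, \code{cumulative_pct}, \code{cos2} (traits x
#'   components), \code{loadings} (eigenvectors scaled by sqrt(eigenvalue)),
#'   \code{rotation} (unit eigenvectors) and genotype \code{scores}.
#' @examples
#' p <- trait_pca(agt_panel())
#' round(p$eigenvalues[1:5], 2)
#' @export
trait_pca <- function(records, traits = NULL) {
  if (is.null(traits)) traits <- intersect(trait_codes(), names(records))
  X <- as.matrix(records[traits])
  if (nrow(X) < length(traits) + 1) {
    stop("need at least one more genotype than traits")
  }
  if (anyNA(X)) stop("missing values not allowed")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant trait(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  n <- nrow(X)
  # population (divisor n) standardization; the correlation matrix itself is
  # divisor-invariant but the genotype scores are not
  Z <- scale(X, center = TRUE, scale = apply(X, 2, function(v) {
    sqrt(sum((v - mean(v))^2) / n)
  }))
  C <- stats::cor(X)
  ee <- eigen(C, symmetric = TRUE)
  ev <- ee$values
  vecs <- ee$vectors
  # deterministic sign: largest-magnitude entry of each eigenvector positive
  for (j in seq_len(ncol(vecs))) {
    m <- which.max(abs(vecs[, j]))
    if (vecs[m, j] < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(colnames(X), paste0("PC", seq_along(ev)))
  loadings <- vecs %*% diag(sqrt(pmax(ev, 0)))
  colnames(loadings) <- colnames(vecs)
  cos2 <- loadings^2
  scores <- Z %*% vecs
  rownames(scores) <- if (!is.null(records$genotype)) records$genotype
  structure(list(
    eigenvalues = ev,
    variance_pct = 100 * ev / sum(ev),
    cumulative_pct = cumsum(100 * ev / sum(ev)),
    cos2 = cos2,
    loadings = loadings,
    rotation = vecs,
    scores = scores,
    n = n
  ), class = "agt_pca")
}

#' @export
print.agt_pca <- function(x, ...) {
  k <- sum(x$eigenvalues > 1)
  cat(sprintf(
    "Correlation-matrix PCA: %d traits, %d genotypes; %d component(s) with eigenvalue > 1 (%.2f%% of variance)\n",
    length(x$eigenvalues), x$n, k, x$cumulative_pct[max(k, 1)]))
  tab <- rbind(eigenvalue = x$eigenvalues,
               `variance %` = x$variance_pct,
               `cumulative %` = x$cumulative_pct)
  colnames(tab) <- paste0("PC", seq_along(x$eigenvalues))
  print(round(tab[, seq_len(min(5, ncol(tab))), drop = FALSE], 2))
  invisible(x)
}

#' Gower distance between genotypes
#'
#' Range-normalized mean absolute difference:
#' \eqn{d_{ij} = \frac{1}{m} \sum_k |x_{ik} - x_{jk}| / R_k}, with
#' \eqn{R_k} the trait range over the panel. All traits here are numeric,
#' so distances lie in [0, 1] and are invariant to affine rescaling of any
#' trait. Zero-range traits are excluded with a warning.
#'
#' @param records Genotype-mean data frame.
#' @param traits Trait codes to use (default: all registered traits
#'   present).
#' @return A \code{stats::dist} object with attribute \code{metric =
#'   "gower"} and genotype labels.
#' @export
gower_distance <- function(records, traits = NULL) {
  if (is.null(traits)) traits <- intersect(trait_codes(), names(records))
  X <- as.matrix(records[traits])
  rng <- apply(X, 2, function(v) diff(range(v)))
  if (any(rng == 0)) {
    warning("zero-range trait(s) excluded: ",
            paste(colnames(X)[rng == 0], collapse = ", "))
    X <- X[, rng > 0, drop = FALSE]
    rng <- rng[rng > 0]
  }
  if (!ncol(X)) stop("no traits with nonzero range")
  Xn <- sweep(X, 2, rng, "/")
  d <- stats::dist(Xn, method = "manhattan") / ncol(X)
  attr(d, "metric") <- "gower"
  attr(d, "Labels") <- if (!is.null(records$genotype))
    as.character(records$genotype) else rownames(X)
  d
}

#' Ward.D2 hierarchical clustering
#'
#' Agglomeration by the Ward.D2 criterion (squared-dissimilarity Ward,
#' Lance-Williams update), cut into \code{k} clusters. Merge heights are
#' monotone non-decreasing and cluster assignments at k are nested
#' refinements of those at k - 1.
#'
#' @param distances A \code{dist} object (e.g. from [gower_distance()] or
#'   [genetic_distance()]).
#' @param k Number of clusters, 1 <= k <= n.
#' @return Object of class \code{agt_clust}: list with the \code{hclust}
#'   \code{tree}, \code{k} and \code{assignments} (named integer vector;
#'   clusters numbered by first appearance in the panel order).
#' @export
ward_d2_cluster <- function(distances, k) {
  stopifnot(inherits(distances, "dist"))
  n <- attr(distances, "Size")
  if (k < 1 || k > n) stop("k must lie in 1..n")
  tree <- stats::hclust(distances, method = "ward.D2")
  assignments <- stats::cutree(tree, k = k)
  if (!is.null(attr(distances, "Labels"))) {
    names(assignments) <- attr(distances, "Labels")
  }
  structure(list(tree = tree, k = k, assignments = assignments,
                 metric = attr(distances, "metric")),
            class = "agt_clust")
}

#' @export
print.agt_clust <- function(x, ...) {
  cat(sprintf("Ward.D2 clustering (%s distance), k = %d\n",
              if (is.null(x$metric)) "unspecified" else x$metric, x$k))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths follow the merge heights of the tree.
#'
#' @param clust An \code{agt_clust} object or an \code{hclust} tree.
#' @param path Optional file to write; if omitted the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to \code{path}.
#' @export
cluster_newick <- function(clust, path = NULL) {
  tree <- if (inherits(clust, "agt_clust")) clust$tree else clust
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Per-cluster trait profiles and distance structure
#'
#' Summarises trait means per cluster with Newman-Keuls letters across
#' clusters, plus the mean pairwise dissimilarity within each cluster and
#' between each pair of clusters.
#'
#' @param assignments Named vector mapping genotype to cluster (e.g. from
#'   [ward_d2_cluster()]).
#' @param records Genotype-mean data frame covering all assigned genotypes.
#' @param traits Trait codes to profile.
#' @param distances Optional \code{dist} used for the within/between
#'   summaries (same genotype order as \code{records}).
#' @param alpha Significance level for the letter display.
#' @return Object of class \code{agt_cluster_profile}: list with
#'   \code{summary} (an [group_summary()] table by cluster),
#'   \code{within} (mean within-cluster distance per cluster; 0 and flagged
#'   for singletons) and \code{between} (cluster x cluster matrix of mean
#'   cross-pair distances).
#' @export
cluster_profile <- function(assignments, records, traits = NULL,
                            distances = NULL, alpha = 0.05) {
  key <- normalize_genotype(records$genotype)
  akey <- normalize_genotype(names(assignments))
  if (any(!key %in% akey)) {
    stop("assignments must cover all records; missing: ",
         paste(records$genotype[!key %in% akey][1], "..."))
  }
  records$cluster <- as.character(assignments[match(key, akey)])
  summary <- group_summary(records, by = "cluster", traits = traits,
                           alpha = alpha)

  within <- between <- NULL
  flags <- character(0)
  if (!is.null(distances)) {
    m <- as.matrix(distances)
    cl <- records$cluster
    ids <- sort(unique(cl))
    within <- stats::setNames(numeric(length(ids)), ids)
    between <- matrix(NA_real_, length(ids), length(ids),
                      dimnames = list(ids, ids))
    for (a in seq_along(ids)) {
      ia <- which(cl == ids[a])
      if (length(ia) < 2) {
        within[a] <- 0
        flags <- c(flags, paste0("singleton cluster ", ids[a],
                                 ": within-distance reported as 0"))
      } else {
        sub <- m[ia, ia]
        within[a] <- mean(sub[upper.tri(sub)])
      }
      for (b in seq_along(ids)) {
        if (a == b) { between[a, b] <- within[a]; next }
        between[a, b] <- mean(m[ia, which(cl == ids[b])])
      }
    }
  }
  structure(list(summary = summary, within = within, between = between,
                 flags = flags),
            class = "agt_cluster_profile")
}

#' @export
print.agt_cluster_profile <- function(x, ...) {
  print(as.data.frame(x$summary), row.names = FALSE)
  if (!is.null(x$within)) {
    cat("Mean within-cluster distance:\n")
    print(round(x$within, 4))
  }
  if (length(x$flags)) cat("Flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
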