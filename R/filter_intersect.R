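#' Frequent-alteration filter specification
#'
#' Two named presets mirror the two published threshold statements:
#' `"text-2.0"` (|Z| > 2 in 35 percent of tumors) and `"figure-2.5"`
#' (|Z| > 2.5 in 35 percent of tumors).
#'
#' @param z_threshold Z-score threshold t (> 0); the Z comparison is
#'   strict.
#' @param tumor_fraction Minimum fraction f of tumors altered, in (0, 1];
#'   the fraction comparison is non-strict (>= f).
#' @param direction "either" (|Z| > t), "down" (Z < -t) or "up" (Z > t).
#' @param preset Optional preset name overriding `z_threshold`.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(z_threshold = 2.5, tumor_fraction = 0.35,
                        direction = c("either", "down", "up"),
                        preset = NULL) {
  direction <- match.arg(direction)
  if (!is.null(preset)) {
    z_threshold <- switch(preset,
                          "text-2.0" = 2.0,
                          "figure-2.5" = 2.5,
                          stop("unknown preset: ", preset))
  }
  stopifnot(z_threshold > 0, tumor_fraction > 0, tumor_fraction <= 1)
  structure(list(z_threshold = z_threshold,
                 tumor_fraction = tumor_fraction,
                 direction = direction),
            class = "filter_spec")
}

#' Select genes frequently and strongly altered across tumors
#'
#' Keeps the genes whose Z-score exceeds the threshold (strictly) in at
#' least the given fraction of tumors (non-strictly), e.g. genes altered by
#' more than 2.5 Z-scores in 35 percent of tumors.
#'
#' @param z Genes x tumors Z-score matrix.
#' @param spec A [filter_spec()].
#' @return Character vector of surviving gene names.
#' @export
frequent_alteration_filter <- function(z, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (!is.matrix(z) || nrow(z) == 0 || ncol(z) == 0) {
    stop("Z-score matrix is empty")
  }
  t <- spec$z_threshold
  hit <- switch(spec$direction,
                either = abs(z) > t,
                down = z < -t,
                up = z > t)
  frac <- rowMeans(hit, na.rm = TRUE)
  rownames(z)[frac >= spec$tumor_fraction]
}

#' Hierarchically cluster tumors on a gene-subset Z matrix
#'
#' Tumors (columns) are clustered by hierarchical agglomeration on
#' Euclidean distance with complete linkage (the defaults of the usual
#' clustered-heatmap display) and the tree cut at `k` clusters.
#'
#' @param z_subset Genes x tumors matrix (typically the filtered genes).
#' @param k Number of clusters (default 2).
#' @param method Linkage method for [stats::hclust()].
#' @param distance Distance measure for [stats::dist()].
#' @return Named integer vector of cluster labels per tumor; the `hclust`
#'   tree is attached as attribute `tree`.
#' @export
cluster_tumors <- function(z_subset, k = 2, method = "complete",
                           distance = "euclidean") {
  stopifnot(is.matrix(z_subset), k >= 2)
  if (k > ncol(z_subset)) stop("k exceeds the number of tumors")
  hc <- stats::hclust(stats::dist(t(z_subset), method = distance),
                      method = method)
  labels <- stats::cutree(hc, k = k)
  attr(labels, "tree") <- hc
  labels
}

#' Chi-squared association between cluster membership and a clinical factor
#'
#' Pearson chi-squared test on the cluster x category contingency table,
#' without continuity correction.  Continuous clinical variables should be
#' categorized first (see [categorize_at_median()]).
#'
#' @param labels Cluster labels per sample.
#' @param clinical_category Clinical category per sample (same order).
#' @return A `cluster_association` list: table, statistic, df, p.value.
#' @export
cluster_outcome_association <- function(labels, clinical_category) {
  labels <- labels[!is.na(clinical_category)]
  clinical_category <- clinical_category[!is.na(clinical_category)]
  tab <- table(cluster = labels, category = clinical_category)
  if (nrow(tab) < 2 || ncol(tab) < 2 || any(rowSums(tab) == 0) ||
      any(colSums(tab) == 0)) {
    stop("degenerate contingency table: need >= 2 clusters and >= 2 ",
         "categories with non-zero margins")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(table = tab,
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p.value = ct$p.value),
            class = "cluster_association")
}

#' @export
print.cluster_association <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.cluster_association <- function(x, ...) {
  sprintf("X-squared = %s, p-value = %s",
          format(signif(x$statistic, 5)), format(signif(x$p.value, 3)))
}

#' Dichotomize a continuous clinical variable at its median
#'
#' @param x Numeric vector.
#' @param cut Cut point (default the median of `x`).
#' @return Factor with levels "low", "high" (values <= cut are "low").
#' @export
categorize_at_median <- function(x, cut = stats::median(x, na.rm = TRUE)) {
  factor(ifelse(x <= cut, "low", "high"), levels = c("low", "high"))
}

#' Intersect per-cohort gene lists
#'
#' Builds the exact membership matrix of the union of all genes across
#' cohorts together with the size of every exclusive cohort combination
#' (the quantities an UpSet display shows).
#'
#' @param gene_lists Named list (>= 2 entries) of character vectors.
#' @return An `intersection_report`: `membership` (logical matrix, genes x
#'   cohorts) and `combination_sizes` (named integer vector keyed by
#'   "cohortA&cohortB"; exclusive sizes summing to the union size).
#' @export
intersect_cohorts <- function(gene_lists) {
  stopifnot(is.list(gene_lists), length(gene_lists) >= 2,
            !is.null(names(gene_lists)))
  all_genes <- sort(unique(unlist(gene_lists)))
  membership <- vapply(gene_lists, function(g) all_genes %in% g,
                       logical(length(all_genes)))
  if (length(all_genes) == 1L) {
    membership <- matrix(membership, nrow = 1,
                         dimnames = list(all_genes, names(gene_lists)))
  } else {
    rownames(membership) <- all_genes
  }
  key <- apply(membership, 1, function(r) {
    paste(colnames(membership)[r], collapse = "&")
  })
  sizes <- table(key)
  structure(list(membership = membership,
                 combination_sizes = stats::setNames(as.integer(sizes),
                                                     names(sizes))),
            class = "intersection_report")
}

#' @export
print.intersection_report <- function(x, ...) {
  cat("intersection over", ncol(x$membership), "cohorts;",
      nrow(x$membership), "genes in the union\n")
  print(sort(x$combination_sizes, decreasing = TRUE))
  invisible(x)
}

#' Barplot of exclusive intersection sizes (UpSet-style content)
#'
#' @param report An `intersection_report`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_intersections <- function(report, ...) {
  sizes <- sort(report$combination_sizes, decreasing = TRUE)
  graphics::barplot(sizes, las = 2, ylab = "genes",
                    main = "exclusive cohort combinations", ...)
  invisible(report)
}
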