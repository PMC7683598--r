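.stat_fun <- function(statistic, direction, threshold) {
  switch(statistic,
    proportion = switch(direction,
      down = function(v) mean(v < -threshold),
      up = function(v) mean(v > threshold),
      two_sided = function(v) mean(abs(v) > threshold)),
    mean = function(v) mean(v),
    mean_rank = function(v) mean(v))  # applied to ranks, see caller
}

#' Random-set resampling test for family-wide alteration
#'
#' Tests whether a gene class is altered more than random gene sets of the
#' same size drawn from the cohort-detected universe.  The observed
#' statistic on the class is compared with its distribution over `B`
#' random subsets (sampled without replacement within each draw), and the
#' empirical p-value computed with the add-one estimator
#' p = (1 + r) / (B + 1), where r counts null draws at least as extreme as
#' the observed value (ties count against significance).  The attainable
#' floor is therefore exactly 1/(B+1).
#'
#' Three statistics are available: `proportion` (fraction of class genes
#' with score beyond `threshold` in the tested direction -- e.g. the
#' fraction down-regulated by more than 2 Z-scores), `mean` (mean score)
#' and `mean_rank` (mean rank of the class genes within the universe).
#' For `proportion` extremeness is always a larger proportion; for `mean`
#' and `mean_rank` direction "down" means a smaller observed value is more
#' extreme, "up" a larger one, and "two_sided" doubles the smaller
#' one-sided p (capped at 1).
#'
#' @param scores Named numeric vector of per-gene alteration scores; the
#'   names are the detected-gene universe (no duplicates).
#' @param class_genes Character vector, a subset of the universe with at
#'   least 2 genes.
#' @param statistic One of "proportion", "mean", "mean_rank".
#' @param direction One of "down", "up", "two_sided".
#' @param threshold Z-score threshold for the proportion statistic
#'   (default 2).
#' @param B Number of resampling draws (>= 100; 100000 for full runs).
#' @param seed Optional integer seed for reproducibility.
#' @param class_label,cohort,data_type Metadata carried into the result.
#' @return A one-row data frame of class `family_test_result`: class,
#'   cohort, data_type, statistic, direction, threshold, n_class,
#'   n_universe, observed, null_mean, null_sd, B, empirical_p.
#' @export
family_alteration_test <- function(scores, class_genes,
                                   statistic = c("proportion", "mean",
                                                 "mean_rank"),
                                   direction = c("down", "up", "two_sided"),
                                   threshold = 2, B = 100000L, seed = NULL,
                                   class_label = NA_character_,
                                   cohort = NA_character_,
                                   data_type = NA_character_) {
  statistic <- match.arg(statistic)
  direction <- match.arg(direction)
  universe <- names(scores)
  if (is.null(universe) || anyDuplicated(universe)) {
    stop("scores must be a named vector over a duplicate-free universe")
  }
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (B < 100) stop("B must be at least 100")
  class_genes <- unique(class_genes)
  if (!all(class_genes %in% universe)) {
    stop("class_genes must be a subset of the score universe")
  }
  if (length(class_genes) > length(universe)) {
    stop("class larger than universe")
  }
  if (length(class_genes) < 2) stop("class must contain at least 2 genes")
  if (!is.null(seed)) set.seed(seed)

  vals <- if (statistic == "mean_rank") rank(scores) else scores
  names(vals) <- universe
  f <- .stat_fun(statistic, direction, threshold)
  k <- length(class_genes)
  n <- length(vals)
  obs <- f(vals[class_genes])
  vals_u <- unname(vals)
  null <- vapply(seq_len(B), function(i) f(vals_u[sample.int(n, k)]),
                 numeric(1))

  # numerical tie tolerance: summation order can perturb equal statistics
  # in the last bits; near-ties count against significance (conservative)
  eps <- sqrt(.Machine$double.eps) * (1 + abs(obs))
  if (statistic == "proportion") {
    r <- sum(null >= obs - eps)
    p <- (1 + r) / (B + 1)
  } else if (direction == "down") {
    p <- (1 + sum(null <= obs + eps)) / (B + 1)
  } else if (direction == "up") {
    p <- (1 + sum(null >= obs - eps)) / (B + 1)
  } else {
    p_lo <- (1 + sum(null <= obs + eps)) / (B + 1)
    p_hi <- (1 + sum(null >= obs - eps)) / (B + 1)
    p <- min(1, 2 * min(p_lo, p_hi))
  }

  res <- data.frame(class = class_label, cohort = cohort,
                    data_type = data_type, statistic = statistic,
                    direction = direction, threshold = threshold,
                    n_class = k, n_universe = n, observed = obs,
                    null_mean = mean(null), null_sd = stats::sd(null),
                    B = as.integer(B), empirical_p = p,
                    stringsAsFactors = FALSE)
  class(res) <- c("family_test_result", class(res))
  res
}

.panel_expression_scores <- function(cohort, detect_threshold = 0.80) {
  if (length(normal_samples(cohort)) >= 2) {
    z <- tumor_normal_zscores(cohort, detect_threshold = detect_threshold)
  } else {
    z <- median_zscores(cohort$expr[, tumor_samples(cohort), drop = FALSE])
  }
  rowMeans(z)
}

#' Run the family test over classes, cohorts, data types and directions
#'
#' For each cohort the catalog is first restricted to the cohort's detected
#' genes; each class is then tested in both directions against the
#' cohort-detected universe.  Per-gene score vectors are built per data
#' type: expression uses the per-gene mean Z-score (tumor-normal when >= 2
#' normals are present, otherwise median-centered); copy number uses the
#' per-gene fraction of tumors carrying a deletion (direction "down") or
#' amplification (direction "up") call; mutation uses the length-normalized
#' burden score (direction "up" only).  Benjamini-Hochberg FDR is applied
#' across the whole panel within each data type.  Classes that are empty
#' after restriction are reported as skipped rows, not dropped.
#'
#' @param cohorts Named list of `cohort` objects.
#' @param catalog A `gene_class_catalog`.
#' @param data_types Subset of c("expression", "cna", "mutation").
#' @param statistic Statistic for the expression tests (copy number and
#'   mutation always use the mean of their per-gene alteration frequency).
#' @param threshold Z threshold for the proportion statistic.
#' @param B Resampling draws per test.
#' @param seed Integer seed (each test derives its own substream
#'   deterministically).
#' @param extra_classes Optional named list of gene sets tested alongside
#'   the catalog classes (e.g. positive-control families).
#' @param cna_level Passed to [cna_alteration_calls()].
#' @return A `family_panel` data frame: one row per test with `empirical_p`,
#'   `q` and `neglog10_q`, plus a `skipped` flag.
#' @export
run_family_panel <- function(cohorts, catalog,
                             data_types = "expression",
                             statistic = "proportion", threshold = 2,
                             B = 10000L, seed = 1L, extra_classes = NULL,
                             cna_level = "deep") {
  stopifnot(length(cohorts) >= 1, inherits(catalog, "gene_class_catalog"))
  if (is.null(names(cohorts))) {
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  }
  data_types <- match.arg(data_types, c("expression", "cna", "mutation"),
                          several.ok = TRUE)
  rows <- list()
  test_i <- 0L
  for (cn in names(cohorts)) {
    co <- cohorts[[cn]]
    for (dt in data_types) {
      score_sets <- list()
      if (dt == "expression") {
        s <- .panel_expression_scores(co)
        score_sets <- list(down = list(scores = s, stat = statistic,
                                       dir = "down"),
                           up = list(scores = s, stat = statistic,
                                     dir = "up"))
      } else if (dt == "cna") {
        if (is.null(co$cna)) next
        calls <- cna_alteration_calls(co$cna, level = cna_level)
        score_sets <- list(
          down = list(scores = rowMeans(calls$deletion), stat = "mean",
                      dir = "up"),
          up = list(scores = rowMeans(calls$amplification), stat = "mean",
                    dir = "up"))
      } else {
        if (is.null(co$mutations) || is.null(co$gene_models)) next
        mb <- mutation_burden(co$mutations, co$gene_models,
                              n_tumors = length(tumor_samples(co)))
        s <- stats::setNames(mb$score, mb$gene)
        score_sets <- list(up = list(scores = s, stat = "mean", dir = "up"))
      }
      cat_r <- restrict_to_detected(catalog, names(score_sets[[1]]$scores))
      fams <- c(stats::setNames(
                  lapply(c("TF", "COA", "COR", "MIXED"), class_genes,
                         catalog = cat_r),
                  c("TF", "COA", "COR", "MIXED")),
                extra_classes)
      for (fam in names(fams)) {
        for (dir_label in names(score_sets)) {
          ss <- score_sets[[dir_label]]
          cg <- intersect(fams[[fam]], names(ss$scores))
          test_i <- test_i + 1L
          if (length(cg) < 2) {
            row <- data.frame(class = fam, cohort = cn, data_type = dt,
                              statistic = ss$stat, direction = dir_label,
                              threshold = threshold, n_class = length(cg),
                              n_universe = length(ss$scores),
                              observed = NA_real_, null_mean = NA_real_,
                              null_sd = NA_real_, B = as.integer(B),
                              empirical_p = NA_real_,
                              stringsAsFactors = FALSE)
          } else {
            row <- family_alteration_test(
              ss$scores, cg, statistic = ss$stat, direction = ss$dir,
              threshold = threshold, B = B,
              seed = (seed * 10007L + test_i) %% .Machine$integer.max,
              class_label = fam, cohort = cn, data_type = dt)
            row$direction <- dir_label
            class(row) <- "data.frame"
          }
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  panel <- do.call(rbind, rows)
  panel$skipped <- is.na(panel$empirical_p)
  panel$q <- NA_real_
  for (dt in unique(panel$data_type)) {
    sel <- panel$data_type == dt & !panel$skipped
    panel$q[sel] <- stats::p.adjust(panel$empirical_p[sel], method = "BH")
  }
  panel$neglog10_q <- -log10(panel$q)
  class(panel) <- c("family_panel", class(panel))
  panel
}

#' Reshape a family panel into a -log10(q) matrix for plotting
#'
#' @param panel A `family_panel` data frame.
#' @param data_type Which data type to extract.
#' @return Matrix classes x (cohort.direction) of -log10(q) values.
#' @export
panel_neglog10_matrix <- function(panel, data_type = "expression") {
  p <- panel[panel$data_type == data_type & !panel$skipped, , drop = FALSE]
  cols <- paste(p$cohort, p$direction, sep = ".")
  m <- matrix(NA_real_, length(unique(p$class)), length(unique(cols)),
              dimnames = list(unique(p$class), unique(cols)))
  m[cbind(p$class, cols)] <- p$neglog10_q
  m
}

#' One-sided hypergeometric over-representation test
#'
#' Tests whether a gene class overlaps a reference gene set (e.g. genes
#' protected from loss-of-function variation, or pan-cancer fitness genes)
#' more than expected for a random set of the same size drawn from the
#' universe.
#'
#' @param class_genes,reference_set Character vectors, subsets of
#'   `universe`.
#' @param universe Character vector of all candidate genes (non-empty).
#' @return A list: overlap, n_class, n_reference, n_universe, p (upper-tail
#'   hypergeometric).
#' @export
enrichment_vs_geneset <- function(class_genes, reference_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("universe is empty")
  class_genes <- unique(class_genes)
  reference_set <- unique(reference_set)
  stopifnot(all(class_genes %in% universe),
            all(reference_set %in% universe))
  k <- length(intersect(class_genes, reference_set))
  p <- stats::phyper(k - 1, length(reference_set),
                     length(universe) - length(reference_set),
                     length(class_genes), lower.tail = FALSE)
  list(overlap = k, n_class = length(class_genes),
       n_reference = length(reference_set), n_universe = length(universe),
       p = p)
}

#' Write a family panel as TSV
#'
#' @param panel A `family_panel` data frame.
#' @param path Output path.
#' @export
write_panel_tsv <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
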