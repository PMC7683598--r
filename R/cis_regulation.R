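.check_chrom_naming <- function(a, b) {
  ac <- unique(as.character(a)); bc <- unique(as.character(b))
  a_chr <- grepl("^chr", ac); b_chr <- grepl("^chr", bc)
  if ((any(a_chr) && any(!b_chr)) || (any(!a_chr) && any(b_chr)) ||
      (any(a_chr) && any(!a_chr)) || (any(b_chr) && any(!b_chr))) {
    stop("mixed chromosome naming conventions ('chr1' vs '1')")
  }
}

.peaks_granges <- function(peaks) {
  stopifnot(all(peaks$start < peaks$end))
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(start = peaks$start + 1L,
                                          end = peaks$end))
}

#' Annotate binding peaks to genes within a distance window
#'
#' Links every (peak, gene) pair whose genomic separation between the peak
#' interval and the gene anchor is at most `window` bp (100 kb by default,
#' reflecting typical enhancer-promoter distances).  A peak overlapping the
#' anchor has distance 0; distance is measured strand-ignorantly from the
#' nearest peak edge.  One peak may link several genes and vice versa.
#'
#' @param peaks Data frame: chrom, start, end (0-based half-open), name.
#' @param models Gene-model data frame with gene, chrom, tss (and
#'   optionally exon columns when `anchor = "body"`).
#' @param window Window size W in bp.
#' @param anchor "tss" (default) anchors distance at the TSS; "body"
#'   anchors at the gene interval from first exon start to last exon end.
#' @return Data frame of class `peak_gene_links`: peak, gene, chrom,
#'   distance, window.  Peaks on chromosomes absent from the models are
#'   skipped with a warning; mixed naming conventions are an error.
#' @export
annotate_peaks_to_genes <- function(peaks, models, window = 100000,
                                    anchor = c("tss", "body")) {
  anchor <- match.arg(anchor)
  stopifnot(nrow(peaks) > 0, nrow(models) > 0)
  .check_chrom_naming(peaks$chrom, models$chrom)
  unknown <- !(peaks$chrom %in% models$chrom)
  if (any(unknown)) {
    warning(sum(unknown), " peak(s) on chromosome(s) without gene models ",
            "skipped: ", paste(unique(peaks$chrom[unknown]), collapse = ","))
    peaks <- peaks[!unknown, , drop = FALSE]
  }
  if (nrow(peaks) == 0) {
    return(structure(data.frame(peak = character(0), gene = character(0),
                                chrom = character(0), distance = numeric(0),
                                window = numeric(0)),
                     class = c("peak_gene_links", "data.frame")))
  }
  if (anchor == "tss") {
    a_start <- models$tss; a_end <- models$tss + 1L
  } else {
    ex <- .parse_model_exons(models)
    a_start <- vapply(ex, function(e) min(e$starts), numeric(1))
    a_end <- vapply(ex, function(e) max(e$ends), numeric(1))
  }
  # anchor window [a_start - W, a_end + W) intersected with peak intervals
  pg <- .peaks_granges(peaks)
  wg <- GenomicRanges::GRanges(models$chrom,
                               IRanges::IRanges(start = pmax(1, a_start - window + 1),
                                                end = a_end + window))
  hits <- GenomicRanges::findOverlaps(pg, wg)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (length(qi) == 0) {
    return(structure(data.frame(peak = character(0), gene = character(0),
                                chrom = character(0), distance = numeric(0),
                                window = numeric(0)),
                     class = c("peak_gene_links", "data.frame")))
  }
  dist <- pmax(0,
               peaks$start[qi] - (a_end[si] - 1L),
               a_start[si] - (peaks$end[qi] - 1L))
  structure(data.frame(peak = peaks$name[qi], gene = models$gene[si],
                       chrom = peaks$chrom[qi], distance = dist,
                       window = window, stringsAsFactors = FALSE),
            class = c("peak_gene_links", "data.frame"))
}

#' Retain peaks overlapping chromatin-state segments
#'
#' Keeps peaks whose intersection with at least one state segment is at
#' least `min_overlap` bp (default 1 bp) and attaches all overlapping state
#' labels.  Intervals are 0-based half-open, so touching intervals share no
#' base and do not overlap.
#'
#' @param peaks Peak data frame (chrom, start, end, name).
#' @param states State data frame (chrom, start, end, state).
#' @param min_overlap Minimum overlap in bp.
#' @return The retained subset of `peaks` with an added `states` column
#'   (unique labels, ";"-separated).
#' @export
overlap_states <- function(peaks, states, min_overlap = 1) {
  stopifnot(min_overlap >= 1)
  if (nrow(peaks) == 0 || nrow(states) == 0) {
    out <- peaks[integer(0), , drop = FALSE]
    out$states <- character(0)
    return(out)
  }
  .check_chrom_naming(peaks$chrom, states$chrom)
  pg <- .peaks_granges(peaks)
  sg <- .peaks_granges(states[, c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(pg, sg,
                                      minoverlap = as.integer(min_overlap))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (length(qi) == 0) {
    out <- peaks[integer(0), , drop = FALSE]
    out$states <- character(0)
    return(out)
  }
  lab <- vapply(split(states$state[si], qi), function(s) {
    paste(sort(unique(s)), collapse = ";")
  }, character(1))
  keep <- as.integer(names(lab))
  out <- peaks[keep, , drop = FALSE]
  out$states <- unname(lab)
  rownames(out) <- NULL
  out
}

#' Construct a differential-expression result table
#'
#' @param df Data frame with columns gene, logFC, p (and optionally fdr).
#' @param contrast Contrast label, e.g. "knockdown_vs_control".
#' @param fdr_threshold,lfc_threshold Significance rule recorded with the
#'   table: significant = fdr < fdr_threshold and |logFC| > lfc_threshold.
#' @return A `de_table` data frame with `fdr` and `significant` columns.
#' @export
de_table <- function(df, contrast = "contrast", fdr_threshold = 0.05,
                     lfc_threshold = 1.5) {
  stopifnot(all(c("gene", "logFC", "p") %in% names(df)))
  if (!"fdr" %in% names(df)) {
    df$fdr <- stats::p.adjust(df$p, method = "BH")
  }
  df$significant <- !is.na(df$fdr) & df$fdr < fdr_threshold &
    abs(df$logFC) > lfc_threshold
  attr(df, "contrast") <- contrast
  attr(df, "fdr_threshold") <- fdr_threshold
  attr(df, "lfc_threshold") <- lfc_threshold
  class(df) <- c("de_table", class(df))
  df
}

#' Differential expression between upper- and lower-quartile tumors
#'
#' Splits tumors by the expression quartiles of an index gene and tests
#' every other gene between the two groups with a two-sample rank-sum
#' (Wilcoxon) test; logFC is the difference of group means (log-scale input
#' assumed).  This is a dependency-light surrogate for a count-model DE fit
#' and behaves equivalently for the rank-based significance calls used
#' downstream.
#'
#' @param expr Genes x samples matrix (tumors).
#' @param index_gene Gene whose quartiles define the groups.
#' @param fdr_threshold,lfc_threshold Significance rule for the resulting
#'   table.
#' @param exclude_index Drop the index gene from its own result (default).
#' @return A `de_table` with contrast "upper_vs_lower_quartile".
#' @export
quartile_de <- function(expr, index_gene, fdr_threshold = 0.05,
                        lfc_threshold = 1.5, exclude_index = TRUE) {
  stopifnot(index_gene %in% rownames(expr))
  grp <- quartile_groups(expr[index_gene, ])
  up <- which(grp == "upper_quartile"); lo <- which(grp == "lower_quartile")
  if (length(up) < 2 || length(lo) < 2) {
    stop("degenerate quartile groups for index gene ", index_gene)
  }
  genes <- rownames(expr)
  if (exclude_index) genes <- setdiff(genes, index_gene)
  res <- vapply(genes, function(g) {
    x <- expr[g, up]; y <- expr[g, lo]
    p <- tryCatch(
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value),
      error = function(e) NA_real_)
    c(mean(x) - mean(y), p)
  }, numeric(2))
  de_table(data.frame(gene = genes, logFC = res[1, ], p = res[2, ],
                      stringsAsFactors = FALSE, row.names = NULL),
           contrast = "upper_vs_lower_quartile",
           fdr_threshold = fdr_threshold, lfc_threshold = lfc_threshold)
}

#' Correlation profile of a gene set against an index gene
#'
#' Computes the per-gene correlation with the index gene across samples and
#' compares the correlation distribution of a gene set against a background
#' set with a two-sample Kolmogorov-Smirnov test.  A set shifted toward
#' stronger positive correlation than background is reported as
#' "more_positive" (the pattern expected of coactivator targets),
#' the converse as "more_negative".
#'
#' @param expr Genes x samples matrix with >= 10 samples.
#' @param index_gene Index gene (row of `expr`).
#' @param gene_set,background_set Character vectors of genes (rows of
#'   `expr`).
#' @param method Correlation method, "spearman" (default) or "pearson".
#' @return A `correlation_profile` list: correlations (named vector over
#'   both sets), D, p, direction, n_excluded (constant rows dropped).
#' @export
correlation_profile <- function(expr, index_gene, gene_set, background_set,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(index_gene %in% rownames(expr), ncol(expr) >= 10,
            all(gene_set %in% rownames(expr)),
            all(background_set %in% rownames(expr)))
  idx <- expr[index_gene, ]
  all_genes <- unique(c(gene_set, background_set))
  cors <- suppressWarnings(
    apply(expr[all_genes, , drop = FALSE], 1, stats::cor, y = idx,
          method = method, use = "pairwise.complete.obs"))
  n_excluded <- sum(is.na(cors))
  set_c <- cors[intersect(gene_set, names(cors)[!is.na(cors)])]
  bg_c <- cors[intersect(background_set, names(cors)[!is.na(cors)])]
  ks <- suppressWarnings(stats::ks.test(set_c, bg_c))
  direction <- if (mean(set_c) >= mean(bg_c)) "more_positive" else
    "more_negative"
  structure(list(correlations = cors, D = unname(ks$statistic),
                 p = ks$p.value, direction = direction,
                 n_excluded = n_excluded, method = method),
            class = "correlation_profile")
}

#' Genes bound by the regulator and regulated in both contrasts
#'
#' The cascade's final intersection: genes carrying at least one peak link
#' AND significantly altered by the knockdown AND significantly altered
#' between cohort quartile groups.  Each gene is annotated with its
#' direction in both contrasts; the table can be truncated to the `top_k`
#' genes by absolute cohort log-fold-change.
#'
#' @param links `peak_gene_links` from [annotate_peaks_to_genes()]
#'   (typically computed on state-overlapping peaks).
#' @param de_knockdown,de_cohort `de_table` objects carrying `significant`
#'   flags.
#' @param top_k Optional truncation by |cohort logFC|.
#' @return A `bound_regulated` data frame: gene, n_peaks, min_distance,
#'   kd_logFC, kd_direction, cohort_logFC, cohort_direction; attributes
#'   `n_up` / `n_down` count cohort directions over the full (untruncated)
#'   network.
#' @export
bound_and_regulated <- function(links, de_knockdown, de_cohort,
                                top_k = NULL) {
  sig_kd <- de_knockdown$gene[de_knockdown$significant]
  sig_co <- de_cohort$gene[de_cohort$significant]
  genes <- intersect(intersect(unique(links$gene), sig_kd), sig_co)
  if (length(genes) == 0) {
    message("bound_and_regulated: empty network")
    out <- data.frame(gene = character(0), n_peaks = integer(0),
                      min_distance = numeric(0), kd_logFC = numeric(0),
                      kd_direction = character(0), cohort_logFC = numeric(0),
                      cohort_direction = character(0))
    attr(out, "n_up") <- 0L; attr(out, "n_down") <- 0L
    class(out) <- c("bound_regulated", class(out))
    return(out)
  }
  n_peaks <- vapply(genes, function(g) sum(links$gene == g), integer(1))
  min_d <- vapply(genes, function(g) min(links$distance[links$gene == g]),
                  numeric(1))
  kd_lfc <- de_knockdown$logFC[match(genes, de_knockdown$gene)]
  co_lfc <- de_cohort$logFC[match(genes, de_cohort$gene)]
  out <- data.frame(gene = genes, n_peaks = n_peaks, min_distance = min_d,
                    kd_logFC = kd_lfc,
                    kd_direction = ifelse(kd_lfc >= 0, "up", "down"),
                    cohort_logFC = co_lfc,
                    cohort_direction = ifelse(co_lfc >= 0, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-abs(out$cohort_logFC)), , drop = FALSE]
  attr_up <- sum(out$cohort_direction == "up")
  attr_down <- sum(out$cohort_direction == "down")
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  rownames(out) <- NULL
  attr(out, "n_up") <- attr_up
  attr(out, "n_down") <- attr_down
  class(out) <- c("bound_regulated", class(out))
  out
}
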