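#' Tumor-normal expression Z-scores
#'
#' For cohorts with matched or pooled normal samples, each gene's tumor
#' expression is standardized against the distribution of that gene across
#' the normal samples: Z = (tumor value - mean over normals) / SD over
#' normals (SD with the n-1 denominator).  Genes detectable in fewer than
#' `detect_threshold` of samples are dropped first; "detectable" means
#' non-missing and above `detect_floor`.
#'
#' @param cohort A `cohort` object with at least 2 normal samples.
#' @param detect_threshold Minimum fraction of samples in which a gene must
#'   be detectable (default 0.80, i.e. at least 80 percent of samples).
#' @param detect_floor Expression floor defining detectability (default 0).
#' @return A genes x tumors Z-score matrix with attribute
#'   `convention = "tumor_vs_normal"`.  Genes whose normal-sample SD is zero
#'   are dropped with a warning.
#' @export
tumor_normal_zscores <- function(cohort, detect_threshold = 0.80,
                                 detect_floor = 0) {
  stopifnot(inherits(cohort, "cohort"))
  norm_ids <- normal_samples(cohort)
  if (length(norm_ids) < 2L) {
    stop("tumor-normal Z-scores require at least 2 normal samples")
  }
  tum_ids <- tumor_samples(cohort)
  expr <- cohort$expr
  detected <- rowMeans(!is.na(expr) & expr > detect_floor)
  keep <- detected >= detect_threshold
  expr <- expr[keep, , drop = FALSE]
  nm <- expr[, norm_ids, drop = FALSE]
  mu <- rowMeans(nm, na.rm = TRUE)
  sd_n <- apply(nm, 1, stats::sd, na.rm = TRUE)
  zero <- !is.finite(sd_n) | sd_n == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) dropped: zero variance across normals")
  }
  z <- (expr[!zero, tum_ids, drop = FALSE] - mu[!zero]) / sd_n[!zero]
  attr(z, "convention") <- "tumor_vs_normal"
  attr(z, "detect_threshold") <- detect_threshold
  z
}

#' Median-centered expression Z-scores
#'
#' For cohorts without normals, each gene row is centered at its median and
#' scaled by its SD: Z = (value - row median) / row SD.
#'
#' @param matrix Genes x samples numeric matrix.
#' @return A Z-score matrix with attribute `convention = "median_centered"`.
#'   Zero-SD rows are dropped with a warning; an error is raised if nothing
#'   remains.
#' @export
median_zscores <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) > 0)
  med <- apply(matrix, 1, stats::median, na.rm = TRUE)
  sd_r <- apply(matrix, 1, stats::sd, na.rm = TRUE)
  zero <- !is.finite(sd_r) | sd_r == 0
  if (all(zero)) stop("all rows have zero variance; matrix is constant")
  if (any(zero)) {
    warning(sum(zero), " zero-variance row(s) dropped")
  }
  z <- (matrix[!zero, , drop = FALSE] - med[!zero]) / sd_r[!zero]
  attr(z, "convention") <- "median_centered"
  z
}

#' Total CDS length of a gene model
#'
#' The coding length of a gene including all alternative exons: the length
#' of the genomic union of its exon intervals, so bases shared by
#' overlapping alternative exons are counted once.  Intervals are 0-based
#' half-open.
#'
#' @param exon_starts,exon_ends Integer vectors of exon interval bounds.
#' @return Union length in bp.
#' @export
cds_length <- function(exon_starts, exon_ends) {
  stopifnot(length(exon_starts) == length(exon_ends),
            length(exon_starts) >= 1)
  if (any(exon_starts >= exon_ends)) {
    stop("inverted or empty exon interval (start >= end)")
  }
  r <- IRanges::reduce(IRanges::IRanges(start = exon_starts + 1L,
                                        end = exon_ends))
  sum(IRanges::width(r))
}

.parse_model_exons <- function(models) {
  lapply(seq_len(nrow(models)), function(i) {
    list(starts = as.integer(strsplit(as.character(models$exon_starts[i]),
                                      ",")[[1]]),
         ends = as.integer(strsplit(as.character(models$exon_ends[i]),
                                    ",")[[1]]))
  })
}

#' Gene-length-normalized mutation burden
#'
#' Summed per-gene mutation counts are normalized by the gene's total CDS
#' length, and the square root of that rate taken as the default score to
#' damp cohort-size differences: score_g = sqrt(count_g / CDS_g).  Genes
#' with a model but no mutations score 0.
#'
#' @param mutations MAF-like data frame with at least `gene` and `sample`
#'   columns (one row per mutation).
#' @param models Gene-model data frame (gene, exon_starts, exon_ends,
#'   comma-separated 0-based half-open intervals).
#' @param n_tumors Number of tumors in the cohort; used only when
#'   `per_tumor = TRUE`.
#' @param per_tumor If `TRUE`, counts are divided by `n_tumors` before
#'   normalization (alternative reading of the cohort-size control).
#' @param transform "sqrt" (default) or "rate" for the untransformed
#'   per-bp mutation rate.
#' @return Data frame: gene, raw_count, cds_length, rate, score.
#' @export
mutation_burden <- function(mutations, models, n_tumors = 1L,
                            per_tumor = FALSE,
                            transform = c("sqrt", "rate")) {
  transform <- match.arg(transform)
  stopifnot(n_tumors >= 1)
  missing_models <- setdiff(unique(mutations$gene), models$gene)
  if (length(missing_models) > 0) {
    stop("mutated gene(s) lacking a gene model: ",
         paste(sort(missing_models), collapse = ", "))
  }
  exons <- .parse_model_exons(models)
  lens <- vapply(exons, function(e) cds_length(e$starts, e$ends), numeric(1))
  counts <- table(factor(mutations$gene, levels = models$gene))
  raw <- as.numeric(counts)
  eff <- if (per_tumor) raw / n_tumors else raw
  rate <- eff / lens
  score <- if (transform == "sqrt") sqrt(rate) else rate
  data.frame(gene = models$gene, raw_count = raw, cds_length = lens,
             rate = rate, score = score, stringsAsFactors = FALSE)
}

#' Copy-number alteration calls from GISTIC codes
#'
#' @param cna Genes x samples integer matrix with GISTIC codes in
#'   (-2, -1, 0, 1, 2).
#' @param level "deep" calls only deep deletions (-2) and amplifications
#'   (+2); "any" calls any non-neutral code (|code| >= 1).
#' @return A list with logical matrices `amplification` and `deletion`.
#' @export
cna_alteration_calls <- function(cna, level = c("deep", "any")) {
  level <- match.arg(level)
  stopifnot(is.matrix(cna))
  if (!all(cna %in% c(-2L, -1L, 0L, 1L, 2L))) {
    stop("CNA codes outside the GISTIC set {-2,-1,0,1,2}")
  }
  if (level == "deep") {
    list(amplification = cna == 2L, deletion = cna == -2L)
  } else {
    list(amplification = cna >= 1L, deletion = cna <= -1L)
  }
}

#' Write a Z-score or burden table as TSV
#'
#' @param x Matrix (written with a leading `gene` column) or data frame.
#' @param path Output path.
#' @export
write_scores_tsv <- function(x, path) {
  if (is.matrix(x)) {
    x <- data.frame(gene = rownames(x), x, check.names = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
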