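#' Configuration for the synthetic cistrome generator
#'
#' Genes are laid out on one synthetic chromosome with a spacing larger than
#' twice the annotation window, so that "decoy" peaks can be placed provably
#' outside every gene's window.  Truth peaks are placed inside the window of
#' designated truth genes and are guaranteed to overlap a chromatin-state
#' segment by at least 1 bp; decoy peaks either sit beyond the window of all
#' genes (but on a state) or within a window but on a state gap.
#'
#' @param n_genes Number of genes on the synthetic chromosome.
#' @param n_truth_genes Number of genes planted as bound-and-regulated.
#' @param window Annotation window in bp (peak edge to TSS).
#' @param n_far_decoys Decoy peaks placed farther than `window` from every
#'   TSS but overlapping a state segment.
#' @param n_stateless_decoys Decoy peaks placed inside a non-truth gene's
#'   window but overlapping no state segment.
#' @param peak_width Width of each peak in bp.
#' @param state_labels Chromatin-state vocabulary to sample labels from.
#' @param chrom_length Optional fixed chromosome length in bp; by default
#'   the chromosome is sized to fit the gene layout.  Must exceed the
#'   window when given.
#' @param seed Integer seed.
#' @return A `cistrome_config` list.
#' @export
cistrome_config <- function(n_genes = 40, n_truth_genes = 20,
                            window = 100000, n_far_decoys = 15,
                            n_stateless_decoys = 10, peak_width = 400,
                            state_labels = c("Promoter", "Active Enhancer",
                                             "Poised Enhancer",
                                             "Transcribed"),
                            chrom_length = NULL,
                            seed = 1L) {
  stopifnot(n_genes >= 1, n_truth_genes >= 0, n_truth_genes <= n_genes,
            window > 0, peak_width > 0, n_far_decoys >= 0,
            n_stateless_decoys >= 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_truth_genes = as.integer(n_truth_genes),
                 window = as.integer(window),
                 n_far_decoys = as.integer(n_far_decoys),
                 n_stateless_decoys = as.integer(n_stateless_decoys),
                 peak_width = as.integer(peak_width),
                 state_labels = state_labels,
                 chrom_length = chrom_length,
                 seed = as.integer(seed)),
            class = "cistrome_config")
}

#' Simulate a cistrome fixture with planted bound genes
#'
#' @param config A [cistrome_config()] object.
#' @return A list of class `sim_cistrome` with `peaks` (BED-like data
#'   frame: chrom, start, end, name, score; 0-based half-open), `states`
#'   (chrom, start, end, state), `gene_models`, and `truth` (list with
#'   `bound_genes`, the planted truth gene symbols).
#' @export
simulate_cistrome <- function(config) {
  stopifnot(inherits(config, "cistrome_config"))
  set.seed(config$seed)
  W <- as.numeric(config$window); pw <- config$peak_width
  spacing <- 2 * W + 50000
  chrom <- "chrS"
  chrom_len <- if (!is.null(config$chrom_length)) {
    as.numeric(config$chrom_length)
  } else {
    2 * spacing + config$n_genes * spacing
  }
  if (W >= chrom_len) stop("annotation window larger than the chromosome")
  if (spacing * (config$n_genes + 1) > chrom_len) {
    stop("chromosome too short for the gene layout")
  }
  tss <- spacing + (seq_len(config$n_genes) - 1) * spacing
  genes <- sprintf("CG%03d", seq_len(config$n_genes))
  models <- data.frame(gene = genes, chrom = chrom, strand = "+",
                       tss = tss,
                       exon_starts = as.character(tss),
                       exon_ends = as.character(tss + 2000L),
                       stringsAsFactors = FALSE)

  truth_genes <- if (config$n_truth_genes > 0) {
    sort(sample(genes, config$n_truth_genes))
  } else character(0)

  peaks <- list(); states <- list()
  add_peak <- function(start, name) {
    peaks[[length(peaks) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = start + pw, name = name,
      score = round(runif(1, 10, 1000)), stringsAsFactors = FALSE)
  }
  add_state <- function(start, end) {
    states[[length(states) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end,
      state = sample(config$state_labels, 1), stringsAsFactors = FALSE)
  }

  # truth peaks: inside the window of a truth gene, overlapping a state
  for (g in truth_genes) {
    anchor <- tss[match(g, genes)]
    offset <- round(runif(1, -0.8 * W, 0.8 * W))
    start <- anchor + offset
    add_peak(start, paste0("peak_truth_", g))
    add_state(start - 1000L, start + 1L + round(runif(1, 500, 3000)))
  }
  # far decoys: at inter-gene midpoints, distance W + 25 kb from both TSSs
  if (config$n_far_decoys > 0) {
    mids <- tss + spacing %/% 2L
    for (i in seq_len(config$n_far_decoys)) {
      start <- mids[1L + (i - 1L) %% length(mids)] +
        round(runif(1, -5000, 5000))
      add_peak(start, sprintf("peak_far_%03d", i))
      add_state(start - 500L, start + pw + 500L)
    }
  }
  # stateless decoys: inside a non-truth gene window, no state placed there
  non_truth <- setdiff(genes, truth_genes)
  if (config$n_stateless_decoys > 0 && length(non_truth) > 0) {
    for (i in seq_len(config$n_stateless_decoys)) {
      g <- non_truth[1L + (i - 1L) %% length(non_truth)]
      anchor <- tss[match(g, genes)]
      start <- anchor + round(runif(1, 0.2 * W, 0.8 * W))
      add_peak(start, sprintf("peak_nostate_%03d", i))
    }
  }

  peaks <- do.call(rbind, peaks)
  states <- do.call(rbind, states)
  structure(list(peaks = peaks, states = states, gene_models = models,
                 truth = list(bound_genes = truth_genes,
                              seed = config$seed),
                 config = config),
            class = "sim_cistrome")
}

#' Write cistrome fixtures as BED / TSV files
#'
#' @param sim A `sim_cistrome` from [simulate_cistrome()].
#' @param outdir Output directory.
#' @return The output directory, invisibly.
#' @export
write_cistrome <- function(sim, outdir) {
  stopifnot(inherits(sim, "sim_cistrome"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- sim$peaks
  bed6 <- data.frame(p$chrom, p$start, p$end, p$name, p$score, ".")
  utils::write.table(bed6, file.path(outdir, "peaks.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  s <- sim$states
  bed4 <- data.frame(s$chrom, s$start, s$end, s$state)
  utils::write.table(bed4, file.path(outdir, "states.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$gene_models, file.path(outdir, "gene_models.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(bound_genes = as.list(sim$truth$bound_genes),
                        seed = sim$truth$seed),
                   file.path(outdir, "truth.yaml"))
  invisible(outdir)
}

#' Read a BED file of peaks or chromatin states
#'
#' BED3/BED6 files load as peak tables (a `name` is synthesized when the
#' 4th column is missing); files whose 4th column is a state label load as
#' state tables when `type = "states"`.
#'
#' @param path BED file path.
#' @param type "peaks" or "states".
#' @return A data frame with 0-based half-open `start`/`end` columns.
#' @export
read_bed <- function(path, type = c("peaks", "states")) {
  type <- match.arg(type)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (type == "states") {
    stopifnot(ncol(df) >= 4)
    names(df)[4] <- "state"
    return(df[, c("chrom", "start", "end", "state")])
  }
  df$name <- if (ncol(df) >= 4) as.character(df[[4]]) else
    sprintf("peak_%05d", seq_len(nrow(df)))
  df$score <- if (ncol(df) >= 5) df[[5]] else NA_real_
  df[, c("chrom", "start", "end", "name", "score")]
}

#' Simulate a shRNA-knockdown differential-expression table
#'
#' Emulates the output of a count-based differential-expression pipeline
#' applied to a coactivator knockdown: down-regulation dominates both in
#' gene count and effect size.  Defaults plant 1993 down- and 1607
#' up-regulated protein-coding genes with mean log-fold-changes of -1.11
#' and +0.83 respectively, on a background of unaffected genes.
#'
#' @param n_genes Total number of genes in the table.
#' @param n_down,n_up Planted numbers of significantly down-/up-regulated
#'   genes; both may be 0.
#' @param mean_lfc_down,mean_lfc_up Mean log-fold-change of the planted
#'   down-/up-regulated genes.
#' @param sd_lfc SD of the planted log-fold-changes.
#' @param genes Optional character vector of gene names (length `n_genes`);
#'   autogenerated when `NULL`.
#' @param seed Integer seed.
#' @return A list of class `sim_kd_de` with `de` (a `de_table` data frame:
#'   gene, logFC, p, fdr, significant) and `truth` (down_genes, up_genes).
#' @export
simulate_knockdown_de <- function(n_genes = 15000, n_down = 1993,
                                  n_up = 1607, mean_lfc_down = -1.11,
                                  mean_lfc_up = 0.83, sd_lfc = 0.35,
                                  genes = NULL, seed = 1L) {
  if (n_down < 0 || n_up < 0) stop("planted DEG counts must be non-negative")
  stopifnot(n_down + n_up <= n_genes, sd_lfc >= 0)
  set.seed(seed)
  if (is.null(genes)) genes <- sprintf("G%05d", seq_len(n_genes))
  stopifnot(length(genes) == n_genes, !anyDuplicated(genes))
  idx <- sample.int(n_genes, n_down + n_up)
  down <- idx[seq_len(n_down)]
  up <- if (n_up > 0) idx[n_down + seq_len(n_up)] else integer(0)
  lfc <- rnorm(n_genes, 0, 0.2)
  p <- runif(n_genes)
  if (n_down > 0) {
    lfc[down] <- rnorm(n_down, mean_lfc_down, sd_lfc)
    p[down] <- runif(n_down, 0, 1e-4)
  }
  if (n_up > 0) {
    lfc[up] <- rnorm(n_up, mean_lfc_up, sd_lfc)
    p[up] <- runif(n_up, 0, 1e-4)
  }
  de <- de_table(data.frame(gene = genes, logFC = lfc, p = p,
                            stringsAsFactors = FALSE),
                 contrast = "knockdown_vs_control",
                 fdr_threshold = 0.05, lfc_threshold = 0.5)
  structure(list(de = de,
                 truth = list(down_genes = sort(genes[down]),
                              up_genes = sort(genes[up]),
                              seed = seed)),
            class = "sim_kd_de")
}
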