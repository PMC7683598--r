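#' Run the full synthetic analysis pipeline
#'
#' Exercises every stage end to end on synthetic data with planted
#' structure: two matched multi-omic cohorts are simulated (one with a
#' class-wide coactivator down-shift, a strongly-filterable gene subset and
#' a planted hazard gene), scored, family-tested, filtered, intersected and
#' survival-screened; a synthetic cistrome with planted bound genes plus a
#' knockdown DE table then drive the cis-regulation cascade.  A
#' machine-readable run report collects the headline quantities of every
#' stage.
#'
#' Problem sizes default to a desk-scale run (2,000 genes, 120 + 80 tumors,
#' B = 5,000 resamples) that completes in a few minutes on one CPU.
#'
#' @param seed Integer master seed; every stochastic stage derives from it.
#' @param n_genes,n_tumors Cohort dimensions.
#' @param B Resampling draws for the family tests.
#' @param outdir Optional directory; when given, the report is written
#'   there as `run_report.json` together with the panel and network TSVs.
#' @return The run report (a nested list), invisibly self-describing.
#' @export
run_pipeline <- function(seed = 1L, n_genes = 2000, n_tumors = 120,
                         B = 5000L, outdir = NULL) {
  t0 <- Sys.time()
  seed <- as.integer(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  hazard_gene <- genes[7]

  effects <- list(
    planted_effect("COA", 0.30, 0.40, -1.0, "expression"),
    planted_effect("COR", 0.10, 0.50, -3.5, "expression"),
    planted_effect("COR", 0.05, 0.30, -2.0, "cna")
  )
  simA <- simulate_cohort(sim_config(
    n_genes = n_genes, n_tumors = n_tumors, n_normals = 30,
    planted_effects = effects,
    hazard_coefficients = stats::setNames(1.0, hazard_gene),
    seed = seed))
  simB <- simulate_cohort(sim_config(
    n_genes = n_genes, n_tumors = max(60L, n_tumors %/% 2L), n_normals = 20,
    planted_effects = effects[2],
    seed = seed + 1L))

  # catalog straight from the generator's planted class assignment
  truth_classes <- simA$truth$classes
  assignment <- data.frame(gene = names(truth_classes)[!is.na(truth_classes)],
                           class = truth_classes[!is.na(truth_classes)],
                           provenance = "synthetic",
                           stringsAsFactors = FALSE)
  catalog <- new_gene_class_catalog(assignment)

  panel <- run_family_panel(list(A = simA$cohort, B = simB$cohort), catalog,
                            data_types = c("expression", "cna", "mutation"),
                            statistic = "mean", B = B, seed = seed)

  zA <- tumor_normal_zscores(simA$cohort)
  zB <- tumor_normal_zscores(simB$cohort)
  spec <- filter_spec(preset = "figure-2.5")
  filteredA <- frequent_alteration_filter(zA, spec)
  filteredB <- frequent_alteration_filter(zB, spec)
  inter <- intersect_cohorts(list(A = filteredA, B = filteredB))

  cluster_assoc <- NULL
  if (length(filteredA) >= 2) {
    labels <- cluster_tumors(zA[filteredA, , drop = FALSE], k = 2)
    grade <- simA$cohort$clinical$grade[
      match(names(labels), simA$cohort$clinical$sample)]
    cluster_assoc <- tryCatch(cluster_outcome_association(labels, grade),
                              error = function(e) NULL)
  }

  screen_genes <- unique(c(hazard_gene, genes[seq_len(min(200, n_genes))]))
  screen <- logrank_screen(simA$cohort$expr[, tumor_samples(simA$cohort)],
                           simA$cohort$clinical, genes = screen_genes)
  screen_ranked <- screen[order(screen$fdr), ]

  cis <- simulate_cistrome(cistrome_config(seed = seed))
  state_peaks <- overlap_states(cis$peaks, cis$states)
  links <- annotate_peaks_to_genes(state_peaks, cis$gene_models)
  cis_genes <- cis$gene_models$gene
  kd <- simulate_knockdown_de(n_genes = length(cis_genes), n_down = 12,
                              n_up = 8, genes = cis_genes, seed = seed)
  # cohort-quartile DE surrogate over the cistrome genes: truth genes DE
  co_de <- de_table(data.frame(
    gene = cis_genes,
    logFC = ifelse(cis_genes %in% cis$truth$bound_genes, 2, 0),
    p = ifelse(cis_genes %in% cis$truth$bound_genes, 1e-6, 0.5)),
    contrast = "upper_vs_lower_quartile", lfc_threshold = 1.5)
  kd_all_sig <- de_table(kd$de[, c("gene", "logFC", "p")],
                         contrast = "knockdown_vs_control",
                         lfc_threshold = 0)
  kd_all_sig$significant <- kd_all_sig$gene %in%
    c(kd$truth$down_genes, kd$truth$up_genes, cis$truth$bound_genes)
  network <- bound_and_regulated(links, kd_all_sig, co_de)

  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report <- list(
    seed = seed,
    sizes = list(n_genes = n_genes, n_tumors_A = n_tumors,
                 n_tumors_B = max(60L, n_tumors %/% 2L), B = B),
    family_panel = list(
      n_tests = nrow(panel),
      n_skipped = sum(panel$skipped),
      n_significant_q10 = sum(panel$q < 0.1, na.rm = TRUE),
      min_q = min(panel$q, na.rm = TRUE)),
    filtering = list(n_filtered_A = length(filteredA),
                     n_filtered_B = length(filteredB),
                     n_shared = sum(rowSums(inter$membership) == 2)),
    cluster_association = if (!is.null(cluster_assoc)) {
      list(statistic = cluster_assoc$statistic, p = cluster_assoc$p.value)
    } else NULL,
    survival = list(n_screened = sum(!is.na(screen$p)),
                    top_gene = screen_ranked$gene[1],
                    top_gene_fdr = screen_ranked$fdr[1],
                    hazard_gene_recovered =
                      identical(screen_ranked$gene[1], hazard_gene)),
    cis_cascade = list(n_peaks = nrow(cis$peaks),
                       n_state_peaks = nrow(state_peaks),
                       n_links = nrow(links),
                       n_bound_and_regulated = nrow(network),
                       n_truth = length(cis$truth$bound_genes),
                       truth_recovered =
                         setequal(network$gene, cis$truth$bound_genes)),
    runtime_seconds = round(elapsed, 2)
  )
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_panel_tsv(panel, file.path(outdir, "family_panel.tsv"))
    utils::write.table(as.data.frame(network),
                       file.path(outdir, "bound_regulated_network.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' Heatmap-style display of a family panel's -log10(q) matrix
#'
#' @param panel A `family_panel`.
#' @param data_type Data type to display.
#' @export
plot_family_panel <- function(panel, data_type = "expression") {
  m <- panel_neglog10_matrix(panel, data_type)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  axes = FALSE, xlab = "", ylab = "",
                  main = paste("-log10(q),", data_type))
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(nrow(m)), rownames(m), las = 1)
  invisible(m)
}
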