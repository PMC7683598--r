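#' Planted effect specification
#'
#' Describes a class-level alteration planted into a synthetic cohort: a
#' fraction of the genes in one class is shifted in a fraction of tumors.
#' For expression data `z_shift` is the location shift in units of the
#' gene's own SD (so it is recovered directly on the Z-score scale).  For
#' copy-number data the sign of `z_shift` selects deep deletion (negative)
#' or amplification (positive) in the affected cells.  For mutation data the
#' per-cell Poisson rate is multiplied by `exp(z_shift)`.
#'
#' @param target_class One of "TF", "COA", "COR", "MIXED".
#' @param affected_gene_fraction Fraction of class genes affected, in (0, 1].
#' @param affected_tumor_fraction Fraction of tumors affected, in (0, 1].
#' @param z_shift Effect size (see Details above).
#' @param data_type One of "expression", "cna", "mutation".
#' @return A `planted_effect` list.
#' @export
planted_effect <- function(target_class, affected_gene_fraction,
                           affected_tumor_fraction, z_shift,
                           data_type = c("expression", "cna", "mutation")) {
  data_type <- match.arg(data_type)
  stopifnot(target_class %in% c("TF", "COA", "COR", "MIXED"),
            affected_gene_fraction > 0, affected_gene_fraction <= 1,
            affected_tumor_fraction > 0, affected_tumor_fraction <= 1,
            is.finite(z_shift))
  structure(list(target_class = target_class,
                 affected_gene_fraction = affected_gene_fraction,
                 affected_tumor_fraction = affected_tumor_fraction,
                 z_shift = z_shift, data_type = data_type),
            class = "planted_effect")
}

#' Simulation configuration for a synthetic multi-omic cohort
#'
#' Defaults emulate a localized prostate-cancer cohort: ~150 tumors with a
#' matched-normal subset, class fractions matching the share of detected
#' TF/COA/COR/MIXED genes in a typical expression panel, sparse GISTIC
#' background, and an exome-like somatic mutation rate of about 2 mutations
#' per megabase of coding sequence per tumor.
#'
#' @param n_genes Number of genes.
#' @param n_tumors Number of tumor samples.
#' @param n_normals Number of matched normal samples (paired with the first
#'   `n_normals` tumors); at least 2 are required for tumor-normal Z-scores.
#' @param class_fractions Named fractions of genes assigned to each class;
#'   must sum to at most 1 (the remainder is unassigned background).
#' @param planted_effects List of [planted_effect()] objects.
#' @param mutation_rate_per_bp Background somatic mutation rate per coding
#'   base pair per tumor.
#' @param gistic_background_probs Probabilities over GISTIC codes
#'   (-2, -1, 0, 1, 2); must sum to 1.
#' @param hazard_coefficients Named numeric vector: per-gene log-hazard-ratio
#'   per expression Z-score unit.
#' @param censoring_rate Expected fraction of censored samples under the
#'   null linear predictor, in [0, 1).
#' @param baseline_hazard Exponential baseline event rate per time unit
#'   (months).
#' @param seed Integer seed; recorded in the output metadata.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 10000, n_tumors = 150, n_normals = 30,
                       class_fractions = c(TF = 0.13, COA = 0.066,
                                           COR = 0.042, MIXED = 0.041),
                       planted_effects = list(),
                       mutation_rate_per_bp = 2e-6,
                       gistic_background_probs = c(0.02, 0.08, 0.80, 0.08,
                                                   0.02),
                       hazard_coefficients = numeric(),
                       censoring_rate = 0.5,
                       baseline_hazard = 0.02,
                       seed = 1L) {
  stopifnot(n_genes > 0, n_tumors > 0, n_normals >= 0,
            n_normals <= n_tumors,
            all(class_fractions >= 0), all(class_fractions <= 1),
            sum(class_fractions) <= 1,
            length(gistic_background_probs) == 5L,
            abs(sum(gistic_background_probs) - 1) < 1e-8,
            mutation_rate_per_bp >= 0,
            censoring_rate >= 0, censoring_rate < 1,
            baseline_hazard > 0)
  if (inherits(planted_effects, "planted_effect")) {
    planted_effects <- list(planted_effects)
  }
  stopifnot(all(vapply(planted_effects, inherits, logical(1),
                       "planted_effect")))
  structure(list(n_genes = as.integer(n_genes),
                 n_tumors = as.integer(n_tumors),
                 n_normals = as.integer(n_normals),
                 class_fractions = class_fractions,
                 planted_effects = planted_effects,
                 mutation_rate_per_bp = mutation_rate_per_bp,
                 gistic_background_probs = gistic_background_probs,
                 hazard_coefficients = hazard_coefficients,
                 censoring_rate = censoring_rate,
                 baseline_hazard = baseline_hazard,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.gene_names <- function(n) sprintf("G%05d", seq_len(n))

# synthetic gene models on one chromosome: 1-5 exons, CDS 500-5000 bp total
.simulate_gene_models <- function(n_genes, chrom = "chr1", spacing = 50000L) {
  tss <- 10000L + (seq_len(n_genes) - 1L) * spacing
  n_exons <- sample(1:5, n_genes, replace = TRUE)
  exon_starts <- character(n_genes)
  exon_ends <- character(n_genes)
  for (i in seq_len(n_genes)) {
    len <- round(runif(n_exons[i], 100, 1000))
    gaps <- round(runif(n_exons[i], 200, 2000))
    s <- tss[i] + cumsum(gaps) + cumsum(c(0, len[-n_exons[i]]))
    e <- s + len
    exon_starts[i] <- paste(s, collapse = ",")
    exon_ends[i] <- paste(e, collapse = ",")
  }
  data.frame(gene = .gene_names(n_genes), chrom = chrom,
             strand = sample(c("+", "-"), n_genes, replace = TRUE),
             tss = tss, exon_starts = exon_starts, exon_ends = exon_ends,
             stringsAsFactors = FALSE)
}

#' Simulate a matched multi-omic tumor cohort with planted effects
#'
#' Generates per-gene Gaussian expression baselines shared by tumors and
#' normals, GISTIC-coded copy-number calls, a MAF-like somatic mutation
#' table driven by per-gene CDS length, and a clinical table with
#' exponential proportional-hazards survival times whose linear predictor is
#' the sum of `hazard_coefficients` times the per-gene expression Z-score.
#' Planted effects (see [planted_effect()]) shift selected (gene, tumor)
#' cells; the affected genes, tumors and true shifts are returned in the
#' truth record so recovery can be verified by inspection.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_cohort` with elements `cohort` (a `cohort`
#'   object) and `truth` (a `synthetic_truth` list).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes; nt <- config$n_tumors; nn <- config$n_normals
  genes <- .gene_names(ng)
  tumor_ids <- sprintf("T%04d", seq_len(nt))
  normal_ids <- if (nn > 0) sprintf("N%04d", seq_len(nn)) else character(0)

  # class assignment: contiguous blocks over a seeded permutation
  n_per_class <- floor(config$class_fractions * ng)
  perm <- sample(genes)
  cls <- rep(NA_character_, ng); names(cls) <- perm
  off <- 0L
  for (cl in names(n_per_class)) {
    k <- n_per_class[[cl]]
    if (k > 0) cls[seq_len(k) + off] <- cl
    off <- off + k
  }
  classes <- cls[genes]  # reorder to gene order
  names(classes) <- genes

  mu <- rnorm(ng, 8, 2)
  sdv <- runif(ng, 0.5, 1.5)
  expr_t <- matrix(rnorm(ng * nt), ng, nt) * sdv + mu
  expr_n <- if (nn > 0) matrix(rnorm(ng * nn), ng, nn) * sdv + mu else
    matrix(numeric(0), ng, 0)

  cna <- matrix(sample(c(-2L, -1L, 0L, 1L, 2L), ng * nt, replace = TRUE,
                       prob = config$gistic_background_probs), ng, nt)

  models <- .simulate_gene_models(ng)
  cds_len <- vapply(seq_len(ng), function(i) {
    s <- as.integer(strsplit(models$exon_starts[i], ",")[[1]])
    e <- as.integer(strsplit(models$exon_ends[i], ",")[[1]])
    sum(e - s)  # simulated exons are disjoint by construction
  }, numeric(1))
  mut_rate <- matrix(config$mutation_rate_per_bp * cds_len, ng, nt)

  # apply planted effects; record resolved gene/tumor identities
  truth_effects <- list()
  for (eff in config$planted_effects) {
    in_class <- genes[!is.na(classes) & classes == eff$target_class]
    n_aff_g <- ceiling(eff$affected_gene_fraction * length(in_class))
    if (n_aff_g > length(in_class)) {
      stop("planted effect infeasible: affected genes exceed class size for ",
           eff$target_class)
    }
    if (n_aff_g == 0L || length(in_class) == 0L) {
      stop("planted effect infeasible: class ", eff$target_class,
           " has no genes")
    }
    aff_g <- sample(in_class, n_aff_g)
    n_aff_t <- max(1L, round(eff$affected_tumor_fraction * nt))
    aff_t <- sample(tumor_ids, n_aff_t)
    gi <- match(aff_g, genes); ti <- match(aff_t, tumor_ids)
    if (eff$data_type == "expression") {
      expr_t[gi, ti] <- expr_t[gi, ti] + eff$z_shift * sdv[gi]
    } else if (eff$data_type == "cna") {
      cna[gi, ti] <- if (eff$z_shift < 0) -2L else 2L
    } else {
      mut_rate[gi, ti] <- mut_rate[gi, ti] * exp(eff$z_shift)
    }
    truth_effects[[length(truth_effects) + 1L]] <-
      list(target_class = eff$target_class, data_type = eff$data_type,
           z_shift = eff$z_shift, affected_genes = aff_g,
           affected_tumors = aff_t)
  }

  counts <- matrix(rpois(ng * nt, lambda = mut_rate), ng, nt)
  idx <- which(counts > 0, arr.ind = TRUE)
  mutations <- if (nrow(idx) > 0) {
    reps <- counts[idx]
    gi <- rep(idx[, 1], reps); si <- rep(idx[, 2], reps)
    pos <- vapply(gi, function(i) {
      s <- as.integer(strsplit(models$exon_starts[i], ",")[[1]])
      e <- as.integer(strsplit(models$exon_ends[i], ",")[[1]])
      w <- e - s
      j <- sample.int(length(s), 1, prob = w)
      s[j] + sample.int(w[j], 1) - 1L
    }, numeric(1))
    data.frame(gene = genes[gi], sample = tumor_ids[si], position = pos,
               class = sample(c("Missense_Mutation", "Nonsense_Mutation",
                                "Frame_Shift_Del"),
                              length(gi), replace = TRUE,
                              prob = c(0.8, 0.1, 0.1)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(0), sample = character(0),
               position = integer(0), class = character(0))
  }

  # survival: exponential PH on the tumor-expression Z-scores
  lp <- rep(0, nt)
  hc <- config$hazard_coefficients
  if (length(hc) > 0) {
    stopifnot(!is.null(names(hc)), all(names(hc) %in% genes))
    for (g in names(hc)) {
      x <- expr_t[match(g, genes), ]
      lp <- lp + hc[[g]] * (x - mean(x)) / sd(x)
    }
  }
  t_event <- rexp(nt, rate = config$baseline_hazard * exp(lp))
  cr <- config$censoring_rate
  t_cens <- if (cr > 0) {
    rexp(nt, rate = config$baseline_hazard * cr / (1 - cr))
  } else rep(Inf, nt)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  grade <- ifelse(runif(nt) < plogis(lp), "high", "low")

  pair <- rep(NA_character_, nt)
  if (nn > 0) pair[seq_len(nn)] <- normal_ids
  clinical <- data.frame(
    sample = c(tumor_ids, normal_ids),
    type = c(rep("tumor", nt), rep("normal", nn)),
    normal_pair = c(pair, rep(NA_character_, nn)),
    time = c(round(time, 3), rep(NA_real_, nn)),
    event = c(event, rep(NA_integer_, nn)),
    grade = c(grade, rep(NA_character_, nn)),
    stringsAsFactors = FALSE
  )

  expr <- cbind(expr_t, expr_n)
  rownames(expr) <- genes
  colnames(expr) <- c(tumor_ids, normal_ids)
  rownames(cna) <- genes; colnames(cna) <- tumor_ids

  cohort <- new_cohort(expr = expr, clinical = clinical, cna = cna,
                       mutations = mutations, gene_models = models,
                       label = sprintf("synthetic-seed%d", config$seed))
  truth <- structure(list(effects = truth_effects,
                          classes = classes,
                          gene_sd = stats::setNames(sdv, genes),
                          hazard_coefficients = hc,
                          seed = config$seed),
                     class = "synthetic_truth")
  structure(list(cohort = cohort, truth = truth, config = config),
            class = "sim_cohort")
}

#' Construct a cohort container
#'
#' @param expr Genes x samples numeric matrix (tumors and normals).
#' @param clinical Data frame with at least `sample` and `type`
#'   ("tumor"/"normal") columns; survival screens additionally use `time`
#'   and `event`.
#' @param cna Optional genes x tumors integer matrix of GISTIC codes.
#' @param mutations Optional MAF-like data frame (gene, sample, position,
#'   class).
#' @param gene_models Optional gene-model data frame (gene, chrom, strand,
#'   tss, exon_starts, exon_ends; 0-based half-open, comma-separated).
#' @param label Cohort label used in result tables.
#' @return A `cohort` object.
#' @export
new_cohort <- function(expr, clinical, cna = NULL, mutations = NULL,
                       gene_models = NULL, label = "cohort") {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)),
            all(c("sample", "type") %in% names(clinical)),
            all(colnames(expr) %in% clinical$sample))
  structure(list(expr = expr, clinical = clinical, cna = cna,
                 mutations = mutations, gene_models = gene_models,
                 label = label),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort '", x$label, "': ", nrow(x$expr), " genes, ",
      sum(x$clinical$type == "tumor"), " tumors, ",
      sum(x$clinical$type == "normal"), " normals\n", sep = "")
  invisible(x)
}

#' Tumor / normal sample identifiers of a cohort
#' @param cohort A `cohort` object.
#' @return Character vector of sample ids.
#' @export
tumor_samples <- function(cohort) {
  cohort$clinical$sample[cohort$clinical$type == "tumor"]
}

#' @rdname tumor_samples
#' @export
normal_samples <- function(cohort) {
  cohort$clinical$sample[cohort$clinical$type == "normal"]
}

.write_tsv <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
}

#' Write a simulated cohort and its truth record to disk
#'
#' Emits plain-text files: expression.tsv and cna.tsv (genes x samples),
#' mutations.tsv (MAF-like), clinical.tsv, gene_models.tsv, and truth.yaml.
#' Output is deterministic for a fixed config and seed.
#'
#' @param sim A `sim_cohort` from [simulate_cohort()].
#' @param outdir Output directory (created if missing).
#' @return The output directory, invisibly.
#' @export
write_cohort <- function(sim, outdir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  co <- sim$cohort
  expr <- data.frame(gene = rownames(co$expr),
                     round(co$expr, 6), check.names = FALSE)
  .write_tsv(expr, file.path(outdir, "expression.tsv"))
  if (!is.null(co$cna)) {
    cna <- data.frame(gene = rownames(co$cna), co$cna, check.names = FALSE)
    .write_tsv(cna, file.path(outdir, "cna.tsv"))
  }
  if (!is.null(co$mutations)) {
    .write_tsv(co$mutations, file.path(outdir, "mutations.tsv"))
  }
  .write_tsv(co$clinical, file.path(outdir, "clinical.tsv"))
  if (!is.null(co$gene_models)) {
    .write_tsv(co$gene_models, file.path(outdir, "gene_models.tsv"))
  }
  tr <- sim$truth
  yaml::write_yaml(list(
    seed = tr$seed,
    effects = lapply(tr$effects, function(e) {
      list(target_class = e$target_class, data_type = e$data_type,
           z_shift = e$z_shift,
           affected_genes = as.list(sort(e$affected_genes)),
           affected_tumors = as.list(sort(e$affected_tumors)))
    }),
    hazard_coefficients = as.list(tr$hazard_coefficients)
  ), file.path(outdir, "truth.yaml"))
  invisible(outdir)
}

#' Read a cohort back from a directory written by [write_cohort()]
#'
#' @param dir Directory containing expression.tsv, clinical.tsv and
#'   optionally cna.tsv, mutations.tsv, gene_models.tsv.
#' @param label Cohort label.
#' @return A `cohort` object.
#' @export
read_cohort <- function(dir, label = basename(dir)) {
  expr_df <- utils::read.delim(file.path(dir, "expression.tsv"),
                               check.names = FALSE)
  expr <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expr) <- expr_df$gene
  clinical <- utils::read.delim(file.path(dir, "clinical.tsv"))
  cna <- NULL
  if (file.exists(file.path(dir, "cna.tsv"))) {
    cna_df <- utils::read.delim(file.path(dir, "cna.tsv"),
                                check.names = FALSE)
    cna <- as.matrix(cna_df[, -1, drop = FALSE])
    storage.mode(cna) <- "integer"
    rownames(cna) <- cna_df$gene
  }
  mutations <- if (file.exists(file.path(dir, "mutations.tsv"))) {
    utils::read.delim(file.path(dir, "mutations.tsv"))
  } else NULL
  models <- if (file.exists(file.path(dir, "gene_models.tsv"))) {
    utils::read.delim(file.path(dir, "gene_models.tsv"))
  } else NULL
  new_cohort(expr, clinical, cna, mutations, models, label)
}
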