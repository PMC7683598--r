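# shared fixture builders and brute-force oracles

toy_annotations <- function() {
  data.frame(
    gene = c("COA1", "COA2", "COR1", "MIX1", "MIX1", "TFX1", "NOEV1"),
    term_id = c("T:001", "T:002", "T:003", "T:004", "T:005", "T:006",
                "T:007"),
    term_label = c("transcription co-activator activity",
                   "positive control of transcription",
                   "negative control of transcription",
                   "positive regulation of transcription",
                   "co-repressor binding",
                   "positive control of transcription",
                   "positive control of transcription"),
    stringsAsFactors = FALSE
  )
}

toy_cohort <- function(expr, n_normals) {
  samples <- colnames(expr)
  n <- ncol(expr)
  clinical <- data.frame(
    sample = samples,
    type = c(rep("tumor", n - n_normals), rep("normal", n_normals)),
    stringsAsFactors = FALSE
  )
  new_cohort(expr, clinical, label = "toy")
}

# brute-force all-pairs peak:gene linker (independent of GRanges)
bf_links <- function(peaks, models, window) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(models))) {
      if (peaks$chrom[i] != models$chrom[j]) next
      d <- max(0, peaks$start[i] - models$tss[j],
               models$tss[j] - (peaks$end[i] - 1))
      if (d <= window) {
        out[[length(out) + 1]] <- data.frame(
          peak = peaks$name[i], gene = models$gene[j], distance = d,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(peak = character(0), gene = character(0),
                      distance = numeric(0)))
  }
  do.call(rbind, out)
}

# brute-force overlap filter on 0-based half-open intervals
bf_overlap_keep <- function(peaks, states, min_overlap) {
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(states))) {
      if (peaks$chrom[i] != states$chrom[j]) next
      ov <- min(peaks$end[i], states$end[j]) -
        max(peaks$start[i], states$start[j])
      if (ov >= min_overlap) keep[i] <- TRUE
    }
  }
  keep
}

random_interval_fixture <- function(seed, max_peaks = 200, max_genes = 50,
                                    max_states = 100, span = 2e6) {
  set.seed(seed)
  np <- sample.int(max_peaks, 1)
  ng <- sample.int(max_genes, 1)
  ns <- sample.int(max_states, 1)
  ps <- sort(sample.int(span, np))
  peaks <- data.frame(chrom = "chr1", start = ps,
                      end = ps + sample(50:2000, np, replace = TRUE),
                      name = sprintf("p%04d", seq_len(np)),
                      stringsAsFactors = FALSE)
  models <- data.frame(gene = sprintf("g%03d", seq_len(ng)), chrom = "chr1",
                       strand = "+", tss = sample.int(span, ng),
                       stringsAsFactors = FALSE)
  ss <- sample.int(span, ns)
  states <- data.frame(chrom = "chr1", start = ss,
                       end = ss + sample(100:5000, ns, replace = TRUE),
                       state = sample(c("Promoter", "Enhancer"), ns,
                                      replace = TRUE),
                       stringsAsFactors = FALSE)
  list(peaks = peaks, models = models, states = states)
}

# exhaustive permutation p for the mean statistic, direction down
exact_perm_p_down <- function(scores, class_genes) {
  k <- length(class_genes)
  obs <- mean(scores[class_genes])
  combos <- utils::combn(length(scores), k)
  null <- apply(combos, 2, function(ix) mean(scores[ix]))
  mean(null <= obs + 1e-12)
}
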