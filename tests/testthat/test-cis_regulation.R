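test_that("peak-gene annotation respects the window boundary exactly", {
  models <- data.frame(gene = "G1", chrom = "chr1", strand = "+",
                       tss = 500000, stringsAsFactors = FALSE)
  # nearest edge exactly 100,000 bp from the TSS: linked
  at_w <- data.frame(chrom = "chr1", start = 399601, end = 400001,
                     name = "pA", stringsAsFactors = FALSE)
  # one bp further: not linked
  beyond <- data.frame(chrom = "chr1", start = 399600, end = 400000,
                       name = "pB", stringsAsFactors = FALSE)
  # overlapping the TSS: distance 0
  on_tss <- data.frame(chrom = "chr1", start = 499900, end = 500100,
                       name = "pC", stringsAsFactors = FALSE)
  l1 <- annotate_peaks_to_genes(at_w, models, window = 100000)
  expect_equal(nrow(l1), 1)
  expect_equal(l1$distance, 100000)
  expect_equal(nrow(annotate_peaks_to_genes(beyond, models,
                                            window = 100000)), 0)
  l3 <- annotate_peaks_to_genes(on_tss, models, window = 100000)
  expect_equal(l3$distance, 0)
})

test_that("annotation handles unknown and mixed chromosome naming", {
  models <- data.frame(gene = "G1", chrom = "chr1", strand = "+",
                       tss = 1000, stringsAsFactors = FALSE)
  p <- data.frame(chrom = c("chr1", "chr9"), start = c(500, 500),
                  end = c(700, 700), name = c("a", "b"),
                  stringsAsFactors = FALSE)
  expect_warning(l <- annotate_peaks_to_genes(p, models), "skipped")
  expect_equal(l$peak, "a")
  p_mixed <- data.frame(chrom = "1", start = 500, end = 700, name = "a",
                        stringsAsFactors = FALSE)
  expect_error(annotate_peaks_to_genes(p_mixed, models), "naming")
})

test_that("state overlap respects half-open 1 bp boundaries", {
  peak <- data.frame(chrom = "chr1", start = 100, end = 200, name = "p1",
                     stringsAsFactors = FALSE)
  touching <- data.frame(chrom = "chr1", start = 200, end = 300,
                         state = "Promoter", stringsAsFactors = FALSE)
  one_bp <- data.frame(chrom = "chr1", start = 199, end = 300,
                       state = "Promoter", stringsAsFactors = FALSE)
  expect_equal(nrow(overlap_states(peak, touching)), 0)
  kept <- overlap_states(peak, one_bp)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$states, "Promoter")
  # raising min_overlap drops the 1 bp case again
  expect_equal(nrow(overlap_states(peak, one_bp, min_overlap = 2)), 0)
})

test_that("interval operations match brute force on random fixtures", {
  for (s in 1:20) {
    fx <- random_interval_fixture(s, max_peaks = 60, max_genes = 25,
                                  max_states = 40)
    links <- annotate_peaks_to_genes(fx$peaks, fx$models, window = 100000)
    oracle <- bf_links(fx$peaks, fx$models, 100000)
    expect_equal(nrow(links), nrow(oracle))
    got <- sort(paste(links$peak, links$gene, links$distance))
    want <- sort(paste(oracle$peak, oracle$gene, oracle$distance))
    expect_identical(got, want)

    kept <- overlap_states(fx$peaks, fx$states, min_overlap = 1)
    expect_setequal(kept$name, fx$peaks$name[
      bf_overlap_keep(fx$peaks, fx$states, 1)])
  }
})

test_that("enlarging the window and overlap thresholds act monotonically", {
  fx <- random_interval_fixture(99, max_peaks = 50, max_genes = 20,
                                max_states = 30)
  l_small <- annotate_peaks_to_genes(fx$peaks, fx$models, window = 20000)
  l_big <- annotate_peaks_to_genes(fx$peaks, fx$models, window = 100000)
  expect_true(all(paste(l_small$peak, l_small$gene) %in%
                  paste(l_big$peak, l_big$gene)))
  k1 <- overlap_states(fx$peaks, fx$states, min_overlap = 1)
  k50 <- overlap_states(fx$peaks, fx$states, min_overlap = 50)
  expect_true(all(k50$name %in% k1$name))
})

test_that("quartile DE recovers planted shifts and respects symmetry", {
  set.seed(73)
  n <- 100
  expr <- matrix(rnorm(50 * n, 10), 50, n,
                 dimnames = list(sprintf("g%02d", 1:50), paste0("t", 1:n)))
  expr["g01", ] <- seq(0, 10, length.out = n)  # index gene
  up_idx <- which(quartile_groups(expr["g01", ]) == "upper_quartile")
  expr["g02", up_idx] <- expr["g02", up_idx] + 2
  de <- quartile_de(expr, "g01", lfc_threshold = 0.5)
  expect_false("g01" %in% de$gene)  # index excluded from its own screen
  expect_true(de$significant[de$gene == "g02"])
  expect_gt(de$logFC[de$gene == "g02"], 1)
  # null genes: roughly uniform p-values
  null_p <- de$p[!(de$gene %in% c("g01", "g02"))]
  expect_lt(mean(null_p < 0.05), 0.2)
  # negating the index flips the quartile groups and the logFC signs
  expr_neg <- expr
  expr_neg["g01", ] <- -expr_neg["g01", ]
  de_neg <- quartile_de(expr_neg, "g01", lfc_threshold = 0.5)
  expect_equal(de_neg$logFC[de_neg$gene == "g02"],
               -de$logFC[de$gene == "g02"])
  expect_equal(de_neg$p[de_neg$gene == "g02"], de$p[de$gene == "g02"])
})

test_that("correlation profile D equals the ECDF sup-difference", {
  set.seed(79)
  n_samp <- 40
  expr <- matrix(rnorm(200 * n_samp), 200, n_samp,
                 dimnames = list(sprintf("g%03d", 1:200), NULL))
  idx <- "g001"
  gene_set <- sprintf("g%03d", 2:80)
  bg <- sprintf("g%03d", 81:200)
  prof <- correlation_profile(expr, idx, gene_set, bg)
  cors <- prof$correlations
  f1 <- ecdf(cors[gene_set]); f2 <- ecdf(cors[bg])
  grid <- sort(c(cors[gene_set], cors[bg]))
  d_bf <- max(abs(f1(grid) - f2(grid)))
  expect_equal(prof$D, d_bf, tolerance = 1e-12)
  # identical sets: no separation at all
  same <- correlation_profile(expr, idx, gene_set, gene_set)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  # a positively shifted set is reported as more positive
  expr2 <- expr
  shift_set <- sprintf("g%03d", 2:40)
  for (g in shift_set) {
    expr2[g, ] <- 0.8 * expr2[idx, ] + 0.6 * expr2[g, ]
  }
  prof2 <- correlation_profile(expr2, idx, shift_set, bg)
  expect_equal(prof2$direction, "more_positive")
  expect_lt(prof2$p, 0.01)
  # constant rows are excluded and counted
  expr3 <- expr
  expr3["g002", ] <- 1
  prof3 <- correlation_profile(expr3, idx, gene_set, bg)
  expect_equal(prof3$n_excluded, 1)
})

test_that("bound_and_regulated is exactly the three-set intersection", {
  links <- data.frame(peak = paste0("p", 1:6),
                      gene = c("A", "B", "B", "C", "D", "E"),
                      distance = c(0, 100, 5000, 200, 40, 10),
                      stringsAsFactors = FALSE)
  kd <- de_table(data.frame(gene = c("A", "B", "C", "F"),
                            logFC = c(-2, 3, -1.6, 2),
                            p = c(1e-6, 1e-6, 1e-6, 1e-6)),
                 lfc_threshold = 1.5)
  co <- de_table(data.frame(gene = c("A", "B", "D", "F"),
                            logFC = c(-1.8, 2.5, 2, 2),
                            p = c(1e-6, 1e-6, 1e-6, 1e-6)),
                 lfc_threshold = 1.5)
  net <- bound_and_regulated(links, kd, co)
  # independent set algebra
  expected <- intersect(intersect(unique(links$gene),
                                  kd$gene[kd$significant]),
                        co$gene[co$significant])
  expect_setequal(net$gene, expected)
  expect_setequal(net$gene, c("A", "B"))
  expect_equal(net$n_peaks[net$gene == "B"], 2L)
  expect_equal(net$min_distance[net$gene == "B"], 100)
  expect_equal(net$cohort_direction, c("B" = "up", "A" = "down")[net$gene],
               ignore_attr = TRUE)
  # ordering by |cohort logFC| and top_k truncation
  expect_equal(net$gene, c("B", "A"))
  top1 <- bound_and_regulated(links, kd, co, top_k = 1)
  expect_equal(top1$gene, "B")
  expect_equal(attr(top1, "n_up") + attr(top1, "n_down"), 2L)
  # an empty knockdown table empties the network without error
  kd_empty <- de_table(data.frame(gene = character(0), logFC = numeric(0),
                                  p = numeric(0)))
  expect_message(net0 <- bound_and_regulated(links, kd_empty, co), "empty")
  expect_equal(nrow(net0), 0)
})

test_that("the cascade recovers planted bound-and-regulated genes exactly", {
  cis <- simulate_cistrome(cistrome_config(n_genes = 40,
                                           n_truth_genes = 20, seed = 83))
  kept <- overlap_states(cis$peaks, cis$states, min_overlap = 1)
  links <- annotate_peaks_to_genes(kept, cis$gene_models, window = 100000)
  genes <- cis$gene_models$gene
  sig <- genes %in% cis$truth$bound_genes
  kd <- de_table(data.frame(gene = genes,
                            logFC = ifelse(sig, -2, 0),
                            p = ifelse(sig, 1e-8, 0.6)))
  co <- de_table(data.frame(gene = genes,
                            logFC = ifelse(sig, 2, 0),
                            p = ifelse(sig, 1e-8, 0.6)))
  net <- bound_and_regulated(links, kd, co)
  expect_setequal(net$gene, cis$truth$bound_genes)
  expect_equal(nrow(net), 20)
})
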