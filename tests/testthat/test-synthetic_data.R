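test_that("the null generator plants nothing: class mean Z near zero", {
  sim <- simulate_cohort(sim_config(n_genes = 1000, n_tumors = 60,
                                    n_normals = 20, seed = 17))
  z <- tumor_normal_zscores(sim$cohort)
  cls <- sim$truth$classes
  for (cl in c("TF", "COA", "COR", "MIXED")) {
    genes <- intersect(names(cls)[!is.na(cls) & cls == cl], rownames(z))
    cells <- z[genes, ]
    se <- sd(cells) / sqrt(length(cells))
    expect_lt(abs(mean(cells)), 3 * se + 0.02)
  }
})

test_that("planted expression shifts are recovered from the emitted matrix", {
  eff <- planted_effect("COA", 0.3, 0.4, -1.0, "expression")
  sim <- simulate_cohort(sim_config(n_genes = 2000, n_tumors = 100,
                                    n_normals = 30,
                                    planted_effects = list(eff),
                                    seed = 23))
  z <- tumor_normal_zscores(sim$cohort)
  tr <- sim$truth$effects[[1]]
  cells <- z[intersect(tr$affected_genes, rownames(z)), tr$affected_tumors]
  se <- sd(cells) / sqrt(length(cells))
  expect_lt(abs(mean(cells) - (-1.0)), 3 * se + 0.05)
  # unaffected cells stay centred at zero
  other <- z[setdiff(rownames(z), tr$affected_genes), ]
  expect_lt(abs(mean(other)), 0.05)
})

test_that("planted CNA and mutation effects appear in the right matrices", {
  effs <- list(planted_effect("COR", 0.5, 0.3, -2, "cna"),
               planted_effect("MIXED", 0.5, 1.0, 2.5, "mutation"))
  sim <- simulate_cohort(sim_config(n_genes = 1000, n_tumors = 60,
                                    n_normals = 10, planted_effects = effs,
                                    mutation_rate_per_bp = 2e-5,
                                    seed = 31))
  tr_cna <- sim$truth$effects[[1]]
  expect_true(all(sim$cohort$cna[tr_cna$affected_genes,
                                 tr_cna$affected_tumors] == -2L))
  # mutated class carries a higher burden than background
  mb <- mutation_burden(sim$cohort$mutations, sim$cohort$gene_models,
                        n_tumors = 60)
  tr_mut <- sim$truth$effects[[2]]
  in_cls <- mb$score[mb$gene %in% tr_mut$affected_genes]
  out_cls <- mb$score[!(mb$gene %in% tr_mut$affected_genes)]
  expect_gt(mean(in_cls), mean(out_cls) * 1.5)
})

test_that("an infeasible planted effect errors instead of silently shrinking", {
  eff <- planted_effect("COA", 0.5, 0.5, -1, "expression")
  cfg <- sim_config(n_genes = 100, n_tumors = 20, n_normals = 5,
                    class_fractions = c(TF = 0.2, COA = 0, COR = 0.1,
                                        MIXED = 0.1),
                    planted_effects = list(eff), seed = 1)
  expect_error(simulate_cohort(cfg), "infeasible")
})

test_that("identical configs give byte-identical output files", {
  cfg <- sim_config(n_genes = 200, n_tumors = 30, n_normals = 10,
                    planted_effects = list(
                      planted_effect("TF", 0.2, 0.5, -1, "expression")),
                    hazard_coefficients = setNames(0.5, "G00003"),
                    seed = 77)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  # and a cohort read back equals the one written
  co <- read_cohort(d1)
  expect_equal(dim(co$expr), dim(simulate_cohort(cfg)$cohort$expr))
})

test_that("null survival times carry no signal between random halves", {
  nonsig <- 0
  for (s in 1:50) {
    sim <- simulate_cohort(sim_config(n_genes = 20, n_tumors = 100,
                                      n_normals = 0, seed = 400 + s))
    cl <- sim$cohort$clinical
    set.seed(s)
    half <- sample(c("a", "b"), nrow(cl), replace = TRUE)
    if (length(unique(half)) < 2) next
    lr <- logrank_test(cl$time, cl$event, half)
    if (lr$p.value > 0.05) nonsig <- nonsig + 1
  }
  expect_gte(nonsig, 45)  # >= 90% of seeds non-significant at alpha 0.05
})

test_that("doubling the tumor count leaves the per-sample mutation rate", {
  r <- vapply(c(100L, 200L), function(nt) {
    sim <- simulate_cohort(sim_config(n_genes = 500, n_tumors = nt,
                                      n_normals = 0,
                                      mutation_rate_per_bp = 5e-5,
                                      seed = 55))
    nrow(sim$cohort$mutations) / nt / 500
  }, numeric(1))
  expect_lt(abs(r[1] - r[2]) / r[1], 0.1)
})

test_that("knockdown DE defaults reproduce the planted skew", {
  kd <- simulate_knockdown_de(seed = 9)
  de <- kd$de
  down <- de$logFC[de$gene %in% kd$truth$down_genes]
  up <- de$logFC[de$gene %in% kd$truth$up_genes]
  expect_equal(length(down), 1993)
  expect_equal(length(up), 1607)
  expect_lt(abs(mean(down) - (-1.11)), 3 * 0.35 / sqrt(1993))
  expect_lt(abs(mean(up) - 0.83), 3 * 0.35 / sqrt(1607))
  # planted genes are overwhelmingly significant under the recorded rule
  # (the |logFC| > 0.5 component trims the weakest planted effects)
  expect_gt(mean(de$significant[de$gene %in% kd$truth$down_genes]), 0.9)
  expect_gt(mean(de$significant[de$gene %in% kd$truth$up_genes]), 0.7)
  expect_true(all(de$fdr >= de$p))
  # determinism
  kd2 <- simulate_knockdown_de(seed = 9)
  expect_identical(kd$de$p, kd2$de$p)
  # zero planted DEGs leave the table flat
  kd0 <- simulate_knockdown_de(n_genes = 2000, n_down = 0, n_up = 0,
                               seed = 4)
  expect_equal(sum(kd0$de$significant), 0)
  expect_error(simulate_knockdown_de(n_down = -1), "non-negative")
})

test_that("cistrome truth peaks sit in windows and decoys stay out", {
  cis <- simulate_cistrome(cistrome_config(n_genes = 30, n_truth_genes = 10,
                                           seed = 12))
  links <- annotate_peaks_to_genes(cis$peaks, cis$gene_models,
                                   window = 100000)
  truth_peaks <- grepl("^peak_truth_", links$peak)
  linked_truth <- unique(links$gene[truth_peaks])
  expect_setequal(linked_truth, cis$truth$bound_genes)
  # far decoys link to no gene at all
  expect_false(any(grepl("^peak_far_", links$peak)))
  # zero truth genes requested -> no truth peak exists
  cis0 <- simulate_cistrome(cistrome_config(n_genes = 10,
                                            n_truth_genes = 0, seed = 3))
  expect_false(any(grepl("^peak_truth_", cis0$peaks$name)))
  # window larger than the chromosome is rejected
  expect_error(simulate_cistrome(cistrome_config(n_genes = 2,
                                                 n_truth_genes = 1,
                                                 window = 1e6,
                                                 chrom_length = 5e5,
                                                 seed = 1)),
               "chromosome")
  # determinism of the whole cistrome module
  cis2 <- simulate_cistrome(cistrome_config(n_genes = 30,
                                            n_truth_genes = 10, seed = 12))
  expect_identical(cis$peaks, cis2$peaks)
  expect_identical(cis$states, cis2$states)
})
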