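test_that("config validation enforces counts, fractions and hostable spans", {
  expect_error(sim_config(n_loci = 0), "n_loci")
  expect_error(sim_config(missing_rate = 1.5), "missing_rate")
  expect_error(sim_config(causal_signal_strength = -1), "causal_signal_strength")
  expect_error(sim_config(locus_span = c(2e4, 5e4), genes_per_locus = c(1, 40)),
               class = "l2g_span_too_small")
  expect_error(sim_config(locus_span = c(5e5, 2e6)), "1 Mb")
})

test_that("forced single-gene loci plant the only gene", {
  cfg <- sim_config(n_loci = 2, n_leads = 2, genes_per_locus = c(1, 1),
                    locus_span = c(5e4, 1e5), n_positive_labels = 1,
                    seed = 3L)
  sim <- simulate_loci(cfg)
  expect_equal(nrow(sim$truth$planted), 2)
  genes_by_locus <- split(sim$truth$genes$gene_id, sim$truth$genes$sim_locus)
  for (i in seq_len(2)) {
    sl <- sim$truth$planted$sim_locus[i]
    expect_equal(sim$truth$planted$gene_id[i], genes_by_locus[[sl]])
  }
})

test_that("the generator is byte-identical under a fixed seed", {
  cfg <- tiny_sim_config(seed = 12)
  a <- simulate_loci(cfg)
  b <- simulate_loci(cfg)
  expect_identical(a, b)
  fa <- simulate_features(a$truth, cfg)
  fb <- simulate_features(b$truth, cfg)
  expect_identical(fa, fb)
  ca <- simulate_cohort(a$truth, cfg)
  cb <- simulate_cohort(b$truth, cfg)
  expect_identical(ca$phenotypes$status, cb$phenotypes$status)
  expect_identical(ca$genotypes, cb$genotypes)
  expect_identical(simulate_gene_sets(a$truth), simulate_gene_sets(b$truth))
})

test_that("emitted leads merge back to the recorded locus count", {
  cfg <- sim_config(n_loci = 80, n_leads = 92, seed = 7L)
  sim <- simulate_loci(cfg)
  leads <- dplyr::filter(sim$variants, source == "lead")
  expect_equal(nrow(leads), 92)
  loci <- merge_variants(leads)
  expect_equal(nrow(loci), sim$truth$expected_n_loci)
})

test_that("every simulated gene lies within 1 Mb of its locus lead", {
  sim <- simulate_loci(tiny_sim_config(seed = 19))
  leads <- dplyr::filter(sim$variants, source == "lead")
  loci <- merge_variants(leads)
  assigned <- assign_genes(loci, sim$genes, biotype = NULL)
  expect_setequal(unlist(assigned$genes), sim$genes$gene_id)
})

test_that("zero signal strength leaves informative and noise features
           indistinguishable; strong signal separates causal genes", {
  cfg0 <- sim_config(n_loci = 60, n_leads = 60, genes_per_locus = c(3, 8),
                     n_features_per_modality = c(distance = 4, consequence = 10,
                                                 qtl = 20, expression = 20),
                     causal_signal_strength = 0, missing_rate = 0,
                     n_positive_labels = 5, seed = 23L)
  sim0 <- simulate_loci(cfg0)
  f0 <- simulate_features(sim0$truth, cfg0)
  expect_false(anyNA(f0$tables$qtl))
  inf_col <- sim0$truth$effects$feature[sim0$truth$effects$modality == "qtl"][1]
  noise_col <- setdiff(names(f0$tables$qtl), c("gene_id",
                                               sim0$truth$effects$feature))[1]
  ks <- suppressWarnings(stats::ks.test(f0$tables$qtl[[inf_col]],
                                        f0$tables$qtl[[noise_col]]))
  expect_gt(ks$p.value, 0.01)

  cfg3 <- sim_config(n_loci = 60, n_leads = 60, genes_per_locus = c(3, 8),
                     n_features_per_modality = c(distance = 4, consequence = 10,
                                                 qtl = 20, expression = 20),
                     causal_signal_strength = 3, missing_rate = 0,
                     n_positive_labels = 5, seed = 23L)
  sim3 <- simulate_loci(cfg3)
  f3 <- simulate_features(sim3$truth, cfg3)
  causal <- f3$tables$qtl$gene_id %in% sim3$truth$planted$gene_id
  inf3 <- sim3$truth$effects$feature[sim3$truth$effects$modality == "qtl"][1]
  tt <- stats::t.test(f3$tables$qtl[[inf3]][causal],
                      f3$tables$qtl[[inf3]][!causal], alternative = "greater")
  expect_lt(tt$p.value, 1e-6)
})

test_that("causal-vs-decoy separation grows monotonically with signal strength", {
  gaps <- vapply(c(0.5, 1.5, 3), function(s) {
    cfg <- sim_config(n_loci = 40, n_leads = 40, genes_per_locus = c(3, 8),
                      n_features_per_modality = c(distance = 4, consequence = 8,
                                                  qtl = 16, expression = 16),
                      causal_signal_strength = s, missing_rate = 0,
                      n_positive_labels = 5, seed = 29L)
    sim <- simulate_loci(cfg)
    f <- simulate_features(sim$truth, cfg)
    causal <- f$tables$expression$gene_id %in% sim$truth$planted$gene_id
    inf <- sim$truth$effects$feature[sim$truth$effects$modality == "expression"]
    vals <- as.matrix(f$tables$expression[, inf])
    mean(vals[causal, ]) - mean(vals[!causal, ])
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("missingness and labels follow the configuration", {
  cfg <- tiny_sim_config(seed = 31)
  sim <- simulate_loci(cfg)
  f <- simulate_features(sim$truth, cfg)
  vals <- as.matrix(f$tables$expression[, -1])
  expect_lt(abs(mean(is.na(vals)) - cfg$missing_rate), 0.08)
  lab <- f$labels
  expect_equal(sum(lab$label == 1, na.rm = TRUE), cfg$n_positive_labels)
  # labels only within the training loci; negatives share loci with positives
  pos_loci <- lab$sim_locus[!is.na(lab$label) & lab$label == 1]
  neg_loci <- unique(lab$sim_locus[!is.na(lab$label) & lab$label == 0])
  expect_setequal(neg_loci, pos_loci)
  # every planted positive is the truth's causal gene of its locus
  for (sl in pos_loci) {
    expect_equal(lab$gene_id[which(lab$sim_locus == sl & lab$label == 1)],
                 sim$truth$planted$gene_id[sim$truth$planted$sim_locus == sl])
  }
})

test_that("cohort simulation respects MAF edge cases and guards", {
  cfg <- tiny_sim_config(seed = 41, maf_range = c(0, 0))
  sim <- simulate_loci(cfg)
  coh <- simulate_cohort(sim$truth, cfg)
  expect_true(all(coh$genotypes == 0))
  expect_error(simulate_cohort(sim$truth,
                               tiny_sim_config(seed = 41, n_individuals = 10)),
               "n_individuals")
  expect_error(simulate_features(list(), tiny_sim_config()), "truth")
  expect_error(simulate_cohort(list(), tiny_sim_config()), "truth")
})

test_that("a zero pathway effect leaves the confidence interval covering OR 1", {
  cfg <- sim_config(n_loci = 6, n_leads = 6, genes_per_locus = c(2, 4),
                    n_features_per_modality = c(distance = 4, consequence = 4,
                                                qtl = 6, expression = 6),
                    n_positive_labels = 2, n_individuals = 600,
                    n_discovery = 1500, snps_per_gene = 5,
                    pathway_effect_beta = 0, seed = 43L)
  sim <- simulate_loci(cfg)
  covered <- vapply(1:30, function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    coh <- simulate_cohort(sim$truth, cfg_i)
    prs <- score_pathway(coh$genotypes, coh$snps, sim$truth$pathway_members,
                         sim$genes)
    res <- associate(prs, coh$phenotypes)
    res$ci_lower <= 1 && 1 <= res$ci_upper
  }, logical(1))
  expect_gte(mean(covered), 0.8)
})
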