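simple_geno <- function(mat, ids = NULL) {
  if (is.null(ids)) ids <- colnames(mat)
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(ncol(mat)))
  colnames(mat) <- ids
  rownames(mat) <- sprintf("id%03d", seq_len(nrow(mat)))
  mat
}

test_that("SNP filters apply MAF and GWAS-p as conjunct inclusion rules", {
  G <- simple_geno(cbind(
    rare = stats::rbinom(1000, 2, 0.005),
    common_weak = stats::rbinom(1000, 2, 0.3),
    common_strong = stats::rbinom(1000, 2, 0.3)))
  gwas <- tibble::tibble(snp_id = colnames(G), p = c(0.001, 0.2, 0.01))
  expect_equal(filter_snps(gwas, G), "common_strong")
  # the alternative reading only drops SNPs that are both rare and nominal
  expect_setequal(filter_snps(gwas, G, rule = "conjunct_exclusion"),
                  c("common_weak", "common_strong"))
  expect_error(filter_snps(gwas[3, ], G[, 3, drop = FALSE] * 0 + 0,
                           maf_min = 0.5), "survive")
  # random tables match the row-wise predicate
  set.seed(12)
  G2 <- simple_geno(sapply(stats::runif(30, 0, 0.5),
                           function(f) stats::rbinom(500, 2, f)))
  gw2 <- tibble::tibble(snp_id = colnames(G2), p = stats::runif(30))
  got <- filter_snps(gw2, G2)
  af <- colMeans(G2) / 2
  maf <- pmin(af, 1 - af)
  expect_setequal(got, colnames(G2)[maf >= 0.01 & gw2$p <= 0.05])
})

test_that("clumping keeps independent SNPs and prunes correlated ones", {
  set.seed(21)
  # independent SNPs: everyone is an index
  G <- simple_geno(sapply(rep(0.3, 5), function(f) stats::rbinom(400, 2, f)))
  snps <- tibble::tibble(snp_id = colnames(G), chrom = "1",
                         pos = seq(1e5, 5e5, length.out = 5),
                         p = stats::runif(5))
  expect_setequal(clump(snps, G), snps$snp_id)
  # two perfectly correlated SNPs 10 kb apart: smaller p survives
  g <- stats::rbinom(400, 2, 0.4)
  G2 <- simple_geno(cbind(g, g), c("a", "b"))
  snps2 <- tibble::tibble(snp_id = c("a", "b"), chrom = "1",
                          pos = c(1e5, 1.1e5), p = c(0.04, 0.001))
  expect_equal(clump(snps2, G2), "b")
  # outside the window they both survive even if correlated
  snps3 <- snps2
  snps3$pos <- c(1e5, 1e6)
  expect_setequal(clump(snps3, G2), c("a", "b"))
})

test_that("clumping on an LD block matches the greedy oracle and ignores row order", {
  cfg <- tiny_sim_config(seed = 31, ld_rho = 0.85)
  sim <- simulate_loci(cfg)
  coh <- simulate_cohort(sim$truth, cfg)
  snps <- coh$snps[!is.na(coh$snps$p), ]
  got <- clump(snps, coh$genotypes)
  expect_setequal(got, oracle_clump(snps, coh$genotypes))
  shuffled <- snps[sample.int(nrow(snps)), ]
  expect_equal(sort(clump(shuffled, coh$genotypes)), sort(got))
  # with strong within-gene LD, clumping must actually remove SNPs
  expect_lt(length(got), nrow(snps))
})

test_that("pathway scoring is the dosage-beta product over overlapping SNPs", {
  ann <- tibble::tibble(gene_id = "gene1", chrom = "1",
                        start = 100, end = 1000)
  snps <- tibble::tibble(snp_id = "s1", chrom = "1", pos = 500, beta = 0.2)
  G <- simple_geno(matrix(c(0, 1, 2), 3, 1), "s1")
  prs <- score_pathway(G, snps, "gene1", ann, standardize = FALSE)
  expect_equal(prs$prs_raw, c(0, 0.2, 0.4))
  expect_equal(attr(prs, "n_snps_used"), 1)
  # all-zero dosages give an all-zero raw score
  G0 <- simple_geno(matrix(0, 5, 1), "s1")
  expect_equal(score_pathway(G0, snps, "gene1", ann)$prs_raw, rep(0, 5))
  # no overlap is an explicit classed error
  expect_error(score_pathway(G, snps, "gene1",
                             dplyr::mutate(ann, start = 2000, end = 3000)),
               class = "l2g_empty_pathway")
  # random case equals the matrix product
  set.seed(44)
  ann2 <- tibble::tibble(gene_id = c("g1", "g2", "g3"), chrom = "1",
                         start = c(100, 5000, 9000), end = c(900, 5900, 9900))
  snps2 <- tibble::tibble(snp_id = sprintf("s%d", 1:6), chrom = "1",
                          pos = c(150, 800, 5100, 7000, 9100, 9800),
                          beta = stats::rnorm(6))
  G2 <- simple_geno(matrix(stats::rbinom(60, 2, 0.3), 10, 6),
                    snps2$snp_id)
  prs2 <- score_pathway(G2, snps2, c("g1", "g3"), ann2, standardize = FALSE)
  inside <- c("s1", "s2", "s5", "s6")
  expect_equal(prs2$prs_raw,
               as.numeric(G2[, inside] %*% snps2$beta[match(inside, snps2$snp_id)]))
  # standardization yields mean 0 sd 1 without changing the z-score sign
  prs2s <- score_pathway(G2, snps2, c("g1", "g3"), ann2)
  expect_equal(mean(prs2s$prs), 0, tolerance = 1e-12)
  expect_equal(stats::sd(prs2s$prs), 1, tolerance = 1e-12)
})

test_that("logistic association recovers a planted effect and flags edge cases", {
  set.seed(55)
  n <- 4000
  prs_val <- stats::rnorm(n)
  status <- stats::rbinom(n, 1, stats::plogis(0.3 * prs_val))
  prs <- tibble::tibble(iid = sprintf("i%d", 1:n), prs_raw = prs_val,
                        prs = prs_val)
  pheno <- tibble::tibble(iid = prs$iid, status = status,
                          age = stats::rnorm(n, 60, 8),
                          sex = stats::rbinom(n, 1, 0.5))
  res <- associate(prs, pheno, covariates = c("age", "sex"))
  expect_lt(abs(res$beta - 0.3), 0.08)
  expect_equal(res$or, exp(res$beta))
  expect_equal(res$ci_lower, exp(res$beta - 1.96 * res$se))
  expect_true(res$p_asymptotic < 1e-6)
  expect_true(res$liability_r2 > 0 && res$liability_r2 < 1)
  expect_error(associate(prs, dplyr::mutate(pheno, status = 1)), "case")
  # permuted phenotype gives a null-centred beta
  betas <- replicate(20, {
    ph <- pheno
    ph$status <- sample(ph$status)
    associate(prs, ph, covariates = c("age", "sex"))$beta
  })
  expect_lt(abs(mean(betas)), 0.05)
})

test_that("permutation p follows the +1 smoothing formula", {
  set.seed(66)
  n <- 600
  prs_val <- stats::rnorm(n)
  status <- stats::rbinom(n, 1, stats::plogis(1.5 * prs_val))  # strong effect
  prs <- tibble::tibble(iid = sprintf("i%d", 1:n), prs_raw = prs_val,
                        prs = prs_val)
  pheno <- tibble::tibble(iid = prs$iid, status = status)
  res <- suppressWarnings(permutation_p(prs, pheno, covariates = character(0),
                                        n_permutations = 99, seed = 2))
  # no permuted |z| can beat the real signal here -> p = 1/100 exactly
  expect_equal(res$p_empirical, 0.01)
  expect_warning(permutation_p(prs, pheno, covariates = character(0),
                               n_permutations = 50, seed = 2), "permutations")
  # permutation p is seed-reproducible
  res2 <- suppressWarnings(permutation_p(prs, pheno, covariates = character(0),
                                         n_permutations = 99, seed = 2))
  expect_equal(res, res2)
})

test_that("fixed-effect meta-analysis matches closed forms and metafor", {
  # two identical cohorts: pooled beta unchanged, SE shrinks by sqrt(2), Q = 0
  m <- meta_analyze(tibble::tibble(cohort = c("a", "b"),
                                   beta = c(0.2, 0.2), se = c(0.1, 0.1)))
  expect_equal(m$pooled$beta, 0.2)
  expect_equal(m$pooled$se, 0.1 / sqrt(2))
  expect_equal(m$pooled$Q, 0)
  # hand-computed heterogeneous case
  m2 <- meta_analyze(tibble::tibble(cohort = c("a", "b"),
                                    beta = c(0.1, 0.3), se = c(0.1, 0.1)))
  expect_equal(m2$pooled$beta, 0.2)
  expect_equal(m2$pooled$Q, 2)
  expect_equal(m2$pooled$het_p, stats::pchisq(2, 1, lower.tail = FALSE))
  # single cohort passes through with Q reported absent
  m1 <- meta_analyze(tibble::tibble(cohort = "a", beta = 0.15, se = 0.05))
  expect_equal(m1$pooled$beta, 0.15)
  expect_true(is.na(m1$pooled$Q))
  expect_error(meta_analyze(tibble::tibble(beta = 1, se = 0)), "finite")
  # random inputs against the closed-form oracle and metafor's FE model
  set.seed(77)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    beta <- stats::rnorm(k, 0.1, 0.2)
    se <- stats::runif(k, 0.02, 0.3)
    got <- meta_analyze(tibble::tibble(cohort = letters[1:k],
                                       beta = beta, se = se))
    o <- oracle_ivw(beta, se)
    expect_equal(got$pooled$beta, o$beta)
    expect_equal(got$pooled$se, o$se)
    expect_equal(got$pooled$Q, o$Q)
    expect_lte(got$pooled$se, min(se))
    if (requireNamespace("metafor", quietly = TRUE)) {
      mf <- metafor::rma(yi = beta, sei = se, method = "FE")
      expect_equal(got$pooled$beta, as.numeric(mf$beta), tolerance = 1e-10)
      expect_equal(got$pooled$se, mf$se, tolerance = 1e-10)
      expect_equal(got$pooled$Q, mf$QE, tolerance = 1e-10)
    }
  }
})

test_that("leave-one-out report flags the cohort driving heterogeneity", {
  res <- tibble::tibble(cohort = c("a", "b", "c", "outlier"),
                        beta = c(0.10, 0.12, 0.11, 0.90),
                        se = c(0.05, 0.05, 0.05, 0.05))
  m <- meta_analyze(res)
  expect_true(m$pooled$het_p < 0.05)
  expect_equal(m$leave_one_out$excluded[m$leave_one_out$outlier_flag],
               "outlier")
})
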