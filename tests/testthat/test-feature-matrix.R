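make_loci_pairs <- function(lead_pos, genes) {
  loci <- merge_variants(tibble::tibble(chrom = "1", pos = lead_pos,
                                        id = sprintf("v%d", seq_along(lead_pos))))
  loci <- assign_genes(loci, genes)
  list(loci = loci, pairs = locus_gene_pairs(loci, genes))
}

test_that("distance features follow the interval and strand-aware TSS rules", {
  genes <- tibble::tibble(
    gene_id = c("a", "b"), chrom = "1",
    start = c(50, 200), end = c(150, 300),
    strand = c("+", "-"), biotype = "protein_coding")
  lp <- make_loci_pairs(100, genes)
  d <- compute_distance_features(lp$loci, lp$pairs) |> dplyr::arrange(gene_id)
  # lead inside gene a: body distance 0, TSS = start (+) -> 50
  expect_equal(d$dist_lead_gene[1], 0)
  expect_equal(d$dist_lead_tss[1], 50)
  # gene b on '-': body distance 100, TSS = end -> |300 - 100| = 200
  expect_equal(d$dist_lead_gene[2], 100)
  expect_equal(d$dist_lead_tss[2], 200)
  # without credible SNPs the credible minima equal the lead minima
  expect_equal(d$dist_credible_gene, d$dist_lead_gene)
})

test_that("distance features equal brute force over SNP x {start,end,interval}", {
  set.seed(11)
  for (rep in 1:10) {
    n_genes <- 10
    genes <- tibble::tibble(
      gene_id = sprintf("g%d", 1:n_genes), chrom = "1",
      start = sample.int(2e6, n_genes),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      biotype = "protein_coding")
    genes$end <- genes$start + sample.int(2e5, n_genes)
    lead_pos <- sort(sample(seq(5e5, 2e6, by = 1000), 3))
    lp <- make_loci_pairs(lead_pos, genes)
    loci <- suppressWarnings(attach_credible_snps(lp$loci, tibble::tibble(
      chrom = "1", pos = sample.int(2.5e6, 5), id = sprintf("c%d", 1:5))))
    pairs <- locus_gene_pairs(loci, genes)
    d <- compute_distance_features(loci, pairs)
    for (i in seq_len(nrow(d))) {
      li <- match(d$locus_id[i], loci$locus_id)
      leads <- loci$lead_pos[[li]]
      cred <- unique(c(leads, loci$credible_pos[[li]]))
      tss <- if (d$strand[i] == "-") d$end[i] else d$start[i]
      body <- function(v) if (v >= d$start[i] && v <= d$end[i]) 0 else
        min(abs(d$start[i] - v), abs(d$end[i] - v))
      expect_equal(d$dist_lead_gene[i], min(vapply(leads, body, 1)))
      expect_equal(d$dist_lead_tss[i], min(abs(leads - tss)))
      expect_equal(d$dist_credible_gene[i], min(vapply(cred, body, 1)))
      expect_equal(d$dist_credible_tss[i], min(abs(cred - tss)))
    }
  }
})

nb_block <- function(values, direction = "higher_better", locus = "L1") {
  specs <- feature_spec("f", if (direction == "higher_better") "expression"
                        else "distance", direction)
  m <- tibble::tibble(pair_id = sprintf("%s:g%d", locus, seq_along(values)),
                      locus_id = locus,
                      gene_id = sprintf("g%d", seq_along(values)),
                      f = values)
  attr(m, "state") <- "raw"
  neighbourhood_transform(m, specs)$f
}

test_that("neighbourhood transform matches the divide-by-best and neg-log rules", {
  expect_equal(nb_block(c(10, 5, 0)), c(1, 0.5, 0))
  expect_equal(nb_block(c(0, 999), "distance_like"), c(1, 0))
  # hand evaluation: t = {2, 1, 0} -> {1, 0.5, 0}
  expect_equal(nb_block(c(0, 9, 99), "distance_like"), c(1, 0.5, 0))
  # single gene locus scores 1 for any non-missing positive value
  expect_equal(nb_block(7), 1)
  expect_equal(nb_block(123, "distance_like"), 1)
  # all-zero higher_better feature stays 0
  expect_equal(nb_block(c(0, 0)), c(0, 0))
  # missing values propagate and are excluded from maxima
  expect_equal(nb_block(c(NA, 4, 2)), c(NA, 1, 0.5))
  expect_error(nb_block(c(-1, 5), "distance_like"), "negative")
})

test_that("neighbourhood invariants hold over random blocks with missingness", {
  set.seed(22)
  for (rep in 1:200) {
    n <- sample(1:8, 1)
    v <- round(stats::runif(n, 0, 1000))
    v[stats::runif(n) < 0.25] <- NA
    for (dir in c("higher_better", "distance_like")) {
      s <- nb_block(v, dir)
      expect_true(all(is.na(s) == is.na(v)))
      ok <- !is.na(s)
      if (!any(ok)) next
      expect_true(all(s[ok] >= 0 & s[ok] <= 1))
      if (dir == "higher_better" && any(v[ok] > 0)) {
        expect_equal(max(s[ok]), 1)
        # scale invariance
        expect_equal(nb_block(v * 3.7, dir), s)
      }
      if (dir == "distance_like") {
        expect_equal(max(s[ok]), 1)
        # strictly decreasing with distance, ties equal
        o <- order(v[ok])
        expect_true(all(diff(s[ok][o]) <= 0))
        expect_true(all((diff(v[ok][o]) == 0) == (diff(s[ok][o]) == 0)))
      }
    }
  }
})

test_that("matrix assembly joins tables by key, errors on conflicts", {
  genes <- tibble::tibble(gene_id = c("a", "b"), chrom = "1",
                          start = c(100, 5e5), end = c(200, 6e5),
                          strand = "+", biotype = "protein_coding")
  # gene 'a' is within 1 Mb of both leads -> appears in both loci
  lp <- make_loci_pairs(c(150, 1.0e6), genes)
  pairs <- lp$pairs
  expect_equal(sum(pairs$gene_id == "a"), 2)
  specs <- dplyr::bind_rows(feature_spec("x", "qtl", "higher_better"),
                            feature_spec("y", "expression", "higher_better"))
  tabs <- list(qtl = tibble::tibble(gene_id = "a", x = 3),
               expr = tibble::tibble(gene_id = character(0), y = numeric(0)))
  m <- assemble_matrix(pairs, tabs, specs)
  expect_equal(names(m), c("pair_id", "locus_id", "gene_id", "x", "y"))
  # empty modality -> all missing; gene-keyed values repeat across loci
  expect_true(all(is.na(m$y)))
  expect_equal(m$x[m$gene_id == "a"], c(3, 3))
  expect_true(all(is.na(m$x[m$gene_id == "b"])))
  # conflicting duplicates are an error naming the offender
  expect_error(
    assemble_matrix(pairs, list(qtl = tibble::tibble(
      gene_id = c("a", "a"), x = c(1, 2))), specs),
    class = "l2g_dup_feature")
  # identical duplicates collapse silently
  m2 <- assemble_matrix(pairs, list(qtl = tibble::tibble(
    gene_id = c("a", "a"), x = c(3, 3))), specs)
  expect_equal(m2$x, m$x)
})

test_that("random joins equal a brute-force nested-loop join", {
  set.seed(33)
  genes <- tibble::tibble(gene_id = sprintf("g%d", 1:12), chrom = "1",
                          start = seq(1e5, 1.2e6, length.out = 12),
                          end = seq(1e5, 1.2e6, length.out = 12) + 1e4,
                          strand = "+", biotype = "protein_coding")
  lp <- make_loci_pairs(c(2e5, 9e5), genes)
  specs <- dplyr::bind_rows(feature_spec("q1", "qtl", "higher_better"),
                            feature_spec("e1", "expression", "higher_better"),
                            feature_spec("p1", "consequence", "higher_better"))
  tabs <- list(
    a = tibble::tibble(gene_id = sample(genes$gene_id, 8), q1 = stats::runif(8)),
    b = tibble::tibble(gene_id = sample(genes$gene_id, 5), e1 = stats::runif(5)),
    c = tibble::tibble(pair_id = sample(lp$pairs$pair_id, 6), p1 = stats::runif(6)))
  m <- assemble_matrix(lp$pairs, tabs, specs)
  expected <- oracle_join(lp$pairs, tabs, specs$name)
  expect_equal(as.matrix(m[, specs$name]), expected, ignore_attr = TRUE)
  # idempotent join: assembling again from the same inputs is identical
  expect_equal(assemble_matrix(lp$pairs, tabs, specs), m)
})
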