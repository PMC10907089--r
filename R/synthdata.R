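#' Configuration for the synthetic GWAS benchmark generator
#'
#' The generator emulates the structure of a large Parkinson's-disease-style
#' locus-to-gene study: ~78 loci formed from 90 independent lead variants,
#' 1-40 candidate genes per locus, 284 raw features across four modalities
#' with missingness, a handful of positively labelled training loci, and
#' case-control cohorts in which a chosen pathway carries a planted
#' liability effect. All downstream stages can then be tested against the
#' planted truth.
#'
#' @param n_loci Number of loci to plant (default 78).
#' @param n_leads Number of lead variants; extras beyond `n_loci` are placed
#'   within the merge window of an existing lead so that 250 kb
#'   single-linkage merging recovers exactly `n_loci` loci (default 90).
#' @param genes_per_locus Integer range, genes drawn uniformly (default
#'   `c(1, 40)`).
#' @param locus_span Range (bp) for the half-width of the gene-hosting
#'   window around the first lead; must not exceed the 1 Mb assignment
#'   window so every planted gene is a candidate by construction.
#' @param n_features_per_modality Named counts for
#'   `distance`/`consequence`/`qtl`/`expression`; the defaults sum to 284
#'   raw features (4 distance features are derived from coordinates).
#' @param causal_signal_strength Effect-size multiplier separating planted
#'   causal genes from decoys on the informative features; 0 means no
#'   signal (default 3).
#' @param missing_rate Fraction of feature cells set missing (default 0.25).
#' @param n_positive_labels Number of training loci whose planted gene is
#'   labelled positive (default 7).
#' @param n_individuals Target-cohort size for the PRS stage (default 2000).
#' @param n_discovery Independent discovery-sample size used to compute
#'   per-SNP GWAS summary statistics (default 20000).
#' @param snps_per_gene SNPs simulated per gene (default 10).
#' @param maf_range Minor-allele-frequency range, uniform (default
#'   `c(0.005, 0.5)` so the MAF >= 0.01 filter is exercised).
#' @param ld_rho AR(1) haplotype correlation between adjacent SNPs within a
#'   gene; 0 simulates linkage equilibrium (default 0).
#' @param pathway_effect_beta Planted log-odds per standard deviation of
#'   true pathway burden (default 0.18).
#' @param prevalence_like_case_fraction Target case fraction (default 0.5,
#'   a balanced case-control design).
#' @param seed Integer seed; fully determines all generator outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_loci = 78,
                       n_leads = 90,
                       genes_per_locus = c(1, 40),
                       locus_span = c(1e5, 1e6),
                       n_features_per_modality = c(distance = 4,
                                                   consequence = 20,
                                                   qtl = 130,
                                                   expression = 130),
                       causal_signal_strength = 3,
                       missing_rate = 0.25,
                       n_positive_labels = 7,
                       n_individuals = 2000,
                       n_discovery = 20000,
                       snps_per_gene = 10,
                       maf_range = c(0.005, 0.5),
                       ld_rho = 0,
                       pathway_effect_beta = 0.18,
                       prevalence_like_case_fraction = 0.5,
                       seed = 42L) {
  n_loci <- check_count(n_loci, "n_loci")
  n_leads <- check_count(n_leads, "n_leads", min = n_loci)
  stopifnot(length(genes_per_locus) == 2, genes_per_locus[1] >= 1,
            genes_per_locus[1] <= genes_per_locus[2])
  stopifnot(length(locus_span) == 2, locus_span[1] > 0,
            locus_span[1] <= locus_span[2])
  if (locus_span[2] > 1e6) {
    abort("locus_span must not exceed 1 Mb: genes would fall outside the assignment window")
  }
  min_gene_len <- 5e3
  if (2 * locus_span[1] < genes_per_locus[2] * min_gene_len) {
    abort(sprintf(
      "locus_span too small to host up to %d genes of >= %d bp",
      genes_per_locus[2], min_gene_len), class = "l2g_span_too_small")
  }
  stopifnot(all(c("distance", "consequence", "qtl", "expression") %in%
                  names(n_features_per_modality)))
  if (!is.numeric(causal_signal_strength) || causal_signal_strength < 0) {
    abort("causal_signal_strength must be >= 0")
  }
  cfg <- list(
    n_loci = n_loci, n_leads = n_leads,
    genes_per_locus = as.integer(genes_per_locus),
    locus_span = as.numeric(locus_span),
    n_features_per_modality = n_features_per_modality,
    causal_signal_strength = as.numeric(causal_signal_strength),
    missing_rate = check_fraction(missing_rate, "missing_rate"),
    n_positive_labels = check_count(n_positive_labels, "n_positive_labels"),
    n_individuals = check_count(n_individuals, "n_individuals"),
    n_discovery = check_count(n_discovery, "n_discovery"),
    snps_per_gene = check_count(snps_per_gene, "snps_per_gene"),
    maf_range = as.numeric(maf_range),
    ld_rho = as.numeric(ld_rho),
    pathway_effect_beta = as.numeric(pathway_effect_beta),
    prevalence_like_case_fraction =
      check_fraction(prevalence_like_case_fraction, "prevalence_like_case_fraction"),
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' Simulate lead variants, credible SNPs, gene annotation and planted truth
#'
#' Loci are spread over autosomes with >= 5 Mb spacing so locus identity is
#' unambiguous; extra leads (beyond `n_loci`) are chained within 250 kb of
#' an existing lead of a randomly chosen locus, so single-linkage merging at
#' 250 kb recovers exactly `n_loci` loci. Genes are placed inside a per-locus
#' window of half-width drawn from `locus_span`, guaranteeing every gene lies
#' within 1 Mb of its locus's first lead. The planted causal gene of each
#' locus is drawn uniformly among its protein-coding genes (so it is NOT
#' always the closest gene), and pathway membership for the PRS stage is a
#' recorded subset of planted and decoy genes.
#'
#' @param config A [sim_config()].
#' @return A list with `variants` (leads and credible SNPs; columns `chrom`,
#'   `pos`, `id`, `ref`, `alt`, `beta`, `se`, `p`, `source`), `genes`
#'   (annotation with `gene_id`, `symbol`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`) and `truth` (a `sim_truth` list recording the
#'   planted causal gene per locus, pathway members, informative-feature
#'   effect sizes, and the expected merged locus count).
#' @export
simulate_loci <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n_loci <- config$n_loci
    chroms <- as.character(rep_len(1:22, n_loci))
    within_idx <- stats::ave(seq_len(n_loci), chroms, FUN = seq_along)
    lead1_pos <- 1e7 + (within_idx - 1) * 5e6 + round(stats::runif(n_loci, 0, 1e6))

    lead_tbl <- tibble(
      sim_locus = sprintf("SL%03d", seq_len(n_loci)),
      chrom = chroms, pos = lead1_pos
    )
    # chain extra leads within the merge window of the last lead of their locus
    n_extra <- config$n_leads - n_loci
    if (n_extra > 0) {
      extra_host <- sample(seq_len(n_loci), n_extra, replace = TRUE)
      last_pos <- lead1_pos
      extra_rows <- vector("list", n_extra)
      for (i in seq_len(n_extra)) {
        h <- extra_host[i]
        newpos <- last_pos[h] + round(stats::runif(1, 5e4, 2.4e5))
        last_pos[h] <- newpos
        extra_rows[[i]] <- tibble(sim_locus = lead_tbl$sim_locus[h],
                                  chrom = chroms[h], pos = newpos)
      }
      lead_tbl <- bind_rows(lead_tbl, bind_rows(extra_rows))
    }
    lead_tbl <- lead_tbl |>
      arrange(chrom_rank(.data$chrom), .data$pos) |>
      mutate(
        id = sprintf("rs%06d", sample.int(999999, dplyr::n())),
        ref = sample(c("A", "C", "G", "T"), dplyr::n(), replace = TRUE),
        alt = sample(c("A", "C", "G", "T"), dplyr::n(), replace = TRUE),
        beta = stats::rnorm(dplyr::n(), 0, 0.12) +
          sample(c(-0.05, 0.05), dplyr::n(), replace = TRUE),
        se = abs(.data$beta) / stats::runif(dplyr::n(), 5.6, 12),
        p = 2 * stats::pnorm(-abs(.data$beta) / .data$se),
        source = "lead"
      )

    # genes
    first_lead <- lead_tbl |>
      group_by(.data$sim_locus) |>
      summarise(chrom = .data$chrom[1], lead1 = min(.data$pos), .groups = "drop")
    gene_rows <- purrr::pmap(
      list(first_lead$sim_locus, first_lead$chrom, first_lead$lead1),
      function(sl, chr, lead1) {
        ng <- resample1(seq(config$genes_per_locus[1], config$genes_per_locus[2]))
        span <- stats::runif(1, config$locus_span[1], config$locus_span[2])
        len <- pmin(pmax(round(stats::rlnorm(ng, log(3e4), 0.7)), 5e3),
                    pmin(2e5, span))
        # the causal gene is chosen uniformly among the protein-coding genes
        # (gene 1 is forced protein-coding so every locus has a candidate),
        # then placed with a tighter offset so that causal genes sit closer
        # to the lead ON AVERAGE -- but decoys regularly end up closer, as
        # in real loci where the nearest gene is causal in only ~2/3 of loci
        biotype <- c("protein_coding",
                     sample(c("protein_coding", "lncRNA"), ng - 1,
                            replace = TRUE, prob = c(0.85, 0.15)))[seq_len(ng)]
        causal_pick <- resample1(which(biotype == "protein_coding"))
        offset_span <- rep(span, ng)
        offset_span[causal_pick] <- max(span * stats::runif(1, 0.01, 0.12),
                                        len[causal_pick])
        start <- lead1 + round(stats::runif(ng, -offset_span,
                                            offset_span - len))
        tibble(sim_locus = sl, chrom = chr, start = start,
               end = start + len,
               strand = sample(c("+", "-"), ng, replace = TRUE),
               biotype = biotype,
               is_causal = seq_len(ng) == causal_pick)
      }
    )
    genes <- bind_rows(gene_rows) |>
      arrange(chrom_rank(.data$chrom), .data$start) |>
      mutate(gene_id = sprintf("G%04d", row_number()),
             symbol = .data$gene_id) |>
      select("gene_id", "symbol", "chrom", "start", "end", "strand",
             "biotype", "sim_locus", "is_causal")

    planted <- genes |>
      filter(.data$is_causal) |>
      select("sim_locus", "gene_id")
    genes <- genes |> select(-"is_causal")
    lead_ids_by_locus <- lead_tbl |>
      group_by(.data$sim_locus) |>
      summarise(lead_ids = list(.data$id), .groups = "drop")
    planted <- planted |> left_join(lead_ids_by_locus, by = "sim_locus")

    # credible SNPs near a random lead of each locus
    cred_rows <- lead_tbl |>
      group_by(.data$sim_locus) |>
      summarise(chrom = .data$chrom[1], anchor = resample1(.data$pos),
                .groups = "drop") |>
      mutate(n_cred = stats::rpois(dplyr::n(), 3)) |>
      tidyr::uncount(.data$n_cred, .remove = FALSE) |>
      mutate(pos = pmax(1, .data$anchor + round(stats::rnorm(dplyr::n(), 0, 5e4))))
    credible <- if (nrow(cred_rows) > 0) {
      cred_rows |>
        mutate(id = sprintf("cs%05d", row_number()),
               ref = "A", alt = "G",
               beta = stats::rnorm(dplyr::n(), 0, 0.08),
               se = abs(.data$beta) / stats::runif(dplyr::n(), 2, 8),
               p = 2 * stats::pnorm(-abs(.data$beta) / pmax(.data$se, 1e-9)),
               source = "credible") |>
        select("chrom", "pos", "id", "ref", "alt", "beta", "se", "p", "source")
    } else {
      tibble()
    }

    # pathway: planted genes of ~40% of loci plus a few decoy genes
    pc_genes <- genes$gene_id[genes$biotype == "protein_coding"]
    path_loci <- sample(planted$sim_locus,
                        min(nrow(planted), max(2, ceiling(0.4 * n_loci))))
    decoys <- sample(setdiff(pc_genes, planted$gene_id),
                     min(3, length(setdiff(pc_genes, planted$gene_id))))
    pathway_members <- unique(c(
      planted$gene_id[planted$sim_locus %in% path_loci], decoys))

    # informative-feature design for the three gene-level modalities
    effects <- purrr::map_dfr(c("consequence", "qtl", "expression"), function(m) {
      n_m <- config$n_features_per_modality[[m]]
      n_inf <- max(2, round(0.05 * n_m))
      tibble(feature = sprintf("%s_%03d", m, seq_len(n_inf)),
             modality = m,
             effect = stats::runif(n_inf, 0.6, 1))
    })

    truth <- structure(list(
      planted = planted,
      pathway_members = pathway_members,
      effects = effects,
      genes = genes,
      expected_n_loci = n_loci,
      seed = config$seed
    ), class = "sim_truth")

    list(
      variants = bind_rows(lead_tbl |>
                             select("chrom", "pos", "id", "ref", "alt",
                                    "beta", "se", "p", "source"),
                           credible),
      genes = genes |> select(-"sim_locus"),
      truth = truth
    )
  })
}

#' Simulate raw multi-omic feature tables with planted signal
#'
#' Planted causal genes receive stochastically elevated values on the
#' informative features recorded in the truth (higher consequence severity,
#' stronger QTL weight, higher expression in designated cell-type columns);
#' all remaining features are pure noise from the same family, so at
#' `causal_signal_strength = 0` informative and noise features are
#' identically distributed. Cells are set missing independently at
#' `missing_rate`. Labels are assigned only within `n_positive_labels`
#' randomly chosen multi-gene "training loci": the planted gene is positive,
#' its co-locus protein-coding genes negative, everything else unlabelled.
#'
#' @param truth A `sim_truth` from [simulate_loci()].
#' @param config The same [sim_config()].
#' @return A list with `tables` (named list of wide gene-keyed tibbles, one
#'   per modality) and `labels` (`gene_id`, `sim_locus`, `label` in
#'   `{1, 0, NA}`).
#' @export
simulate_features <- function(truth, config) {
  if (!inherits(truth, "sim_truth")) abort("`truth` must come from simulate_loci()")
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    genes <- truth$genes
    n_genes <- nrow(genes)
    is_causal <- genes$gene_id %in% truth$planted$gene_id
    strength <- config$causal_signal_strength

    make_modality <- function(modality, n_feat, rng) {
      eff <- truth$effects |> filter(.data$modality == !!modality)
      cols <- sprintf("%s_%03d", modality, seq_len(n_feat))
      vals <- matrix(0, n_genes, n_feat, dimnames = list(NULL, cols))
      for (j in seq_len(n_feat)) {
        shift <- numeric(n_genes)
        k <- match(cols[j], eff$feature)
        if (!is.na(k)) shift[is_causal] <- strength * eff$effect[k]
        vals[, j] <- rng(n_genes, shift)
      }
      if (config$missing_rate > 0) {
        vals[stats::runif(length(vals)) < config$missing_rate] <- NA_real_
      }
      bind_cols(tibble(gene_id = genes$gene_id), as_tibble(vals))
    }

    tables <- list(
      consequence = make_modality(
        "consequence", config$n_features_per_modality[["consequence"]],
        function(n, shift) stats::plogis(stats::rnorm(n, shift, 1.5))),
      qtl = make_modality(
        "qtl", config$n_features_per_modality[["qtl"]],
        function(n, shift) abs(stats::rnorm(n, shift, 1))),
      expression = make_modality(
        "expression", config$n_features_per_modality[["expression"]],
        function(n, shift) abs(stats::rnorm(n, shift, 1)))
    )

    # labels within training loci only
    multi <- genes |>
      filter(.data$biotype == "protein_coding") |>
      dplyr::count(.data$sim_locus) |>
      filter(.data$n >= 2)
    if (nrow(multi) < config$n_positive_labels) {
      abort("not enough multi-gene loci to host the requested positive labels")
    }
    train_loci <- sample(multi$sim_locus, config$n_positive_labels)
    labels <- genes |>
      select("gene_id", "sim_locus", "biotype") |>
      mutate(label = dplyr::case_when(
        .data$sim_locus %in% train_loci &
          .data$gene_id %in% truth$planted$gene_id ~ 1,
        .data$sim_locus %in% train_loci & .data$biotype == "protein_coding" ~ 0,
        TRUE ~ NA_real_
      )) |>
      select("gene_id", "sim_locus", "label")

    list(tables = tables, labels = labels)
  })
}

# dosages for one gene's SNP block, optionally with AR(1) haplotype LD
simulate_dosages <- function(n, mafs, ld_rho) {
  m <- length(mafs)
  if (ld_rho <= 0) {
    mat <- matrix(stats::rbinom(n * m, 2L, rep(mafs, each = n)), n, m)
  } else {
    hap <- function() {
      z <- matrix(stats::rnorm(n * m), n, m)
      if (m > 1) for (k in 2:m) {
        z[, k] <- ld_rho * z[, k - 1] + sqrt(1 - ld_rho^2) * z[, k]
      }
      sweep(z, 2, stats::qnorm(mafs), "<") + 0
    }
    mat <- hap() + hap()
  }
  storage.mode(mat) <- "integer"
  mat
}

#' Simulate case-control cohort genotypes with a planted pathway effect
#'
#' Per-SNP dosages in `{0, 1, 2}` are drawn binomially from a uniform MAF
#' (optionally with within-gene AR(1) haplotype correlation so that LD
#' clumping is exercised non-trivially). The true pathway burden is a fixed
#' weighted sum of dosages at SNPs inside pathway member genes; case status
#' follows a logistic model with linear predictor
#' `intercept + pathway_effect_beta * standardized burden + covariates`.
#' GWAS-style per-SNP `beta`/`se`/`p` are computed by marginal regression on
#' an independent simulated discovery sample of `n_discovery` individuals
#' drawn from the same model (processed in SNP blocks to bound memory).
#'
#' @param truth A `sim_truth` from [simulate_loci()].
#' @param config The same [sim_config()].
#' @return A list with `genotypes` (individuals x SNPs integer matrix),
#'   `snps` (`snp_id`, `gene_id`, `chrom`, `pos`, `maf`, `beta`, `se`, `p`),
#'   `phenotypes` (`iid`, `status`, `age`, `sex`, `PC1`..`PC10`) and
#'   `snp_weights` (the true per-SNP burden weights).
#' @export
simulate_cohort <- function(truth, config) {
  if (!inherits(truth, "sim_truth")) abort("`truth` must come from simulate_loci()")
  stopifnot(inherits(config, "sim_config"))
  if (config$n_individuals < 50) {
    abort("n_individuals < 50: downstream association would be unstable")
  }
  withr::with_seed(config$seed + 2L, {
    genes <- truth$genes
    snps <- genes |>
      select("gene_id", "chrom", "start", "end") |>
      tidyr::uncount(config$snps_per_gene) |>
      mutate(
        pos = round(stats::runif(dplyr::n(), .data$start, .data$end)),
        maf = stats::runif(dplyr::n(), config$maf_range[1], config$maf_range[2]),
        snp_id = sprintf("snp%05d", row_number())
      ) |>
      select("snp_id", "gene_id", "chrom", "pos", "maf")

    in_path <- snps$gene_id %in% truth$pathway_members
    w <- numeric(nrow(snps))
    w[in_path] <- stats::rnorm(sum(in_path))

    gene_blocks <- split(seq_len(nrow(snps)), snps$gene_id)

    draw_cohort <- function(n) {
      G <- matrix(0L, n, nrow(snps), dimnames = list(NULL, snps$snp_id))
      for (idx in gene_blocks) {
        G[, idx] <- simulate_dosages(n, snps$maf[idx], config$ld_rho)
      }
      age <- stats::rnorm(n, 62, 10)
      sex <- stats::rbinom(n, 1, 0.5)
      pcs <- matrix(stats::rnorm(n * 10), n, 10,
                    dimnames = list(NULL, paste0("PC", 1:10)))
      burden <- as.numeric(G[, in_path, drop = FALSE] %*% w[in_path])
      sdb <- stats::sd(burden)
      burden_std <- if (is.na(sdb) || sdb == 0) burden * 0 else
        (burden - mean(burden)) / sdb
      lp <- stats::qlogis(min(max(config$prevalence_like_case_fraction, 1e-6),
                              1 - 1e-6)) +
        config$pathway_effect_beta * burden_std +
        0.25 * (sex - 0.5) + 0.1 * (age - 62) / 10
      status <- stats::rbinom(n, 1, stats::plogis(lp))
      list(G = G, pheno = bind_cols(
        tibble(status = status, age = age, sex = sex), as_tibble(pcs)))
    }

    target <- draw_cohort(config$n_individuals)

    # discovery sample: per-SNP marginal linear regression, one gene block
    # at a time so the full n_discovery x n_snps matrix is never held
    nd <- config$n_discovery
    path_idx <- which(in_path)
    Gpath <- matrix(0L, nd, length(path_idx))
    path_block_of <- split(seq_along(path_idx), snps$gene_id[path_idx])
    path_gene_idx <- split(path_idx, snps$gene_id[path_idx])
    for (g in names(path_gene_idx)) {
      Gpath[, path_block_of[[g]]] <- simulate_dosages(
        nd, snps$maf[path_gene_idx[[g]]], config$ld_rho)
    }
    sexd <- stats::rbinom(nd, 1, 0.5)
    aged <- stats::rnorm(nd, 62, 10)
    burden <- as.numeric(Gpath %*% w[path_idx])
    sdb <- stats::sd(burden)
    burden_std <- if (is.na(sdb) || sdb == 0) burden * 0 else
      (burden - mean(burden)) / sdb
    lp <- stats::qlogis(min(max(config$prevalence_like_case_fraction, 1e-6),
                            1 - 1e-6)) +
      config$pathway_effect_beta * burden_std +
      0.25 * (sexd - 0.5) + 0.1 * (aged - 62) / 10
    y <- stats::rbinom(nd, 1, stats::plogis(lp))
    yc <- y - mean(y)
    ss_y <- sum(yc^2)

    marginal_stats <- function(G) {
      gm <- colMeans(G)
      ss_g <- colSums(G^2) - nd * gm^2
      ss_g[ss_g == 0] <- NA_real_
      xy <- as.numeric(crossprod(G, yc))
      beta_hat <- xy / ss_g
      sigma2 <- pmax(ss_y - beta_hat * xy, 0) / (nd - 2)
      se_hat <- sqrt(sigma2 / ss_g)
      list(beta = beta_hat, se = se_hat,
           p = 2 * stats::pnorm(-abs(beta_hat / se_hat)))
    }

    beta_hat <- se_hat <- pval <- rep(NA_real_, nrow(snps))
    st <- marginal_stats(Gpath)
    beta_hat[path_idx] <- st$beta; se_hat[path_idx] <- st$se; pval[path_idx] <- st$p
    for (g in names(gene_blocks)) {
      idx <- gene_blocks[[g]]
      idx <- idx[!idx %in% path_idx]
      if (length(idx) == 0) next
      st <- marginal_stats(simulate_dosages(nd, snps$maf[idx], config$ld_rho))
      beta_hat[idx] <- st$beta; se_hat[idx] <- st$se; pval[idx] <- st$p
    }
    snps <- snps |> mutate(beta = beta_hat, se = se_hat, p = pval)

    rownames(target$G) <- sprintf("id%05d", seq_len(config$n_individuals))
    list(
      genotypes = target$G,
      snps = snps,
      phenotypes = bind_cols(tibble(iid = rownames(target$G)), target$pheno),
      snp_weights = setNames(w, snps$snp_id)
    )
  })
}

#' Simulate a gene-set collection containing the planted pathway
#'
#' @param truth A `sim_truth` from [simulate_loci()].
#' @param n_sets Number of decoy sets (default 40).
#' @param size_range Decoy set size range (default `c(5, 50)`).
#' @param seed Seed (defaults to the truth's seed).
#' @return Named list of gene-id vectors; the planted pathway is
#'   `"PLANTED_PATHWAY"`.
#' @export
simulate_gene_sets <- function(truth, n_sets = 40, size_range = c(5, 50),
                               seed = truth$seed) {
  if (!inherits(truth, "sim_truth")) abort("`truth` must come from simulate_loci()")
  withr::with_seed(seed + 3L, {
    universe <- truth$genes$gene_id[truth$genes$biotype == "protein_coding"]
    sets <- purrr::map(seq_len(n_sets), function(i) {
      sz <- resample1(seq(size_range[1], min(size_range[2], length(universe))))
      sample(universe, sz)
    })
    names(sets) <- sprintf("DECOY_SET_%03d", seq_len(n_sets))
    c(list(PLANTED_PATHWAY = truth$pathway_members), sets)
  })
}
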