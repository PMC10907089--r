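# Independent oracles used across the suite. Each one is a deliberately
# naive re-derivation (enumeration, nested loops, closed form) kept separate
# from the implementation paths it checks.

# connected components under "pairwise distance <= window on same chromosome",
# by explicit O(n^2) chain propagation
oracle_merge_components <- function(chrom, pos, window) {
  n <- length(pos)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (chrom[i] == chrom[j] && abs(pos[i] - pos[j]) <= window &&
            comp[j] != comp[i]) {
          new <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# literal definition of average precision
oracle_ap <- function(y) {
  hits <- 0
  total <- 0
  vals <- c()
  for (k in seq_along(y)) {
    if (y[k] == 1) {
      hits <- hits + 1
      vals <- c(vals, hits / k)
    }
  }
  mean(vals)
}

# hypergeometric upper tail by enumerating every size-n draw from the universe
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)  # set = elements 1..K
  mean(overlap >= k)
}

# closed-form fixed-effect inverse-variance pooling
oracle_ivw <- function(beta, se) {
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  list(beta = b, se = sqrt(1 / sum(w)), Q = sum(w * (beta - b)^2))
}

# nested-loop left join of modality tables onto pairs (gene- or pair-keyed)
oracle_join <- function(pairs, tables, feature_names) {
  out <- matrix(NA_real_, nrow(pairs), length(feature_names),
                dimnames = list(pairs$pair_id, feature_names))
  for (tab in tables) {
    key <- if ("pair_id" %in% names(tab)) "pair_id" else "gene_id"
    for (i in seq_len(nrow(pairs))) {
      hit <- which(tab[[key]] == pairs[[key]][i])
      if (length(hit) == 1) {
        for (f in intersect(names(tab), feature_names)) {
          out[i, f] <- tab[[f]][hit]
        }
      }
    }
  }
  out
}

# round-trip a double through IEEE float32 (xgboost compares features and
# split thresholds in single precision)
f32 <- function(x) readBin(writeBin(as.numeric(x), raw(), size = 4),
                           what = "numeric", size = 4, n = length(x))

# exact Shapley values for an xgboost tree ensemble by coalition enumeration
# over each tree's used features, with cover-weighted conditional expectations
# (the EXPVALUE recursion); feasible for models using few distinct features
oracle_tree_shap <- function(model, X) {
  td_all <- as.data.frame(xgboost::xgb.model.dt.tree(model = model))
  td_all$Split <- f32(td_all$Split)  # comparisons happen in single precision
  feats <- colnames(X)
  X <- apply(X, 2, f32)
  contrib <- matrix(0, nrow(X), length(feats), dimnames = list(NULL, feats))
  base_score <- as.numeric(
    xgboost::xgb.config(model)$learner$learner_model_param$base_score)
  base <- stats::qlogis(base_score)
  for (tr in unique(td_all$Tree)) {
    td <- td_all[td_all$Tree == tr, ]
    expvalue <- function(i, x, S) {
      if (td$Feature[i] == "Leaf") return(td$Gain[i])
      iy <- which(td$ID == td$Yes[i])
      ino <- which(td$ID == td$No[i])
      if (td$Feature[i] %in% S) {
        v <- x[[td$Feature[i]]]
        if (is.na(v)) return(expvalue(which(td$ID == td$Missing[i]), x, S))
        if (v < td$Split[i]) return(expvalue(iy, x, S))
        return(expvalue(ino, x, S))
      }
      (td$Cover[iy] * expvalue(iy, x, S) +
         td$Cover[ino] * expvalue(ino, x, S)) / td$Cover[i]
    }
    U <- unique(td$Feature[td$Feature != "Leaf"])
    M <- length(U)
    root <- which(td$Node == 0)
    if (M == 0) { base <- base + td$Gain[root]; next }
    subsets <- lapply(0:(2^M - 1), function(b) U[bitwAnd(b, 2^(seq_len(M) - 1)) > 0])
    for (r in seq_len(nrow(X))) {
      x <- as.list(X[r, , drop = TRUE])
      v <- vapply(subsets, function(S) expvalue(root, x, S), numeric(1))
      names(v) <- vapply(subsets, function(S) paste(sort(S), collapse = ","),
                         character(1))
      for (f in U) {
        phi <- 0
        for (si in seq_along(subsets)) {
          S <- subsets[[si]]
          if (f %in% S) next
          key_with <- paste(sort(c(S, f)), collapse = ",")
          wgt <- factorial(length(S)) * factorial(M - length(S) - 1) / factorial(M)
          phi <- phi + wgt * (v[[key_with]] - v[[si]])
        }
        contrib[r, f] <- contrib[r, f] + phi
      }
      if (r == 1) base <- base + v[[1]]  # v(empty), same for all rows
    }
  }
  list(contrib = contrib, base = base)
}

# independent O(n^2) greedy clumping re-derivation
oracle_clump <- function(snps, genotypes, r2 = 0.1, window = 250000) {
  s <- snps[order(snps$p, snps$pos, snps$snp_id), ]
  kept <- character(0)
  removed <- character(0)
  for (i in seq_len(nrow(s))) {
    id <- s$snp_id[i]
    if (id %in% removed) next
    kept <- c(kept, id)
    for (j in seq_len(nrow(s))) {
      jd <- s$snp_id[j]
      if (jd == id || jd %in% removed || jd %in% kept) next
      if (s$chrom[j] == s$chrom[i] && abs(s$pos[j] - s$pos[i]) <= window) {
        r <- suppressWarnings(stats::cor(genotypes[, id], genotypes[, jd]))
        if (!is.na(r) && r^2 >= r2) removed <- c(removed, jd)
      }
    }
  }
  kept
}

# small default simulation config shared by unit tests
tiny_sim_config <- function(seed = 7L, ...) {
  sim_config(n_loci = 8, n_leads = 10, genes_per_locus = c(2, 6),
             n_features_per_modality = c(distance = 4, consequence = 6,
                                         qtl = 10, expression = 10),
             n_positive_labels = 4, n_individuals = 300, n_discovery = 2000,
             snps_per_gene = 4, seed = seed, ...)
}

# run the tiny config through loci + features up to the neighbourhood matrix
tiny_matrix_setup <- function(seed = 7L) {
  cfg <- tiny_sim_config(seed)
  sim <- simulate_loci(cfg)
  loci <- merge_variants(dplyr::filter(sim$variants, source == "lead"))
  loci <- attach_credible_snps(loci,
                               dplyr::filter(sim$variants, source == "credible"))
  loci <- assign_genes(loci, sim$genes)
  pairs <- locus_gene_pairs(loci, sim$genes)
  dist <- compute_distance_features(loci, pairs)
  feats <- simulate_features(sim$truth, cfg)
  specs <- dplyr::bind_rows(distance_feature_specs(),
                            modality_feature_specs(feats$tables))
  tables <- c(list(distance = dplyr::select(dist, pair_id,
                                            dplyr::starts_with("dist_"))),
              feats$tables)
  raw <- assemble_matrix(pairs, tables, specs)
  nbhd <- neighbourhood_transform(raw, specs)
  labels <- dplyr::left_join(pairs[, c("pair_id", "locus_id", "gene_id")],
                             dplyr::select(feats$labels, gene_id, label),
                             by = "gene_id")
  list(cfg = cfg, sim = sim, loci = loci, pairs = pairs, specs = specs,
       raw = raw, nbhd = nbhd, labels = labels)
}

# the 80-locus strong-signal benchmark shared by several acceptance checks;
# computed once per test session
benchmark_cache <- new.env(parent = emptyenv())
benchmark_run <- function() {
  if (!is.null(benchmark_cache$run)) return(benchmark_cache$run)
  cfg <- sim_config(n_loci = 80, n_leads = 90, seed = 11L)
  sim <- simulate_loci(cfg)
  loci <- merge_variants(dplyr::filter(sim$variants, source == "lead"))
  loci <- attach_credible_snps(loci,
                               dplyr::filter(sim$variants, source == "credible"))
  loci <- assign_genes(loci, sim$genes)
  pairs <- locus_gene_pairs(loci, sim$genes)
  dist <- compute_distance_features(loci, pairs)
  feats <- simulate_features(sim$truth, cfg)
  specs <- dplyr::bind_rows(distance_feature_specs(),
                            modality_feature_specs(feats$tables))
  raw <- assemble_matrix(pairs, c(list(distance = dplyr::select(
    dist, pair_id, dplyr::starts_with("dist_"))), feats$tables), specs)
  nbhd <- neighbourhood_transform(raw, specs)
  lmap <- dplyr::left_join(
    dplyr::mutate(sim$truth$planted,
                  lead_id = purrr::map_chr(lead_ids, 1)),
    tidyr::unnest_longer(dplyr::select(loci, locus_id, lead_ids),
                         lead_ids, values_to = "lead_id"),
    by = "lead_id")
  labels <- dplyr::left_join(
    pairs[, c("pair_id", "locus_id", "gene_id")],
    dplyr::left_join(feats$labels,
                     dplyr::select(lmap, sim_locus, locus_id),
                     by = "sim_locus")[, c("gene_id", "locus_id", "label")],
    by = c("gene_id", "locus_id"))
  model <- train_two_step(nbhd, labels, model_config(seed = 11L))
  scores <- score_genes(model, nbhd)
  benchmark_cache$run <- list(cfg = cfg, sim = sim, loci = loci, pairs = pairs,
                              nbhd = nbhd, labels = labels, model = model,
                              scores = scores)
  benchmark_cache$run
}
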