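#' Feature specs for simulated modality tables
#'
#' All simulated gene-level modalities (consequence severity, QTL weight,
#' expression) are `higher_better`; distance features carry their own specs.
#'
#' @param tables Named list of modality tables ([simulate_features()]).
#' @return A spec tibble covering every feature column.
#' @export
modality_feature_specs <- function(tables) {
  purrr::imap_dfr(tables, function(tab, modality) {
    cols <- setdiff(names(tab), c("gene_id", "pair_id"))
    purrr::map_dfr(cols, feature_spec, modality = modality,
                   direction = "higher_better")
  })
}

#' Synthetic 90-lead variant table with the reference design structure
#'
#' A reproducible lead-variant table with the structure this package
#' emulates: 90 independent risk variants that single-linkage merge at
#' 250 kb into exactly 78 loci. The coordinates are synthetic (generated by
#' [simulate_loci()]), not real GWAS positions.
#'
#' @param seed Seed (default 2019).
#' @return Tibble of 90 lead variants (`chrom`, `pos`, `id`, `ref`, `alt`,
#'   `beta`, `se`, `p`).
#' @export
synthetic_study_leads <- function(seed = 2019L) {
  sim <- simulate_loci(sim_config(n_loci = 78, n_leads = 90, seed = seed))
  sim$variants |> filter(.data$source == "lead") |> select(-"source")
}

# map each simulated locus to the built locus containing its first lead
sim_locus_map <- function(truth, loci) {
  lead_to_locus <- loci |>
    select("locus_id", "lead_ids") |>
    tidyr::unnest_longer("lead_ids", values_to = "lead_id")
  truth$planted |>
    mutate(lead_id = purrr::map_chr(.data$lead_ids, 1)) |>
    left_join(lead_to_locus, by = "lead_id") |>
    select("sim_locus", "locus_id", planted_gene = "gene_id")
}

#' Fraction of loci whose planted causal gene ranks first
#'
#' @param scores Output of [score_genes()].
#' @param truth The generator's `sim_truth`.
#' @param loci Built locus table (to map simulated loci onto built loci).
#' @return A list with `rate` (fraction in `[0, 1]`), `n_loci`, and the
#'   per-locus `detail` tibble.
#' @export
planted_top1_rate <- function(scores, truth, loci) {
  map <- sim_locus_map(truth, loci)
  top <- scores |>
    group_by(.data$locus_id) |>
    dplyr::slice_max(.data$probability, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("locus_id", top_gene = "gene_id", "probability")
  detail <- map |>
    inner_join(top, by = "locus_id") |>
    mutate(hit = .data$top_gene == .data$planted_gene)
  list(rate = mean(detail$hit), n_loci = nrow(detail), detail = detail)
}

#' Run the full locus-to-gene pipeline on synthetic data
#'
#' Chains every stage end-to-end on generator output with planted truth:
#' simulate - build loci - assign genes - distance + modality features -
#' neighbourhood transform - two-step training - scoring - Shapley
#' explanation - nomination - over-representation analysis - pathway PRS
#' with permutation inference per cohort - fixed-effect meta-analysis.
#'
#' @param config A [sim_config()]; its seed drives every stage.
#' @param n_cohorts Number of independent cohorts for the PRS stage
#'   (default 3).
#' @param n_permutations Label permutations per cohort (default 10000).
#' @param search_budget Hyperparameter draws per training step (default 10).
#' @param out_dir Optional directory; when given, the main tables are
#'   written as TSV (plus `truth.json`).
#' @return An `l2g_run` list with all intermediate and final artifacts.
#' @export
l2g_pipeline <- function(config = sim_config(), n_cohorts = 3,
                         n_permutations = 10000, search_budget = 10,
                         out_dir = NULL) {
  sim <- simulate_loci(config)
  leads <- sim$variants |> filter(.data$source == "lead")
  credible <- sim$variants |> filter(.data$source == "credible")

  loci <- merge_variants(leads, window = 250000)
  loci <- attach_credible_snps(loci, credible)
  loci <- assign_genes(loci, sim$genes, window = 1e6,
                       biotype = "protein_coding")
  pairs <- locus_gene_pairs(loci, sim$genes)
  dist <- compute_distance_features(loci, pairs)

  feats <- simulate_features(sim$truth, config)
  specs <- bind_rows(distance_feature_specs(),
                     modality_feature_specs(feats$tables))
  tables <- c(list(distance = dist |>
                     select("pair_id", dplyr::starts_with("dist_"))),
              feats$tables)
  raw <- assemble_matrix(pairs, tables, specs)
  nbhd <- neighbourhood_transform(raw, specs)

  lmap <- sim_locus_map(sim$truth, loci)
  pair_labels <- pairs |>
    select("pair_id", "locus_id", "gene_id") |>
    left_join(feats$labels |>
                left_join(lmap |> select("sim_locus", "locus_id"),
                          by = "sim_locus") |>
                select("gene_id", "locus_id", "label"),
              by = c("gene_id", "locus_id"))

  model <- train_two_step(nbhd, pair_labels,
                          model_config(seed = config$seed,
                                       search_budget = search_budget))
  scores <- score_genes(model, nbhd)
  attributions <- attribute(model, nbhd)
  importance <- global_importance(attributions)
  nominations <- nominate(scores, sim$genes)
  recovery <- planted_top1_rate(scores, sim$truth, loci)

  sets <- simulate_gene_sets(sim$truth)
  universe <- sim$genes$gene_id[sim$genes$biotype == "protein_coding"]
  enrichment <- ora(unique(nominations$gene_id), sets, universe)

  cohort_results <- purrr::map_dfr(seq_len(n_cohorts), function(ci) {
    cfg_c <- config
    cfg_c$seed <- config$seed + 1000L * ci
    cohort <- simulate_cohort(sim$truth, cfg_c)
    eligible <- filter_snps(cohort$snps, cohort$genotypes)
    snps_eligible <- cohort$snps |> filter(.data$snp_id %in% eligible)
    idx <- clump(snps_eligible, cohort$genotypes)
    snps_idx <- snps_eligible |> filter(.data$snp_id %in% idx)
    prs <- score_pathway(cohort$genotypes, snps_idx,
                         sim$truth$pathway_members, sim$genes)
    assoc <- associate(prs, cohort$phenotypes)
    perm <- permutation_p(prs, cohort$phenotypes,
                          n_permutations = n_permutations,
                          seed = cfg_c$seed + 1L)
    bind_cols(tibble(cohort = sprintf("cohort_%d", ci),
                     n_eligible = length(eligible),
                     n_index = length(idx)),
              assoc, perm)
  })
  meta <- meta_analyze(cohort_results |> select("cohort", "beta", "se"))

  run <- structure(list(
    config = config, truth = sim$truth,
    variants = sim$variants, genes = sim$genes,
    loci = loci, pairs = pairs,
    matrix_raw = raw, matrix = nbhd, labels = pair_labels,
    model = model, scores = scores,
    attributions = attributions, importance = importance,
    nominations = nominations, recovery = recovery,
    gene_sets = sets, enrichment = enrichment,
    prs = cohort_results, meta = meta
  ), class = "l2g_run")

  if (!is.null(out_dir)) write_l2g_run(run, out_dir)
  run
}

#' @export
print.l2g_run <- function(x, ...) {
  cat("<l2g_run>\n")
  cat(sprintf("  %d lead variants -> %d loci; %d locus-gene pairs\n",
              sum(x$variants$source == "lead"), nrow(x$loci), nrow(x$pairs)))
  cat(sprintf("  model: %d/%d features selected, CV MAP %.3f\n",
              length(x$model$selected_features),
              length(x$model$features_step1), x$model$manifest$best_map))
  cat(sprintf("  planted gene ranked first in %.1f%% of %d loci\n",
              100 * x$recovery$rate, x$recovery$n_loci))
  cat(sprintf("  nominations: %d high / %d mid / %d low confidence\n",
              sum(x$nominations$tier == "high"),
              sum(x$nominations$tier == "mid"),
              sum(x$nominations$tier == "low")))
  top_set <- x$enrichment$set[1]
  cat(sprintf("  top enriched set: %s (q = %.3g)\n",
              top_set, x$enrichment$q[1]))
  cat(sprintf("  pathway PRS meta: OR %.3f (%.3f-%.3f), p = %.3g\n",
              x$meta$pooled$or, x$meta$pooled$ci_lower,
              x$meta$pooled$ci_upper, x$meta$pooled$p))
  invisible(x)
}

#' Write the main pipeline tables to a directory
#'
#' @param run An `l2g_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_l2g_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) readr::write_tsv(x, file.path(dir, f))
  w(run$variants, "variants.tsv")
  w(run$genes, "genes.tsv")
  w(run$loci |> select("locus_id", "chrom", "start", "end", "n_leads"),
    "loci.tsv")
  w(run$pairs, "locus_gene_pairs.tsv")
  w(run$matrix, "feature_matrix.tsv")
  w(run$scores, "scores.tsv")
  w(run$nominations, "nominations.tsv")
  w(run$enrichment, "enrichment.tsv")
  w(run$prs, "prs_results.tsv")
  w(run$meta$pooled, "meta_results.tsv")
  truth <- run$truth
  jsonlite::write_json(list(
    planted = truth$planted |> select("sim_locus", "gene_id"),
    pathway_members = truth$pathway_members,
    effects = truth$effects,
    seed = truth$seed
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
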