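#' Declare a feature column
#'
#' @param name Column name, unique across specs.
#' @param modality One of `"distance"`, `"consequence"`, `"qtl"`,
#'   `"expression"`, `"interaction"`.
#' @param direction `"higher_better"` (larger raw value means stronger
#'   evidence; raw values must be non-negative) or `"distance_like"`
#'   (smaller raw value, in bp, means stronger evidence).
#' @param missing_policy `"propagate_missing"` (default; the boosted learner
#'   handles missing values natively) or `"zero_fill"`.
#' @return A one-row tibble; bind rows of these into a spec table.
#' @export
feature_spec <- function(name, modality, direction,
                         missing_policy = "propagate_missing") {
  modality <- match.arg(modality,
    c("distance", "consequence", "qtl", "expression", "interaction"))
  direction <- match.arg(direction, c("higher_better", "distance_like"))
  missing_policy <- match.arg(missing_policy, c("propagate_missing", "zero_fill"))
  tibble(name = name, modality = modality, direction = direction,
         missing_policy = missing_policy)
}

#' Distance features for locus-gene pairs
#'
#' For every locus-gene pair, computes the four canonical proximity
#' features: distance from the nearest lead variant to the gene interval and
#' to the transcription start site (TSS; gene start on "+", gene end on
#' "-"), and the same two minima taken over the locus's credible SNP set
#' (which always includes the leads). Distances are 0 when a variant falls
#' inside the gene body (gene-interval distance only) and are in bp.
#'
#' @param loci Locus tibble with `lead_pos` and `credible_pos` list-columns
#'   ([merge_variants()], optionally [attach_credible_snps()]).
#' @param pairs Pair table from [locus_gene_pairs()].
#' @return `pairs` with columns `dist_lead_gene`, `dist_lead_tss`,
#'   `dist_credible_gene`, `dist_credible_tss`.
#' @export
compute_distance_features <- function(loci, pairs) {
  idx <- match(pairs$locus_id, loci$locus_id)
  if (anyNA(idx)) abort("pair table references unknown locus ids")
  same_chrom <- loci$chrom[idx] == pairs$chrom
  if (any(!same_chrom)) {
    abort(paste0("gene on a different chromosome than its locus: ",
                 paste(utils::head(pairs$pair_id[!same_chrom], 5), collapse = ", ")))
  }
  tss <- tss_position(pairs$start, pairs$end, pairs$strand)
  n <- nrow(pairs)
  dlg <- dlt <- dcg <- dct <- numeric(n)
  for (i in seq_len(n)) {
    leads <- loci$lead_pos[[idx[i]]]
    cred <- unique(c(leads, loci$credible_pos[[idx[i]]]))
    dlg[i] <- min(interval_distance(leads, pairs$start[i], pairs$end[i]))
    dlt[i] <- min(abs(leads - tss[i]))
    dcg[i] <- min(interval_distance(cred, pairs$start[i], pairs$end[i]))
    dct[i] <- min(abs(cred - tss[i]))
  }
  pairs |>
    mutate(dist_lead_gene = dlg, dist_lead_tss = dlt,
           dist_credible_gene = dcg, dist_credible_tss = dct)
}

#' Default feature specs for the four distance features
#' @return A spec tibble for the columns added by
#'   [compute_distance_features()].
#' @export
distance_feature_specs <- function() {
  bind_rows(
    feature_spec("dist_lead_gene", "distance", "distance_like"),
    feature_spec("dist_lead_tss", "distance", "distance_like"),
    feature_spec("dist_credible_gene", "distance", "distance_like"),
    feature_spec("dist_credible_tss", "distance", "distance_like")
  )
}

#' Assemble the raw locus-gene feature matrix
#'
#' Joins modality tables onto the locus-gene pair table. Tables keyed by
#' `pair_id` (e.g. distance features) join per pair; tables keyed by
#' `gene_id` join per gene, so a gene assigned to two loci contributes two
#' rows with identical gene-level values. Keys present in a table but absent
#' from `pairs` are dropped; pairs unmatched in a table get missing values.
#'
#' @param pairs Pair table ([locus_gene_pairs()]).
#' @param tables Named list of data frames, each keyed by `pair_id` or
#'   `gene_id`, remaining columns being feature columns.
#' @param specs Feature spec table (rows from [feature_spec()]); columns are
#'   emitted in spec order. Spec names absent from every table become
#'   all-missing columns.
#' @return A raw feature matrix tibble: `pair_id`, `locus_id`, `gene_id`
#'   then one column per spec row, with attribute `state = "raw"`.
#' @export
assemble_matrix <- function(pairs, tables, specs) {
  stopifnot(is.data.frame(specs), all(c("name", "direction") %in% names(specs)))
  if (anyDuplicated(specs$name)) abort("duplicate feature names in `specs`")
  out <- pairs |> select("pair_id", "locus_id", "gene_id")
  for (tab_name in names(tables)) {
    tab <- tables[[tab_name]]
    if (is.null(tab) || nrow(tab) == 0 || ncol(tab) <= 1) next
    key <- if ("pair_id" %in% names(tab)) "pair_id" else "gene_id"
    if (!key %in% names(tab)) abort(sprintf("table `%s` has no pair_id/gene_id key", tab_name))
    feat_cols <- intersect(setdiff(names(tab), key), specs$name)
    if (length(feat_cols) == 0) next
    tab <- tab[, c(key, feat_cols)]
    # conflicting duplicate keys are a data error; identical duplicates collapse
    tab <- distinct(tab)
    if (anyDuplicated(tab[[key]])) {
      offenders <- unique(tab[[key]][duplicated(tab[[key]])])
      abort(paste0("table `", tab_name, "` has conflicting duplicate entries for: ",
                   paste(utils::head(offenders, 5), collapse = ", ")),
            class = "l2g_dup_feature")
    }
    out <- left_join(out, tab, by = key)
  }
  for (nm in setdiff(specs$name, names(out))) out[[nm]] <- NA_real_
  out <- out[, c("pair_id", "locus_id", "gene_id", specs$name)]
  zf <- specs$name[specs$missing_policy == "zero_fill"]
  for (nm in zf) out[[nm]][is.na(out[[nm]])] <- 0
  attr(out, "state") <- "raw"
  out
}

#' Neighbourhood (locus-relative) score transform
#'
#' Rescales every feature within each locus relative to the best gene for
#' that feature, so the model sees locus-relative evidence rather than
#' absolute values. For `higher_better` features the best gene in the locus
#' scores 1 and the others score value / (locus maximum); an all-zero locus
#' scores 0. For `distance_like` features the raw bp distance `d` is
#' negative-log transformed, `t = log10(d_max + 1) - log10(d + 1)` with
#' `d_max` the largest distance in the locus, then max-normalised,
#' `score = t / max(t)`, so the closest gene scores 1 and the farthest 0;
#' when all distances in a locus are equal every non-missing gene scores 1.
#' Missing values are excluded from maxima and stay missing.
#'
#' @param matrix Raw feature matrix from [assemble_matrix()].
#' @param specs Feature spec table covering every feature column.
#' @return The matrix with every non-missing value in `[0, 1]` and attribute
#'   `state = "neighbourhood"`.
#' @export
neighbourhood_transform <- function(matrix, specs) {
  state <- attr(matrix, "state") %||% "raw"
  if (identical(state, "neighbourhood")) {
    abort("matrix is already neighbourhood-transformed")
  }
  feat_cols <- setdiff(names(matrix), c("pair_id", "locus_id", "gene_id"))
  unknown <- setdiff(feat_cols, specs$name)
  if (length(unknown) > 0) {
    abort(paste0("feature(s) without a spec/direction: ",
                 paste(unknown, collapse = ", ")))
  }
  dir <- setNames(specs$direction, specs$name)
  out <- matrix
  grp <- out$locus_id
  for (nm in feat_cols) {
    v <- out[[nm]]
    if (dir[[nm]] == "distance_like" && any(v < 0, na.rm = TRUE)) {
      abort(sprintf("negative raw distance in feature `%s`", nm))
    }
    if (dir[[nm]] == "higher_better" && any(v < 0, na.rm = TRUE)) {
      abort(sprintf("negative raw value in higher_better feature `%s`", nm))
    }
    out[[nm]] <- stats::ave(v, grp, FUN = function(x) {
      ok <- !is.na(x)
      if (!any(ok)) return(x)
      if (dir[[nm]] == "higher_better") {
        m <- max(x[ok])
        x[ok] <- if (m > 0) x[ok] / m else 0
      } else {
        t <- log10(max(x[ok]) + 1) - log10(x[ok] + 1)
        mt <- max(t)
        x[ok] <- if (mt > 0) t / mt else 1
      }
      x
    })
  }
  attr(out, "state") <- "neighbourhood"
  out
}
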