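#' Merge independent risk variants into loci
#'
#' Lead variants on the same chromosome are merged into a single locus by
#' single-linkage chaining: two leads share a locus if and only if a chain of
#' pairwise distances, each at most `window`, connects them. This reproduces
#' the usual GWAS locus definition in which independent signals closer than
#' the merge window are treated as one genomic locus (e.g. 90 independent
#' Parkinson's disease risk variants collapse into 78 loci at a 250 kb
#' window).
#'
#' @param leads A data frame of lead variants with columns `chrom`, `pos`
#'   (1-based bp) and `id` (unique); extra columns (`ref`, `alt`, `beta`,
#'   `se`, `p`, ...) are carried along inside the `lead` list-column.
#' @param window Merge window in bp; leads at distance `<= window` (inclusive)
#'   are chained. Default 250000.
#' @return A tibble with one row per locus: `locus_id`, `chrom`, `start`,
#'   `end` (min/max lead position), `n_leads`, and list-columns `lead_ids`,
#'   `lead_pos` plus empty `credible_ids`/`credible_pos` placeholders.
#'   Loci are sorted by chromosome then position.
#' @examples
#' leads <- tibble::tibble(chrom = "1", pos = c(1e6, 1.25e6, 1.6e6),
#'                         id = c("v1", "v2", "v3"))
#' merge_variants(leads) # two loci: {v1, v2} chain at 250 kb, v3 alone
#' @export
merge_variants <- function(leads, window = 250000) {
  stopifnot(is.data.frame(leads))
  if (nrow(leads) == 0) abort("`leads` must contain at least one variant")
  required <- c("chrom", "pos", "id")
  missing_cols <- setdiff(required, names(leads))
  if (length(missing_cols) > 0) {
    abort(paste0("`leads` is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(leads$id)) {
    abort(paste0(
      "Duplicate variant id(s): ",
      paste(unique(leads$id[duplicated(leads$id)]), collapse = ", ")
    ), class = "l2g_dup_id")
  }
  if (any(leads$pos < 1 | is.na(leads$pos))) abort("variant positions must be >= 1")

  leads <- leads |>
    mutate(chrom = normalize_chrom(.data$chrom)) |>
    arrange(chrom_rank(.data$chrom), .data$pos, .data$id)

  # On sorted positions single-linkage chaining is equivalent to cutting at
  # consecutive gaps > window.
  new_chrom <- c(TRUE, leads$chrom[-1] != leads$chrom[-nrow(leads)])
  gap <- c(Inf, diff(leads$pos))
  cut <- new_chrom | gap > window
  leads$.locus <- cumsum(cut)

  loci <- leads |>
    group_by(.data$.locus) |>
    summarise(
      chrom = .data$chrom[1],
      start = min(.data$pos),
      end = max(.data$pos),
      n_leads = dplyr::n(),
      lead_ids = list(.data$id),
      lead_pos = list(.data$pos),
      .groups = "drop"
    ) |>
    arrange(chrom_rank(.data$chrom), .data$start) |>
    mutate(
      locus_id = sprintf("locus_%03d", row_number()),
      credible_ids = purrr::map(.data$lead_ids, ~ character(0)),
      credible_pos = purrr::map(.data$lead_ids, ~ numeric(0))
    ) |>
    select("locus_id", "chrom", "start", "end", "n_leads",
           "lead_ids", "lead_pos", "credible_ids", "credible_pos")
  loci
}

#' Assign candidate genes to loci
#'
#' A gene is a candidate for a locus if its biotype matches and the smallest
#' distance between any of the locus's lead variants and the gene interval is
#' at most `window` (inclusive). The distance from a variant at position `v`
#' to a gene `[start, end]` is 0 when the variant falls inside the gene body
#' and `min(|start - v|, |end - v|)` otherwise. A gene may be assigned to
#' several loci (the situation of MAPT-like genes sitting between two merged
#' signals), producing one locus-gene row per assignment.
#'
#' @param loci Locus tibble from [merge_variants()].
#' @param annotation Gene table with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand` ("+"/"-") and `biotype`.
#' @param window Assignment window in bp (default 1e6).
#' @param biotype Biotype to retain (default `"protein_coding"`); `NULL`
#'   keeps all genes.
#' @return `loci` with an added `genes` list-column of assigned gene ids.
#' @seealso [locus_gene_pairs()] for the unnested pair table.
#' @export
assign_genes <- function(loci, annotation, window = 1e6,
                         biotype = "protein_coding") {
  stopifnot(is.data.frame(annotation))
  if (nrow(annotation) == 0) abort("`annotation` must be non-empty")
  ann <- annotation |> mutate(chrom = normalize_chrom(.data$chrom))
  if (any(ann$start > ann$end)) abort("gene annotation has start > end")
  if (!is.null(biotype)) ann <- ann |> filter(.data$biotype %in% !!biotype)
  if (nrow(ann) == 0) {
    warn("no genes left after biotype filter; assignments are empty")
  }

  loci$genes <- purrr::pmap(
    list(loci$chrom, loci$lead_pos),
    function(chr, pos) {
      cand <- ann[ann$chrom == chr, ]
      if (nrow(cand) == 0) return(character(0))
      keep <- vapply(seq_len(nrow(cand)), function(i) {
        min(interval_distance(pos, cand$start[i], cand$end[i])) <= window
      }, logical(1))
      cand$gene_id[keep]
    }
  )
  loci
}

#' Unnest locus-gene assignments into a pair table
#'
#' @param loci Locus tibble from [assign_genes()].
#' @param annotation Gene table (same as passed to [assign_genes()]).
#' @return A tibble with one row per locus-gene pair: `pair_id`, `locus_id`,
#'   `gene_id` plus gene coordinates.
#' @export
locus_gene_pairs <- function(loci, annotation) {
  stopifnot("genes" %in% names(loci))
  ann <- annotation |>
    mutate(chrom = normalize_chrom(.data$chrom)) |>
    select("gene_id", "chrom", "start", "end", "strand")
  pairs <- loci |>
    select("locus_id", "genes") |>
    tidyr::unnest_longer("genes", values_to = "gene_id") |>
    left_join(ann, by = "gene_id") |>
    mutate(pair_id = paste(.data$locus_id, .data$gene_id, sep = ":")) |>
    relocate("pair_id")
  pairs
}

#' Attach fine-mapped credible SNPs to loci
#'
#' Each credible SNP is attached to the locus on its chromosome whose lead
#' span, padded by `window` on both sides, contains it; when several loci
#' qualify the one with the nearest span is chosen. Lead variants are always
#' retained as part of the credible set when distances are computed
#' downstream. Credible SNPs matching no locus are recorded (in the
#' `unmatched` attribute) and skipped, not fatal.
#'
#' @param loci Locus tibble from [merge_variants()].
#' @param credible Data frame of credible SNPs with `chrom`, `pos`, `id`.
#' @param window Padding in bp around the lead span (default 1e6).
#' @return `loci` with filled `credible_ids`/`credible_pos` list-columns.
#' @export
attach_credible_snps <- function(loci, credible, window = 1e6) {
  if (is.null(credible) || nrow(credible) == 0) return(loci)
  cred <- credible |> mutate(chrom = normalize_chrom(.data$chrom))
  hit <- integer(nrow(cred))
  for (i in seq_len(nrow(cred))) {
    same <- which(loci$chrom == cred$chrom[i])
    if (length(same) == 0) { hit[i] <- NA_integer_; next }
    d <- pmax(loci$start[same] - cred$pos[i], cred$pos[i] - loci$end[same], 0)
    ok <- same[d <= window]
    hit[i] <- if (length(ok) == 0) NA_integer_ else ok[which.min(d[d <= window])]
  }
  unmatched <- cred$id[is.na(hit)]
  for (j in unique(hit[!is.na(hit)])) {
    rows <- which(hit == j)
    loci$credible_ids[[j]] <- c(loci$credible_ids[[j]], cred$id[rows])
    loci$credible_pos[[j]] <- c(loci$credible_pos[[j]], cred$pos[rows])
  }
  if (length(unmatched) > 0) {
    warn(sprintf("%d credible SNP(s) matched no locus and were skipped",
                 length(unmatched)))
  }
  attr(loci, "unmatched_credible") <- unmatched
  loci
}
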