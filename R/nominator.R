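#' Nominate the top candidate gene in each locus
#'
#' The gene with the highest probability in each locus is nominated.
#' Nominations are tiered by probability: `high` above
#' `high_confidence_threshold` (default 0.75), `low` below
#' `low_confidence_threshold` (default 0.30), `mid` in between. A runner-up
#' gene is reported when the second-ranked probability exceeds
#' `runner_up_threshold` (loci where two genes both carry strong evidence).
#' Probabilities equal within `1e-12` are treated as tied; ties are broken
#' by genomic position (upstream-most gene) or lexicographically, and are
#' always flagged.
#'
#' @param scores Gene scores from [score_genes()].
#' @param genes Gene annotation (needed for the genomic-position
#'   tie-break); optional when `tie_break = "lexicographic"`.
#' @param high_confidence_threshold,low_confidence_threshold,runner_up_threshold
#'   Tier and runner-up probability cut-offs.
#' @param tie_break `"genomic_position"` (default) or `"lexicographic"`.
#' @return Tibble `locus_id`, `gene_id`, `probability`, `tier`,
#'   `runner_up_gene`, `runner_up_probability`, `tie_flag`.
#' @export
nominate <- function(scores, genes = NULL,
                     high_confidence_threshold = 0.75,
                     low_confidence_threshold = 0.30,
                     runner_up_threshold = 0.75,
                     tie_break = c("genomic_position", "lexicographic")) {
  tie_break <- match.arg(tie_break)
  stopifnot(low_confidence_threshold >= 0,
            low_confidence_threshold < high_confidence_threshold,
            high_confidence_threshold <= 1)
  if (nrow(scores) == 0) abort("empty score table")
  if (any(is.na(scores$probability))) abort("scores contain missing probabilities")
  if (tie_break == "genomic_position") {
    if (is.null(genes)) {
      abort("genomic_position tie-break requires the `genes` annotation")
    }
    scores <- scores |>
      left_join(genes |> select("gene_id", "start"), by = "gene_id")
  } else {
    scores$start <- NA_real_
  }
  tol <- 1e-12
  scores |>
    group_by(.data$locus_id) |>
    dplyr::group_modify(function(d, key) {
      top_p <- max(d$probability)
      tied <- which(d$probability >= top_p - tol)
      pick <- if (length(tied) == 1) tied else if (tie_break == "genomic_position") {
        tied[order(d$start[tied], d$gene_id[tied])][1]
      } else {
        tied[order(d$gene_id[tied])][1]
      }
      rest <- d[-pick, , drop = FALSE]
      ru <- if (nrow(rest) > 0) which.max(rest$probability) else integer(0)
      ru_ok <- length(ru) == 1 && rest$probability[ru] > runner_up_threshold
      tibble(
        gene_id = d$gene_id[pick],
        probability = d$probability[pick],
        tier = dplyr::case_when(
          d$probability[pick] > high_confidence_threshold ~ "high",
          d$probability[pick] < low_confidence_threshold ~ "low",
          TRUE ~ "mid"),
        runner_up_gene = if (ru_ok) rest$gene_id[ru] else NA_character_,
        runner_up_probability = if (ru_ok) rest$probability[ru] else NA_real_,
        tie_flag = length(tied) > 1
      )
    }) |>
    ungroup()
}

#' Distinct nominated genes with locus multiplicity
#'
#' A gene sitting between two merged signals can be nominated in both
#' neighbouring loci; this summary counts each gene once and records the
#' loci that nominated it, so `number of unique genes <= number of loci`.
#'
#' @param nominations Output of [nominate()].
#' @return Tibble `gene_id`, `n_loci`, `loci` (list-column), sorted by
#'   multiplicity then gene.
#' @export
unique_gene_summary <- function(nominations) {
  if (nrow(nominations) == 0) abort("no nominations supplied")
  nominations |>
    group_by(.data$gene_id) |>
    summarise(n_loci = dplyr::n(), loci = list(.data$locus_id),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$n_loci), .data$gene_id)
}
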