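#' Read a GWAS variant table
#'
#' Expects a TSV with at least `chrom`, `pos`, `id` and optionally `ref`,
#' `alt`, `beta`, `se`, `p`, `source`. Coordinates are 1-based.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_variants <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = readr::col_character()))
}

#' Read a gene annotation table
#'
#' Expects a TSV with `gene_id`, `chrom`, `start`, `end`, `strand`,
#' `biotype` (1-based inclusive coordinates; convert BED-style 0-based
#' half-open inputs by adding 1 to starts before calling).
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_gene_annotation <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = readr::col_character()))
}

#' Read a dosage matrix
#'
#' Expects a TSV whose first column is `iid` and remaining columns are
#' per-SNP dosages in `[0, 2]`.
#'
#' @param path TSV path.
#' @return A numeric matrix with individual ids as row names.
#' @export
read_dosages <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d[[1]]
  m
}
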