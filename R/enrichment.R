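#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (one set per line: name, description,
#'   then member gene ids, tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(x) unique(x[-(1:2)])),
           vapply(parts, `[[`, character(1), 1))
}

#' Write gene sets to a GMT file
#' @param sets Named list of gene-id vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with monotonicity enforcement, so
#' `q >= p` and q is non-decreasing in sorted-p order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis of a gene list against gene sets
#'
#' For each set, the overlap `k` between the query and the set (both
#' intersected with the universe of `N` genes) is tested with the
#' hypergeometric upper tail `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`, where `K` is the set size in the universe
#' and `n` the query size — the classic one-sided over-representation test
#' against a protein-coding reference list. Query and set ids are
#' de-duplicated. FDR is controlled with [bh_fdr()] across all sets tested
#' in the call (run separate calls for separate collections, e.g. GO
#' biological processes vs cellular components).
#'
#' @param query Character vector of query gene ids (e.g. nominated genes).
#' @param sets Named list of gene-id vectors ([read_gmt()]).
#' @param universe Reference gene list (e.g. all protein-coding genes).
#' @param min_size,max_size Set-size filters applied after intersection
#'   with the universe (defaults 5 and 2000).
#' @return Tibble `set`, `N`, `K`, `n`, `k`, `expected`,
#'   `enrichment_ratio`, `p`, `q`, sorted by `p`.
#' @examples
#' ora(query = c("a", "b", "c"),
#'     sets = list(S = c("a", "b", "c", "d", "e")),
#'     universe = letters[1:10], min_size = 1)
#' @export
ora <- function(query, sets, universe, min_size = 5, max_size = 2000) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe")
  query <- intersect(unique(query), universe)
  if (length(query) == 0) abort("query is disjoint from the universe")
  N <- length(universe)
  n <- length(query)
  res <- purrr::imap_dfr(sets, function(members, nm) {
    set_u <- intersect(unique(members), universe)
    K <- length(set_u)
    if (K < min_size || K > max_size) return(NULL)
    k <- length(intersect(query, set_u))
    expected <- n * K / N
    tibble(set = nm, N = N, K = K, n = n, k = k,
           expected = expected,
           enrichment_ratio = k / expected,
           p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  if (nrow(res) == 0) {
    warn("no gene set passed the size filters")
    return(res)
  }
  res |>
    mutate(q = bh_fdr(.data$p)) |>
    arrange(.data$p, .data$set)
}
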