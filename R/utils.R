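#' @useDynLib locus2gene, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across left_join inner_join bind_rows bind_cols distinct n row_number
#'   rename relocate pull if_else
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

# Chromosome labels arrive as "chr1", "1", "X", ... ; internally we keep the
# bare label and order autosomes numerically before X, Y, MT.
normalize_chrom <- function(chrom) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(chrom))
  x[x %in% c("M", "m", "mt")] <- "MT"
  bad <- !grepl("^([0-9]+|X|Y|MT)$", x)
  if (any(bad)) {
    abort(paste0(
      "Malformed chromosome label(s): ",
      paste(unique(chrom[bad]), collapse = ", ")
    ), class = "l2g_bad_chrom")
  }
  x
}

chrom_rank <- function(chrom) {
  suppressWarnings(num <- as.numeric(chrom))
  num[chrom == "X"] <- 1e3
  num[chrom == "Y"] <- 1e3 + 1
  num[chrom == "MT"] <- 1e3 + 2
  num
}

# Distance from a point position to a gene interval; 0 if inside.
interval_distance <- function(pos, start, end) {
  d <- pmax(start - pos, pos - end, 0)
  d
}

tss_position <- function(start, end, strand) {
  if_else(strand == "-", end, start)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

# sample() treats a length-1 numeric as 1:n; this picks one element safely
resample1 <- function(x) x[sample.int(length(x), 1L)]

# round-trip doubles through IEEE float32; the boosted learner stores feature
# values and split thresholds in single precision, so exact re-walking of its
# trees must compare at that precision
f32 <- function(x) {
  out <- readBin(writeBin(as.numeric(x), raw(), size = 4),
                 what = "numeric", size = 4, n = length(x))
  out[is.na(x)] <- NA_real_
  out
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1]", name))
  }
  as.numeric(x)
}
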