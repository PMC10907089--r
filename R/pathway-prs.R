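#' Base SNP filters for pathway PRS construction
#'
#' The default reading retains SNPs with minor allele frequency
#' `>= maf_min` (computed from the cohort dosages, folded to the minor
#' allele) AND discovery GWAS `p <= gwas_p_max` — two conjunct inclusion
#' filters, the self-contained base filtering used by pathway-PRS tools.
#' The alternative reading, excluding only SNPs that are simultaneously
#' rare and nominally associated, is available as
#' `rule = "conjunct_exclusion"`.
#'
#' @param gwas SNP table with `snp_id` and `p` (discovery GWAS p-value).
#' @param genotypes Dosage matrix (individuals x SNPs, columns named by
#'   `snp_id`).
#' @param maf_min MAF threshold (default 0.01).
#' @param gwas_p_max GWAS p-value threshold (default 0.05).
#' @param rule `"two_filters"` (default) or `"conjunct_exclusion"`.
#' @return Character vector of eligible SNP ids.
#' @export
filter_snps <- function(gwas, genotypes, maf_min = 0.01, gwas_p_max = 0.05,
                        rule = c("two_filters", "conjunct_exclusion")) {
  rule <- match.arg(rule)
  ids <- intersect(gwas$snp_id, colnames(genotypes))
  if (length(ids) == 0) abort("no SNPs shared between GWAS table and genotypes")
  af <- colMeans(genotypes[, ids, drop = FALSE], na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  p <- gwas$p[match(ids, gwas$snp_id)]
  keep <- switch(rule,
    two_filters = maf >= maf_min & p <= gwas_p_max,
    conjunct_exclusion = !(maf < maf_min & p < gwas_p_max)
  )
  keep[is.na(keep)] <- FALSE
  out <- ids[keep]
  if (length(out) == 0) abort("no SNPs survive the MAF/p filters")
  out
}

#' Greedy LD clumping of SNPs
#'
#' Repeatedly takes the unclumped SNP with the smallest GWAS p-value as an
#' index SNP and removes every remaining SNP within `clump_window` bp on
#' the same chromosome whose squared dosage correlation with the index is
#' at least `clump_r2`. Ties on p are broken by position then id, so the
#' result is deterministic and independent of input row order.
#'
#' @param snps SNP table with `snp_id`, `chrom`, `pos`, `p`, restricted to
#'   eligible SNPs.
#' @param genotypes Dosage matrix with columns named by `snp_id`.
#' @param clump_r2 r-squared threshold (default 0.1).
#' @param clump_window Distance window in bp (default 250000).
#' @return Character vector of index SNP ids.
#' @export
clump <- function(snps, genotypes, clump_r2 = 0.1, clump_window = 250000) {
  snps <- snps |>
    filter(.data$snp_id %in% colnames(genotypes)) |>
    arrange(.data$p, .data$pos, .data$snp_id)
  alive <- rep(TRUE, nrow(snps))
  index <- character(0)
  for (i in seq_len(nrow(snps))) {
    if (!alive[i]) next
    index <- c(index, snps$snp_id[i])
    near <- which(alive & snps$chrom == snps$chrom[i] &
                    abs(snps$pos - snps$pos[i]) <= clump_window)
    near <- setdiff(near, i)
    if (length(near) > 0) {
      g0 <- genotypes[, snps$snp_id[i]]
      r <- suppressWarnings(
        stats::cor(g0, genotypes[, snps$snp_id[near], drop = FALSE]))
      r2 <- as.numeric(r)^2
      r2[is.na(r2)] <- 0
      alive[near[r2 >= clump_r2]] <- FALSE
    }
    alive[i] <- FALSE
  }
  index
}

#' Pathway-specific polygenic risk score
#'
#' Index SNPs are assigned to genes by coordinate overlap with the gene
#' body (no padding); SNPs falling inside any pathway member gene
#' contribute `dosage x GWAS beta` to each individual's score, which is
#' then standardised to mean 0, SD 1 across individuals.
#'
#' @param genotypes Dosage matrix (individuals x SNPs).
#' @param snps SNP table with `snp_id`, `chrom`, `pos`, `beta`, restricted
#'   to the clumped index SNPs to score.
#' @param pathway Character vector of pathway member gene ids.
#' @param annotation Gene table with `gene_id`, `chrom`, `start`, `end`.
#' @param standardize Standardise the score (default TRUE).
#' @return Tibble `iid`, `prs_raw`, `prs`, with attribute `n_snps_used`.
#' @export
score_pathway <- function(genotypes, snps, pathway, annotation,
                          standardize = TRUE) {
  genes <- annotation |>
    filter(.data$gene_id %in% pathway) |>
    mutate(chrom = normalize_chrom(.data$chrom))
  snps <- snps |> mutate(chrom = normalize_chrom(.data$chrom))
  in_path <- vapply(seq_len(nrow(snps)), function(i) {
    any(genes$chrom == snps$chrom[i] &
          genes$start <= snps$pos[i] & snps$pos[i] <= genes$end)
  }, logical(1))
  use <- snps$snp_id[in_path & snps$snp_id %in% colnames(genotypes)]
  if (length(use) == 0) {
    abort("no index SNPs overlap the pathway's gene bodies",
          class = "l2g_empty_pathway")
  }
  b <- snps$beta[match(use, snps$snp_id)]
  raw <- as.numeric(genotypes[, use, drop = FALSE] %*% b)
  sdr <- stats::sd(raw)
  std <- if (standardize && !is.na(sdr) && sdr > 0) (raw - mean(raw)) / sdr else raw
  iid <- rownames(genotypes) %||% sprintf("id%05d", seq_along(raw))
  out <- tibble(iid = iid, prs_raw = raw, prs = std)
  attr(out, "n_snps_used") <- length(use)
  out
}

# design matrix + glm fit shared by associate()/permutation_p()
prs_design <- function(prs, phenotypes, covariates) {
  dat <- inner_join(prs, phenotypes, by = "iid")
  covariates <- intersect(covariates, names(dat))
  X <- cbind(`(Intercept)` = 1, prs = dat$prs,
             as.matrix(dat[, covariates, drop = FALSE]))
  list(y = dat$status, X = X)
}

glm_prs_z <- function(y, X) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  cf <- fit$coefficients
  # Wald SE from the unscaled covariance of the IRLS solution
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  V <- tryCatch(chol2inv(chol(XtWX)), error = function(e) solve(XtWX))
  se <- sqrt(diag(V))
  j <- which(colnames(X) == "prs")
  list(beta = cf[j], se = se[j], z = cf[j] / se[j], converged = fit$converged,
       deviance = fit$deviance, null_deviance = fit$null.deviance)
}

#' Logistic association of a pathway PRS with case status
#'
#' Fits `status ~ PRS + covariates` by logistic regression and reports the
#' PRS effect as log-odds per standard deviation of the score: beta, SE,
#' OR with Wald 95% CI (`exp(beta +/- 1.96 SE)`) and asymptotic p. The
#' variance explained is additionally reported on the liability scale via
#' the prevalence-based transformation of the observed-scale R-squared
#' (`R2_liab = R2_obs * K^2 (1-K)^2 / (z(K)^2 P (1-P))`, with `K` the
#' assumed population prevalence, `P` the sample case fraction and `z` the
#' standard-normal density at the liability threshold).
#'
#' @param prs PRS tibble from [score_pathway()].
#' @param phenotypes Phenotype/covariate tibble with `iid`, `status` (0/1)
#'   and covariate columns.
#' @param covariates Covariate column names (default age, sex, PC1-PC10;
#'   silently restricted to columns actually present).
#' @param prevalence Assumed population prevalence for the liability
#'   transformation (default 0.005).
#' @return One-row tibble `n`, `n_cases`, `n_controls`, `n_snps_used`,
#'   `beta`, `se`, `or`, `ci_lower`, `ci_upper`, `p_asymptotic`,
#'   `liability_r2`.
#' @export
associate <- function(prs, phenotypes,
                      covariates = c("age", "sex", paste0("PC", 1:10)),
                      prevalence = 0.005) {
  d <- prs_design(prs, phenotypes, covariates)
  if (sum(d$y == 1) < 1 || sum(d$y == 0) < 1) {
    abort("need at least one case and one control")
  }
  fit <- glm_prs_z(d$y, d$X)
  if (!fit$converged || abs(fit$beta) > 15) {
    abort("logistic fit did not converge (possible separation): inspect the PRS/phenotype overlap",
          class = "l2g_separation")
  }
  # observed-scale R2 of the PRS alone, then liability transformation
  r2_obs <- suppressWarnings(stats::cor(d$y, d$X[, "prs"])^2)
  if (is.na(r2_obs)) r2_obs <- 0
  K <- prevalence
  P <- mean(d$y)
  zK <- stats::dnorm(stats::qnorm(K))
  r2_liab <- r2_obs * K^2 * (1 - K)^2 / (zK^2 * P * (1 - P))
  tibble(
    n = length(d$y), n_cases = sum(d$y == 1), n_controls = sum(d$y == 0),
    n_snps_used = attr(prs, "n_snps_used") %||% NA_integer_,
    beta = unname(fit$beta), se = unname(fit$se),
    or = exp(unname(fit$beta)),
    ci_lower = exp(unname(fit$beta) - 1.96 * unname(fit$se)),
    ci_upper = exp(unname(fit$beta) + 1.96 * unname(fit$se)),
    p_asymptotic = 2 * stats::pnorm(-abs(unname(fit$z))),
    liability_r2 = unname(r2_liab)
  )
}

#' Label-permutation empirical p-value for a pathway PRS
#'
#' Case/control labels are permuted `n_permutations` times (covariates stay
#' attached to their individuals), the logistic model is refit each time,
#' and the two-sided empirical p-value is
#' `(1 + #( |z_perm| >= |z_obs| )) / (n_permutations + 1)`.
#'
#' @inheritParams associate
#' @param n_permutations Number of label permutations (default 10000; a
#'   warning is raised below 100).
#' @param seed Seed for the permutation stream.
#' @return One-row tibble `z_observed`, `n_permutations`, `p_empirical`.
#' @export
permutation_p <- function(prs, phenotypes,
                          covariates = c("age", "sex", paste0("PC", 1:10)),
                          n_permutations = 10000, seed = 1L) {
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  if (n_permutations < 100) warn("fewer than 100 permutations: empirical p is coarse")
  d <- prs_design(prs, phenotypes, covariates)
  z_obs <- glm_prs_z(d$y, d$X)$z
  withr::with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_permutations)) {
      yp <- d$y[sample.int(length(d$y))]
      zp <- tryCatch(glm_prs_z(yp, d$X)$z, error = function(e) NA_real_)
      if (!is.na(zp) && abs(zp) >= abs(z_obs)) exceed <- exceed + 1L
    }
  })
  tibble(z_observed = unname(z_obs), n_permutations = n_permutations,
         p_empirical = (1 + exceed) / (n_permutations + 1))
}

#' Fixed-effect inverse-variance meta-analysis across cohorts
#'
#' Pools per-cohort log-odds ratios with weights `1/SE^2`, reports the
#' pooled OR/CI/p, Cochran's Q with `k - 1` degrees of freedom for
#' heterogeneity, and a leave-one-out report flagging cohorts whose
#' exclusion removes significant heterogeneity (the flag mirrors the manual
#' exclusion of an outlier cohort; nothing is dropped automatically).
#'
#' @param results Tibble with one row per cohort: `cohort`, `beta`, `se`
#'   (e.g. stacked outputs of [associate()]).
#' @param het_alpha Heterogeneity significance level for flagging
#'   (default 0.05).
#' @return An `l2g_meta` list with `pooled` (one-row tibble: `k`, `beta`,
#'   `se`, `or`, `ci_lower`, `ci_upper`, `p`, `Q`, `het_p`) and
#'   `leave_one_out` (per-cohort Q/het p when that cohort is excluded,
#'   with an `outlier_flag`).
#' @export
meta_analyze <- function(results, het_alpha = 0.05) {
  stopifnot(all(c("beta", "se") %in% names(results)))
  if (!"cohort" %in% names(results)) {
    results$cohort <- sprintf("cohort_%d", seq_len(nrow(results)))
  }
  if (any(!is.finite(results$se)) || any(results$se <= 0)) {
    abort("all cohort SEs must be finite and positive")
  }
  ivw <- function(beta, se) {
    w <- 1 / se^2
    b <- sum(w * beta) / sum(w)
    s <- sqrt(1 / sum(w))
    Q <- sum(w * (beta - b)^2)
    k <- length(beta)
    list(beta = b, se = s, Q = Q,
         het_p = if (k >= 2) stats::pchisq(Q, k - 1, lower.tail = FALSE) else NA_real_)
  }
  k <- nrow(results)
  fit <- ivw(results$beta, results$se)
  pooled <- tibble(
    k = k, beta = fit$beta, se = fit$se,
    or = exp(fit$beta),
    ci_lower = exp(fit$beta - 1.96 * fit$se),
    ci_upper = exp(fit$beta + 1.96 * fit$se),
    p = 2 * stats::pnorm(-abs(fit$beta / fit$se)),
    Q = if (k >= 2) fit$Q else NA_real_,
    het_p = fit$het_p
  )
  loo <- if (k >= 3) {
    purrr::map_dfr(seq_len(k), function(i) {
      f <- ivw(results$beta[-i], results$se[-i])
      tibble(excluded = results$cohort[i], Q = f$Q, het_p = f$het_p)
    }) |>
      mutate(outlier_flag = !is.na(pooled$het_p) & pooled$het_p < het_alpha &
               .data$het_p >= het_alpha)
  } else {
    tibble(excluded = character(0), Q = numeric(0), het_p = numeric(0),
           outlier_flag = logical(0))
  }
  structure(list(pooled = pooled, leave_one_out = loo,
                 cohorts = results$cohort), class = "l2g_meta")
}

#' @export
print.l2g_meta <- function(x, ...) {
  cat(sprintf("<l2g_meta> %d cohort(s)\n", x$pooled$k))
  cat(sprintf("  pooled OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$pooled$or, x$pooled$ci_lower, x$pooled$ci_upper, x$pooled$p))
  if (!is.na(x$pooled$Q)) {
    cat(sprintf("  Cochran's Q = %.3f, het p = %.3g\n", x$pooled$Q, x$pooled$het_p))
  }
  flagged <- x$leave_one_out$excluded[x$leave_one_out$outlier_flag]
  if (length(flagged) > 0) {
    cat("  heterogeneity resolved when excluding:",
        paste(flagged, collapse = ", "), "\n")
  }
  invisible(x)
}
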