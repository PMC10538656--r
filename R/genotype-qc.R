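#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the sum of the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count
#' (Wigginton-style). Computed in log space so it is stable for large counts.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative integers).
#' @return exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)  # exact HWE proportions -> p = 1
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero", call. = FALSE)
  n_a <- 2 * n_aa + n_Aa  # minor-arbitrary allele count
  n_A <- 2 * n_AA + n_Aa
  rare <- min(n_a, n_A)
  # feasible heterozygote counts share the parity of the rare allele count
  het <- seq(rare %% 2, rare, by = 2)
  # log P(n_Aa = h | allele counts): lchoose-based hypergeometric-type mass
  log_p <- lchoose(n, (rare - het) / 2) +
    lchoose(n - (rare - het) / 2, het) +
    lchoose(n - (rare - het) / 2 - het, (2 * n - rare - het) / 2) +
    het * log(2) - lchoose(2 * n, rare)
  log_p <- log_p - max(log_p)
  p_mass <- exp(log_p)
  p_mass <- p_mass / sum(p_mass)
  obs <- p_mass[match(n_Aa, het)]
  min(1, sum(p_mass[p_mass <= obs * (1 + 1e-12)]))
}

.fold_maf <- function(af) pmin(af, 1 - af)

# Per-variant QC statistics; `use` selects the samples the statistics are
# computed on (females only for X variants).
.variant_stats <- function(dosage_col) {
  obs <- !is.na(dosage_col)
  n <- sum(obs)
  if (n == 0) {
    return(list(maf = NA_real_, missingness = 1, hwe_p = NA_real_))
  }
  maf <- .fold_maf(mean(dosage_col[obs]) / 2)
  hard <- round(dosage_col[obs])
  counts <- tabulate(hard + 1, nbins = 3)
  hwe_p <- hwe_exact_test(counts[1], counts[2], counts[3])
  list(maf = maf, missingness = mean(!obs), hwe_p = hwe_p)
}

#' Variant-level genotype QC
#'
#' A variant is excluded when its exact Hardy-Weinberg p-value is below
#' `hwe_p_max`, its missingness exceeds `miss_max`, or its minor allele
#' frequency is below `maf_min` (all inequalities strict, matching the
#' conventional thresholds HWE p < 1e-6, missingness > 0.05, MAF < 0.01).
#' For X-chromosome variants (PAR and non-PAR alike) all three statistics are
#' computed on female samples only; the male samples inherit the female
#' decisions. MAF is computed from dosages (folded mean/2), not hard calls.
#'
#' @param dm a [dosage_matrix()].
#' @param hwe_p_max,miss_max,maf_min thresholds (see Details).
#' @return list with `kept` (variant ids) and `report` (data.frame: variant,
#'   maf, missingness, hwe_p, decision, reason).
#' @export
qc_filter_variants <- function(dm, hwe_p_max = 1e-6, miss_max = 0.05,
                               maf_min = 0.01) {
  is_x <- dm$variants$region != "autosome"
  females <- dm$sex == "female"
  if (any(is_x) && !any(females)) {
    warning("X variants present but no female samples; flagged unevaluable")
  }
  report <- lapply(seq_len(ncol(dm$dosage)), function(j) {
    col <- dm$dosage[, j]
    if (is_x[j]) {
      if (!any(females)) {
        return(data.frame(variant = dm$variants$id[j], maf = NA, missingness = NA,
                          hwe_p = NA, decision = "unevaluable",
                          reason = "no_females", stringsAsFactors = FALSE))
      }
      col <- col[females]
    }
    s <- .variant_stats(col)
    reasons <- c(
      if (!is.na(s$hwe_p) && s$hwe_p < hwe_p_max) "hwe",
      if (s$missingness > miss_max) "missingness",
      if (!is.na(s$maf) && s$maf < maf_min) "maf")
    data.frame(variant = dm$variants$id[j], maf = s$maf,
               missingness = s$missingness, hwe_p = s$hwe_p,
               decision = if (length(reasons)) "exclude" else "keep",
               reason = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, report)
  list(kept = report$variant[report$decision == "keep"], report = report)
}

#' Sample-level missingness filter
#'
#' Samples with more than `miss_max` (default 5%) of their genotypes missing
#' are excluded; a sample at exactly the threshold is kept.
#'
#' @param dm a [dosage_matrix()].
#' @param miss_max maximum tolerated missing fraction.
#' @return character vector of kept sample ids.
#' @export
qc_filter_samples <- function(dm, miss_max = 0.05) {
  frac <- rowMeans(is.na(dm$dosage))
  dm$samples[frac <= miss_max]
}

#' Harmonise male X-chromosome dosages
#'
#' Male genotype dosages in the X non-PAR region are multiplied by two so
#' that they share the 0-2 scale of the female diploid genotypes (then
#' clipped to \[0, 2\]). Male non-PAR hard calls that round to heterozygous —
#' biologically impossible on a haploid region — are set to missing before
#' doubling. Female samples and PAR variants are untouched.
#'
#' @param dm a [dosage_matrix()].
#' @return the harmonised [dosage_matrix()].
#' @export
harmonise_x_dosage <- function(dm) {
  males <- dm$sex == "male"
  nonpar <- dm$variants$region == "X_nonPAR"
  if (!any(males) || !any(nonpar)) return(dm)
  block <- dm$dosage[males, nonpar, drop = FALSE]
  if (any(block > 1 + 1e-8 & abs(block - round(block)) > 0.25, na.rm = TRUE) ||
      any(block > 1.75, na.rm = TRUE)) {
    warning("male non-PAR dosages > 1 before doubling; haploid expectation violated")
  }
  block[!is.na(block) & abs(block - 1) <= 0.25] <- NA  # impossible het calls
  dm$dosage[males, nonpar] <- pmin(2, pmax(0, 2 * block))
  dm
}

#' Post-imputation variant filter
#'
#' Variants are kept when MAF >= `maf_min` and imputation quality R2 >=
#' `r2_min`; a variant with no R2 recorded is excluded (reason `no_r2`).
#'
#' @param dm a [dosage_matrix()] whose `variants` carry an `r2` column.
#' @param maf_min,r2_min thresholds.
#' @return list with `kept` (variant ids) and `report`.
#' @export
post_imputation_filter <- function(dm, maf_min = 0.01, r2_min = 0.4) {
  if (is.null(dm$variants$r2)) {
    stop("variants carry no imputation R2 column", call. = FALSE)
  }
  maf <- .fold_maf(colMeans(dm$dosage, na.rm = TRUE) / 2)
  r2 <- dm$variants$r2
  reason <- character(nrow(dm$variants))
  reason[!is.na(maf) & maf < maf_min] <- "maf"
  low_r2 <- !is.na(r2) & r2 < r2_min
  reason[low_r2] <- trimws(paste(reason[low_r2], "r2"), which = "left")
  reason[is.na(r2)] <- "no_r2"
  keep <- reason == ""
  list(kept = dm$variants$id[keep],
       report = data.frame(variant = dm$variants$id, maf = maf, r2 = r2,
                           decision = ifelse(keep, "keep", "exclude"),
                           reason = reason, stringsAsFactors = FALSE))
}
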