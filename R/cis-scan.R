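#' Define a cis window around a gene
#'
#' The window is +/- `size` bp (default 1 Mb) around the strand-aware
#' transcription start of the gene: the leftmost base for `+` strand genes
#' and the rightmost for `-` strand, clamped at the chromosome bounds.
#'
#' @param gene list/data.frame row with `chromosome`, `start`, `end`
#'   (1-based closed), `strand` and optionally `group_id`.
#' @param size half-window in bp.
#' @param chromosome_length optional upper clamp.
#' @return list with `group_id`, `chromosome`, `start`, `end`, `anchor`.
#' @export
define_cis_window <- function(gene, size = 1e6, chromosome_length = NULL) {
  anchor <- if (identical(gene$strand, "-")) gene$end else gene$start
  start <- max(1, anchor - size)
  end <- anchor + size
  if (!is.null(chromosome_length)) end <- min(end, chromosome_length)
  list(group_id = gene$group_id %||% gene$gene_id %||% NA_character_,
       chromosome = gene$chromosome, start = start, end = end,
       anchor = anchor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Principal components for covariate adjustment
#'
#' Columns are centred and scaled (zero-variance columns dropped) and the
#' first `k` principal component scores are returned with a deterministic
#' sign convention: each component is oriented so that its largest-magnitude
#' loading is positive.
#'
#' @param x samples x features matrix (genotype dosages or standardised
#'   traits).
#' @param k number of components.
#' @param scale. scale columns to unit variance before decomposition
#'   (default TRUE).
#' @return samples x k score matrix.
#' @export
compute_pcs <- function(x, k = 6, scale. = TRUE) {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  x <- x[, !is.na(sds) & sds > 0, drop = FALSE]
  if (k >= min(nrow(x), ncol(x))) {
    stop("k must be smaller than min(n samples, n informative features)",
         call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale., rank. = k)
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

# Residualise columns of m on covariates Z (with intercept); returns the
# residual matrix and the regression degrees of freedom consumed.
.residualise <- function(m, covariates = NULL) {
  n <- nrow(m)
  Z <- cbind(rep(1, n), covariates)
  qz <- qr(Z)
  list(resid = qr.resid(qz, m), rank = qz$rank)
}

#' Nominal cis association scan for one trait
#'
#' Per variant: ordinary least squares of the trait on the dosage plus
#' covariates; reports the effect per alt-allele dosage (`beta`), its
#' standard error, the two-sided t-test p-value, and allele summaries
#' (`maf`, `ac`, `an`) from the observed dosages. Samples with a missing
#' dosage are dropped pairwise per variant. Traits with fewer than
#' `min_variants` variants in the window, or zero variance, are skipped with
#' a classed condition (`qtl_skip`).
#'
#' @param y numeric trait vector (one value per sample).
#' @param dosages samples x variants dosage matrix for the cis window.
#' @param covariates optional samples x q covariate matrix.
#' @param min_variants minimum cis-window variant count (default 5).
#' @param molecular_trait_id,group_id identifiers copied into the records.
#' @return data.frame of summary statistic records (one row per variant).
#' @export
nominal_scan <- function(y, dosages, covariates = NULL, min_variants = 5,
                         molecular_trait_id = "trait", group_id = "group") {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) < min_variants) {
    stop(structure(class = c("qtl_skip", "error", "condition"),
                   list(message = sprintf(
                     "trait %s skipped: %d cis variants < %d",
                     molecular_trait_id, ncol(dosages), min_variants),
                     call = NULL)))
  }
  if (stats::sd(y, na.rm = TRUE) == 0 || all(is.na(y))) {
    stop(structure(class = c("qtl_skip", "error", "condition"),
                   list(message = sprintf("trait %s skipped: zero variance",
                                          molecular_trait_id), call = NULL)))
  }
  vids <- colnames(dosages) %||% paste0("v", seq_len(ncol(dosages)))
  rows <- lapply(seq_len(ncol(dosages)), function(j) {
    g <- dosages[, j]
    use <- !is.na(g) & !is.na(y)
    n <- sum(use)
    an <- 2L * n
    ac <- as.integer(round(sum(g[use])))
    maf <- .fold_maf(mean(g[use]) / 2)
    rec <- data.frame(molecular_trait_id = molecular_trait_id,
                      molecular_trait_object_id = group_id,
                      variant = vids[j], maf = maf, beta = NA_real_,
                      se = NA_real_, pvalue = NA_real_, ac = ac, an = an,
                      n = n, stringsAsFactors = FALSE)
    if (stats::sd(g[use]) == 0) return(rec)  # monomorphic in observed samples
    Zc <- if (is.null(covariates)) NULL else covariates[use, , drop = FALSE]
    r <- .residualise(cbind(y[use], g[use]), Zc)
    yr <- r$resid[, 1]; gr <- r$resid[, 2]
    gg <- sum(gr^2)
    if (gg < 1e-12) return(rec)
    beta <- sum(gr * yr) / gg
    df <- n - r$rank - 1
    rss <- sum(yr^2) - beta^2 * gg
    se <- sqrt(max(rss, 0) / df / gg)
    rec$beta <- beta
    rec$se <- se
    rec$pvalue <- 2 * stats::pt(abs(beta / se), df, lower.tail = FALSE)
    rec
  })
  do.call(rbind, rows)
}

# Min nominal p over a residualised trait block for each permutation of the
# sample labels; the same shuffle is applied to all traits of the group.
.min_p_stat <- function(Gs, Ps, df) {
  r <- crossprod(Gs, Ps)  # correlations (unit-norm columns)
  r2 <- pmin(r^2, 1 - 1e-15)
  tstat <- sqrt(df) * abs(r) / sqrt(1 - r2)
  2 * stats::pt(max(tstat), df, lower.tail = FALSE)
}

#' Group-level permutation p-value
#'
#' The observed statistic is the minimum nominal p over all (trait, variant)
#' pairs of the group. Each permutation shuffles the sample labels of the
#' trait matrix — the same shuffle for every trait of the group, preserving
#' trait-trait correlation — and recomputes the minimum p. The empirical
#' p-value uses the add-one estimator
#' `(1 + #\{perm min-p <= observed\}) / (1 + n_perm)`.
#'
#' Covariates are projected out of both the traits and the dosages first, so
#' the per-variant t-statistics match the covariate-adjusted scan
#' (Frisch-Waugh). Missing dosages are mean-imputed for this scan.
#'
#' @param traits samples x m matrix of the group's (standardised) traits.
#' @param dosages samples x p cis-window dosage matrix.
#' @param covariates optional samples x q covariate matrix.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return list with `empirical_p`, `observed_p`, `lead` (trait, variant),
#'   `n_perm`.
#' @export
group_permutation <- function(traits, dosages, covariates = NULL,
                              n_perm = 1000, seed = 1) {
  if (n_perm < 100) warning("fewer than 100 permutations; empirical p coarse")
  traits <- as.matrix(traits); dosages <- as.matrix(dosages)
  n <- nrow(traits)
  for (j in seq_len(ncol(dosages))) {    # mean-impute missing dosages
    miss <- is.na(dosages[, j])
    if (any(miss)) dosages[miss, j] <- mean(dosages[, j], na.rm = TRUE)
  }
  keep <- apply(dosages, 2, stats::sd) > 0
  dosages <- dosages[, keep, drop = FALSE]
  rz <- .residualise(cbind(traits, dosages), covariates)
  m <- ncol(traits)
  Pr <- rz$resid[, seq_len(m), drop = FALSE]
  Gr <- rz$resid[, -seq_len(m), drop = FALSE]
  unitise <- function(x) sweep(x, 2, sqrt(colSums(x^2)), "/")
  Ps <- unitise(Pr); Gs <- unitise(Gr)
  df <- n - rz$rank - 1
  robs <- crossprod(Gs, Ps)
  r2 <- pmin(robs^2, 1 - 1e-15)
  tobs <- sqrt(df) * abs(robs) / sqrt(1 - r2)
  lead_idx <- which(tobs == max(tobs), arr.ind = TRUE)[1, ]
  observed_p <- 2 * stats::pt(max(tobs), df, lower.tail = FALSE)
  set.seed(seed)
  perm_p <- vapply(seq_len(n_perm), function(i) {
    .min_p_stat(Gs, Ps[sample.int(n), , drop = FALSE], df)
  }, numeric(1))
  list(empirical_p = (1 + sum(perm_p <= observed_p)) / (1 + n_perm),
       observed_p = observed_p,
       lead = c(trait = colnames(traits)[lead_idx["col"]] %||% lead_idx["col"],
                variant = colnames(dosages)[lead_idx["row"]] %||%
                  lead_idx["row"]),
       n_perm = n_perm)
}

#' Dataset-level FDR across groups
#'
#' Benjamini-Hochberg correction of the group-level empirical p-values at
#' `level` (default 1%); returns the significant groups (the "eGenes").
#'
#' @param empirical_p named vector of one empirical p-value per group.
#' @param level FDR level.
#' @return character vector of significant group names.
#' @export
dataset_fdr <- function(empirical_p, level = 0.01) {
  padj <- stats::p.adjust(empirical_p, method = "BH")
  names(empirical_p)[padj <= level]
}

#' Per-exon effect profile of a lead variant
#'
#' For each exon-level trait of a gene: OLS effect of the lead-variant
#' dosage (with covariates), the 95% confidence interval `beta +/- 1.96 se`,
#' and a significance flag from Benjamini-Hochberg at FDR <= 1% across the
#' gene's exons. Exons with zero variance are excluded and noted.
#'
#' @param dosage lead-variant dosage per sample.
#' @param exon_traits samples x exons matrix of standardised exon traits.
#' @param covariates optional covariate matrix.
#' @param fdr_level FDR level for the flag (default 0.01).
#' @return data.frame: exon, beta, se, ci_low, ci_high, pvalue, padj,
#'   significant; attribute `excluded` lists zero-variance exons.
#' @export
exon_effect_profile <- function(dosage, exon_traits, covariates = NULL,
                                fdr_level = 0.01) {
  exon_traits <- as.matrix(exon_traits)
  ids <- colnames(exon_traits) %||% paste0("exon", seq_len(ncol(exon_traits)))
  sds <- apply(exon_traits, 2, stats::sd, na.rm = TRUE)
  excluded <- ids[is.na(sds) | sds == 0]
  keep <- !(ids %in% excluded)
  rows <- lapply(which(keep), function(j) {
    rec <- nominal_scan(exon_traits[, j], cbind(v = dosage), covariates,
                        min_variants = 1, molecular_trait_id = ids[j])
    data.frame(exon = ids[j], beta = rec$beta, se = rec$se,
               pvalue = rec$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ci_low <- out$beta - 1.96 * out$se
  out$ci_high <- out$beta + 1.96 * out$se
  out$padj <- stats::p.adjust(out$pvalue, method = "BH")
  out$significant <- !is.na(out$padj) & out$padj <= fdr_level
  out <- out[, c("exon", "beta", "se", "ci_low", "ci_high", "pvalue", "padj",
                 "significant")]
  attr(out, "excluded") <- excluded
  out
}
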