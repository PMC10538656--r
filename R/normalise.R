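#' Construct a trait matrix
#'
#' Container for molecular trait quantifications: samples x traits values with
#' per-trait metadata (grouping unit and genomic span) and a processing-stage
#' tag. The group is a gene for exon/transcript/event traits and a
#' splice-junction cluster for junction traits.
#'
#' @param values numeric matrix, samples in rows, traits in columns.
#' @param traits data.frame with columns `trait_id`, `group_id` and
#'   optionally `chromosome`, `start`, `end`, `strand`, `method`
#'   (one of `ge`, `exon`, `tx`, `txrevise`, `leafcutter`).
#' @param stage one of `raw`, `tpm`, `usage`, `standardised`.
#' @return object of class `trait_matrix`.
#' @export
trait_matrix <- function(values, traits,
                         stage = c("raw", "tpm", "usage", "standardised")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  stopifnot(ncol(values) == nrow(traits), !is.null(traits$trait_id),
            !is.null(traits$group_id))
  colnames(values) <- traits$trait_id
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  }
  structure(list(values = values, traits = traits,
                 samples = rownames(values), stage = stage),
            class = "trait_matrix")
}

#' @exportS3Method base::print
print.trait_matrix <- function(x, ...) {
  cat("trait_matrix [", x$stage, "]: ", length(x$samples), " samples x ",
      nrow(x$traits), " traits (", length(unique(x$traits$group_id)),
      " groups)\n", sep = "")
  invisible(x)
}

#' Transcripts-per-million normalisation
#'
#' `tpm = (count / effective_length)` rescaled so each sample sums to 1e6.
#'
#' @param counts samples x traits matrix of non-negative read counts.
#' @param effective_lengths per-trait effective lengths (> 0), recycled by
#'   column.
#' @return TPM matrix of the same shape.
#' @export
compute_tpm <- function(counts, effective_lengths) {
  counts <- as.matrix(counts)
  stopifnot(length(effective_lengths) == ncol(counts),
            all(effective_lengths > 0), all(counts >= 0, na.rm = TRUE))
  rate <- sweep(counts, 2, effective_lengths, "/")
  totals <- rowSums(rate, na.rm = TRUE)
  if (any(totals == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(rownames(counts)[totals == 0], collapse = ", "), call. = FALSE)
  }
  sweep(rate, 1, totals, "/") * 1e6
}

#' Low-expression filter
#'
#' A trait is excluded when at least `frac` (default 95%) of the samples
#' have TPM below `threshold` (default 1): reaching the 95% fraction
#' triggers exclusion.
#'
#' @param tpm samples x traits TPM matrix.
#' @param threshold TPM cut-off.
#' @param frac fraction of low samples at or above which the trait is dropped.
#' @return character vector of kept trait (column) names.
#' @export
low_expression_filter <- function(tpm, threshold = 1, frac = 0.95) {
  low_frac <- colMeans(tpm < threshold, na.rm = TRUE)
  colnames(tpm)[low_frac < frac]
}

#' Usage ratios within trait groups
#'
#' Divides each trait's expression by the per-sample total over all traits of
#' its group (all transcripts of a gene, all junctions of a cluster). A
#' sample whose group total is zero gets missing usages for that group.
#' Groups of a single trait are degenerate (usage identically 1) and trigger
#' a warning.
#'
#' @param expr samples x traits non-negative expression matrix.
#' @param grouping per-trait group id vector (column order).
#' @return usage matrix of the same shape; rows of each group sum to 1 over
#'   non-missing entries.
#' @export
usage_ratios <- function(expr, grouping) {
  expr <- as.matrix(expr)
  stopifnot(length(grouping) == ncol(expr), all(expr >= 0, na.rm = TRUE))
  sizes <- table(grouping)
  if (any(sizes == 1)) {
    warning("degenerate singleton group(s): ",
            paste(names(sizes)[sizes == 1], collapse = ", "))
  }
  out <- expr
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    tot <- rowSums(expr[, idx, drop = FALSE], na.rm = TRUE)
    tot[tot == 0] <- NA
    out[, idx] <- expr[, idx, drop = FALSE] / tot
  }
  out
}

#' Rank-based inverse normal transform
#'
#' Maps values onto standard normal quantiles via
#' `qnorm((rank - 0.5) / n)` with ties assigned their average rank; missing
#' values propagate. The transform depends only on ranks, so any monotone
#' transformation of the input yields identical output.
#'
#' @param x numeric vector (or samples x traits matrix, transformed per
#'   column).
#' @return transformed vector/matrix of the same shape.
#' @export
inverse_normal_transform <- function(x) {
  if (is.matrix(x)) {
    res <- apply(x, 2, inverse_normal_transform)
    dimnames(res) <- dimnames(x)
    return(res)
  }
  out <- rep(NA_real_, length(x))
  obs <- !is.na(x)
  n <- sum(obs)
  if (n < 2) return(out)
  r <- rank(x[obs], ties.method = "average")
  out[obs] <- stats::qnorm((r - 0.5) / n)
  out
}

#' Remove per-sample GC-content trends from count data
#'
#' A light-weight GC correction for gene/exon counts: per sample, a loess
#' curve of length-normalised log2 counts on trait GC content is fitted and
#' subtracted, then each trait is re-centred on its original mean. This
#' removes sample-specific systematic GC trends (the dominant artefact of
#' library preparation chemistry); it performs smooth trend removal only, not
#' full conditional quantile normalisation.
#'
#' @param counts samples x traits non-negative counts.
#' @param gc per-trait GC fraction in (0, 1).
#' @param lengths optional per-trait lengths for length normalisation.
#' @param span loess span.
#' @return samples x traits matrix of adjusted log2 expression.
#' @export
gc_correct <- function(counts, gc, lengths = NULL, span = 0.75) {
  counts <- as.matrix(counts)
  stopifnot(length(gc) == ncol(counts), all(gc > 0 & gc < 1))
  if (is.null(lengths)) lengths <- rep(1000, ncol(counts))
  y <- log2(sweep(counts + 0.5, 2, lengths / 1000, "/"))
  if (ncol(counts) < 20) {
    warning("fewer than 20 traits; GC correction skipped")
    return(y)
  }
  adj <- y
  for (i in seq_len(nrow(y))) {
    fit <- stats::loess(y[i, ] ~ gc, span = span, degree = 1,
                        family = "gaussian")
    adj[i, ] <- y[i, ] - stats::predict(fit, gc)
  }
  # re-centre each trait on its pre-correction mean
  sweep(adj, 2, colMeans(y, na.rm = TRUE) - colMeans(adj, na.rm = TRUE), "+")
}

#' Full normalisation pipeline for one quantification method
#'
#' Gene and exon counts: GC correction, low-expression filter (gene level),
#' then the inverse normal transform. Transcript / event / junction
#' expression: usage ratios within groups, then the inverse normal transform.
#'
#' @param tm a [trait_matrix()] at stage `raw` (counts or TPM as appropriate
#'   for the method).
#' @param method quantification method.
#' @param gc,lengths per-trait covariates for the count-based methods.
#' @param tpm optional TPM matrix for the low-expression filter (gene level).
#' @return a [trait_matrix()] at stage `standardised`.
#' @export
normalise_traits <- function(tm, method = c("ge", "exon", "tx", "txrevise",
                                            "leafcutter"),
                             gc = NULL, lengths = NULL, tpm = NULL) {
  method <- match.arg(method)
  vals <- tm$values
  traits <- tm$traits
  if (method %in% c("ge", "exon")) {
    if (!is.null(gc)) vals <- gc_correct(vals, gc, lengths)
    if (method == "ge" && !is.null(tpm)) {
      kept <- low_expression_filter(tpm)
      keep_idx <- traits$trait_id %in% kept
      vals <- vals[, keep_idx, drop = FALSE]
      traits <- traits[keep_idx, , drop = FALSE]
    }
  } else {
    vals <- usage_ratios(vals, traits$group_id)
  }
  std <- inverse_normal_transform(vals)
  # zero-variance traits cannot be rank-standardised meaningfully
  sdv <- apply(std, 2, stats::sd, na.rm = TRUE)
  keep <- !is.na(sdv) & sdv > 0
  trait_matrix(std[, keep, drop = FALSE], traits[keep, , drop = FALSE],
               stage = "standardised")
}
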