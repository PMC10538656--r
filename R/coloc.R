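.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(e^x - e^y) for x > y, stable; -Inf when y >= x.
.logdiff <- function(x, y) {
  if (y >= x) return(-Inf)
  x + log1p(-exp(y - x))
}

#' Signal-level colocalisation from log Bayes factors
#'
#' Given the per-variant natural-log Bayes factors of two independently
#' fine-mapped signals over a shared cis region, computes the posterior
#' probabilities of the five colocalisation hypotheses: H0 no association,
#' H1/H2 association in one study only, H3 two distinct causal variants, H4
#' one shared causal variant. With `a`, `b` the LBF vectors over the K
#' shared variants and `S1 = logsumexp(a)`, `S2 = logsumexp(b)`,
#' `S12 = logsumexp(a + b)`, the unnormalised log posterior weights are
#' `0`, `log(p1) + S1`, `log(p2) + S2`,
#' `log(p1) + log(p2) + log(exp(S1 + S2) - exp(S12))` and
#' `log(p12) + S12`; the posteriors are their softmax. All arithmetic is in
#' log space; the H3 weight is `-Inf` when only one variant is shared or
#' when `S1 + S2 <= S12` numerically.
#'
#' Variants are intersected on canonical ids; an id missing from one side is
#' rescued when its complement-swapped alias (ref/alt swapped and strand
#' complemented) matches.
#'
#' @param lbf_a,lbf_b named numeric vectors of log Bayes factors (names are
#'   canonical variant ids).
#' @param p1,p2,p12 prior probabilities that a variant is causal for study 1
#'   only, study 2 only, or both (defaults 1e-4, 1e-4, 5e-6).
#' @return object of class `coloc_result`: list with `pp` (named PP0..PP4,
#'   summing to 1), `n_shared_variants`, `priors`.
#' @export
pairwise_coloc <- function(lbf_a, lbf_b, p1 = 1e-4, p2 = 1e-4, p12 = 5e-6) {
  if (anyNA(lbf_a) || anyNA(lbf_b) || any(!is.finite(c(lbf_a, lbf_b)))) {
    stop("non-finite log Bayes factors", call. = FALSE)
  }
  shared <- intersect(names(lbf_a), names(lbf_b))
  only_a <- setdiff(names(lbf_a), shared)
  if (length(only_a)) {   # rescue strand-flip representations
    alias <- variant_id_flip_alias(only_a)
    hit <- alias %in% setdiff(names(lbf_b), shared)
    if (any(hit)) {
      names(lbf_a)[match(only_a[hit], names(lbf_a))] <- alias[hit]
      shared <- intersect(names(lbf_a), names(lbf_b))
    }
  }
  if (length(shared) == 0) {
    stop("no shared variants between the two signals", call. = FALSE)
  }
  a <- lbf_a[shared]; b <- lbf_b[shared]
  s1 <- .logsumexp(a); s2 <- .logsumexp(b); s12 <- .logsumexp(a + b)
  lh3 <- if (length(shared) == 1) -Inf else
    log(p1) + log(p2) + .logdiff(s1 + s2, s12)
  lw <- c(PP0 = 0, PP1 = log(p1) + s1, PP2 = log(p2) + s2, PP3 = lh3,
          PP4 = log(p12) + s12)
  lw <- lw - max(lw)
  pp <- exp(lw) / sum(exp(lw))
  structure(list(pp = pp, n_shared_variants = length(shared),
                 priors = c(p1 = p1, p2 = p2, p12 = p12)),
            class = "coloc_result")
}

#' @exportS3Method base::print
print.coloc_result <- function(x, ...) {
  cat("coloc_result over", x$n_shared_variants, "shared variants\n")
  print(round(x$pp, 4))
  invisible(x)
}

#' Colocalisation scan over all signal pairs
#'
#' Evaluates every cross pair of fine-mapped signals between a molecular QTL
#' study and a GWAS within each region, flagging pairs with PP4 strictly
#' above `threshold` as colocalised. At most `max_signals` signals per
#' trait/locus are used (extra signals are dropped with a warning); pairs
#' with no variant overlap are skipped with a message.
#'
#' @param qtl_lbf,gwas_lbf long-format log-Bayes-factor tables
#'   (`molecular_trait_id`, `signal_index`, `variant`, `lbf`) as read by
#'   [read_lbf()].
#' @param threshold PP4 reporting threshold (default 0.9, strict).
#' @param max_signals per-locus signal cap (default 10).
#' @param p1,p2,p12 priors passed to [pairwise_coloc()].
#' @return data.frame: one row per evaluated pair with PP0..PP4, `nsnps`
#'   and `colocalised`.
#' @export
coloc_scan <- function(qtl_lbf, gwas_lbf, threshold = 0.9, max_signals = 10,
                       p1 = 1e-4, p2 = 1e-4, p12 = 5e-6) {
  cap_signals <- function(df, label) {
    keep <- list()
    for (tr in unique(df$molecular_trait_id)) {
      d <- df[df$molecular_trait_id == tr, , drop = FALSE]
      sig <- sort(unique(d$signal_index))
      if (length(sig) > max_signals) {
        warning(label, " ", tr, ": ", length(sig), " signals supplied, using ",
                max_signals)
        sig <- sig[seq_len(max_signals)]
      }
      keep[[tr]] <- d[d$signal_index %in% sig, , drop = FALSE]
    }
    do.call(rbind, keep)
  }
  qtl_lbf <- cap_signals(qtl_lbf, "QTL trait")
  gwas_lbf <- cap_signals(gwas_lbf, "GWAS locus")
  as_vectors <- function(df) {
    lapply(split(df, list(df$molecular_trait_id, df$signal_index),
                 drop = TRUE),
           function(d) stats::setNames(d$lbf, d$variant))
  }
  qs <- as_vectors(qtl_lbf); gs <- as_vectors(gwas_lbf)
  rows <- list()
  for (qn in names(qs)) {
    for (gn in names(gs)) {
      res <- tryCatch(pairwise_coloc(qs[[qn]], gs[[gn]], p1, p2, p12),
                      error = function(e) e)
      if (inherits(res, "error")) {
        message("pair ", qn, " x ", gn, " skipped: ", conditionMessage(res))
        next
      }
      rows[[paste(qn, gn)]] <- data.frame(
        qtl_signal = qn, gwas_signal = gn, nsnps = res$n_shared_variants,
        PP0 = res$pp["PP0"], PP1 = res$pp["PP1"], PP2 = res$pp["PP2"],
        PP3 = res$pp["PP3"], PP4 = res$pp["PP4"],
        colocalised = unname(res$pp["PP4"] > threshold),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(qtl_signal = character(0), gwas_signal = character(0),
               nsnps = integer(0), PP0 = numeric(0), PP1 = numeric(0),
               PP2 = numeric(0), PP3 = numeric(0), PP4 = numeric(0),
               colocalised = logical(0))
  rownames(out) <- NULL
  out
}
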