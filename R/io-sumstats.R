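# Plain TSV reading/writing over base connections; file() transparently
# decompresses gzip, and a ".gz" output suffix selects a gzfile() sink.
.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.write_tsv <- function(df, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.sumstat_cols <- c("molecular_trait_id", "molecular_trait_object_id",
                   "variant", "chromosome", "position", "ref", "alt",
                   "maf", "beta", "se", "pvalue", "ac", "an")

.cs_cols <- c("molecular_trait_id", "molecular_trait_object_id", "cs_id",
              "variant", "pip", "z")

.lbf_cols <- c("molecular_trait_id", "signal_index", "variant", "lbf")

.check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(what, ": missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

# Fill chromosome/position/ref/alt from the variant id column where absent,
# erroring with the offending line number on unparseable ids.
.expand_variant_column <- function(df) {
  parsed <- tryCatch(parse_variant_id(df$variant), error = function(e) e)
  if (inherits(parsed, "error")) {
    stop("variant id parse failure: ", conditionMessage(parsed), call. = FALSE)
  }
  for (col in c("chromosome", "position", "ref", "alt")) {
    if (is.null(df[[col]])) df[[col]] <- parsed[[col]]
  }
  df
}

#' Read eQTL-Catalogue-style summary statistics
#'
#' Tab-separated, one association per row, with the fixed column set
#' `molecular_trait_id`, `molecular_trait_object_id`, `variant`, `chromosome`,
#' `position`, `ref`, `alt`, `maf`, `beta`, `se`, `pvalue`, `ac`, `an`.
#' Gzipped files are accepted. Columns `chromosome`/`position`/`ref`/`alt`
#' are reconstructed from `variant` when absent; any extra columns are
#' preserved untouched.
#'
#' @param path file path (optionally `.gz`).
#' @return data.frame of summary statistic records.
#' @export
read_sumstats <- function(path) {
  df <- .read_tsv(path)
  .check_columns(df, setdiff(.sumstat_cols,
                             c("chromosome", "position", "ref", "alt")),
                 "summary statistics")
  df <- .expand_variant_column(df)
  if (any(df$ac > df$an)) {
    stop("summary statistics: ac exceeds an", call. = FALSE)
  }
  df
}

#' Write summary statistics, sorted by genomic position
#'
#' @param records data.frame as returned by [read_sumstats()].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(records, path) {
  .check_columns(records, setdiff(.sumstat_cols,
                                  c("chromosome", "position", "ref", "alt")),
                 "summary statistics")
  records <- .expand_variant_column(records)
  ord <- order(records$chromosome, records$position)
  .write_tsv(records[ord, , drop = FALSE], path)
  invisible(path)
}

#' Read fine-mapped credible sets
#'
#' Long-format table with one row per credible-set member variant: columns
#' `molecular_trait_id`, `molecular_trait_object_id`, `cs_id`, `variant`,
#' `pip`, `z`. `cs_id` identifies one independent signal of one trait
#' (conventionally `<trait>_L<signal>`).
#'
#' @param path file path (optionally `.gz`).
#' @return data.frame of credible-set records.
#' @export
read_credible_sets <- function(path) {
  df <- .read_tsv(path)
  .check_columns(df, .cs_cols, "credible sets")
  df <- .expand_variant_column(df)
  if (any(df$pip < 0 | df$pip > 1, na.rm = TRUE)) {
    stop("credible sets: pip outside [0,1]", call. = FALSE)
  }
  df
}

#' @rdname read_credible_sets
#' @param records data.frame of credible-set records.
#' @export
write_credible_sets <- function(records, path) {
  .check_columns(records, .cs_cols, "credible sets")
  .write_tsv(records[order(records$cs_id), , drop = FALSE], path)
  invisible(path)
}

#' Read per-signal log Bayes factors
#'
#' Long-format table: `molecular_trait_id`, `signal_index` (1..L),
#' `variant`, `lbf` (natural-log Bayes factor of the variant being causal for
#' that signal). The long layout keeps the reader agnostic to the number of
#' signals per trait.
#'
#' @param path file path (optionally `.gz`).
#' @return data.frame of log-Bayes-factor records.
#' @export
read_lbf <- function(path) {
  df <- .read_tsv(path)
  .check_columns(df, .lbf_cols, "log Bayes factors")
  df <- .expand_variant_column(df)
  df
}

#' @rdname read_lbf
#' @param records data.frame of log-Bayes-factor records.
#' @export
write_lbf <- function(records, path) {
  .check_columns(records, .lbf_cols, "log Bayes factors")
  ord <- order(records$molecular_trait_id, records$signal_index)
  .write_tsv(records[ord, , drop = FALSE], path)
  invisible(path)
}
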