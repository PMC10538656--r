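#' Read transcript models from GFF3
#'
#' Parses gene/transcript/exon features (GENCODE conventions, `Parent`
#' attributes) into a flat exon table. All coordinates are converted to the
#' package's internal 0-based half-open convention; [write_gff3()] converts
#' back, so GFF3 round-trips losslessly.
#'
#' @param path GFF3 file.
#' @return object of class `transcript_models`: a list with `exons`
#'   (data.frame: `transcript_id`, `gene_id`, `chromosome`, `strand`,
#'   `start`, `end` — 0-based half-open) and `transcripts` (data.frame:
#'   `transcript_id`, `gene_id`, `chromosome`, `strand`, `start`, `end`).
#' @export
read_transcript_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  type <- as.character(df$type)
  tx_types <- c("mRNA", "transcript")
  tx <- df[type %in% tx_types, , drop = FALSE]
  ex <- df[type == "exon", , drop = FALSE]
  if (nrow(ex) == 0) stop("GFF3 contains no exon features", call. = FALSE)
  if (is.null(ex$Parent)) {
    stop("exon feature without Parent attribute", call. = FALSE)
  }
  ex_parent <- vapply(ex$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[1])
  }, character(1))
  if (anyNA(ex_parent)) {
    stop("exon feature without Parent attribute", call. = FALSE)
  }
  tx_id <- as.character(tx$ID)
  tx_gene <- vapply(tx$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[1])
  }, character(1))
  gene_of <- stats::setNames(tx_gene, tx_id)
  exons <- data.frame(
    transcript_id = ex_parent,
    gene_id = unname(gene_of[ex_parent]),
    chromosome = as.character(ex$seqnames),
    strand = as.character(ex$strand),
    start = ex$start - 1L,  # to 0-based half-open
    end = ex$end,
    stringsAsFactors = FALSE)
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  transcripts <- do.call(rbind, lapply(split(exons, exons$transcript_id),
    function(e) data.frame(
      transcript_id = e$transcript_id[1], gene_id = e$gene_id[1],
      chromosome = e$chromosome[1], strand = e$strand[1],
      start = min(e$start), end = max(e$end), stringsAsFactors = FALSE)))
  rownames(transcripts) <- NULL
  structure(list(exons = exons, transcripts = transcripts),
            class = "transcript_models")
}

#' @exportS3Method base::print
print.transcript_models <- function(x, ...) {
  cat("transcript_models:", nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons\n")
  invisible(x)
}

#' Write transcript models as GFF3
#'
#' @param models a `transcript_models` object (internal 0-based half-open
#'   coordinates; written back as 1-based closed GFF3).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  ex <- models$exons
  tx <- models$transcripts
  genes <- do.call(rbind, lapply(split(tx, tx$gene_id), function(t) {
    data.frame(gene_id = t$gene_id[1], chromosome = t$chromosome[1],
               strand = t$strand[1], start = min(t$start), end = max(t$end),
               stringsAsFactors = FALSE)
  }))
  lines <- c("##gff-version 3",
    sprintf("%s\tqtlcurator\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            genes$chromosome, genes$start + 1L, genes$end, genes$strand,
            genes$gene_id),
    sprintf("%s\tqtlcurator\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
            tx$chromosome, tx$start + 1L, tx$end, tx$strand,
            tx$transcript_id, tx$gene_id),
    sprintf("%s\tqtlcurator\texon\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
            ex$chromosome, ex$start + 1L, ex$end, ex$strand,
            paste0(ex$transcript_id, ":exon", seq_len(nrow(ex))),
            ex$transcript_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' bedGraph intervals are 0-based half-open; they are kept in that convention
#' internally. Overlapping intervals are rejected — binned coverage written by
#' standard coverage tools is always disjoint.
#'
#' @param path bedGraph file.
#' @return data.frame with `chromosome`, `start`, `end` (0-based half-open)
#'   and `score`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- data.frame(chromosome = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   score = gr$score, stringsAsFactors = FALSE)
  df <- df[order(df$chromosome, df$start), , drop = FALSE]
  by_chr <- split(df, df$chromosome)
  for (d in by_chr) {
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      stop("overlapping bedGraph intervals on ", d$chromosome[1],
           call. = FALSE)
    }
  }
  rownames(df) <- NULL
  df
}

#' Write a bedGraph coverage track
#'
#' @param track data.frame with `chromosome`, `start`, `end` (0-based
#'   half-open) and `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  ord <- order(track$chromosome, track$start)
  writeLines(sprintf("%s\t%d\t%d\t%s", track$chromosome[ord],
                     as.integer(track$start[ord]), as.integer(track$end[ord]),
                     formatC(track$score[ord], format = "g", digits = 8)),
             path)
  invisible(path)
}

#' Binned coverage over a query span
#'
#' Averages a bedGraph track into fixed-width bins over the requested
#' 0-based half-open span; bases not covered by any interval count as 0.
#'
#' @param track data.frame from [read_bedgraph()].
#' @param chromosome chromosome name.
#' @param start,end query span, 0-based half-open.
#' @param bin bin width in bp (default 5, the convention used when coverage
#'   files are generated with 5-bp bins).
#' @return numeric vector of length `ceiling((end - start) / bin)`.
#' @export
coverage_vector <- function(track, chromosome, start, end, bin = 5L) {
  stopifnot(end > start, bin >= 1)
  n_bins <- ceiling((end - start) / bin)
  out <- numeric(n_bins)
  d <- track[track$chromosome == chromosome &
               track$end > start & track$start < end, , drop = FALSE]
  if (nrow(d) == 0) return(out)
  # accumulate base-weighted sums per bin
  sums <- numeric(n_bins)
  for (i in seq_len(nrow(d))) {
    s <- max(d$start[i], start); e <- min(d$end[i], end)
    b0 <- (s - start) %/% bin; b1 <- (e - 1 - start) %/% bin
    for (b in b0:b1) {
      lo <- start + b * bin; hi <- min(lo + bin, end)
      ov <- min(e, hi) - max(s, lo)
      sums[b + 1] <- sums[b + 1] + ov * d$score[i]
    }
  }
  widths <- pmin(start + seq_len(n_bins) * bin, end) -
    (start + (seq_len(n_bins) - 1) * bin)
  sums / widths
}
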