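#' Piecewise-linear coordinate map with fixed-width introns
#'
#' Builds the transform used by QTL coverage plots: the union of exons across
#' the displayed transcripts is merged and kept at real scale, while every
#' intervening intron is compressed to a fixed target width (default 50 nt)
#' so that exonic coverage variation dominates the plot. Optional flanks are
#' included either side at real scale. The map is strictly increasing,
#' length-preserving (hence invertible) on exonic bases, and its total target
#' length is `sum(merged exon lengths) + intron_width * n_gaps + 2 * flank`.
#'
#' @param exons data.frame with `start`, `end` (0-based half-open, one
#'   chromosome) — typically the exon union of the displayed transcripts.
#' @param intron_width target width of every intron in bp.
#' @param flank real-scale bp included either side of the exon span.
#' @return object of class `coordinate_map` with a `segments` table
#'   (`real_start`, `real_end`, `target_start`, `target_end`, `type`).
#' @export
build_coordinate_map <- function(exons, intron_width = 50, flank = 0) {
  if (nrow(exons) == 0) stop("empty exon list", call. = FALSE)
  ex <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  # union-merge overlapping or touching exons
  merged <- list(c(ex$start[1], ex$end[1]))
  for (i in seq_len(nrow(ex))[-1]) {
    last <- merged[[length(merged)]]
    if (ex$start[i] <= last[2]) {
      merged[[length(merged)]][2] <- max(last[2], ex$end[i])
    } else {
      merged[[length(merged) + 1]] <- c(ex$start[i], ex$end[i])
    }
  }
  m <- do.call(rbind, merged)
  segs <- list()
  cursor <- 0
  add <- function(rs, re, tlen, type) {
    segs[[length(segs) + 1]] <<- data.frame(
      real_start = rs, real_end = re, target_start = cursor,
      target_end = cursor + tlen, type = type, stringsAsFactors = FALSE)
    cursor <<- cursor + tlen
  }
  if (flank > 0) add(m[1, 1] - flank, m[1, 1], flank, "flank")
  for (i in seq_len(nrow(m))) {
    if (i > 1) add(m[i - 1, 2], m[i, 1], intron_width, "intron")
    add(m[i, 1], m[i, 2], m[i, 2] - m[i, 1], "exon")
  }
  if (flank > 0) add(m[nrow(m), 2], m[nrow(m), 2] + flank, flank, "flank")
  structure(list(segments = do.call(rbind, segs),
                 intron_width = intron_width, flank = flank),
            class = "coordinate_map")
}

#' @exportS3Method base::print
print.coordinate_map <- function(x, ...) {
  s <- x$segments
  cat("coordinate_map:", sum(s$type == "exon"), "exon segment(s),",
      sum(s$type == "intron"), "intron(s) at width", x$intron_width,
      "| target length", max(s$target_end), "\n")
  invisible(x)
}

#' Map real genomic positions onto the rescaled axis
#'
#' Exonic (and flank) positions map length-preservingly; intronic positions
#' are compressed linearly into the fixed intron width. Positions outside
#' the mapped region return `NA`.
#'
#' @param cmap a [build_coordinate_map()] object.
#' @param pos real-scale positions (0-based).
#' @return target-scale positions.
#' @export
map_to_target <- function(cmap, pos) {
  s <- cmap$segments
  out <- rep(NA_real_, length(pos))
  for (i in seq_len(nrow(s))) {
    in_seg <- !is.na(pos) & pos >= s$real_start[i] & pos < s$real_end[i]
    if (!any(in_seg)) next
    scale <- (s$target_end[i] - s$target_start[i]) /
      (s$real_end[i] - s$real_start[i])
    out[in_seg] <- s$target_start[i] + (pos[in_seg] - s$real_start[i]) * scale
  }
  out
}

#' @rdname map_to_target
#' @param target target-scale positions to map back to the real scale
#'   (exact on exonic bases).
#' @export
map_from_target <- function(cmap, target) {
  s <- cmap$segments
  out <- rep(NA_real_, length(target))
  for (i in seq_len(nrow(s))) {
    in_seg <- !is.na(target) & target >= s$target_start[i] &
      target < s$target_end[i]
    if (!any(in_seg)) next
    scale <- (s$real_end[i] - s$real_start[i]) /
      (s$target_end[i] - s$target_start[i])
    out[in_seg] <- s$real_start[i] +
      (target[in_seg] - s$target_start[i]) * scale
  }
  out
}

#' Rescale a binned coverage vector onto the fixed-intron axis
#'
#' @param coverage per-bin coverage over the real-scale region.
#' @param cov_start 0-based start of the coverage vector's span.
#' @param cmap a [build_coordinate_map()] object.
#' @param bin bin width of the input (and output) coverage.
#' @return per-bin coverage on the target scale (length
#'   `ceiling(target_length / bin)`), averaging real-scale bases that map
#'   into each target bin.
#' @export
rescale_coverage <- function(coverage, cov_start, cmap, bin = 5L) {
  s <- cmap$segments
  t_len <- max(s$target_end)
  bases <- seq.int(min(s$real_start), max(s$real_end) - 1L)
  src_bin <- (bases - cov_start) %/% bin + 1L
  val <- ifelse(src_bin >= 1 & src_bin <= length(coverage),
                coverage[pmax(pmin(src_bin, length(coverage)), 1L)], 0)
  tpos <- map_to_target(cmap, bases)
  ok <- !is.na(tpos)
  tb <- pmin(floor(tpos[ok] / bin) + 1L, ceiling(t_len / bin))
  sums <- tapply(val[ok], tb, sum)
  counts <- tapply(val[ok], tb, length)
  out <- numeric(ceiling(t_len / bin))
  out[as.integer(names(sums))] <- sums / counts
  out
}

#' Genotype-stratified mean coverage
#'
#' Samples are assigned to genotype classes 0/1/2 by rounding their dosage;
#' samples whose dosage is more than 0.25 from an integer are dropped from
#' the stratification (and counted). Each retained sample's coverage vector
#' is divided by its own mean over the span — making the class means
#' invariant to per-sample sequencing depth — and the per-class arithmetic
#' mean is returned. Classes with no samples are omitted.
#'
#' @param coverage samples x bins matrix of coverage over a common span.
#' @param dosages per-sample dosage at the stratifying variant.
#' @return object of class `stratified_coverage`: list with `means`
#'   (classes x bins), `class_counts`, `n_dropped`.
#' @export
stratify_coverage <- function(coverage, dosages) {
  coverage <- as.matrix(coverage)
  stopifnot(nrow(coverage) == length(dosages))
  cls <- round(dosages)
  ok <- !is.na(dosages) & abs(dosages - cls) <= 0.25
  sample_means <- rowMeans(coverage)
  ok <- ok & sample_means > 0
  if (!any(ok)) stop("all samples dropped from stratification", call. = FALSE)
  norm <- coverage[ok, , drop = FALSE] / sample_means[ok]
  cls <- cls[ok]
  classes <- sort(unique(cls))
  means <- t(vapply(classes, function(c) {
    colMeans(norm[cls == c, , drop = FALSE])
  }, numeric(ncol(coverage))))
  rownames(means) <- as.character(classes)
  structure(list(means = means,
                 class_counts = stats::setNames(
                   as.integer(table(factor(cls, levels = classes))),
                   as.character(classes)),
                 n_dropped = sum(!ok)),
            class = "stratified_coverage")
}

#' @exportS3Method base::print
print.stratified_coverage <- function(x, ...) {
  cat("stratified_coverage:", nrow(x$means), "genotype class(es) x",
      ncol(x$means), "bins;", x$n_dropped, "sample(s) dropped\n")
  invisible(x)
}

#' Render a QTL coverage plot
#'
#' Composes the three-panel figure used to interpret transcript-level QTLs:
#' (A) genotype-stratified mean read coverage on the fixed-intron axis, (B)
#' per-exon effect sizes of the lead variant with 95% confidence intervals
#' (significant exons highlighted), and (C) the transcript structures used
#' in testing. Every rendered number is also emitted as a plain table
#' (`<prefix>_coverage.tsv`, `<prefix>_exon_effects.tsv`,
#' `<prefix>_tracks.tsv`) so downstream checks never need image diffing. A
#' missing panel input leaves that panel out with a note.
#'
#' @param strat a [stratify_coverage()] result (or NULL).
#' @param effects an [exon_effect_profile()] table, optionally with
#'   `start`/`end` exon coordinates (0-based, real scale); or NULL.
#' @param models a `transcript_models` object (or NULL).
#' @param cmap the shared [build_coordinate_map()].
#' @param out_prefix output path prefix; the image lands at
#'   `<prefix>.png` (falling back to pdf when png is unavailable).
#' @param bin coverage bin width.
#' @return (invisibly) list with the three tables and the image path.
#' @export
render_qtl_plot <- function(strat, effects, models, cmap, out_prefix,
                            bin = 5L) {
  t_max <- max(cmap$segments$target_end)
  tables <- list(coverage = NULL, exon_effects = NULL, tracks = NULL)
  panels <- list()

  if (!is.null(strat)) {
    nb <- ncol(strat$means)
    cov_tab <- do.call(rbind, lapply(rownames(strat$means), function(cl) {
      data.frame(genotype_class = cl,
                 target_start = (seq_len(nb) - 1) * bin,
                 coverage = strat$means[cl, ], stringsAsFactors = FALSE)
    }))
    tables$coverage <- cov_tab
    panels$A <- ggplot2::ggplot(cov_tab, ggplot2::aes(
        x = .data$target_start, y = .data$coverage,
        colour = .data$genotype_class)) +
      ggplot2::geom_step() +
      ggplot2::coord_cartesian(xlim = c(0, t_max)) +
      ggplot2::labs(x = NULL, y = "normalised coverage", colour = "genotype") +
      ggplot2::theme_minimal()
  } else {
    message("coverage panel omitted: no stratified coverage supplied")
  }

  if (!is.null(effects)) {
    eff <- effects
    if (!is.null(eff$start)) {
      eff$target_mid <- map_to_target(cmap, (eff$start + eff$end) / 2)
    } else {
      eff$target_mid <- seq(0, t_max, length.out = nrow(eff) + 2)[-c(1, nrow(eff) + 2)]
    }
    tables$exon_effects <- eff
    panels$B <- ggplot2::ggplot(eff, ggplot2::aes(
        x = .data$target_mid, y = .data$beta, colour = .data$significant)) +
      ggplot2::geom_point() +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high), width = 0) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::scale_colour_manual(values = c(`TRUE` = "darkblue",
                                              `FALSE` = "grey60")) +
      ggplot2::coord_cartesian(xlim = c(0, t_max)) +
      ggplot2::labs(x = NULL, y = "exon effect (95% CI)") +
      ggplot2::theme_minimal()
  } else {
    message("effect panel omitted: no exon effects supplied")
  }

  if (!is.null(models)) {
    ex <- models$exons
    tracks <- data.frame(transcript_id = ex$transcript_id,
                         target_start = map_to_target(cmap, ex$start),
                         target_end = map_to_target(cmap, ex$end - 1L) + 1,
                         stringsAsFactors = FALSE)
    tables$tracks <- tracks
    tracks$y <- as.integer(factor(tracks$transcript_id))
    spines <- do.call(rbind, lapply(split(tracks, tracks$y), function(d) {
      data.frame(y = d$y[1], x0 = min(d$target_start),
                 x1 = max(d$target_end))
    }))
    panels$C <- ggplot2::ggplot(tracks) +
      ggplot2::geom_segment(data = spines,
                            ggplot2::aes(x = .data$x0, xend = .data$x1,
                                         y = .data$y, yend = .data$y)) +
      ggplot2::geom_rect(ggplot2::aes(xmin = .data$target_start,
                                      xmax = .data$target_end,
                                      ymin = .data$y - 0.3,
                                      ymax = .data$y + 0.3)) +
      ggplot2::scale_y_continuous(
        breaks = unique(tracks$y),
        labels = unique(tracks$transcript_id)) +
      ggplot2::coord_cartesian(xlim = c(0, t_max)) +
      ggplot2::labs(x = "rescaled position (introns fixed width)", y = NULL) +
      ggplot2::theme_minimal()
  } else {
    message("annotation panel omitted: no transcript models supplied")
  }

  for (nm in names(tables)) {
    if (!is.null(tables[[nm]])) {
      utils::write.table(tables[[nm]],
                         paste0(out_prefix, "_", nm, ".tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  img <- NULL
  if (length(panels)) {
    fig <- cowplot::plot_grid(plotlist = panels, ncol = 1, align = "v",
                              rel_heights = rep(1, length(panels)))
    img <- paste0(out_prefix, ".png")
    ok <- tryCatch({
      ggplot2::ggsave(img, fig, width = 7, height = 2.5 * length(panels),
                      dpi = 150)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      img <- paste0(out_prefix, ".pdf")
      ggplot2::ggsave(img, fig, width = 7, height = 2.5 * length(panels))
    }
  }
  invisible(c(tables, list(image = img)))
}
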