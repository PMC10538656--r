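#' Simulate hard-call genotype dosages
#'
#' Genotypes are drawn under Hardy-Weinberg equilibrium at the requested
#' allele frequencies by sampling two haplotypes per individual. Optional
#' block LD is induced by copying the previous variant's haplotype alleles
#' within a block, refreshing each allele independently with probability
#' `switch_prob` (small values give tight LD).
#'
#' @param n_samples,n_variants dimensions.
#' @param maf per-variant minor allele frequencies in (0, 0.5], recycled.
#' @param ld_blocks optional integer vector assigning variants to LD blocks.
#' @param switch_prob within-block haplotype refresh probability.
#' @param chromosome chromosome name for the variant ids.
#' @param pos_start,pos_step genomic positions of the simulated variants.
#' @param seed integer seed; fully determines the output.
#' @return a [dosage_matrix()].
#' @export
simulate_genotypes <- function(n_samples, n_variants, maf = 0.25,
                               ld_blocks = NULL, switch_prob = 0.1,
                               chromosome = "chr1", pos_start = 1e6,
                               pos_step = 1000, seed = 1) {
  stopifnot(all(maf > 0 & maf <= 0.5))
  maf <- rep_len(maf, n_variants)
  set.seed(seed)
  hap <- function() {
    h <- matrix(0L, n_samples, n_variants)
    for (j in seq_len(n_variants)) {
      fresh <- stats::rbinom(n_samples, 1, maf[j])
      if (!is.null(ld_blocks) && j > 1 && ld_blocks[j] == ld_blocks[j - 1]) {
        sw <- stats::runif(n_samples) < switch_prob
        h[, j] <- ifelse(sw, fresh, h[, j - 1])
      } else {
        h[, j] <- fresh
      }
    }
    h
  }
  dosage <- hap() + hap()
  pos <- pos_start + (seq_len(n_variants) - 1L) * pos_step
  alleles <- c("A", "C", "G", "T")
  ref <- alleles[1 + (seq_len(n_variants) %% 4)]
  alt <- alleles[1 + ((seq_len(n_variants) + 1) %% 4)]
  variants <- data.frame(
    id = format_variant_id(chromosome, pos, ref, alt),
    chromosome = chromosome, position = pos, ref = ref, alt = alt,
    stringsAsFactors = FALSE)
  rownames(dosage) <- sprintf("sample_%03d", seq_len(n_samples))
  dosage_matrix(dosage, variants)
}

# Fixed two-transcript gene layout used by the splicing fixtures: five exons
# on chr11; transcript T2 carries a short version of exon 4 (3' end
# truncated), the motif of an NMD-coupled alternative splicing event.
.fixture_gene_model <- function(gene_start = 14880000) {
  ex <- data.frame(
    exon = 1:5,
    start = gene_start + c(0, 2000, 4000, 6000, 9000),
    end = gene_start + c(300, 2300, 4400, 6600, 9500))
  short4_end <- ex$end[4] - 300  # short exon 4 used by transcript 2
  list(exons = ex, short4_end = short4_end,
       chromosome = "chr11", gene_start = gene_start)
}

#' Simulate a two-transcript gene with a planted splicing QTL
#'
#' Emulates the canonical splicing-QTL motif: a gene with two annotated
#' transcripts differing only in the length of one exon (a short version of
#' exon 4). Per sample, the usage fraction of the short transcript follows
#' `plogis(base_logit + effect * dosage + noise)`; exon and gene read counts
#' are Poisson around the mixture expectations, and per-sample read coverage
#' is the depth-scaled expected per-base density of the transcript mixture,
#' binned at `bin` bp. Gene-level counts do not depend on the usage effect,
#' so the planted signal is a pure sQTL with no eQTL component.
#'
#' @param dosage per-sample dosage at the causal variant.
#' @param effect usage effect per alt allele, logit units.
#' @param base_logit baseline logit usage of the short transcript.
#' @param depth expected gene-level read count per sample.
#' @param noise_sd per-sample logit-scale usage noise.
#' @param bin coverage bin width (bp).
#' @param seed integer seed.
#' @return list: `usage` (samples x 2 transcript usage), `exon_counts`,
#'   `gene_counts`, `coverage` (samples x bins over the gene span),
#'   `models` (a `transcript_models`), `span` (0-based half-open),
#'   `truth` (planted parameters).
#' @export
simulate_gene <- function(dosage, effect = 1, base_logit = -1, depth = 500,
                          noise_sd = 0.3, bin = 5L, seed = 1) {
  set.seed(seed)
  gm <- .fixture_gene_model()
  n <- length(dosage)
  u2 <- stats::plogis(base_logit + effect * dosage +
                        stats::rnorm(n, 0, noise_sd))
  usage <- cbind(T1 = 1 - u2, T2 = u2)
  ex <- gm$exons
  # transcript exon structures (0-based half-open)
  t1_ex <- data.frame(transcript_id = "T1", start = ex$start, end = ex$end)
  t2_end <- ex$end; t2_end[4] <- gm$short4_end
  t2_ex <- data.frame(transcript_id = "T2", start = ex$start, end = t2_end)
  exons <- rbind(t1_ex, t2_ex)
  exons$gene_id <- "GFIX1"
  exons$chromosome <- gm$chromosome
  exons$strand <- "+"
  models <- structure(list(
    exons = exons[, c("transcript_id", "gene_id", "chromosome", "strand",
                      "start", "end")],
    transcripts = data.frame(
      transcript_id = c("T1", "T2"), gene_id = "GFIX1",
      chromosome = gm$chromosome, strand = "+",
      start = min(ex$start), end = max(ex$end))),
    class = "transcript_models")
  span <- c(min(ex$start), max(ex$end))
  len1 <- sum(t1_ex$end - t1_ex$start)
  # per-base inclusion indicator of each transcript over the span
  bases <- seq.int(span[1], span[2] - 1L)
  in_tx <- function(e) {
    ind <- rep(0, length(bases))
    for (i in seq_len(nrow(e))) ind[bases >= e$start[i] & bases < e$end[i]] <- 1
    ind
  }
  ind1 <- in_tx(t1_ex); ind2 <- in_tx(t2_ex)
  n_bins <- ceiling(length(bases) / bin)
  bin_of <- (seq_along(bases) - 1L) %/% bin + 1L
  coverage <- matrix(0, n, n_bins)
  exon_counts <- matrix(0, n, nrow(ex))
  gene_counts <- stats::rpois(n, depth)
  # per-base expected coverage: each transcript contributes its usage
  # fraction uniformly over its exonic bases, so shared bases sit at a
  # dosage-independent level and only the alternative segment of exon 4
  # carries the usage signal
  c0 <- depth / 100
  for (i in seq_len(n)) {
    dens <- c0 * ((1 - u2[i]) * ind1 + u2[i] * ind2)
    lam_bin <- as.numeric(tapply(dens, bin_of, sum))
    coverage[i, ] <- stats::rpois(n_bins, lam_bin)
    lam_ex <- depth * ((1 - u2[i]) * (ex$end - ex$start) +
                         u2[i] * (t2_end - ex$start)) / len1
    exon_counts[i, ] <- stats::rpois(nrow(ex), lam_ex)
  }
  colnames(exon_counts) <- paste0("GFIX1_exon", ex$exon)
  rownames(coverage) <- rownames(exon_counts) <- rownames(usage) <-
    names(dosage)
  list(usage = usage, exon_counts = exon_counts, gene_counts = gene_counts,
       coverage = coverage, models = models, span = span, bin = bin,
       truth = list(effect = effect, base_logit = base_logit,
                    affected_transcript = "T2", affected_exon = "GFIX1_exon4",
                    seed = seed))
}

#' Wakefield-style fine-mapping outputs from a nominal scan
#'
#' Builds single-effect fine-mapping summaries from per-variant effect
#' estimates using approximate Bayes factors:
#' `ln ABF = 0.5 * ln(se^2 / (se^2 + W)) + 0.5 * z^2 * W / (se^2 + W)`
#' with prior effect variance `W` (default 0.15^2). Posterior inclusion
#' probabilities are the normalised ABFs and the credible set is the
#' smallest variant set whose cumulative PIP reaches `coverage_of`. One
#' signal per trait (single-effect regime); the emitted tables use the same
#' dialects the pipeline readers consume.
#'
#' @param sumstats nominal-scan records for one trait (columns `variant`,
#'   `beta`, `se`, `molecular_trait_id`, `molecular_trait_object_id`).
#' @param coverage_of credible-set coverage (default 0.95).
#' @param W prior effect-size variance (default 0.0225 = 0.15^2).
#' @param signal_index index of the emitted signal (default 1).
#' @return list: `credible_sets` (credible-set records), `lbf`
#'   (log-Bayes-factor records for all variants), `pip` (named vector).
#' @export
simulate_finemap_outputs <- function(sumstats, coverage_of = 0.95,
                                     W = 0.0225, signal_index = 1L) {
  ok <- is.finite(sumstats$beta) & is.finite(sumstats$se) & sumstats$se > 0
  ss <- sumstats[ok, , drop = FALSE]
  z <- ss$beta / ss$se
  lbf <- 0.5 * log(ss$se^2 / (ss$se^2 + W)) +
    0.5 * z^2 * W / (ss$se^2 + W)
  w <- lbf - max(lbf)
  pip <- exp(w) / sum(exp(w))
  if (all(abs(z) < 1e-12)) {
    warning("degenerate all-zero z; uniform PIPs, credible set spans all variants")
  }
  ord <- order(pip, decreasing = TRUE)
  take <- seq_len(which(cumsum(pip[ord]) >= coverage_of)[1])
  cs_members <- ord[take]
  trait <- ss$molecular_trait_id[1]
  group <- if (!is.null(ss$molecular_trait_object_id))
    ss$molecular_trait_object_id[1] else trait
  list(
    credible_sets = data.frame(
      molecular_trait_id = trait, molecular_trait_object_id = group,
      cs_id = paste0(trait, "_L", signal_index),
      variant = ss$variant[cs_members], pip = pip[cs_members],
      z = z[cs_members], stringsAsFactors = FALSE),
    lbf = data.frame(
      molecular_trait_id = trait, signal_index = as.integer(signal_index),
      variant = ss$variant, lbf = lbf, stringsAsFactors = FALSE),
    pip = stats::setNames(pip, ss$variant))
}

#' Write a complete synthetic study bundle to disk
#'
#' Generates genotypes, a splicing fixture gene, per-sample coverage tracks,
#' trait matrices and the planted-truth table, and writes them in the
#' pipeline's external formats (VCF, GFF3, bedGraph, TSV). Byte-identical
#' for a fixed seed.
#'
#' @param out_dir output directory.
#' @param n_samples number of samples.
#' @param n_variants cis-region variants.
#' @param effect planted usage effect (logit units per alt allele).
#' @param maf causal-variant and background MAF.
#' @param depth gene-level read depth.
#' @param seed integer seed.
#' @param force overwrite an existing non-empty directory.
#' @return (invisibly) list of written paths plus the in-memory objects.
#' @export
make_dataset <- function(out_dir, n_samples = 100, n_variants = 50,
                         effect = 1, maf = 0.3, depth = 500, seed = 1,
                         force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    stop("output directory exists and is not empty (use force = TRUE)",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gm <- .fixture_gene_model()
  dm <- simulate_genotypes(n_samples, n_variants, maf = maf,
                           chromosome = gm$chromosome,
                           pos_start = gm$gene_start - 25000,
                           pos_step = 1000, seed = seed)
  causal_idx <- ceiling(n_variants / 2)
  dosage <- stats::setNames(dm$dosage[, causal_idx], dm$samples)
  gene <- simulate_gene(dosage, effect = effect, depth = depth,
                        seed = seed + 1)
  paths <- list(
    vcf = file.path(out_dir, "genotypes.vcf"),
    gff3 = file.path(out_dir, "annotations.gff3"),
    usage = file.path(out_dir, "transcript_usage.tsv"),
    exon_counts = file.path(out_dir, "exon_counts.tsv"),
    gene_counts = file.path(out_dir, "gene_counts.tsv"),
    truth = file.path(out_dir, "truth.tsv"))
  write_vcf(dm, paths$vcf)
  write_gff3(gene$models, paths$gff3)
  wr <- function(m, p) {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(gene$usage, paths$usage)
  wr(gene$exon_counts, paths$exon_counts)
  wr(matrix(gene$gene_counts, ncol = 1,
            dimnames = list(dm$samples, "GFIX1")), paths$gene_counts)
  bg_dir <- file.path(out_dir, "coverage")
  dir.create(bg_dir, showWarnings = FALSE)
  n_bins <- ncol(gene$coverage)
  starts <- gene$span[1] + (seq_len(n_bins) - 1L) * gene$bin
  for (i in seq_len(nrow(gene$coverage))) {
    p <- file.path(bg_dir, paste0(dm$samples[i], ".bedgraph"))
    write_bedgraph(data.frame(
      chromosome = gm$chromosome, start = starts,
      end = pmin(starts + gene$bin, gene$span[2]),
      score = gene$coverage[i, ]), p)
  }
  utils::write.table(data.frame(
    gene_id = "GFIX1", causal_variant = dm$variants$id[causal_idx],
    effect = effect, affected_trait = gene$truth$affected_transcript,
    trait_type = "sQTL", seed = seed), paths$truth,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, list(coverage_dir = bg_dir, genotypes = dm,
                          gene = gene,
                          causal_variant = dm$variants$id[causal_idx])))
}
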