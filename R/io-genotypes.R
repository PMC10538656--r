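#' Construct a dosage matrix
#'
#' The central genotype container: an n-samples x p-variants matrix of
#' alternative-allele dosages in \[0, 2\] (NA where missing), with per-variant
#' metadata and optional per-sample sex labels. X-chromosome variants are
#' tagged `X_PAR` or `X_nonPAR` using GRCh38 pseudoautosomal boundaries
#' (PAR1 chrX:10,001-2,781,479; PAR2 chrX:155,701,383-156,030,895),
#' overridable via `par_regions`.
#'
#' @param dosage numeric matrix, samples in rows, variants in columns;
#'   column names are canonical variant ids.
#' @param variants data.frame with columns `id`, `chromosome`, `position`,
#'   `ref`, `alt` and optionally `r2` (imputation quality).
#' @param sex optional character vector per sample in
#'   `c("female", "male", "unknown")`.
#' @param par_regions 2x2 matrix of PAR start/end (1-based, inclusive).
#' @return object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(dosage, variants, sex = NULL, par_regions = NULL) {
  dosage <- as.matrix(dosage)
  stopifnot(ncol(dosage) == nrow(variants))
  rng <- range(dosage, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < -1e-8 || rng[2] > 2 + 1e-8)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("sample_", seq_len(nrow(dosage)))
  }
  colnames(dosage) <- variants$id
  if (is.null(sex)) sex <- rep("unknown", nrow(dosage))
  sex <- match.arg(sex, c("female", "male", "unknown"), several.ok = TRUE)
  stopifnot(length(sex) == nrow(dosage))
  variants$region <- x_region(variants$chromosome, variants$position,
                              par_regions)
  structure(list(dosage = dosage, variants = variants,
                 samples = rownames(dosage), sex = sex),
            class = "dosage_matrix")
}

#' @exportS3Method base::print
print.dosage_matrix <- function(x, ...) {
  cat("dosage_matrix:", length(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  cat("  missing:", sum(is.na(x$dosage)), "entries;",
      sum(x$variants$region != "autosome"), "X variants\n")
  invisible(x)
}

#' @exportS3Method base::dim
dim.dosage_matrix <- function(x) dim(x$dosage)

# GRCh38 pseudoautosomal regions (1-based inclusive).
.default_par <- rbind(PAR1 = c(10001, 2781479),
                      PAR2 = c(155701383, 156030895))

#' Classify variants into autosome / X PAR / X non-PAR
#'
#' @param chromosome,position variant coordinates (1-based).
#' @param par_regions optional matrix of PAR intervals (rows), 1-based
#'   inclusive; defaults to GRCh38 PAR1/PAR2.
#' @return character vector in `c("autosome", "X_PAR", "X_nonPAR")`.
#' @export
x_region <- function(chromosome, position, par_regions = NULL) {
  if (is.null(par_regions)) par_regions <- .default_par
  is_x <- sub("^chr", "", chromosome) %in% c("X", "x")
  in_par <- rep(FALSE, length(position))
  for (i in seq_len(nrow(par_regions))) {
    in_par <- in_par | (position >= par_regions[i, 1] &
                        position <= par_regions[i, 2])
  }
  ifelse(!is_x, "autosome", ifelse(in_par, "X_PAR", "X_nonPAR"))
}

#' Read genotype dosages from a VCF
#'
#' Uses the `DS` FORMAT field when present and falls back to counting
#' alternative alleles in `GT` otherwise. Missing genotypes become `NA`,
#' never 0. Per-variant imputation quality is taken from an `R2` (or `DR2`)
#' INFO key when available.
#'
#' @param vcf_path path to a VCF (optionally bgzipped).
#' @param region optional `"chrom:start-end"` restriction, 1-based inclusive.
#' @param sex optional named character vector (`female`/`male`/`unknown`) per
#'   sample id.
#' @return a [dosage_matrix()].
#' @export
read_dosages <- function(vcf_path, region = NULL, sex = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no variant records", call. = FALSE)
  pos <- as.integer(fix$POS)
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^(.+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) stop("region must be 'chrom:start-end'", call. = FALSE)
    keep <- fix$CHROM == m[2] & pos >= as.integer(m[3]) & pos <= as.integer(m[4])
    if (!any(keep)) stop("no variants in region ", region, call. = FALSE)
  }
  fmt_keys <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  if ("DS" %in% fmt_keys) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else if ("GT" %in% fmt_keys) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- apply(gt, 2, function(col) {
      vapply(strsplit(col, "[/|]"), function(a) {
        if (length(a) == 0 || anyNA(a) || any(a == ".")) return(NA_real_)
        sum(a != "0")
      }, numeric(1))
    })
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(vcf@gt), byrow = FALSE)
  } else {
    stop("VCF has neither DS nor GT FORMAT fields", call. = FALSE)
  }
  ds <- matrix(as.numeric(ds), nrow = nrow(fix),
               dimnames = list(NULL, colnames(vcf@gt)[-1]))
  info <- vcfR::extract.info(vcf, element = "R2", as.numeric = TRUE)
  if (all(is.na(info))) {
    info <- vcfR::extract.info(vcf, element = "DR2", as.numeric = TRUE)
  }
  variants <- data.frame(
    id = format_variant_id(fix$CHROM, pos, fix$REF, fix$ALT),
    chromosome = fix$CHROM, position = pos, ref = fix$REF, alt = fix$ALT,
    r2 = as.numeric(info), stringsAsFactors = FALSE)
  dosage <- t(ds[keep, , drop = FALSE])
  variants <- variants[keep, , drop = FALSE]
  sample_ids <- colnames(vcf@gt)[-1]
  rownames(dosage) <- sample_ids
  sex_vec <- NULL
  if (!is.null(sex)) {
    sex_vec <- unname(sex[sample_ids])
    sex_vec[is.na(sex_vec)] <- "unknown"
  }
  dosage_matrix(dosage, variants, sex = sex_vec)
}

#' Write a dosage matrix as a minimal VCF
#'
#' Emits a VCF 4.2 file with `GT:DS` genotype fields (GT hard-called by
#' rounding) and an `R2` INFO key where imputation quality is present.
#' Intended for fixture generation and for round-tripping through
#' [read_dosages()].
#'
#' @param dm a [dosage_matrix()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(dm, path) {
  v <- dm$variants
  hdr <- c("##fileformat=VCFv4.2",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dm$samples), collapse = "\t"))
  gt_codes <- c("0/0", "0/1", "1/1")
  lines <- vapply(seq_len(nrow(v)), function(j) {
    d <- dm$dosage[, j]
    hard <- round(d)
    gt <- ifelse(is.na(d), "./.", gt_codes[hard + 1])
    dsf <- ifelse(is.na(d), ".", formatC(d, format = "g", digits = 6))
    info <- if (!is.null(v$r2) && !is.na(v$r2[j])) {
      paste0("R2=", formatC(v$r2[j], format = "g", digits = 6))
    } else "."
    paste(c(v$chromosome[j], v$position[j], v$id[j], v$ref[j], v$alt[j],
            ".", ".", info, "GT:DS", paste(gt, dsf, sep = ":")),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines[order(v$chromosome, v$position)]), path)
  invisible(path)
}
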