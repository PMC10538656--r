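#' Parse canonical variant identifiers
#'
#' Variant identifiers follow the `chr_pos_ref_alt` convention used throughout
#' molecular QTL summary statistics (e.g. `"chr11_14855172_G_A"`). Chromosome
#' names may themselves contain underscores (alt contigs), so the identifier is
#' parsed from the right: the last three underscore-separated fields are the
#' position, reference and alternative allele.
#'
#' @param id character vector of variant identifiers.
#' @return A data.frame with columns `chromosome`, `position` (1-based),
#'   `ref`, `alt` and the canonical `id` (re-formatted, so that
#'   `parse_variant_id(format_variant_id(...))` round-trips).
#' @examples
#' parse_variant_id("chr11_14855172_G_A")
#' @export
parse_variant_id <- function(id) {
  id <- as.character(id)
  m <- regmatches(id, regexec("^(.+)_([0-9]+)_([A-Za-z]+)_([A-Za-z*]+)$", id))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) {
    stop("unparseable variant id at position ", which(bad)[1], ": '",
         id[which(bad)[1]], "'", call. = FALSE)
  }
  chromosome <- vapply(m, `[`, "", 2L)
  position <- as.integer(vapply(m, `[`, "", 3L))
  ref <- vapply(m, `[`, "", 4L)
  alt <- vapply(m, `[`, "", 5L)
  if (any(position < 1L)) stop("variant position must be >= 1", call. = FALSE)
  if (any(ref == alt)) stop("ref and alt alleles must differ", call. = FALSE)
  data.frame(chromosome = chromosome, position = position, ref = ref,
             alt = alt, id = format_variant_id(chromosome, position, ref, alt),
             stringsAsFactors = FALSE)
}

#' Format canonical variant identifiers
#'
#' @param chromosome,position,ref,alt vectors describing the variants.
#' @return character vector `chr_pos_ref_alt`.
#' @export
format_variant_id <- function(chromosome, position, ref, alt) {
  paste(chromosome, as.integer(position), ref, alt, sep = "_")
}

# Complement-swapped alias of a variant id (ref/alt swapped and complemented),
# used to rescue strand-flip representations when intersecting variant sets.
variant_id_flip_alias <- function(id) {
  v <- parse_variant_id(id)
  comp <- function(x) chartr("ACGTacgt", "TGCAtgca", x)
  format_variant_id(v$chromosome, v$position, comp(v$alt), comp(v$ref))
}
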