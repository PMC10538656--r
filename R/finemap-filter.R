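#' Quality filter for credible sets
#'
#' A credible set is discarded when the maximum absolute univariate z-score
#' over its member variants is below 3 (`low_z`) or when it contains more
#' than 200 variants (`oversized`); both inequalities are strict, and both
#' reasons are recorded when both hold.
#'
#' @param cs data.frame of credible-set records for one group (columns
#'   `cs_id`, `variant`, `pip`, `z`, ...).
#' @param z_min,size_max thresholds.
#' @return list with `kept` (surviving cs_ids) and `discarded` (data.frame:
#'   cs_id, reason).
#' @export
filter_credible_sets <- function(cs, z_min = 3, size_max = 200) {
  per_cs <- split(cs, cs$cs_id)
  discarded <- list()
  kept <- character(0)
  for (id in sort(names(per_cs))) {
    d <- per_cs[[id]]
    reasons <- c(if (max(abs(d$z)) < z_min) "low_z",
                 if (nrow(d) > size_max) "oversized")
    if (length(reasons)) {
      discarded[[id]] <- data.frame(cs_id = id,
                                    reason = paste(reasons, collapse = ";"),
                                    stringsAsFactors = FALSE)
    } else {
      kept <- c(kept, id)
    }
  }
  list(kept = kept,
       discarded = if (length(discarded)) do.call(rbind, discarded) else
         data.frame(cs_id = character(0), reason = character(0)))
}

#' Connected components of credible sets sharing variants
#'
#' Builds the undirected graph whose nodes are the surviving credible sets of
#' one group, with an edge whenever two sets share at least one variant
#' (canonical id equality), and returns its connected components — the
#' transitive closure of pairwise overlap. Components are ordered by their
#' lexicographically smallest cs_id, making the partition deterministic and
#' independent of input row order.
#'
#' @param cs data.frame of credible-set records (already quality-filtered).
#' @return object of class `component_partition`: list with `components`
#'   (each a list: `cs_ids`, `variants`) and `membership` (named component
#'   index per cs_id).
#' @export
build_components <- function(cs) {
  ids <- sort(unique(cs$cs_id))
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  # union all CSs containing each variant
  for (members in split(match(cs$cs_id, ids), cs$variant)) {
    u <- unique(members)
    if (length(u) > 1) for (k in u[-1]) union_(u[1], k)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp_of <- match(roots, sort(unique(roots)))  # roots are minimal indices
  components <- lapply(sort(unique(comp_of)), function(c) {
    cs_ids <- ids[comp_of == c]
    list(cs_ids = cs_ids,
         variants = sort(unique(cs$variant[cs$cs_id %in% cs_ids])))
  })
  structure(list(components = components,
                 membership = stats::setNames(comp_of, ids)),
            class = "component_partition")
}

#' @exportS3Method base::print
print.component_partition <- function(x, ...) {
  cat("component_partition:", length(x$components), "component(s) over",
      length(x$membership), "credible set(s)\n")
  invisible(x)
}

#' Select the tag trait of each connected component
#'
#' Within each component the credible set whose maximum member posterior
#' inclusion probability (PIP) is largest wins, and the molecular trait
#' owning it becomes the component's tag trait. Exact PIP ties are broken by
#' the lexicographically smallest trait id, then cs_id, so the selection is
#' deterministic.
#'
#' @param partition a `component_partition` from [build_components()].
#' @param cs the credible-set records the partition was built from (columns
#'   `cs_id`, `molecular_trait_id`, `pip`).
#' @return data.frame: component, cs_id, molecular_trait_id, max_pip.
#' @export
select_tags <- function(partition, cs) {
  per_cs <- stats::aggregate(pip ~ cs_id + molecular_trait_id, data = cs, max)
  do.call(rbind, lapply(seq_along(partition$components), function(ci) {
    cand <- per_cs[per_cs$cs_id %in% partition$components[[ci]]$cs_ids, ,
                   drop = FALSE]
    cand <- cand[order(-cand$pip, cand$molecular_trait_id, cand$cs_id), ,
                 drop = FALSE]
    data.frame(component = ci, cs_id = cand$cs_id[1],
               molecular_trait_id = cand$molecular_trait_id[1],
               max_pip = cand$pip[1], stringsAsFactors = FALSE)
  }))
}

#' Filter summary statistics down to tag traits
#'
#' Retains every summary-statistic row of the tag traits and drops the rest;
#' a group with no surviving credible set contributes no rows. The report
#' quantifies the file-size reduction, `1 - rows_out / rows_in`.
#'
#' @param sumstats summary statistics of one group.
#' @param tags data.frame from [select_tags()] (or a character vector of tag
#'   trait ids).
#' @return list: `sumstats` (filtered), `report` (rows_in, rows_out,
#'   reduction, n_tags).
#' @export
filter_sumstats <- function(sumstats, tags) {
  tag_traits <- if (is.character(tags)) tags else
    unique(tags$molecular_trait_id)
  missing <- setdiff(tag_traits, unique(sumstats$molecular_trait_id))
  if (length(missing)) {
    stop("tag trait(s) absent from summary statistics: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- sumstats[sumstats$molecular_trait_id %in% tag_traits, , drop = FALSE]
  list(sumstats = out,
       report = data.frame(rows_in = nrow(sumstats), rows_out = nrow(out),
                           reduction = 1 - nrow(out) / max(nrow(sumstats), 1),
                           n_tags = length(tag_traits)))
}

#' Fine-mapping-based filtering of transcript-level summary statistics
#'
#' The full per-dataset procedure, applied group by group (a gene for
#' exon/transcript/event traits, a junction cluster for junction traits):
#' quality-filter the credible sets (max |z| >= 3, size <= 200), link
#' credible sets that share variants into connected components, select the
#' highest-PIP trait of each component as its tag, and keep only the tag
#' traits' summary statistics. Gene-level (`ge`) statistics are passed
#' through untouched — only transcript-level quantifications carry the
#' redundant correlated traits this filter removes.
#'
#' @param sumstats summary-statistic records (all groups).
#' @param cs credible-set records (all groups, column
#'   `molecular_trait_object_id` as the group).
#' @param method quantification method of the dataset.
#' @return list: `sumstats` (filtered), `report` (per-dataset reduction),
#'   `tags` (per-group tag table), `discarded` (per-group CS discards).
#' @export
finemap_filter <- function(sumstats, cs,
                           method = c("exon", "tx", "txrevise", "leafcutter",
                                      "ge")) {
  method <- match.arg(method)
  if (method == "ge") {
    return(list(sumstats = sumstats,
                report = data.frame(rows_in = nrow(sumstats),
                                    rows_out = nrow(sumstats), reduction = 0,
                                    n_tags = NA_integer_),
                tags = NULL, discarded = NULL))
  }
  groups <- unique(sumstats$molecular_trait_object_id)
  kept_rows <- list(); tag_tables <- list(); discards <- list()
  for (g in groups) {
    ss_g <- sumstats[sumstats$molecular_trait_object_id == g, , drop = FALSE]
    cs_g <- cs[cs$molecular_trait_object_id == g, , drop = FALSE]
    if (nrow(cs_g) == 0) next  # no fine-mapped signal: drop the group
    fl <- filter_credible_sets(cs_g)
    if (nrow(fl$discarded)) {
      discards[[g]] <- cbind(group_id = g, fl$discarded)
    }
    if (length(fl$kept) == 0) next
    surv <- cs_g[cs_g$cs_id %in% fl$kept, , drop = FALSE]
    tags <- select_tags(build_components(surv), surv)
    tag_tables[[g]] <- cbind(group_id = g, tags)
    kept_rows[[g]] <- filter_sumstats(ss_g, tags)$sumstats
  }
  out <- if (length(kept_rows)) do.call(rbind, kept_rows) else
    sumstats[0, , drop = FALSE]
  rownames(out) <- NULL
  list(sumstats = out,
       report = data.frame(rows_in = nrow(sumstats), rows_out = nrow(out),
                           reduction = 1 - nrow(out) / max(nrow(sumstats), 1),
                           n_tags = sum(vapply(tag_tables, nrow, 1L))),
       tags = if (length(tag_tables)) do.call(rbind, tag_tables) else NULL,
       discarded = if (length(discards)) do.call(rbind, discards) else NULL)
}
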