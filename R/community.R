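#' Aggregate an OTU table by taxonomic rank
#'
#' Sums reads per taxon per sample at the chosen rank and reports both raw
#' counts and within-sample read fractions (low-read archaeal libraries are
#' usually displayed as counts, everything else as percentages, so both are
#' always carried). Lineages that are unclassified at the requested rank are
#' pooled under `"unclassified_<deepest classified parent>"`.
#'
#' @param table an [otu_table()] (typically the screened table, or a
#'   bin-restricted subset of the filtered table).
#' @param taxonomy a `TaxonomyMap` covering every OTU in `table`.
#' @param rank rank name (`"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`) or a 1-based rank index.
#' @return data.frame of class `CompositionTable`: `sample_id`, `taxon`,
#'   `reads`, `fraction`, sorted by sample then taxon.
#' @export
aggregate_by_rank <- function(table, taxonomy, rank = "class") {
  stopifnot(inherits(table, "OtuTable"), inherits(taxonomy, "TaxonomyMap"))
  rank_names <- c("domain", "phylum", "class", "order", "family", "genus")
  if (is.character(rank)) {
    ri <- match(tolower(rank), rank_names)
    if (is.na(ri)) stop("unknown rank '", rank, "'")
  } else ri <- as.integer(rank)
  if (ri < 1L) stop("rank index must be >= 1")

  missing_tax <- setdiff(otu_ids(table), names(taxonomy))
  if (length(missing_tax))
    stop("no lineage for OTU(s): ", paste(utils::head(missing_tax, 5L),
                                          collapse = ", "))

  taxon_at <- vapply(otu_ids(table), function(id) {
    lin <- taxonomy[[id]]
    lab <- if (ri <= length(lin)) lin[[ri]] else "unclassified"
    if (lab != "unclassified") return(lab)
    parent <- rev(setdiff(utils::head(lin, ri - 1L), "unclassified"))
    if (length(parent)) paste0("unclassified_", parent[[1L]])
    else "unclassified"
  }, "")

  agg <- rowsum(table$counts, group = taxon_at)
  n <- library_sizes(table)
  out <- do.call(rbind, lapply(colnames(agg), function(s) {
    data.frame(sample_id = s, taxon = rownames(agg),
               reads = as.integer(agg[, s]),
               fraction = if (n[[s]] > 0) agg[, s] / n[[s]] else 0,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$sample_id, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("CompositionTable", "data.frame")
  out
}

#' Shared-OTU abundance view
#'
#' Restricts a (screened) table to OTUs present in at least two samples and
#' orders them by total read abundance, descending - the layout used for
#' shared-OTU heatmaps. Ties in total abundance are broken by OTU id,
#' ascending, for determinism.
#'
#' @param table an [otu_table()].
#' @return integer matrix (shared OTUs x samples), possibly with zero rows.
#' @export
shared_otu_matrix <- function(table) {
  stopifnot(inherits(table, "OtuTable"))
  prevalence <- rowSums(table$counts > 0)
  m <- table$counts[prevalence >= 2L, , drop = FALSE]
  m[order(-rowSums(m), rownames(m)), , drop = FALSE]
}

#' Jaccard similarity between sample OTU sets
#'
#' Presence/absence community similarity: `J(s, t) = |A intersect B| /
#' |A union B|` where `A`, `B` are the sets of OTUs with count > 0 in each
#' sample. A pair of empty samples has an undefined union; it is reported as
#' 0 with a warning.
#'
#' @param table an [otu_table()] (post-screen by default in the pipeline).
#' @return symmetric numeric matrix of class `SimilarityMatrix` with
#'   diagonal 1 for non-empty samples.
#' @export
jaccard_matrix <- function(table) {
  stopifnot(inherits(table, "OtuTable"))
  pres <- table$counts > 0
  shared <- crossprod(pres)            # |A n B|
  sizes <- diag(shared)
  union <- outer(sizes, sizes, "+") - shared
  if (any(union == 0))
    warning("sample pair(s) with empty OTU sets; Jaccard reported as 0")
  j <- ifelse(union > 0, shared / union, 0)
  dimnames(j) <- list(sample_ids(table), sample_ids(table))
  structure(j, class = c("SimilarityMatrix", class(j)))
}
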