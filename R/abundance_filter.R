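#' Remove putatively spurious rare OTUs
#'
#' Low-abundance OTUs in pyrosequencing data are enriched in sequencing
#' artifacts, so the screen first drops OTUs whose pooled read count (summed
#' over every sample, control included) falls below a minimum abundance
#' threshold. In `"fixed_count"` mode the threshold is `rare_count_min` reads
#' (default 5); in `"fraction_of_total"` mode it is
#' `ceiling(rare_fraction * grand total)`, the 0.005%-of-total-tags form of
#' the same rule. The comparison at the threshold is `>=` by default
#' (`rare_keep_at_threshold`). Filtering removes whole OTU rows only: the
#' sample set is unchanged and reads are conserved between the retained and
#' removed fractions.
#'
#' Note: this filter deliberately discards singleton information, so
#' richness estimators that rely on singleton counts (e.g. Chao1) must not
#' be computed downstream.
#'
#' @param table an [otu_table()].
#' @param config a [screen_config()].
#' @return list with elements `table` (filtered `OtuTable`; may have zero
#'   rows, with a warning) and `report` (data.frame: `otu_id`,
#'   `total_count`, `retained`, plus attribute `threshold` giving the
#'   effective read-count cutoff).
#' @export
filter_rare_otus <- function(table, config = screen_config()) {
  stopifnot(inherits(table, "OtuTable"), inherits(config, "ScreenConfig"))
  totals <- rowSums(table$counts)
  threshold <- switch(config$rare_otu_mode,
    fixed_count = as.numeric(config$rare_count_min),
    fraction_of_total = ceiling(config$rare_fraction * sum(totals)))
  retained <- if (config$rare_keep_at_threshold) totals >= threshold
              else totals > threshold

  report <- data.frame(otu_id = otu_ids(table),
                       total_count = as.integer(totals),
                       retained = unname(retained),
                       stringsAsFactors = FALSE)
  report <- report[order(report$otu_id), , drop = FALSE]
  rownames(report) <- NULL
  attr(report, "threshold") <- threshold
  attr(report, "otus_removed") <- sum(!retained)
  attr(report, "reads_removed") <- sum(totals[!retained])

  if (!any(retained))
    warning("rare-OTU filter removed every OTU (threshold ", threshold, ")")
  out <- table
  out$counts <- table$counts[retained, , drop = FALSE]
  out$library_sizes <- colSums(out$counts)
  list(table = out, report = report)
}
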