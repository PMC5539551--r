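#' Relative abundance matrix
#'
#' Normalizes counts to relative abundance within each library,
#' r[o, s] = c[o, s] / N_s. This is the deterministic equivalent of scaling
#' every library to a common number of sequences; no rarefaction is
#' performed.
#'
#' @param table an [otu_table()].
#' @return numeric matrix of the same shape, columns summing to 1.
#' @export
compute_relative_abundance <- function(table) {
  stopifnot(inherits(table, "OtuTable"))
  n <- library_sizes(table)
  if (any(n == 0))
    stop("sample(s) with zero reads: ",
         paste(names(n)[n == 0], collapse = ", "))
  sweep(table$counts, 2L, n, "/")
}

bin_levels <- c("CONTROL_ONLY", "SAMPLES_ONLY", "TENFOLD_SAMPLE", "CONTROL_SAMPLE")

#' Classify OTUs into four provenance bins against a background control
#'
#' The screen's central step. Every OTU in the (already abundance-filtered)
#' table is compared with the background contamination control library and
#' placed in exactly one bin:
#'
#' * `CONTROL_ONLY` - present in the control, absent from every sample;
#' * `SAMPLES_ONLY` - absent from the control, present in some sample (the
#'   only fraction retained for community analysis);
#' * `TENFOLD_SAMPLE` - present in both, and at least `ratio_threshold`
#'   (default 10) times more abundant, on a relative-abundance basis, in at
#'   least one sample than in the control;
#' * `CONTROL_SAMPLE` - present in both at comparable abundance (ratio below
#'   threshold).
#'
#' The ratio reported for doubly present OTUs is
#' `R_o = max_s r[o, s] / r[o, control]` over non-control samples; it is `NA`
#' for OTUs absent from the control. Presence means count > 0 - no
#' pseudocounts are added anywhere.
#'
#' @param abund relative-abundance matrix from
#'   [compute_relative_abundance()] (or an `OtuTable`, normalized
#'   internally).
#' @param control control sample id (column name).
#' @param config a [screen_config()]; uses `ratio_threshold` and
#'   `ratio_comparison`.
#' @return data.frame of class `BinAssignment`: `otu_id`, `bin` (factor with
#'   the four levels above), `ratio`, sorted by OTU id.
#' @export
assign_bins <- function(abund, control, config = screen_config()) {
  if (inherits(abund, "OtuTable")) {
    if (missing(control)) control <- control_id(abund)
    abund <- compute_relative_abundance(abund)
  }
  stopifnot(is.matrix(abund), inherits(config, "ScreenConfig"))
  if (is.null(control) || is.na(control))
    stop("screening requires a control sample; none designated")
  if (!control %in% colnames(abund))
    stop("control sample '", control, "' not found in table")

  r_ctrl <- abund[, control]
  smp <- abund[, setdiff(colnames(abund), control), drop = FALSE]
  if (ncol(smp) == 0L) stop("no non-control samples to screen")
  r_max <- apply(smp, 1L, max)
  if (any(r_ctrl == 0 & r_max == 0))
    stop("OTU(s) with zero counts in every sample: ",
         paste(rownames(abund)[r_ctrl == 0 & r_max == 0], collapse = ", "))

  ratio <- ifelse(r_ctrl > 0, r_max / r_ctrl, NA_real_)
  enriched <- if (config$ratio_comparison == "ge")
    ratio >= config$ratio_threshold else ratio > config$ratio_threshold

  bin <- character(nrow(abund))
  bin[r_ctrl > 0 & r_max == 0] <- "CONTROL_ONLY"
  bin[r_ctrl == 0 & r_max > 0] <- "SAMPLES_ONLY"
  both <- r_ctrl > 0 & r_max > 0
  bin[both] <- ifelse(enriched[both], "TENFOLD_SAMPLE", "CONTROL_SAMPLE")

  out <- data.frame(otu_id = rownames(abund),
                    bin = factor(bin, levels = bin_levels),
                    ratio = unname(ratio),
                    stringsAsFactors = FALSE)
  out <- out[order(out$otu_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("BinAssignment", "data.frame")
  out
}

bins_of <- function(bins, which) {
  stopifnot(inherits(bins, "BinAssignment"))
  bins$otu_id[bins$bin %in% which]
}

#' Flag and exclude drilling-fluid-contaminated samples
#'
#' A sample is excluded from all downstream analysis only when two
#' independent lines of evidence agree: fluorescent tracer microspheres were
#' observed in the sample interior (drilling-fluid intrusion), AND the
#' sequence library is essentially all control-overlapping reads (overlap
#' fraction at or above `sample_exclusion_overlap_threshold`, default 0.99).
#' Microsphere-positive samples whose libraries are dominated by
#' sample-specific OTUs are retained with a QC flag; samples lacking a
#' microsphere measurement are treated as not flagged.
#'
#' @param table filtered `OtuTable` (control included).
#' @param metadata data.frame from [read_sample_metadata()] with
#'   `sample_id` and `microsphere_count` columns.
#' @param bins a `BinAssignment` from [assign_bins()].
#' @param config a [screen_config()].
#' @return data.frame: `sample_id`, `microsphere_count`, `overlap_fraction`,
#'   `flagged`, `excluded`, `reason`, one row per non-control sample.
#' @export
exclude_contaminated_samples <- function(table, metadata, bins,
                                         config = screen_config()) {
  stopifnot(inherits(table, "OtuTable"), inherits(bins, "BinAssignment"))
  ctrl <- control_id(table)
  samples <- setdiff(sample_ids(table), ctrl)
  overlap <- overlap_fractions(table, bins)[samples]

  ms <- rep(NA_real_, length(samples))
  if (!is.null(metadata)) {
    idx <- match(samples, metadata$sample_id)
    if ("microsphere_count" %in% names(metadata))
      ms <- metadata$microsphere_count[idx]
  }
  flagged <- !is.na(ms) & ms > 0
  excluded <- flagged & overlap >= config$sample_exclusion_overlap_threshold
  reason <- ifelse(excluded,
    sprintf("microspheres present and %.1f%% of reads overlap control",
            100 * overlap),
    ifelse(flagged, "microspheres present; retained (low control overlap)",
           ifelse(is.na(ms), "microspheres not measured", "")))
  data.frame(sample_id = samples,
             microsphere_count = ms,
             overlap_fraction = unname(overlap),
             flagged = flagged,
             excluded = excluded,
             reason = reason,
             stringsAsFactors = FALSE)
}

# per-sample fraction of reads in control-overlapping OTUs (bins 3 and 4)
overlap_fractions <- function(table, bins) {
  shared <- bins_of(bins, c("TENFOLD_SAMPLE", "CONTROL_SAMPLE"))
  n <- library_sizes(table)
  reads <- colSums(table$counts[rownames(table$counts) %in% shared, ,
                                drop = FALSE])
  ifelse(n > 0, reads / n, 0)
}

#' Apply the contamination screen to an OTU table
#'
#' Reduces the filtered table to the fraction safe for community analysis:
#' the control column is dropped, OTUs observed in the control
#' (`TENFOLD_SAMPLE` and `CONTROL_SAMPLE` bins, as well as `CONTROL_ONLY`)
#' are removed from every sample, and samples failing
#' [exclude_contaminated_samples()] are dropped entirely. Per-sample overlap
#' diagnostics are recorded: the fraction of reads in control-overlapping
#' OTUs, the fraction in the control:sample bin alone, and OTU richness
#' before and after the screen.
#'
#' @param table filtered `OtuTable` with a designated control.
#' @param bins `BinAssignment` computed on the same table.
#' @param metadata optional sample metadata for the exclusion rule.
#' @param config a [screen_config()].
#' @return object of class `ScreenResult`: list with `table` (screened
#'   `OtuTable`: retained samples x `SAMPLES_ONLY` OTUs), `samples`
#'   (per-sample data.frame of diagnostics), `exclusions`, `bins`, and
#'   `bin_sizes`.
#' @export
apply_screen <- function(table, bins, metadata = NULL,
                         config = screen_config()) {
  stopifnot(inherits(table, "OtuTable"), inherits(bins, "BinAssignment"))
  if (!setequal(bins$otu_id, otu_ids(table)))
    stop("bin assignment does not match the table's OTU set")
  ctrl <- control_id(table)
  if (is.na(ctrl)) stop("table has no control sample; use a pass-through run")

  exclusions <- exclude_contaminated_samples(table, metadata, bins, config)
  keep_samples <- setdiff(sample_ids(table), c(ctrl, exclusions$sample_id[exclusions$excluded]))

  keep_otus <- bins_of(bins, "SAMPLES_ONLY")
  m <- table$counts[rownames(table$counts) %in% keep_otus, keep_samples,
                    drop = FALSE]
  m <- m[rowSums(m) > 0, , drop = FALSE]  # OTUs only in excluded samples
  screened <- otu_table(m)

  n_pre <- library_sizes(table)
  samples <- setdiff(sample_ids(table), ctrl)
  overlap <- overlap_fractions(table, bins)[samples]
  g4 <- colSums(table$counts[rownames(table$counts) %in%
                               bins_of(bins, "CONTROL_SAMPLE"), samples,
                             drop = FALSE]) / n_pre[samples]
  pre_otus <- colSums(table$counts[, samples, drop = FALSE] > 0)
  post_otus <- post_reads <- stats::setNames(rep(0L, length(samples)), samples)
  post_otus[keep_samples] <- colSums(screened$counts > 0)
  post_reads[keep_samples] <- library_sizes(screened)

  per_sample <- data.frame(
    sample_id = samples,
    pre_screen_reads = as.integer(n_pre[samples]),
    pre_screen_otus = as.integer(pre_otus),
    post_screen_reads = as.integer(post_reads),
    post_screen_otus = as.integer(post_otus),
    overlap_fraction = unname(overlap),
    group4_read_fraction = unname(g4),
    excluded = samples %in% exclusions$sample_id[exclusions$excluded],
    stringsAsFactors = FALSE)
  per_sample <- per_sample[order(per_sample$sample_id), , drop = FALSE]
  rownames(per_sample) <- NULL

  structure(list(table = screened,
                 samples = per_sample,
                 exclusions = exclusions,
                 bins = bins,
                 bin_sizes = table(bins$bin),
                 control = ctrl,
                 config = config),
            class = "ScreenResult")
}

#' @export
print.ScreenResult <- function(x, ...) {
  cat("Contamination screen against control", x$control, "\n")
  print(x$bin_sizes)
  cat(sprintf("screened table: %d OTUs x %d samples; %d sample(s) excluded\n",
              nrow(x$table$counts), ncol(x$table$counts),
              sum(x$exclusions$excluded)))
  invisible(x)
}

#' One-call contamination screen: filter, bin, exclude, screen
#'
#' Convenience wrapper running [filter_rare_otus()], [assign_bins()] and
#' [apply_screen()] in order. When the table has no control sample the
#' screen cannot run; with `allow_no_control = TRUE` (used for e.g. archaeal
#' libraries where no control reads were recovered) the filtered table is
#' passed through unscreened and the result is labelled accordingly.
#'
#' @param table raw `OtuTable`.
#' @param metadata optional sample metadata.
#' @param config a [screen_config()].
#' @param allow_no_control pass the filtered table through when no control
#'   is designated instead of erroring.
#' @return a `ScreenResult` (with `unscreened = TRUE` and empty bins in the
#'   pass-through case), plus element `filter_report`.
#' @export
screen_otu_table <- function(table, metadata = NULL,
                             config = screen_config(),
                             allow_no_control = FALSE) {
  filt <- filter_rare_otus(table, config)
  ctrl <- control_id(table)
  if (is.na(ctrl)) {
    if (!allow_no_control)
      stop("no control sample designated (set allow_no_control = TRUE for ",
           "an unscreened pass-through)")
    res <- structure(list(table = filt$table,
                          samples = data.frame(
                            sample_id = sample_ids(filt$table),
                            pre_screen_reads = as.integer(library_sizes(filt$table)),
                            post_screen_reads = as.integer(library_sizes(filt$table)),
                            stringsAsFactors = FALSE),
                          exclusions = NULL, bins = NULL,
                          bin_sizes = NULL, control = NA_character_,
                          config = config, unscreened = TRUE),
                     class = "ScreenResult")
    res$filter_report <- filt$report
    return(res)
  }
  bins <- assign_bins(filt$table, ctrl, config)
  res <- apply_screen(filt$table, bins, metadata, config)
  res$unscreened <- FALSE
  res$filter_report <- filt$report
  res
}
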