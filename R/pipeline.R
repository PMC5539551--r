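#' Write screening report files
#'
#' Emits the tabular record of a screen as deterministic, diffable TSVs in
#' `dir`: `bin_assignment.tsv` (per-OTU bin and ratio), `sample_summary.tsv`
#' (per-sample pre/post-screen reads, OTU richness, overlap fractions,
#' exclusion status), `filter_report.tsv` when present, and
#' `composition_<rank>.tsv` when a taxonomy is supplied. All rows are sorted
#' by OTU id then sample id; identical inputs give byte-identical files.
#'
#' @param result a `ScreenResult` from [apply_screen()] or
#'   [screen_otu_table()].
#' @param dir output directory (created if needed).
#' @param taxonomy optional `TaxonomyMap` for class-level composition.
#' @param ranks ranks for composition tables (default `"class"`).
#' @return invisibly, the paths written.
#' @export
write_report <- function(result, dir, taxonomy = NULL, ranks = "class") {
  stopifnot(inherits(result, "ScreenResult"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- character()
  if (!is.null(result$bins)) {
    bins <- as.data.frame(result$bins)
    bins$ratio <- ifelse(is.na(bins$ratio), "NA", format(bins$ratio, digits = 6))
    paths <- c(paths, tsv(bins, "bin_assignment.tsv"))
  }
  paths <- c(paths, tsv(result$samples, "sample_summary.tsv"))
  if (!is.null(result$exclusions))
    paths <- c(paths, tsv(result$exclusions, "sample_exclusions.tsv"))
  if (!is.null(result$filter_report))
    paths <- c(paths, tsv(result$filter_report, "filter_report.tsv"))
  paths <- c(paths, {
    p <- file.path(dir, "screened_otu_table.tsv")
    if (nrow(result$table$counts) > 0) write_otu_table(result$table, p)
    else writeLines("otu_id", p)
    p
  })
  if (!is.null(taxonomy) && nrow(result$table$counts) > 0)
    for (rk in ranks)
      paths <- c(paths, tsv(aggregate_by_rank(result$table, taxonomy, rk),
                            sprintf("composition_%s.tsv", rk)))
  invisible(paths)
}

#' Write a synthetic dataset in the pipeline's input formats
#'
#' @param dataset list from [generate_dataset()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  otu_path <- file.path(dir, "otu_table.tsv")
  write_otu_table(dataset$table, otu_path)
  tax_path <- file.path(dir, "taxonomy.tsv")
  tax <- dataset$taxonomy[order(names(dataset$taxonomy))]
  writeLines(paste(names(tax),
                   vapply(tax, paste, "", collapse = ";"), sep = "\t"),
             tax_path)
  meta_path <- file.path(dir, "metadata.tsv")
  utils::write.table(dataset$metadata, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(dir, "truth_otu_sources.tsv")
  src <- dataset$truth$otu_sources
  utils::write.table(
    data.frame(otu_id = names(src), source = unname(src))[order(names(src)), ],
    truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(otu_path, tax_path, meta_path, truth_path))
}

#' Run the full screening pipeline
#'
#' Orchestrates filter -> bin -> exclude -> screen -> summarize (-> quantify)
#' from a single configuration and writes every result table plus a
#' machine-readable `manifest.json` recording the configuration, seed, and
#' per-stage record counts. The run is idempotent: identical inputs give
#' identical outputs (manifests differ only in timestamp).
#'
#' The configuration is a named list (or a JSON file of one) with elements:
#' `otu_table`, `taxonomy`, `metadata` (input paths; `taxonomy` and
#' `metadata` optional), `control_id` (or `NULL` with
#' `allow_no_control = TRUE` for a pass-through run, e.g. archaeal libraries
#' with no recovered control reads), `qpcr` (optional qPCR replicate table
#' path), `out` (output directory), `screen` / `quant` (optional lists of
#' [screen_config()] / [quant_config()] overrides), and `ranks` (composition
#' ranks, default phylum and class).
#'
#' @param config named list or path to a JSON config file.
#' @param seed integer seed recorded in the manifest (the screen itself is
#'   deterministic; the seed matters for simulated inputs).
#' @return invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, seed = 1L) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  for (field in c("otu_table", "out"))
    if (is.null(config[[field]])) stop("config missing required field '", field, "'")
  allow_nc <- isTRUE(config$allow_no_control)
  if (is.null(config$control_id) && !allow_nc)
    stop("config missing required field 'control_id' ",
         "(or set allow_no_control for an unscreened pass-through)")
  scfg <- do.call(screen_config, as.list(config$screen))
  qcfg <- do.call(quant_config, as.list(config$quant))

  table <- read_otu_table(config$otu_table, control = config$control_id)
  taxonomy <- if (!is.null(config$taxonomy)) read_taxonomy(config$taxonomy)
  metadata <- if (!is.null(config$metadata)) read_sample_metadata(config$metadata)

  result <- screen_otu_table(table, metadata, scfg,
                             allow_no_control = allow_nc)
  ranks <- if (is.null(config$ranks)) c("phylum", "class") else config$ranks
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  write_report(result, config$out, taxonomy = taxonomy, ranks = ranks)

  if (nrow(result$table$counts) > 0) {
    shared <- shared_otu_matrix(result$table)
    utils::write.table(
      data.frame(otu_id = rownames(shared), shared, check.names = FALSE),
      file.path(config$out, "shared_otus.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jtab <- if (scfg$jaccard_input == "post_screen") result$table else table
    jac <- jaccard_matrix(jtab)
    utils::write.table(
      data.frame(sample_id = rownames(jac), jac, check.names = FALSE),
      file.path(config$out, "jaccard.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  quant <- NULL
  if (!is.null(config$qpcr)) {
    panels <- read_qpcr_panels(config$qpcr, qcfg)
    quant <- do.call(rbind, c(lapply(panels, quantify_panel),
                              make.row.names = FALSE))
    utils::write.table(quant, file.path(config$out, "quant_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    seed = as.integer(seed),
    control_id = if (is.null(config$control_id)) NA else config$control_id,
    unscreened = isTRUE(result$unscreened),
    screen_config = unclass(scfg),
    stages = list(
      input = list(otus = nrow(table$counts), samples = ncol(table$counts),
                   reads = sum(table$counts)),
      filtered = list(otus = nrow(table$counts) -
                        sum(!result$filter_report$retained)),
      screened = list(otus = nrow(result$table$counts),
                      samples = ncol(result$table$counts),
                      reads = sum(result$table$counts)),
      excluded_samples = if (is.null(result$exclusions)) 0L
                         else sum(result$exclusions$excluded),
      quantified = if (is.null(quant)) 0L else nrow(quant)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  stopifnot(manifest$stages$input$otus >= manifest$stages$filtered$otus,
            manifest$stages$filtered$otus >= manifest$stages$screened$otus)
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
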