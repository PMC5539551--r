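#' OTU count table with sample roles
#'
#' Container for an OTU-by-sample matrix of integer read counts, the unit of
#' analysis for amplicon contamination screening. One sample may be designated
#' the background contamination control; all screening operations compare
#' sample abundances against that column. Library sizes are always recomputed
#' from the counts, never trusted from a file.
#'
#' @param counts integer matrix, OTUs in rows, samples in columns. Row and
#'   column names are required and must be unique.
#' @param control single sample id to mark as the background control, or
#'   `NULL` for an unscreened (no-control) table.
#' @return an object of class `OtuTable`: a list with elements `counts`
#'   (integer matrix), `roles` (named character vector, `"SAMPLE"` or
#'   `"CONTROL"`), and `library_sizes` (named integer vector of column sums).
#' @examples
#' m <- matrix(c(1L, 0L, 2L, 3L, 0L, 5L), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("Otu", 1:3), c("s1", "s2")))
#' tab <- otu_table(m)
#' library_sizes(tab)
#' @export
otu_table <- function(counts, control = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  # R stores character(0) dimnames as NULL, so empty dimensions are exempt
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts))))
    stop("counts must have OTU row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers (found fractional values)")
  storage.mode(counts) <- "integer"

  roles <- stats::setNames(rep("SAMPLE", ncol(counts)), colnames(counts))
  if (!is.null(control)) {
    if (length(control) != 1L)
      stop("at most one CONTROL sample is allowed per screening run")
    if (!control %in% colnames(counts))
      stop("control sample '", control, "' not found in table")
    roles[control] <- "CONTROL"
  }

  structure(
    list(counts = counts, roles = roles,
         library_sizes = colSums(counts)),
    class = "OtuTable"
  )
}

#' @export
print.OtuTable <- function(x, ...) {
  ctrl <- control_id(x)
  cat(sprintf("OtuTable: %d OTUs x %d samples (%s reads)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  cat(if (is.na(ctrl)) "  control: none\n"
      else sprintf("  control: %s\n", ctrl))
  invisible(x)
}

#' @rdname otu_table
#' @param x an `OtuTable`.
#' @export
library_sizes <- function(x) {
  stopifnot(inherits(x, "OtuTable"))
  x$library_sizes
}

#' @rdname otu_table
#' @export
otu_ids <- function(x) {
  stopifnot(inherits(x, "OtuTable"))
  rownames(x$counts)
}

#' @rdname otu_table
#' @export
sample_ids <- function(x) {
  stopifnot(inherits(x, "OtuTable"))
  colnames(x$counts)
}

#' @rdname otu_table
#' @export
control_id <- function(x) {
  stopifnot(inherits(x, "OtuTable"))
  ctrl <- names(x$roles)[x$roles == "CONTROL"]
  if (length(ctrl) == 0L) NA_character_ else ctrl
}

#' Subset an OtuTable by OTU and/or sample ids
#'
#' @param x an `OtuTable`.
#' @param otus,samples character vectors of ids to keep (default: all).
#' @return a new `OtuTable`; control designation is kept if the control
#'   sample survives the subset.
#' @export
subset_otu_table <- function(x, otus = otu_ids(x), samples = sample_ids(x)) {
  stopifnot(inherits(x, "OtuTable"))
  m <- x$counts[otus, samples, drop = FALSE]
  ctrl <- control_id(x)
  otu_table(m, control = if (!is.na(ctrl) && ctrl %in% samples) ctrl else NULL)
}

# ---- readers --------------------------------------------------------------

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
}

#' Read an OTU count table from disk
#'
#' Two dialects are supported: mothur `.shared` layout (columns
#' `label`, `Group`, `numOtus`, then one column per OTU; rows are samples)
#' and plain TSV (first column OTU ids, remaining columns samples). With
#' `dialect = "auto"` the shared layout is recognized by its header, and a
#' plain TSV whose *columns* carry OTU-style ids (`Otu...`) while its rows do
#' not is transposed, so both orientations of the same matrix load
#' identically.
#'
#' @param path file path.
#' @param dialect `"auto"`, `"tsv"`, or `"mothur_shared"`.
#' @param control optional control sample id, passed to [otu_table()].
#' @return an `OtuTable`.
#' @export
read_otu_table <- function(path, dialect = c("auto", "tsv", "mothur_shared"),
                           control = NULL) {
  dialect <- match.arg(dialect)
  lines <- read_tsv_lines(path)
  if (length(lines) < 2L) stop("malformed table (need header plus data): ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]

  is_shared <- length(header) >= 3L &&
    tolower(header[1L]) == "label" && tolower(header[2L]) == "group"
  if (dialect == "mothur_shared" && !is_shared)
    stop("malformed mothur shared header (expected label/Group/numOtus): ", path)
  if (dialect == "tsv") is_shared <- FALSE

  fields <- lapply(lines[-1L], function(l) strsplit(l, "\t", fixed = TRUE)[[1L]])
  bad <- which(vapply(fields, length, 1L) != length(header))
  if (length(bad))
    stop("row ", bad[1L] + 1L, " has ", length(fields[[bad[1L]]]),
         " fields, header has ", length(header))

  parse_counts <- function(values, where) {
    x <- suppressWarnings(as.numeric(values))
    if (anyNA(x)) stop("non-numeric count in ", where)
    if (any(x != round(x)))
      stop("non-integer count '", values[which(x != round(x))[1L]], "' in ", where)
    x
  }

  if (is_shared) {
    otus <- header[-(1:3)]
    samples <- vapply(fields, `[[`, "", 2L)
    m <- t(vapply(seq_along(fields), function(i)
      parse_counts(fields[[i]][-(1:3)], paste0("sample ", samples[i])),
      numeric(length(otus))))
    dimnames(m) <- list(samples, otus)
    m <- t(m)
  } else {
    otus <- vapply(fields, `[[`, "", 1L)
    samples <- header[-1L]
    m <- t(vapply(seq_along(fields), function(i)
      parse_counts(fields[[i]][-1L], paste0("row ", otus[i])),
      numeric(length(samples))))
    dimnames(m) <- list(otus, samples)
    # sample-rows orientation: OTU-style ids in the header, not the rows
    if (dialect == "auto" &&
        !any(grepl("^otu", otus, ignore.case = TRUE)) &&
        all(grepl("^otu", samples, ignore.case = TRUE))) {
      m <- t(m)
    }
  }
  otu_table(m, control = control)
}

#' Write an OtuTable as plain TSV (OTU rows, sample columns)
#'
#' Rows are sorted by OTU id and columns by sample id so output is
#' byte-reproducible. Reading the file back reproduces the counts exactly.
#'
#' @param x an `OtuTable`.
#' @param path output file path.
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "OtuTable"))
  m <- x$counts[order(rownames(x$counts)), order(colnames(x$counts)), drop = FALSE]
  df <- data.frame(otu_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- taxonomy -------------------------------------------------------------

#' Read a mothur/SILVA-style taxonomy file
#'
#' Expects two tab-separated columns: OTU id and a semicolon-delimited
#' lineage. Bootstrap confidence annotations in parentheses (`Bacteria(100)`)
#' are stripped; empty ranks and `unclassified`-style suffixes are normalized
#' to the token `"unclassified"`; lineages are truncated to `n_ranks` levels.
#'
#' @param path file path.
#' @param n_ranks maximum lineage depth retained (default 6:
#'   domain...genus).
#' @return a `TaxonomyMap`: named list of character lineage vectors.
#' @export
read_taxonomy <- function(path, n_ranks = 6L) {
  lines <- read_tsv_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, 1L) < 2L))
    stop("taxonomy lines must have two tab-separated columns")
  # skip a header line if present
  if (tolower(parts[[1L]][1L]) %in% c("otu", "otu_id", "otulabel"))
    parts <- parts[-1L]
  ids <- vapply(parts, `[[`, "", 1L)
  lineages <- lapply(parts, function(p) parse_lineage(p[[2L]], n_ranks))
  if (anyDuplicated(ids)) {
    for (id in unique(ids[duplicated(ids)])) {
      hits <- lineages[ids == id]
      if (length(unique(vapply(hits, paste, "", collapse = ";"))) > 1L)
        stop("otu id '", id, "' repeated with conflicting lineages")
    }
    keep <- !duplicated(ids)
    ids <- ids[keep]; lineages <- lineages[keep]
  }
  structure(stats::setNames(lineages, ids), class = "TaxonomyMap")
}

parse_lineage <- function(s, n_ranks = 6L) {
  # a single trailing ";" is a terminator (strsplit drops it); interior or
  # doubled separators leave empty ranks that become "unclassified"
  ranks <- strsplit(s, ";", fixed = TRUE)[[1L]]
  ranks <- gsub("\\s*\\(\\d+\\)\\s*$", "", trimws(ranks))
  ranks <- ifelse(!nzchar(ranks) | grepl("^(unclassified|unknown)", ranks,
                                         ignore.case = TRUE),
                  "unclassified", ranks)
  utils::head(ranks, n_ranks)
}

#' Build a TaxonomyMap from a named list of lineages
#' @param lineages named list: otu id -> character vector of rank labels.
#' @export
taxonomy_map <- function(lineages) {
  stopifnot(is.list(lineages), !is.null(names(lineages)),
            !anyDuplicated(names(lineages)))
  structure(lineages, class = "TaxonomyMap")
}

# ---- sample metadata ------------------------------------------------------

#' Read sample metadata
#'
#' TSV with columns `sample_id`, and optionally `hole`, `depth_mbsf`,
#' `lithology`, `material`, `microsphere_count`, `sulfate_mM`. Missing
#' microsphere counts (empty, `NA`, `n.m.`) mean "not measured" and are kept
#' as `NA`; negative depths or counts are rejected.
#'
#' @param path file path.
#' @return data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = c("", "NA", "n.a.", "n.m."))
  if (!"sample_id" %in% names(df)) stop("metadata needs a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  for (col in c("depth_mbsf", "microsphere_count", "sulfate_mM"))
    if (col %in% names(df)) {
      df[[col]] <- as.numeric(df[[col]])
      if (any(df[[col]] < 0, na.rm = TRUE)) stop(col, " must be >= 0")
    }
  df
}

# ---- configuration --------------------------------------------------------

#' Screening configuration
#'
#' Bundles the tunable knobs of the contamination screen. Defaults follow the
#' conservative screen used for deep subseafloor samples: retain OTUs with at
#' least five reads in the pooled dataset, call an OTU sample-enriched when
#' it is at least 10x more abundant (relative abundance) in any sample than
#' in the control, and drop a sample entirely only when it is both
#' microsphere-positive and overwhelmingly (>= 99% of reads) composed of
#' control-overlapping OTUs.
#'
#' @param ratio_threshold T, the sample:control abundance ratio separating
#'   sample-enriched from control:sample OTUs. Must be > 1; default 10.
#' @param rare_otu_mode `"fixed_count"` (threshold is `rare_count_min`
#'   reads) or `"fraction_of_total"` (threshold is
#'   `ceiling(rare_fraction * total reads)`).
#' @param rare_count_min minimum pooled read count for an OTU to be kept;
#'   default 5.
#' @param rare_fraction fraction of the pooled read total used in
#'   `"fraction_of_total"` mode; default 5e-5 (0.005%).
#' @param rare_keep_at_threshold if `TRUE` (default) OTUs exactly at the
#'   threshold are kept (comparison `>=`), otherwise dropped (`>`).
#' @param ratio_comparison `"ge"` (default) or `"gt"`: whether an OTU exactly
#'   at `ratio_threshold` counts as sample-enriched.
#' @param sample_exclusion_overlap_threshold minimum control-overlap read
#'   fraction for a microsphere-positive sample to be excluded; default 0.99.
#' @param jaccard_input `"post_screen"` (default) or `"pre_screen"`: which
#'   table community similarity is computed on.
#' @return a list of class `ScreenConfig`.
#' @export
screen_config <- function(ratio_threshold = 10,
                          rare_otu_mode = c("fixed_count", "fraction_of_total"),
                          rare_count_min = 5L,
                          rare_fraction = 5e-5,
                          rare_keep_at_threshold = TRUE,
                          ratio_comparison = c("ge", "gt"),
                          sample_exclusion_overlap_threshold = 0.99,
                          jaccard_input = c("post_screen", "pre_screen")) {
  rare_otu_mode <- match.arg(rare_otu_mode)
  ratio_comparison <- match.arg(ratio_comparison)
  jaccard_input <- match.arg(jaccard_input)
  stopifnot(ratio_threshold > 1,
            rare_count_min >= 0,
            rare_fraction >= 0, rare_fraction <= 1,
            sample_exclusion_overlap_threshold >= 0,
            sample_exclusion_overlap_threshold <= 1)
  structure(list(ratio_threshold = ratio_threshold,
                 rare_otu_mode = rare_otu_mode,
                 rare_count_min = as.integer(rare_count_min),
                 rare_fraction = rare_fraction,
                 rare_keep_at_threshold = isTRUE(rare_keep_at_threshold),
                 ratio_comparison = ratio_comparison,
                 sample_exclusion_overlap_threshold =
                   sample_exclusion_overlap_threshold,
                 jaccard_input = jaccard_input),
            class = "ScreenConfig")
}

#' qPCR quantification configuration
#'
#' @param detection_factor factor by which every sample replicate must exceed
#'   every negative-control replicate to call the target detected; default 2.
#' @param operons_per_cell assumed 16S rRNA operon copies per cell used to
#'   convert gene copies to cells; default 4 (bacterial average).
#' @param sediment_density bulk density in g cm^-3 used to convert copies per
#'   gram to cells per cm^3; default 2.5.
#' @param elution_volume DNA extract elution volume in uL (scales copies/uL
#'   to copies per extraction).
#' @param extracted_mass sample mass extracted, in g.
#' @return a list of class `QuantConfig`.
#' @export
quant_config <- function(detection_factor = 2,
                         operons_per_cell = 4,
                         sediment_density = 2.5,
                         elution_volume = NA_real_,
                         extracted_mass = NA_real_) {
  stopifnot(detection_factor > 0, operons_per_cell > 0, sediment_density > 0)
  if (!is.na(elution_volume) && elution_volume <= 0)
    stop("elution_volume must be > 0")
  if (!is.na(extracted_mass) && extracted_mass <= 0)
    stop("extracted_mass must be > 0")
  structure(list(detection_factor = detection_factor,
                 operons_per_cell = operons_per_cell,
                 sediment_density = sediment_density,
                 elution_volume = elution_volume,
                 extracted_mass = extracted_mass),
            class = "QuantConfig")
}
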