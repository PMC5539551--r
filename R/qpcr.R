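#' qPCR replicate panel for one sample and target
#'
#' Holds the replicate copy-number measurements (copies per uL of extract)
#' for one sample/target pair together with the extraction-negative and
#' PCR-negative control replicates from the same run, and the quantification
#' configuration used to interpret them.
#'
#' @param sample_id sample identifier.
#' @param target `"BACTERIA_16S"` or `"ARCHAEA_16S"`.
#' @param sample_reps numeric vector (>= 1) of sample replicate copies/uL.
#' @param extraction_negs,pcr_negs numeric vectors (>= 1 each) of
#'   negative-control replicate copies/uL.
#' @param config a [quant_config()].
#' @return list of class `QpcrPanel`.
#' @export
qpcr_panel <- function(sample_id, target = c("BACTERIA_16S", "ARCHAEA_16S"),
                       sample_reps, extraction_negs, pcr_negs,
                       config = quant_config()) {
  target <- match.arg(target)
  stopifnot(length(sample_reps) >= 1L, length(extraction_negs) >= 1L,
            length(pcr_negs) >= 1L,
            all(sample_reps >= 0), all(extraction_negs >= 0),
            all(pcr_negs >= 0),
            inherits(config, "QuantConfig"))
  structure(list(sample_id = sample_id, target = target,
                 sample_reps = as.numeric(sample_reps),
                 extraction_negs = as.numeric(extraction_negs),
                 pcr_negs = as.numeric(pcr_negs),
                 config = config),
            class = "QpcrPanel")
}

#' qPCR detection call
#'
#' A target is above detection only if every sample replicate exceeds every
#' extraction-negative AND every PCR-negative replicate by more than the
#' detection factor (default 2). Equivalently:
#' `min(sample reps) > factor * max(all negative reps)`. The rule is
#' deliberately conservative for low-biomass work: one replicate near
#' background fails the whole call.
#'
#' @param panel a [qpcr_panel()].
#' @return logical scalar.
#' @export
qpcr_above_detection <- function(panel) {
  stopifnot(inherits(panel, "QpcrPanel"))
  f <- panel$config$detection_factor
  negs <- c(panel$extraction_negs, panel$pcr_negs)
  all(panel$sample_reps > f * max(negs))
}

#' Limit of detection implied by a panel's negative controls
#'
#' The smallest replicate value that would pass [qpcr_above_detection()]:
#' `factor * max(negative replicates)`, in copies/uL.
#' @param panel a [qpcr_panel()].
#' @export
qpcr_lod <- function(panel) {
  stopifnot(inherits(panel, "QpcrPanel"))
  panel$config$detection_factor * max(c(panel$extraction_negs, panel$pcr_negs))
}

#' Background-subtracted copy number
#'
#' For an above-detection panel, subtracts the mean of the highest negative
#' control (whichever of the extraction- or PCR-negative means is larger in
#' that run) from the mean of the sample replicates; the result is floored
#' at zero. Calling this on a below-detection panel is a contract error -
#' below-detection results must be reported as such (see [quantify_panel()]),
#' never as numbers.
#'
#' @param panel a [qpcr_panel()].
#' @return corrected copies per uL of extract.
#' @export
qpcr_corrected_copies <- function(panel) {
  stopifnot(inherits(panel, "QpcrPanel"))
  if (!qpcr_above_detection(panel))
    stop("panel for '", panel$sample_id,
         "' is below detection; no corrected copy number is defined")
  bg <- max(mean(panel$extraction_negs), mean(panel$pcr_negs))
  max(mean(panel$sample_reps) - bg, 0)
}

#' Scale extract concentration to copies per gram of sample
#'
#' `copies_per_g = copies_per_uL * elution_volume / extracted_mass`.
#'
#' @param corrected copies per uL from [qpcr_corrected_copies()].
#' @param config a [quant_config()] with `elution_volume` (uL) and
#'   `extracted_mass` (g) set.
#' @return copies per gram.
#' @export
copies_per_gram <- function(corrected, config) {
  stopifnot(inherits(config, "QuantConfig"), corrected >= 0)
  if (is.na(config$elution_volume) || is.na(config$extracted_mass))
    stop("copies_per_gram needs elution_volume and extracted_mass in the config")
  if (config$extracted_mass <= 0) stop("extracted_mass must be > 0")
  corrected * config$elution_volume / config$extracted_mass
}

#' Convert gene copies per gram to cell density
#'
#' `cells_per_cm3 = copies_per_g * sediment_density / operons_per_cell`,
#' with defaults of 2.5 g cm^-3 and 4 rRNA operons per (bacterial) cell.
#' For Archaea, supply a different `operons_per_cell` in the config.
#'
#' @param copies_per_g gene copies per gram of sample.
#' @param config a [quant_config()].
#' @return cells per cubic centimetre.
#' @export
cells_per_cm3 <- function(copies_per_g, config = quant_config()) {
  stopifnot(inherits(config, "QuantConfig"), all(copies_per_g >= 0))
  copies_per_g * config$sediment_density / config$operons_per_cell
}

#' Full quantification of one qPCR panel
#'
#' Applies the detection rule, background subtraction, per-gram scaling and
#' cell-density conversion in order. Below-detection panels yield an
#' explicit below-detection record carrying the run's limit of detection,
#' with `NA` (never zero) in the quantitative fields.
#'
#' @param panel a [qpcr_panel()].
#' @return one-row data.frame of class `QuantResult`: `sample_id`, `target`,
#'   `above_detection`, `lod_copies_per_uL`, `corrected_copies_per_uL`,
#'   `copies_per_g`, `cells_per_cm3`.
#' @export
quantify_panel <- function(panel) {
  stopifnot(inherits(panel, "QpcrPanel"))
  det <- qpcr_above_detection(panel)
  cfg <- panel$config
  if (det) {
    corr <- qpcr_corrected_copies(panel)
    cpg <- if (!is.na(cfg$elution_volume) && !is.na(cfg$extracted_mass))
      copies_per_gram(corr, cfg) else NA_real_
    cells <- if (!is.na(cpg)) cells_per_cm3(cpg, cfg) else NA_real_
  } else {
    corr <- cpg <- cells <- NA_real_
  }
  out <- data.frame(sample_id = panel$sample_id, target = panel$target,
                    above_detection = det,
                    lod_copies_per_uL = qpcr_lod(panel),
                    corrected_copies_per_uL = corr,
                    copies_per_g = cpg,
                    cells_per_cm3 = cells,
                    stringsAsFactors = FALSE)
  class(out) <- c("QuantResult", "data.frame")
  out
}

#' Microsphere tracer QC flag
#'
#' Fluorescent microspheres deployed in the core barrel mark drilling-fluid
#' intrusion when recovered from a sample interior.
#'
#' @param microsphere_count count per g or cm^3; `NA` means not measured.
#' @return `"CLEAN"`, `"FLAGGED"`, or `"NOT_MEASURED"` (vectorized).
#' @export
microsphere_flag <- function(microsphere_count) {
  ifelse(is.na(microsphere_count), "NOT_MEASURED",
         ifelse(microsphere_count > 0, "FLAGGED", "CLEAN"))
}

#' Read qPCR replicate tables
#'
#' CSV/TSV with columns `sample_id`, `target`, `replicate`,
#' `copies_per_uL`, `is_extraction_negative`, `is_pcr_negative`. Negative
#' rows apply to every sample of the same target (one shared run background).
#'
#' @param path file path (delimiter sniffed from the header line).
#' @param config a [quant_config()] applied to every panel.
#' @return list of [qpcr_panel()] objects, one per sample/target pair.
#' @export
read_qpcr_panels <- function(path, config = quant_config()) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "target", "copies_per_uL",
            "is_extraction_negative", "is_pcr_negative")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("qPCR table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$is_extraction_negative <- as.logical(df$is_extraction_negative)
  df$is_pcr_negative <- as.logical(df$is_pcr_negative)
  panels <- list()
  for (tgt in unique(df$target)) {
    sub <- df[df$target == tgt, , drop = FALSE]
    ext <- sub$copies_per_uL[sub$is_extraction_negative]
    pcr <- sub$copies_per_uL[sub$is_pcr_negative]
    if (!length(ext) || !length(pcr))
      stop("target ", tgt, " lacks extraction- and/or PCR-negative replicates")
    smp <- sub[!sub$is_extraction_negative & !sub$is_pcr_negative, , drop = FALSE]
    for (sid in unique(smp$sample_id)) {
      panels[[paste(sid, tgt, sep = ":")]] <- qpcr_panel(
        sample_id = sid, target = tgt,
        sample_reps = smp$copies_per_uL[smp$sample_id == sid],
        extraction_negs = ext, pcr_negs = pcr, config = config)
    }
  }
  panels[order(names(panels))]
}
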