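#' Synthetic source community profiles
#'
#' A source profile is a pool of OTUs with a fixed relative-abundance vector,
#' representing one origin of reads in a low-biomass amplicon library:
#' endemic subsurface communities (clay-, carbonate-, or basalt-hosted,
#' Chloroflexi/Atribacteria/Aerophobetes-weighted), seawater and drilling
#' fluid (SAR11/SAR86/Flavobacteriia-weighted), or laboratory reagents
#' (Actinobacteria/Firmicutes-weighted). Rank abundances are drawn lognormal
#' and normalized; lineages are labels for aggregation tests, with no
#' phylogenetic realism claimed.
#'
#' @param label one of `"ENDEMIC_CLAY"`, `"ENDEMIC_CARBONATE"`,
#'   `"ENDEMIC_BASALT"`, `"SEAWATER"`, `"REAGENT"`.
#' @param n_otus pool size.
#' @param sigma lognormal sd of the rank-abundance draw (default 1.5).
#' @return list of class `SourceProfile`: `label`, `otu_ids`, `lineages`
#'   (named list), `abundance` (named, sums to 1).
#' @export
source_profile <- function(label, n_otus = 60L, sigma = 1.5) {
  pools <- list(
    ENDEMIC_CLAY = list(
      c("Bacteria", "Chloroflexi", "Dehalococcoidia"),
      c("Bacteria", "Chloroflexi", "Anaerolineae"),
      c("Bacteria", "Atribacteria", "JS1"),
      c("Bacteria", "Planctomycetes", "Phycisphaerae"),
      c("Bacteria", "Nitrospirae", "Nitrospira")),
    ENDEMIC_CARBONATE = list(
      c("Bacteria", "Chloroflexi", "Dehalococcoidia"),
      c("Bacteria", "Aerophobetes", "Aerophobia"),
      c("Bacteria", "Proteobacteria", "Deltaproteobacteria")),
    ENDEMIC_BASALT = list(
      c("Bacteria", "Actinobacteria", "Actinobacteria"),
      c("Bacteria", "Proteobacteria", "Alphaproteobacteria"),
      c("Bacteria", "Firmicutes", "Bacilli")),
    SEAWATER = list(
      c("Bacteria", "Proteobacteria", "Alphaproteobacteria", "SAR11_clade"),
      c("Bacteria", "Proteobacteria", "Gammaproteobacteria", "SAR86_clade"),
      c("Bacteria", "Bacteroidetes", "Flavobacteriia"),
      c("Bacteria", "Cyanobacteria", "Cyanobacteria")),
    REAGENT = list(
      c("Bacteria", "Actinobacteria", "Actinobacteria", "Micrococcales",
        "Micrococcaceae", "Arthrobacter"),
      c("Bacteria", "Actinobacteria", "Actinobacteria", "Corynebacteriales",
        "Nocardiaceae", "Rhodococcus"),
      c("Bacteria", "Firmicutes", "Bacilli", "Bacillales"),
      c("Bacteria", "Firmicutes", "Clostridia", "Clostridiales"),
      c("Bacteria", "Proteobacteria", "Betaproteobacteria", "Burkholderiales")))
  if (!label %in% names(pools)) stop("unknown source label '", label, "'")
  ids <- sprintf("Otu_%s_%03d", label, seq_len(n_otus))
  ab <- stats::rlnorm(n_otus, meanlog = 0, sdlog = sigma)
  lineages <- pools[[label]][1L + (seq_len(n_otus) - 1L) %% length(pools[[label]])]
  structure(list(label = label, otu_ids = ids,
                 lineages = stats::setNames(lineages, ids),
                 abundance = stats::setNames(ab / sum(ab), ids)),
            class = "SourceProfile")
}

default_source_profiles <- function(n_otus = 60L, sigma = 1.5) {
  labs <- c("ENDEMIC_CLAY", "ENDEMIC_CARBONATE", "ENDEMIC_BASALT",
            "SEAWATER", "REAGENT")
  stats::setNames(lapply(labs, source_profile, n_otus = n_otus, sigma = sigma),
                  labs)
}

#' Mixing specification for synthetic sample libraries
#'
#' Describes the stated world the screen is validated against: each sample
#' library is a multinomial draw from a mixture of its endemic source and a
#' contaminant pool, with the contaminant read fraction
#' `phi_s = kappa / (kappa + B_s)` shrinking as sample biomass `B_s` grows -
#' low-biomass libraries are mostly contamination, high-biomass ones barely
#' touched. The contaminant pool is split `omega` seawater : `1 - omega`
#' reagent. The control library is drawn from the contaminant pool, plus an
#' optional leak `epsilon` of pooled endemic reads (sample material carried
#' into the control during handling).
#'
#' Defaults emulate deep subseafloor amplicon surveys: 8 samples with
#' biomass spanning ~3.5 orders of magnitude so contaminant fractions span
#' roughly 2-98%, and library sizes drawn uniformly from 3,000-16,000 reads.
#'
#' @param samples data.frame with columns `sample_id`, `biomass` (> 0),
#'   `material` (`"clay"`, `"carbonate"`, `"basalt"`), and optionally
#'   `library_size` (`NA` = draw uniformly from `library_size_range`).
#' @param kappa contamination pressure (> 0), default 1.
#' @param omega seawater share of the contaminant pool, in `[0, 1]`.
#' @param epsilon endemic leak fraction into the control, in `[0, 1)`.
#' @param control_id sample id given to the control library.
#' @param control_library_size reads in the control library (default 3732).
#' @param library_size_range range library sizes are drawn from when not
#'   given explicitly.
#' @param shared_fraction fraction of the seawater pool whose OTUs also
#'   occur, at their seawater abundances, in every endemic profile
#'   (genuinely cosmopolitan taxa); default 0 keeps the source supports
#'   pairwise disjoint.
#' @return list of class `MixtureSpec`.
#' @export
mixture_spec <- function(samples = NULL, kappa = 1, omega = 0.5,
                         epsilon = 0, control_id = "CONTROL",
                         control_library_size = 3732L,
                         library_size_range = c(3000L, 16000L),
                         shared_fraction = 0) {
  if (is.null(samples)) {
    n <- 8L
    samples <- data.frame(
      sample_id = sprintf("S%02d", seq_len(n)),
      biomass = 10 ^ seq(log10(0.02), log10(50), length.out = n),
      material = rep(c("clay", "clay", "carbonate", "basalt"), 2L),
      library_size = NA_integer_,
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("sample_id", "biomass", "material") %in% names(samples)),
            all(samples$biomass > 0),
            kappa > 0, omega >= 0, omega <= 1, epsilon >= 0, epsilon < 1,
            control_library_size > 0,
            shared_fraction >= 0, shared_fraction <= 1)
  if (!"library_size" %in% names(samples)) samples$library_size <- NA_integer_
  if (control_id %in% samples$sample_id)
    stop("control_id collides with a sample id")
  structure(list(samples = samples, kappa = kappa, omega = omega,
                 epsilon = epsilon, control_id = control_id,
                 control_library_size = as.integer(control_library_size),
                 library_size_range = as.integer(library_size_range),
                 shared_fraction = shared_fraction),
            class = "MixtureSpec")
}

contaminant_fraction <- function(kappa, biomass) kappa / (kappa + biomass)

#' Generate a synthetic screened-community dataset with ground truth
#'
#' Draws an OTU count table (samples plus one background control), a
#' taxonomy map, sample metadata, and a `SyntheticTruth` record, under a
#' fixed seed (identical seeds give identical datasets). Sample `s` draws
#' `N_s` reads multinomially from
#' `(1 - phi_s) * endemic(material_s) + phi_s * (omega * seawater +
#' (1 - omega) * reagent)`; the control draws from the contaminant pool with
#' an `epsilon`-weighted admixture of the pooled endemic profiles. Every OTU
#' carries exactly one source label; with `epsilon = 0` the endemic and
#' contaminant supports are disjoint, so a perfect screen removes every
#' contaminant-origin read.
#'
#' @param spec a [mixture_spec()].
#' @param profiles named list of [source_profile()]s (all five labels);
#'   default profiles are drawn under the same seed.
#' @param seed integer RNG seed.
#' @return list: `table` (an [otu_table()] with the control designated),
#'   `taxonomy`, `metadata`, `truth` (class `SyntheticTruth`: `otu_sources`,
#'   `sample_mixture` with realized `phi`, `expected_overlap`).
#' @export
generate_dataset <- function(spec = mixture_spec(), profiles = NULL, seed = 1L) {
  stopifnot(inherits(spec, "MixtureSpec"))
  set.seed(as.integer(seed))
  if (is.null(profiles)) profiles <- default_source_profiles()
  need <- c("ENDEMIC_CLAY", "ENDEMIC_CARBONATE", "ENDEMIC_BASALT",
            "SEAWATER", "REAGENT")
  if (!all(need %in% names(profiles)))
    stop("profiles must cover: ", paste(need, collapse = ", "))

  all_ids <- unlist(lapply(profiles[need], `[[`, "otu_ids"), use.names = FALSE)
  if (anyDuplicated(all_ids)) stop("source pools must have disjoint OTU ids")
  sources <- stats::setNames(
    rep(need, vapply(profiles[need], function(p) length(p$otu_ids), 1L)),
    all_ids)

  expand <- function(p) {
    v <- stats::setNames(numeric(length(all_ids)), all_ids)
    v[names(p$abundance)] <- p$abundance
    v
  }
  endemic_of <- c(clay = "ENDEMIC_CLAY", carbonate = "ENDEMIC_CARBONATE",
                  basalt = "ENDEMIC_BASALT")
  contaminant <- spec$omega * expand(profiles$SEAWATER) +
    (1 - spec$omega) * expand(profiles$REAGENT)

  # cosmopolitan taxa: a fraction of the seawater pool also lives in every
  # endemic profile (at its seawater abundance, renormalized)
  endemic_p <- lapply(profiles[unname(endemic_of)], expand)
  names(endemic_p) <- unname(endemic_of)
  if (spec$shared_fraction > 0) {
    sw <- profiles$SEAWATER
    n_shared <- floor(spec$shared_fraction * length(sw$otu_ids))
    shared_ids <- sw$otu_ids[seq_len(n_shared)]
    for (lab in names(endemic_p)) {
      v <- endemic_p[[lab]]
      v[shared_ids] <- v[shared_ids] + sw$abundance[shared_ids]
      endemic_p[[lab]] <- v / sum(v)
    }
  }

  smp <- spec$samples
  smp$library_size <- ifelse(
    is.na(smp$library_size),
    sample(spec$library_size_range[1L]:spec$library_size_range[2L],
           nrow(smp), replace = TRUE),
    smp$library_size)
  phi <- contaminant_fraction(spec$kappa, smp$biomass)

  counts <- matrix(0L, nrow = length(all_ids), ncol = nrow(smp) + 1L,
                   dimnames = list(all_ids,
                                   c(smp$sample_id, spec$control_id)))
  for (i in seq_len(nrow(smp))) {
    p <- (1 - phi[i]) * endemic_p[[endemic_of[[smp$material[i]]]]] +
      phi[i] * contaminant
    counts[, i] <- stats::rmultinom(1L, smp$library_size[i], p)
  }
  pooled_endemic <- Reduce(`+`, endemic_p)
  pooled_endemic <- pooled_endemic / sum(pooled_endemic)
  p_ctrl <- (contaminant + spec$epsilon * pooled_endemic) / (1 + spec$epsilon)
  counts[, spec$control_id] <-
    stats::rmultinom(1L, spec$control_library_size, p_ctrl)

  lineages <- do.call(c, unname(lapply(profiles[need], `[[`, "lineages")))
  metadata <- data.frame(
    sample_id = c(smp$sample_id, spec$control_id),
    depth_mbsf = c(seq(30, 30 + 50 * (nrow(smp) - 1L), by = 50), NA),
    lithology = c(smp$material, "control_artifact"),
    material = c(ifelse(smp$material == "basalt", "basalt", "sediment"),
                 "control_artifact"),
    microsphere_count = c(rep(0, nrow(smp)), NA),
    stringsAsFactors = FALSE)

  truth <- structure(
    list(otu_sources = sources,
         sample_mixture = data.frame(sample_id = smp$sample_id,
                                     biomass = smp$biomass,
                                     phi = phi,
                                     library_size = smp$library_size,
                                     stringsAsFactors = FALSE),
         expected_overlap = stats::setNames(phi, smp$sample_id),
         omega = spec$omega, epsilon = spec$epsilon),
    class = "SyntheticTruth")

  list(table = otu_table(counts[rowSums(counts) > 0, , drop = FALSE],
                         control = spec$control_id),
       taxonomy = taxonomy_map(lineages),
       metadata = metadata,
       truth = truth)
}

#' Generate synthetic qPCR panels with known truth
#'
#' For each named true copy number, draws a run background level
#' log-uniformly so that the implied limit of detection spans the typical
#' low-biomass range (35-285 copies/uL by default), then generates
#' negative-control and sample replicates with multiplicative lognormal
#' noise. With `noise_sigma = 0` replicates are exact, so the detection call
#' matches the deterministic rule on the true values.
#'
#' @param true_copies named numeric vector of true copies/uL per sample.
#' @param seed integer RNG seed.
#' @param lod_range range the implied LOD is drawn from (copies/uL).
#' @param noise_sigma sdlog of the replicate noise (default 0.2).
#' @param n_reps replicates per sample and per negative type (default 2).
#' @param config a [quant_config()].
#' @return list with `panels` (list of [qpcr_panel()]) and `truth`
#'   (data.frame: `sample_id`, `true_copies`, `background`,
#'   `expected_detected`).
#' @export
generate_qpcr_panels <- function(true_copies, seed = 1L,
                                 lod_range = c(35, 285), noise_sigma = 0.2,
                                 n_reps = 2L, config = quant_config()) {
  stopifnot(!is.null(names(true_copies)), all(true_copies >= 0))
  set.seed(as.integer(seed))
  noise <- function(n) if (noise_sigma == 0) rep(1, n)
    else stats::rlnorm(n, meanlog = -noise_sigma^2 / 2, sdlog = noise_sigma)
  panels <- list(); truth <- list()
  for (sid in names(true_copies)) {
    lod <- exp(stats::runif(1L, log(lod_range[1L]), log(lod_range[2L])))
    bg <- lod / config$detection_factor
    panels[[sid]] <- qpcr_panel(
      sample_id = sid, target = "BACTERIA_16S",
      sample_reps = (true_copies[[sid]] + bg) * noise(n_reps),
      extraction_negs = bg * noise(n_reps),
      pcr_negs = bg * noise(n_reps),
      config = config)
    truth[[sid]] <- data.frame(
      sample_id = sid, true_copies = true_copies[[sid]], background = bg,
      expected_detected = (true_copies[[sid]] + bg) >
        config$detection_factor * bg,
      stringsAsFactors = FALSE)
  }
  list(panels = panels, truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Score a bin assignment against synthetic ground truth
#'
#' Sensitivity is the fraction of contaminant-origin (seawater or reagent)
#' OTUs that the screen removes (any bin other than `SAMPLES_ONLY`);
#' specificity is the fraction of endemic-origin OTUs retained
#' (`SAMPLES_ONLY`).
#'
#' @param truth a `SyntheticTruth` from [generate_dataset()].
#' @param bins a `BinAssignment` on (a filtered subset of) the same OTU
#'   universe; OTUs unknown to the truth are an error.
#' @return list of class `RecoveryMetrics`: `sensitivity`, `specificity`,
#'   `confusion` (source label x bin contingency table).
#' @export
evaluate_binning <- function(truth, bins) {
  stopifnot(inherits(truth, "SyntheticTruth"), inherits(bins, "BinAssignment"))
  unknown <- setdiff(bins$otu_id, names(truth$otu_sources))
  if (length(unknown))
    stop("OTU(s) not in the truth universe: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  src <- truth$otu_sources[bins$otu_id]
  contaminant <- src %in% c("SEAWATER", "REAGENT")
  removed <- bins$bin != "SAMPLES_ONLY"
  structure(list(
    sensitivity = if (any(contaminant)) mean(removed[contaminant]) else NA_real_,
    specificity = if (any(!contaminant)) mean(!removed[!contaminant]) else NA_real_,
    confusion = table(source = src, bin = bins$bin)),
    class = "RecoveryMetrics")
}

#' @export
print.RecoveryMetrics <- function(x, ...) {
  cat(sprintf("screen recovery: sensitivity %.3f, specificity %.3f\n",
              x$sensitivity, x$specificity))
  print(x$confusion)
  invisible(x)
}
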