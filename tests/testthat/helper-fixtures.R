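# Fixture builders and independent oracles shared across the suite.

# Counts matrix with auto-generated ids: rows Otu01..., cols s1...
mk_counts <- function(..., nrow, byrow = TRUE) {
  vals <- c(...)
  m <- matrix(as.integer(vals), nrow = nrow, byrow = byrow)
  dimnames(m) <- list(sprintf("Otu%02d", seq_len(nrow(m))),
                      sprintf("s%d", seq_len(ncol(m))))
  m
}

# Random non-degenerate OTU table: every OTU present somewhere, every
# sample column non-zero.
random_table <- function(n_otu, n_sample, max_count = 30L, control = "ctrl") {
  repeat {
    m <- matrix(stats::rpois(n_otu * n_sample, 2), nrow = n_otu)
    m[m > max_count] <- max_count
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
  }
  dimnames(m) <- list(sprintf("Otu%02d", seq_len(n_otu)),
                      c(control, sprintf("s%d", seq_len(n_sample - 1L))))
  otu_table(m, control = control)
}

# Independent brute-force oracle for the four-bin classification: literal
# per-OTU evaluation of the bin definitions, no shared code with assign_bins.
oracle_bins <- function(counts, control, threshold = 10, strict = FALSE) {
  n <- colSums(counts)
  samples <- setdiff(colnames(counts), control)
  out <- character(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    c_ctrl <- counts[i, control]
    c_smp <- counts[i, samples]
    if (c_ctrl > 0 && all(c_smp == 0)) { out[i] <- "CONTROL_ONLY"; next }
    if (c_ctrl == 0) { out[i] <- "SAMPLES_ONLY"; next }
    r_ctrl <- c_ctrl / n[control]
    ratios <- (c_smp / n[samples]) / r_ctrl
    hit <- if (strict) any(ratios > threshold) else any(ratios >= threshold)
    out[i] <- if (hit) "TENFOLD_SAMPLE" else "CONTROL_SAMPLE"
  }
  stats::setNames(out, rownames(counts))
}

# Brute-force Jaccard on explicit sets.
oracle_jaccard <- function(counts) {
  sets <- apply(counts > 0, 2, function(col) rownames(counts)[col],
                simplify = FALSE)
  n <- length(sets)
  j <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    u <- union(sets[[a]], sets[[b]])
    j[a, b] <- if (length(u) == 0) 0 else
      length(intersect(sets[[a]], sets[[b]])) / length(u)
  }
  j
}
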