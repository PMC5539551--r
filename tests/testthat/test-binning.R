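test_that("relative abundance normalizes columns to 1", {
  m <- mk_counts(2, 3, 5, nrow = 3)
  tab <- otu_table(m)
  r <- compute_relative_abundance(tab)
  expect_equal(unname(r[, 1]), c(0.2, 0.3, 0.5))
  expect_equal(unname(colSums(r)), rep(1, ncol(m)), tolerance = 1e-12)

  m0 <- mk_counts(1, 0, 2, 0, nrow = 2)
  expect_error(compute_relative_abundance(otu_table(m0)), "s2")
})

test_that("bin definitions are honored on hand-built cases", {
  # rows: control-only, samples-only, >10x enriched, comparable abundance
  m <- matrix(c(5L,   0L,  0L,
                0L,  20L,  1L,
                1L,  90L,  1L,
                10L, 30L,  1L),
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("Otu", 1:4), c("ctrl", "sA", "sB")))
  tab <- otu_table(m, control = "ctrl")
  bins <- assign_bins(tab)
  expect_equal(as.character(bins$bin),
               c("CONTROL_ONLY", "SAMPLES_ONLY", "TENFOLD_SAMPLE",
                 "CONTROL_SAMPLE"))
  # ratio uses the max over non-control samples on relative abundances
  n <- library_sizes(tab)
  expect_equal(bins$ratio[3], (90 / n[["sA"]]) / (1 / n[["ctrl"]]))
  expect_true(is.na(bins$ratio[2]))

  # an OTU exactly at T is enriched under "ge" but not under "gt"
  at_t <- assign_bins(tab, config = screen_config(
    ratio_threshold = bins$ratio[3], ratio_comparison = "ge"))
  expect_equal(as.character(at_t$bin[3]), "TENFOLD_SAMPLE")
  at_t_gt <- assign_bins(tab, config = screen_config(
    ratio_threshold = bins$ratio[3], ratio_comparison = "gt"))
  expect_equal(as.character(at_t_gt$bin[3]), "CONTROL_SAMPLE")
})

test_that("assign_bins requires a usable control", {
  tab <- otu_table(mk_counts(1, 2, 3, 4, nrow = 2))
  expect_error(assign_bins(tab), "control")
  expect_error(assign_bins(compute_relative_abundance(tab), "zz",
                           screen_config()), "not found")
})

test_that("bins agree with the brute-force oracle on random small tables", {
  set.seed(101)
  for (rep in 1:40) {
    n_otu <- sample(3:20, 1)
    n_smp <- sample(2:5, 1)
    tab <- random_table(n_otu, n_smp)
    threshold <- sample(c(2, 5, 10), 1)
    for (cmp in c("ge", "gt")) {
      bins <- assign_bins(tab, config = screen_config(
        ratio_threshold = threshold, ratio_comparison = cmp))
      expected <- oracle_bins(tab$counts, "ctrl", threshold,
                              strict = (cmp == "gt"))
      expect_equal(stats::setNames(as.character(bins$bin), bins$otu_id),
                   expected[bins$otu_id])
      # partition invariant
      expect_equal(sum(table(bins$bin)), n_otu)
    }
  }
})

test_that("raising T only moves OTUs across the tenfold/control:sample line", {
  set.seed(55)
  tab <- random_table(25, 5)
  thresholds <- c(1.5, 3, 10, 50, 1e6)
  prev <- NULL
  for (T in thresholds) {
    bins <- assign_bins(tab, config = screen_config(ratio_threshold = T))
    sizes <- table(bins$bin)
    if (!is.null(prev)) {
      expect_equal(sizes[["CONTROL_ONLY"]], prev[["CONTROL_ONLY"]])
      expect_equal(sizes[["SAMPLES_ONLY"]], prev[["SAMPLES_ONLY"]])
      expect_lte(sizes[["TENFOLD_SAMPLE"]], prev[["TENFOLD_SAMPLE"]])
      expect_gte(sizes[["CONTROL_SAMPLE"]], prev[["CONTROL_SAMPLE"]])
    }
    prev <- sizes
  }
})

test_that("apply_screen retains only samples-only OTUs and conserves reads", {
  set.seed(9)
  tab <- random_table(20, 5)
  bins <- assign_bins(tab)
  res <- apply_screen(tab, bins)

  expect_false(control_id(tab) %in% sample_ids(res$table))
  kept <- otu_ids(res$table)
  expect_true(all(tab$counts[kept, control_id(tab)] == 0))
  expect_true(all(res$bins$bin[match(kept, res$bins$otu_id)] == "SAMPLES_ONLY"))
  # no reads created; screened counts match the input on the kept block
  expect_true(all(res$samples$post_screen_reads <= res$samples$pre_screen_reads))
  expect_equal(res$table$counts, tab$counts[kept, sample_ids(res$table)])
  expect_true(all(res$samples$overlap_fraction >= 0 &
                  res$samples$overlap_fraction <= 1))
  # overlap + samples-only + control-only-sample-share sums to 1 per sample
  so_reads <- colSums(tab$counts[bins$otu_id[bins$bin == "SAMPLES_ONLY"],
                                 res$samples$sample_id, drop = FALSE])
  expect_equal(res$samples$overlap_fraction +
                 unname(so_reads) / res$samples$pre_screen_reads,
               rep(1, nrow(res$samples)))
})

test_that("a sample of pure samples-only OTUs passes through unchanged", {
  m <- matrix(c(0L, 8L, 0L, 12L, 4L, 0L), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("Otu", 1:3), c("ctrl", "sA")))
  tab <- otu_table(m, control = "ctrl")
  res <- apply_screen(tab, assign_bins(tab))
  expect_equal(unname(res$table$counts[, "sA"]), c(8L, 12L))
  expect_equal(res$samples$overlap_fraction, 0)
  expect_equal(res$samples$group4_read_fraction, 0)
})

test_that("sample exclusion needs both microspheres and overlap dominance", {
  # sA: nearly all reads in control-shared OTUs; sB: low overlap
  m <- matrix(c(10L, 199L,   2L,
                 0L,   1L,  98L),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("Otu1", "Otu2"), c("ctrl", "sA", "sB")))
  tab <- otu_table(m, control = "ctrl")
  bins <- assign_bins(tab)
  md <- data.frame(sample_id = c("sA", "sB"),
                   microsphere_count = c(1.3e4, 5.8e3))
  exc <- exclude_contaminated_samples(tab, md, bins)
  expect_true(exc$excluded[exc$sample_id == "sA"])    # spheres + >99% overlap
  expect_false(exc$excluded[exc$sample_id == "sB"])   # spheres, low overlap
  expect_true(exc$flagged[exc$sample_id == "sB"])

  # microspheres absent or unmeasured: never excluded by this rule
  md2 <- data.frame(sample_id = c("sA", "sB"), microsphere_count = c(0, NA))
  exc2 <- exclude_contaminated_samples(tab, md2, bins)
  expect_false(any(exc2$excluded))
  expect_match(exc2$reason[exc2$sample_id == "sB"], "not measured")

  # the excluded sample is dropped from the screened table entirely
  res <- apply_screen(tab, bins, metadata = md)
  expect_false("sA" %in% sample_ids(res$table))
  expect_true(res$samples$excluded[res$samples$sample_id == "sA"])
})

test_that("screen_otu_table composes the stages; no-control passes through", {
  set.seed(12)
  tab <- random_table(25, 5)
  res <- screen_otu_table(tab)
  expect_s3_class(res, "ScreenResult")
  expect_false(res$unscreened)
  expect_true(nrow(res$filter_report) == 25)

  no_ctrl <- otu_table(tab$counts)
  expect_error(screen_otu_table(no_ctrl), "allow_no_control")
  pass <- screen_otu_table(no_ctrl, allow_no_control = TRUE)
  expect_true(pass$unscreened)
  expect_null(pass$bins)
  expect_equal(ncol(pass$table$counts), ncol(tab$counts))
})
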