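test_that("generation is deterministic under a fixed seed", {
  d1 <- generate_dataset(mixture_spec(), seed = 42)
  d2 <- generate_dataset(mixture_spec(), seed = 42)
  expect_identical(d1$table$counts, d2$table$counts)
  expect_identical(d1$taxonomy, d2$taxonomy)
  expect_identical(d1$truth$sample_mixture, d2$truth$sample_mixture)
  d3 <- generate_dataset(mixture_spec(), seed = 43)
  expect_false(identical(d1$table$counts, d3$table$counts))
})

test_that("requested library sizes are hit exactly and truth is complete", {
  samples <- data.frame(sample_id = c("a", "b"), biomass = c(1, 10),
                        material = c("clay", "basalt"),
                        library_size = c(5000L, 1234L))
  spec <- mixture_spec(samples, control_library_size = 2000L)
  ds <- generate_dataset(spec, seed = 5)
  n <- library_sizes(ds$table)
  expect_equal(unname(n[c("a", "b", "CONTROL")]), c(5000, 1234, 2000))
  # every OTU has exactly one source label and a lineage
  expect_true(all(otu_ids(ds$table) %in% names(ds$truth$otu_sources)))
  expect_true(all(otu_ids(ds$table) %in% names(ds$taxonomy)))
  # phi decreasing in biomass
  expect_equal(ds$truth$sample_mixture$phi, 1 / (1 + c(1, 10)))
})

test_that("invalid mixture specs are rejected", {
  expect_error(mixture_spec(kappa = 0))
  expect_error(mixture_spec(epsilon = 1))
  bad <- data.frame(sample_id = "CONTROL", biomass = 1, material = "clay")
  expect_error(mixture_spec(bad), "collides")
})

test_that("disjoint supports with phi ~ 0 give a perfect screen", {
  # enormous biomass -> contaminant fraction ~ 0; eps = 0 keeps supports
  # disjoint, so every control OTU is contaminant-origin and every sample
  # OTU endemic-origin
  samples <- data.frame(sample_id = sprintf("S%d", 1:4), biomass = 1e9,
                        material = c("clay", "carbonate", "basalt", "clay"))
  ds <- generate_dataset(mixture_spec(samples), seed = 1)
  res <- screen_otu_table(ds$table, ds$metadata)
  m <- evaluate_binning(ds$truth, res$bins)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(sum(res$bins$bin %in% c("TENFOLD_SAMPLE", "CONTROL_SAMPLE")), 0)
  src <- ds$truth$otu_sources[otu_ids(res$table)]
  expect_equal(sum(res$table$counts[src %in% c("SEAWATER", "REAGENT"), ]), 0)
})

test_that("with eps = 0, specificity is exactly 1 and sensitivity equals
           the control's coverage of contaminant OTUs", {
  for (seed in c(2, 7)) {
    ds <- generate_dataset(mixture_spec(), seed = seed)
    res <- screen_otu_table(ds$table, ds$metadata)
    m <- evaluate_binning(ds$truth, res$bins)
    expect_equal(m$specificity, 1)
    src <- ds$truth$otu_sources[res$bins$otu_id]
    contam <- res$bins$otu_id[src %in% c("SEAWATER", "REAGENT")]
    ctrl_cov <- mean(ds$table$counts[contam, "CONTROL"] > 0)
    expect_equal(m$sensitivity, ctrl_cov)
  }
})

test_that("evaluate_binning rejects OTUs outside the truth universe", {
  ds <- generate_dataset(mixture_spec(), seed = 3)
  res <- screen_otu_table(ds$table, ds$metadata)
  bins <- res$bins
  bins$otu_id[1] <- "Otu_NOT_REAL"
  expect_error(evaluate_binning(ds$truth, bins), "truth universe")
})

test_that("mean control overlap decreases strictly with sample biomass", {
  # two samples, biomass ratio 100:1, equal library sizes, 50 seeded reps
  samples <- data.frame(sample_id = c("lo", "hi"), biomass = c(0.05, 5),
                        material = "clay", library_size = 3000L)
  spec <- mixture_spec(samples, control_library_size = 2000L)
  overlap <- vapply(1:50, function(seed) {
    ds <- generate_dataset(spec, seed = seed)
    res <- screen_otu_table(ds$table, ds$metadata)
    stats::setNames(res$samples$overlap_fraction, res$samples$sample_id)[c("lo", "hi")]
  }, numeric(2))
  expect_gt(mean(overlap["lo", ]), mean(overlap["hi", ]))
  # and each seed individually orders the two samples correctly here,
  # since phi differs by more than an order of magnitude
  expect_true(all(overlap["lo", ] > overlap["hi", ]))
})

test_that("shared_fraction plants seawater OTUs in endemic communities", {
  samples <- data.frame(sample_id = "s", biomass = 1e9, material = "clay",
                        library_size = 20000L)
  ds <- generate_dataset(mixture_spec(samples, shared_fraction = 0.5), seed = 4)
  src <- ds$truth$otu_sources[otu_ids(ds$table)]
  sw_in_sample <- sum(ds$table$counts[src == "SEAWATER", "s"] > 0)
  expect_gt(sw_in_sample, 0)  # cosmopolitan OTUs show up despite phi ~ 0
})

test_that("synthetic qPCR panels behave per the detection regime", {
  # zero true copies: never detected (100 seeds)
  det0 <- vapply(1:100, function(s) {
    p <- generate_qpcr_panels(c(a = 0), seed = s)
    qpcr_above_detection(p$panels$a)
  }, logical(1))
  expect_false(any(det0))

  # 1000x the largest possible background: detected in >= 95/100 seeds
  det1k <- vapply(1:100, function(s) {
    p <- generate_qpcr_panels(c(a = 285 * 1000), seed = s)
    qpcr_above_detection(p$panels$a)
  }, logical(1))
  expect_gte(mean(det1k), 0.95)

  # zero noise: call matches the deterministic rule on true values
  for (s in 1:10) {
    p <- generate_qpcr_panels(c(a = 150, b = 5000), seed = s, noise_sigma = 0)
    for (sid in c("a", "b"))
      expect_equal(qpcr_above_detection(p$panels[[sid]]),
                   p$truth$expected_detected[p$truth$sample_id == sid])
  }

  # determinism
  p1 <- generate_qpcr_panels(c(a = 100), seed = 9)
  p2 <- generate_qpcr_panels(c(a = 100), seed = 9)
  expect_identical(p1$panels$a$sample_reps, p2$panels$a$sample_reps)
})
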