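panel <- function(reps, ext = c(10, 12), pcr = c(5, 6), cfg = quant_config())
  qpcr_panel("x", "BACTERIA_16S", reps, ext, pcr, cfg)

test_that("detection requires every replicate to clear 2x every negative", {
  expect_true(qpcr_above_detection(panel(c(100, 120))))   # 100 > 2*12
  expect_false(qpcr_above_detection(panel(c(15, 30))))    # 15 <= 24
  expect_false(qpcr_above_detection(panel(c(24, 100))))   # boundary: not >
  expect_true(qpcr_above_detection(panel(c(1, 1), ext = c(0, 0), pcr = c(0, 0))))
  expect_equal(qpcr_lod(panel(c(100, 120))), 24)
})

test_that("detection is monotone in the negatives", {
  set.seed(3)
  for (rep in 1:20) {
    reps <- stats::runif(2, 0, 300)
    ext <- stats::runif(2, 0, 100)
    pcr <- stats::runif(2, 0, 100)
    before <- qpcr_above_detection(panel(reps, ext, pcr))
    bumped <- ext + c(stats::runif(1, 0, 200), 0)
    after <- qpcr_above_detection(panel(reps, bumped, pcr))
    expect_false(after && !before)  # raising a negative never re-detects
  }
})

test_that("background subtraction uses the larger negative mean, floored", {
  expect_equal(qpcr_corrected_copies(panel(c(100, 120))), 110 - 11)
  expect_equal(qpcr_corrected_copies(panel(c(50, 50), ext = c(0, 0),
                                           pcr = c(0, 0))), 50)
  # PCR negatives higher than extraction negatives: their mean is subtracted
  expect_equal(qpcr_corrected_copies(panel(c(200, 220), ext = c(2, 4),
                                           pcr = c(20, 30))), 210 - 25)
  expect_error(qpcr_corrected_copies(panel(c(15, 30))), "below detection")
})

test_that("per-gram scaling and cell conversion follow the stated formulas", {
  cfg <- quant_config(elution_volume = 100, extracted_mass = 1)
  expect_equal(copies_per_gram(99, cfg), 9900)
  expect_equal(copies_per_gram(0, cfg), 0)
  expect_error(copies_per_gram(10, quant_config()), "elution_volume")

  expect_equal(cells_per_cm3(4.2e3), 2.625e3)        # x 2.5 / 4
  expect_equal(cells_per_cm3(4.2e3, quant_config(operons_per_cell = 1)),
               1.05e4)
  expect_equal(cells_per_cm3(0), 0)
  # linearity and operon scaling
  expect_equal(cells_per_cm3(2e5), 2 * cells_per_cm3(1e5))
  expect_equal(cells_per_cm3(1e5, quant_config(operons_per_cell = 2)),
               2 * cells_per_cm3(1e5, quant_config(operons_per_cell = 4)))
})

test_that("quantify_panel reports below-detection as NA with an LOD", {
  cfg <- quant_config(elution_volume = 50, extracted_mass = 2)
  res <- quantify_panel(qpcr_panel("a", "BACTERIA_16S", c(100, 120),
                                   c(10, 12), c(5, 6), cfg))
  expect_true(res$above_detection)
  expect_equal(res$copies_per_g, 99 * 50 / 2)
  expect_equal(res$cells_per_cm3, res$copies_per_g * 2.5 / 4)

  nd <- quantify_panel(panel(c(15, 30)))
  expect_false(nd$above_detection)
  expect_true(is.na(nd$corrected_copies_per_uL))
  expect_equal(nd$lod_copies_per_uL, 24)
})

test_that("microsphere flags follow presence/absence/missing", {
  expect_equal(microsphere_flag(c(0, 79, NA)),
               c("CLEAN", "FLAGGED", "NOT_MEASURED"))
})

test_that("qPCR replicate tables parse into per-sample panels", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,target,replicate,copies_per_uL,is_extraction_negative,is_pcr_negative",
    "A,BACTERIA_16S,1,100,FALSE,FALSE",
    "A,BACTERIA_16S,2,120,FALSE,FALSE",
    "B,BACTERIA_16S,1,15,FALSE,FALSE",
    "B,BACTERIA_16S,2,30,FALSE,FALSE",
    "NEG,BACTERIA_16S,1,10,TRUE,FALSE",
    "NEG,BACTERIA_16S,2,12,TRUE,FALSE",
    "NEG,BACTERIA_16S,1,5,FALSE,TRUE",
    "NEG,BACTERIA_16S,2,6,FALSE,TRUE"), path)
  panels <- read_qpcr_panels(path)
  expect_length(panels, 2L)
  expect_true(qpcr_above_detection(panels[["A:BACTERIA_16S"]]))
  expect_false(qpcr_above_detection(panels[["B:BACTERIA_16S"]]))
  expect_equal(panels[["A:BACTERIA_16S"]]$extraction_negs, c(10, 12))

  writeLines(c(
    "sample_id,target,replicate,copies_per_uL,is_extraction_negative,is_pcr_negative",
    "A,BACTERIA_16S,1,100,FALSE,FALSE"), path)
  expect_error(read_qpcr_panels(path), "negative")
})
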