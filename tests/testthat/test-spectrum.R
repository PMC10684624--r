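test_that("CSV peak lists round-trip through disk", {
  p <- peaklist(c(100.123456, 250.5, 493.2097), c(10, 0, 35.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_peaklist(p, path)
  q <- read_peaklist(path)
  expect_equal(q$mz, p$mz, tolerance = 1e-6)
  expect_equal(q$intensity, p$intensity, tolerance = 1e-6)
  expect_identical(length(q), 3L)
})

test_that("MSP blocks parse per the NIST text layout", {
  path <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("Name: synthetic EI demo", "Formula: C45H80O7Si5",
               "Num Peaks: 2", "815 100", "872 40"), path)
  p <- read_peaklist(path)
  expect_identical(length(p), 2L)
  expect_identical(p$mz, c(815, 872))
  expect_identical(p$mode, "EI")
  expect_identical(p$resolution, "unit")
  # write-read round trip
  out <- withr::local_tempfile(fileext = ".msp")
  write_peaklist(p, out)
  q <- read_peaklist(out)
  expect_equal(q$mz, p$mz)
  expect_equal(q$intensity, p$intensity)
})

test_that("invalid peak data is rejected with offending rows named", {
  expect_error(peaklist(c(2, 1), c(1, 1)), "row\\(s\\) 2")
  expect_error(peaklist(c(1, 2), c(1, -1)), "row\\(s\\) 2")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,intensity", "200,5", "100,4"), path)
  expect_error(read_peaklist(path), "strictly increasing")
})

test_that("scan averaging merges within tolerance with weighted-mean m/z", {
  s1 <- peaklist(100.000, 10)
  s2 <- peaklist(100.001, 30)
  avg <- average_spectra(list(s1, s2), bin_tolerance_mda = 5)
  expect_identical(length(avg), 1L)
  expect_equal(avg$intensity, 20)
  expect_equal(avg$mz, 100.00075, tolerance = 1e-9)
  # identity cases
  one <- average_spectra(list(s1))
  expect_equal(one$mz, s1$mz)
  expect_equal(one$intensity, s1$intensity)
  same <- average_spectra(list(s2, s2, s2))
  expect_equal(same$mz, s2$mz)
  expect_equal(same$intensity, s2$intensity)
  expect_error(average_spectra(list()), "non-empty")
})

test_that("annotation matches nearest peak within tolerance, ties by intensity", {
  p <- peaklist(c(559.35, 616.0, 617.0), c(80, 5, 50),
                mode = "EI", resolution = "unit")
  preds <- predict_ei_fragments(derivatized_formula(ted13, "TBDMS", 3),
                                "TBDMS")
  ann <- annotate_peaks(p, data.frame(label = preds$label, mz = preds$mz))
  m <- ann$matched
  expect_true("[M-C4H9]+" %in% m$label)             # 559 matches 559.35
  expect_equal(m$peak_mz[m$label == "[M-C4H9]+"], 559.35)
  # prediction 616 ([M]+.) is equidistant from nothing; matches 616.0
  expect_equal(m$peak_mz[m$label == "[M]+."], 616.0)
  # tie-break: two peaks exactly 0.5 from a prediction -> more intense wins
  p2 <- peaklist(c(99.5, 100.5), c(5, 50), mode = "EI", resolution = "unit")
  ann2 <- annotate_peaks(p2, data.frame(label = "x", mz = 100))
  expect_equal(ann2$matched$peak_mz, 100.5)
  # empty peak list: zero annotations, all unmatched, no error
  empty <- peaklist(numeric(0), numeric(0))
  ann3 <- annotate_peaks(empty, data.frame(label = "x", mz = 100))
  expect_identical(nrow(ann3$matched), 0L)
  expect_identical(nrow(ann3$unmatched), 1L)
})

test_that("annotation is tolerance-monotone", {
  set.seed(51)
  p <- peaklist(sort(runif(30, 100, 900)), runif(30, 1, 100))
  preds <- data.frame(label = sprintf("p%d", 1:10),
                      mz = runif(10, 100, 900))
  wide <- annotate_peaks(p, preds, tolerance_da = 2)
  narrow <- annotate_peaks(p, preds, tolerance_da = 0.2)
  expect_true(all(narrow$matched$label %in% wide$matched$label))
  expect_true(all(abs(narrow$matched$error_mda) <= 200 + 1e-9))
})

test_that("EI fragment prediction follows the alpha-cleavage rules", {
  fr <- predict_ei_fragments("C45H80O7Si5", "TBDMS")
  expect_setequal(fr$mz, c(872, 857, 815))
  # for any TBDMS species: molecular ion plus -15 and -57, nothing else
  set.seed(52)
  for (i in 1:5) {
    sp <- derivatized_formula(random_parent(3), "TBDMS", sample(1:3, 1))
    f2 <- predict_ei_fragments(sp, "TBDMS")
    expect_identical(f2$mz - nominal_mass(sp), c(0L, -15L, -57L))
  }
  # Si-free species keep the generic methyl loss but not the t-butyl loss
  f0 <- predict_ei_fragments(ztf, "TBDMS")
  expect_identical(f0$mz, c(378L, 363L))
  # TMS species report the reporter ion at nominal 73
  ft <- predict_ei_fragments(derivatized_formula(quercetin, "TMS", 5), "TMS")
  expect_true(73 %in% ft$mz)
  # unsubtractable losses -> warnings, fragments omitted
  fh <- suppressWarnings(predict_ei_fragments("H2Si", "TBDMS"))
  expect_warning(predict_ei_fragments("C2H6Si", "TBDMS"), "omitted")
  expect_false(any(grepl("C4H9", fh$label)))
})

test_that("derivatization ratios recover constructed intensities", {
  mz0 <- ion_mz(quercetin, "[M-H]-")
  mz4 <- ion_mz(derivatized_formula(quercetin, "TBDMS", 4), "[M-H]-")
  p <- peaklist(sort(c(mz0, mz4)), c(908, 100)[order(c(mz0, mz4))],
                mode = "ESI-neg")
  rep <- derivatization_ratio(p, quercetin, "TBDMS", adducts = "[M-H]-",
                              max_degree = 5, label = "batch")
  expect_identical(rep$status, "ok")
  expect_equal(rep$ratio, 9.08)
  # scale invariance
  p2 <- peaklist(p$mz, p$intensity * 37.5, mode = "ESI-neg")
  rep2 <- derivatization_ratio(p2, quercetin, "TBDMS", adducts = "[M-H]-",
                               max_degree = 5)
  expect_equal(rep2$ratio, rep$ratio)
  # complete derivatization: no underivatized signal
  p3 <- peaklist(mz4, 100, mode = "ESI-neg")
  rep3 <- derivatization_ratio(p3, quercetin, "TBDMS", adducts = "[M-H]-",
                               max_degree = 5)
  expect_identical(rep3$status, "complete-derivatization")
  expect_equal(rep3$ratio, 0)
  # no derivatized signal at all: flagged, not divided through
  p4 <- peaklist(mz0, 908, mode = "ESI-neg")
  rep4 <- derivatization_ratio(p4, quercetin, "TBDMS", adducts = "[M-H]-",
                               max_degree = 5)
  expect_identical(rep4$status, "no-derivatized-signal")
  expect_true(is.na(rep4$ratio))
})

test_that("the efficiency factor reproduces the 25-fold comparison", {
  ef <- efficiency_factor(9.08, 0.366)
  expect_equal(ef$factor, 9.08 / 0.366, tolerance = 1e-12)
  expect_equal(ef$factor_2sf, 25)
  expect_equal(efficiency_factor(1, 1)$factor, 1)
  expect_equal(efficiency_factor(1, 0.5)$factor, 2)
  und <- efficiency_factor(9.08, NA_real_)
  expect_identical(und$status, "undefined-flow-ratio")
  expect_error(efficiency_factor(NA_real_, 0.5), "batch")
})

test_that("known background ions ship as a tentative list", {
  bg <- background_ions()
  expect_setequal(bg$mz, c(73.10, 191.00, 207.10, 281.10))
  expect_true(all(grepl("tentative|unassigned", bg$label)))
})
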