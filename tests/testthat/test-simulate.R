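test_that("simulation is fully reproducible from its seed", {
  spec <- simulation_spec(seed = 7)
  a <- simulate_esi(spec)
  b <- simulate_esi(spec)
  expect_identical(length(a$scans), 25L)
  for (i in seq_along(a$scans)) {
    expect_identical(a$scans[[i]]$mz, b$scans[[i]]$mz)
    expect_identical(a$scans[[i]]$intensity, b$scans[[i]]$intensity)
  }
  c <- simulate_esi(simulation_spec(seed = 8))
  expect_false(identical(a$scans[[1]]$mz, c$scans[[1]]$mz))
})

test_that("noiseless simulations sit exactly on theory and recover the ratio", {
  spec <- simulation_spec(degree_weights = c(0.366, 0, 0, 0, 1, 0),
                          calibration_sigma_mda = 0, intensity_cv = 0,
                          n_background = 0, n_scans = 3, seed = 1)
  sim <- simulate_esi(spec)
  scan <- sim$scans[[1]]
  # every peak annotates back to its generating species with zero error
  ann <- annotate_peaks(scan, data.frame(label = sim$truth$species$formula,
                                         mz = sim$truth$species$mz))
  expect_identical(nrow(ann$unmatched), 0L)
  expect_true(all(abs(ann$matched$error_mda) < 1e-9))
  # the generative ratio is recovered exactly
  rep <- derivatization_ratio(scan, spec$parent, "TBDMS",
                              adducts = "[M-H]-", max_degree = 5,
                              label = "flow")
  expect_equal(rep$ratio, 0.366, tolerance = 1e-12)
  expect_equal(sim$truth$ratio, 0.366)
  # the observed degree set matches the generative one
  deg <- sim$truth$species$degree[sim$truth$species$expected_intensity > 0]
  expect_setequal(deg, c(0L, 4L))
})

test_that("calibration noise leaves the mean recovered ratio on target", {
  truth <- 0.366
  ratios <- vapply(1:200, function(r) {
    spec <- simulation_spec(degree_weights = c(truth, 0, 0, 0, 1, 0),
                            calibration_sigma_mda = 2, intensity_cv = 0,
                            n_background = 0, n_scans = 1, seed = 1000 + r)
    sim <- simulate_esi(spec)
    derivatization_ratio(sim$scans[[1]], spec$parent, "TBDMS",
                         adducts = "[M-H]-", max_degree = 5,
                         tolerance_da = 0.010)$ratio
  }, numeric(1))
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lte(abs(mean(ratios) - truth), max(3 * se, 1e-12))
})

test_that("intensity noise keeps the recovered ratio near truth (sanity band)", {
  ratios <- vapply(1:100, function(r) {
    spec <- simulation_spec(calibration_sigma_mda = 1, intensity_cv = 0.2,
                            n_background = 3, n_scans = 5, seed = 2000 + r)
    sim <- simulate_esi(spec)
    avg <- average_spectra(sim$scans, bin_tolerance_mda = 10)
    derivatization_ratio(avg, spec$parent, "TBDMS", adducts = "[M-H]-",
                         max_degree = 5, tolerance_da = 0.010)$ratio
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.366) / 0.366, 0.10)
})

test_that("noiseless pipelines recover parent formulas end to end", {
  set.seed(61)
  bounds <- list(C = c(0, 60), H = c(0, 130), O = c(0, 15), Si = c(0, 6))
  for (i in 1:2) {
    sites <- sample(2:6, 1)
    parent <- random_parent(sites)
    w <- rep(0, sites + 1)
    w[c(1, 2, sites + 1)] <- c(0.5, 0.8, 1)
    spec <- simulation_spec(parent = parent, n_sites = sites,
                            degree_weights = w,
                            adduct_weights = c("[M+H]+" = 1),
                            calibration_sigma_mda = 0, intensity_cv = 0,
                            n_background = 0, n_scans = 1, seed = 100 + i)
    sim <- simulate_esi(spec)
    scan <- sim$scans[[1]]
    ions <- lapply(c(0L, 1L, sites), function(d) {
      target <- scan$mz[which.min(abs(scan$mz - sim$truth$species$mz[
        sim$truth$species$degree == d]))]
      observed_ion(mz = target, degree = d, adduct = "[M+H]+",
                   candidates = enumerate_formulas(target, tolerance_mda = 5,
                                                   adduct = "[M+H]+",
                                                   bounds = bounds))
    })
    res <- crosscheck(ions, "TBDMS")
    expect_true(format(ion_formula(parent, "[M+H]+")) %in%
                  res$surviving_parents)
  }
})

test_that("EI simulation lands on the nominal fragment set", {
  p <- simulate_ei(quercetin, "TBDMS", degree = 5, jitter_sd = 0)
  expect_identical(p$mz, c(73, 815, 857, 872))
  expect_identical(p$mode, "EI")
  # the t-butyl-loss fragment is the base peak
  expect_equal(p$mz[which.max(p$intensity)], 815)
  # degree 0, Si-free parent: molecular ion plus the generic methyl loss,
  # no reagent-specific t-butyl fragment
  p0 <- simulate_ei(ztf, "TBDMS", degree = 0, include_bleed = FALSE)
  expect_identical(p0$mz, c(363, 378))
  p3 <- simulate_ei(ted13, "TBDMS", degree = 3, include_bleed = FALSE)
  expect_true(559 %in% p3$mz)
  # reproducible under jitter
  j1 <- simulate_ei(quercetin, "TBDMS", 5, jitter_sd = 0.1, seed = 3)
  j2 <- simulate_ei(quercetin, "TBDMS", 5, jitter_sd = 0.1, seed = 3)
  expect_identical(j1$mz, j2$mz)
})

test_that("invalid simulation specs are rejected", {
  expect_error(simulation_spec(degree_weights = c(1, 0)), "length")
  expect_error(simulation_spec(degree_weights = c(-1, 0, 0, 0, 0, 0)),
               "non-negative")
  expect_error(simulation_spec(adduct_weights = c("[M+H]+" = 1,
                                                  "[M-H]-" = 1)),
               "polarity")
  expect_error(simulation_spec(n_scans = 0), "n_scans")
  expect_error(simulation_spec(calibration_sigma_mda = -1), ">= 0")
})
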