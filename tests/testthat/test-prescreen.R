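# EIC extraction, peak detection and the QC verdict logic.

test_that("EIC reproduces planted Gaussian profiles", {
  run <- make_gaussian_run(rt_apex = 12.3, apex = 2e6)
  eic <- extract_eic(run, 164.1070, ppm = 2.5)
  expect_equal(nrow(eic), sum(run$ms_level == 1))
  expect_equal(eic$rt[which.max(eic$intensity)], 12.3, tolerance = 0.011)
  expect_equal(max(eic$intensity), 2e6, tolerance = 0.01)

  # absent target -> all zero
  expect_true(all(extract_eic(run, 500.1234)$intensity == 0))

  # two planted peaks -> two local maxima at the planted RTs
  run2 <- make_gaussian_run(rt_apex = 12.3, apex = 2e6,
                            extra_apexes = list(list(rt = 14.4, apex = 3e6)))
  pk <- detect_peaks(extract_eic(run2, 164.1070))
  expect_equal(nrow(pk), 2)
  expect_equal(pk$rt_apex, c(12.3, 14.4), tolerance = 0.011)
})

test_that("EIC total intensity matches a brute-force re-scan", {
  run <- make_gaussian_run()
  target <- 164.1070; ppm <- 2.5
  eic <- extract_eic(run, target, ppm)
  brute <- 0
  for (i in which(run$ms_level == 1)) {
    p <- run$peaks[[i]]
    sel <- abs(p[, "mz"] - target) / target * 1e6 <= ppm
    brute <- brute + sum(p[sel, "intensity"])
  }
  expect_equal(sum(eic$intensity), brute)
})

test_that("detect_peaks handles empty, noisy and multi-peak traces", {
  zero <- structure(tibble::tibble(rt = seq(0, 5, 0.01), intensity = 0),
                    class = c("eic", class(tibble::tibble())),
                    target_mz = 100, ppm = 2.5)
  expect_equal(nrow(detect_peaks(zero)), 0)

  set.seed(11)
  rt <- seq(0, 10, 0.01)
  y <- 1e6 * exp(-(rt - 5)^2 / (2 * 0.05^2)) + abs(rnorm(length(rt), 0, 1e3))
  eic <- structure(tibble::tibble(rt = rt, intensity = y),
                   class = c("eic", class(tibble::tibble())),
                   target_mz = 100, ppm = 2.5)
  pk <- detect_peaks(eic)
  main <- pk[which.max(pk$intensity_apex), ]
  expect_equal(main$rt_apex, 5, tolerance = 0.02)
  # S/N within a factor 2 of the estimator's definition computed directly
  # on the baseline points of the fixture
  baseline <- y[rt < 4.5 | rt > 5.5]
  snr_def <- max(y) / stats::mad(baseline)
  expect_gt(main$snr, snr_def / 2)
  expect_lt(main$snr, snr_def * 2)
})

test_that("qc verdicts follow the threshold rules exactly", {
  entry <- tibble::tibble(id = "X", mass = monoisotopic_mass("C10H13NO"))
  # all criteria satisfied
  pass_run <- make_gaussian_run(rt_apex = 12.3, apex = 2e5, ms2_rt = 12.4)
  r <- qc_compound(pass_run, entry)
  expect_equal(r$verdict, "pass")
  expect_equal(r$failed[[1]], character())
  expect_equal(length(r$ms2_scans[[1]]), 1)

  # apex below the intensity threshold, all else fine
  low <- make_gaussian_run(rt_apex = 12.3, apex = 5e4, ms2_rt = 12.3)
  r2 <- qc_compound(low, entry)
  expect_equal(r2$verdict, "fail")
  expect_equal(r2$failed[[1]], "intensity")

  # MS2 only outside the RT tolerance
  shifted <- make_gaussian_run(rt_apex = 12.3, apex = 2e6, ms2_rt = 13.0)
  r3 <- qc_compound(shifted, entry)
  expect_equal(r3$failed[[1]], "rt_shift")

  # no MS2 at all
  none <- make_gaussian_run(rt_apex = 12.3, apex = 2e6, ms2_rt = NULL)
  r4 <- qc_compound(none, entry)
  expect_equal(r4$failed[[1]], "ms2_present")

  # polarity mismatch is an error
  expect_error(qc_compound(pass_run, entry, adduct = "[M-H]-"),
               class = "mixlib_prescreen_error")
})

test_that("MS2 matches are ordered nearest the apex first", {
  entry <- tibble::tibble(id = "X", mass = monoisotopic_mass("C10H13NO"))
  run <- make_gaussian_run(rt_apex = 12.3, apex = 2e6,
                           ms2_rt = c(12.0, 12.35, 12.6))
  r <- qc_compound(run, entry)
  scans <- r$ms2_scans[[1]]
  rts <- run$rt[match(scans, run$scan)]
  expect_equal(rts, rts[order(abs(rts - r$rt_apex))])
})

test_that("raising thresholds never converts a fail into a pass", {
  d <- generate_design(sizes = c(8, 8), mix_names = c("A", "B"),
                       violations = c("none", "intensity", "ms2_absent",
                                      "ms2_shifted", "snr", "none", "none",
                                      "none"),
                       seed = 13)
  sim <- simulate_run(d, "A", "+", 45, sim_params(seed = 13, mass_error = c(1, 0)))
  base <- prescreen(list(sim$run), d$compounds, d$design)
  stricter <- list(
    qc_thresholds(min_intensity = 5e5),
    qc_thresholds(min_snr = 10),
    qc_thresholds(min_intensity = 2e5, min_snr = 6, rt_tol = 0.2)
  )
  for (th in stricter) {
    res <- prescreen(list(sim$run), d$compounds, d$design, thresholds = th)
    flipped <- base$verdict == "fail" & res$verdict == "pass"
    expect_false(any(flipped))
  }
})

test_that("prescreen_table tallies verdicts and writes CSV", {
  run <- make_gaussian_run(ms2_rt = 12.3)
  entry <- tibble::tibble(id = c("a", "b", "c"),
                          mass = monoisotopic_mass("C10H13NO") + c(0, 0, 50))
  res <- purrr::map(seq_len(3), function(i) qc_compound(run, entry[i, ])) |>
    purrr::list_rbind()
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  tab <- prescreen_table(res, f)
  expect_equal(sum(tab$verdict == "pass"), 2)
  expect_true(file.exists(f))
  # empty input -> header-only file
  f2 <- tempfile(fileext = ".csv")
  on.exit(unlink(f2), add = TRUE)
  prescreen_table(res[0, ], f2)
  expect_equal(length(readLines(f2)), 1)
})
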