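# Sub-formula enumeration, spectrum annotation, recalibration and cleaning.

test_that("enumeration matches the exhaustive oracle on small precursors", {
  set.seed(99)
  precursors <- list(
    c(C = 7L, H = 8L, N = 1L),          # toluene + N
    c(C = 10L, H = 14L, N = 1L, O = 1L),
    c(C = 6L, H = 12L, O = 6L)[1:2],    # C6H12
    c(C = 4L, H = 6L, N = 2L, O = 2L),
    c(C = 8L, H = 10L, O = 2L)
  )
  n_cases <- 0
  for (counts in precursors) {
    pmass <- monoisotopic_mass(element_counts(counts))
    for (i in seq_len(10)) {
      frag <- runif(1, 30, pmass + 2)
      got <- enumerate_subformulas(element_counts(counts), frag, tol_ppm = 10)
      want <- brute_subformulas(counts, frag, tol_ppm = 10)
      expect_setequal(got$formula, want)
      n_cases <- n_cases + 1
    }
  }
  expect_gte(n_cases, 50)
})

test_that("enumeration reproduces the worked fragment assignments", {
  ion <- adduct_formula("C10H13NO", "[M+H]+")
  # the tropylium-type C7H7+ fragment
  cand <- enumerate_subformulas(ion, 91.0542, tol_ppm = 5)
  expect_true("C7H7" %in% cand$formula)
  # the precursor ion itself annotates at ~0 ppm
  prec_mz <- adduct_mz(monoisotopic_mass("C10H13NO"), "[M+H]+")
  full <- enumerate_subformulas(ion, prec_mz, tol_ppm = 5)
  expect_equal(full$formula[[1]], "C10H14NO")
  expect_lt(abs(full$error_ppm[[1]]), 0.01)
  # a mass with no valid subformula
  expect_equal(nrow(enumerate_subformulas(ion, 50.0000, tol_ppm = 5)), 0)
})

test_that("assigned fragment masses never exceed the precursor ion mass", {
  ion <- adduct_formula("C10H13NO", "[M+H]+")
  pmass <- monoisotopic_mass(ion)
  # probe near true subformula ion masses (with ppm jitter) so candidates exist
  set.seed(5)
  probes <- c("C7H7", "C5H5N", "C9H11O", "C4H9", "C10H13N", "C8H9NO")
  n_nonempty <- 0
  for (f in probes) {
    frag <- (monoisotopic_mass(f) - 0.00054857990946) *
      (1 + runif(1, -10, 10) * 1e-6)
    cand <- enumerate_subformulas(ion, frag, tol_ppm = 20)
    if (nrow(cand)) {
      n_nonempty <- n_nonempty + 1
      expect_true(all(cand$mass <= pmass + 1e-9))
    }
  }
  expect_gt(n_nonempty, 4)
})

test_that("annotate_spectrum assigns planted formulas and flags noise", {
  entry <- tibble::tibble(id = "X", formula = "C10H13NO",
                          mass = monoisotopic_mass("C10H13NO"))
  ion <- adduct_formula(entry$formula, "[M+H]+")
  frags <- c("C7H7", "C8H10N", "C10H14NO")
  mzs <- vapply(frags, function(f) monoisotopic_mass(f) - 0.00054857990946,
                numeric(1))
  scan <- list(peaks = list(cbind(mz = sort(mzs), intensity = c(1e5, 2e5, 3e5))))
  ann <- annotate_spectrum(scan, entry, tol_ppm = 5)
  expect_equal(assignment_rate(ann), 1)
  expect_setequal(ann$formula, frags)
  expect_true(all(abs(ann$error_ppm) < 0.01))

  noise <- list(peaks = list(cbind(mz = c(47.7771, 62.1133, 83.9999),
                                   intensity = rep(1e5, 3))))
  ann2 <- annotate_spectrum(noise, entry, tol_ppm = 2.5)
  expect_equal(assignment_rate(ann2), 0)
  expect_true(all(ann2$status == "failpeak"))

  expect_error(annotate_spectrum(list(peaks = list(cbind(mz = numeric(),
                                                         intensity = numeric()))),
                                 entry),
               class = "mixlib_annotate_error")
})

test_that("recalibration recovers planted error curves", {
  # zero error -> near-zero prediction
  mz <- seq(60, 500, length.out = 40)
  m0 <- fit_recalibration(tibble::tibble(observed = mz, theoretical = mz))
  expect_lt(max(abs(predict(m0, seq(80, 450, 50)))), 0.1)

  # constant +5 ppm offset
  m5 <- fit_recalibration(tibble::tibble(observed = mz * (1 + 5e-6),
                                         theoretical = mz))
  expect_true(all(abs(predict(m5, seq(80, 450, 50)) - 5) < 0.5))

  # planted linear curve e(mz) = 3 + 0.01 (mz - 100) ppm
  err <- 3 + 0.01 * (mz - 100)
  ml <- fit_recalibration(tibble::tibble(observed = mz * (1 + err * 1e-6),
                                         theoretical = mz))
  probes <- seq(100, 480, length.out = 10)
  expect_true(all(abs(predict(ml, probes) - (3 + 0.01 * (probes - 100))) < 0.5))
  expect_lt(glance(ml)$median_residual_ppm, 0.5)

  # linear fallback below the training minimum
  small <- fit_recalibration(tibble::tibble(observed = c(100, 300),
                                            theoretical = c(100, 300) / (1 + 2e-6)))
  expect_equal(small$kind, "linear-fallback")
  expect_error(fit_recalibration(tibble::tibble(observed = 1, theoretical = 1)),
               class = "mixlib_recal_error")
})

test_that("applying recalibration corrects, clamps and is idempotent", {
  mz <- seq(60, 500, length.out = 40)
  m5 <- fit_recalibration(tibble::tibble(observed = mz * (1 + 5e-6),
                                         theoretical = mz))
  pk <- cbind(mz = c(50, 100.0005, 600), intensity = rep(1, 3))
  corr <- apply_recalibration(pk, m5)
  # in-range point corrected by ~5 ppm
  expect_equal(unname(corr[2, "mz"]), 100.0005 * (1 - 5e-6), tolerance = 1e-7)
  # out-of-range m/z receives the boundary correction
  expect_equal(unname(corr[1, "mz"]),
               50 * (1 - predict(m5, m5$range[[1]]) * 1e-6),
               tolerance = 1e-9)
  # identity model leaves the scan unchanged
  corr0 <- apply_recalibration(pk, fit_recalibration(
    tibble::tibble(observed = mz, theoretical = mz)))
  expect_equal(corr0[, "mz"], pk[, "mz"], tolerance = 1e-7)
  # idempotence: re-fitting on corrected data moves m/z < 0.2 ppm median
  corrected <- mz * (1 + 5e-6) * (1 - predict(m5, mz * (1 + 5e-6)) * 1e-6)
  m2 <- fit_recalibration(tibble::tibble(observed = corrected, theoretical = mz))
  twice <- corrected * (1 - predict(m2, corrected) * 1e-6)
  expect_lt(stats::median(abs((twice - corrected) / corrected * 1e6)), 0.2)
})

test_that("recalibration raises the post-correction assignment rate", {
  d <- generate_design(sizes = c(4), mix_names = "A", seed = 31)
  sim <- simulate_run(d, "A", "+", 45,
                      sim_params(seed = 31, mass_error = c(5, 0)))
  run <- sim$run
  ms2 <- run[run$ms_level == 2, ]
  anns <- purrr::map(seq_len(nrow(ms2)), function(i) {
    prec <- ms2$precursor_mz[[i]]
    hit <- which.min(abs(adduct_mz(d$compounds$mass, "[M+H]+") - prec))
    annotate_spectrum(ms2[i, ], d$compounds[hit, ], tol_ppm = 10)
  })
  pairs <- recalibration_pairs(anns)
  expect_gte(nrow(pairs), 20)
  # raw errors sit near the planted +5 ppm
  raw <- ppm_error(pairs$observed, pairs$theoretical)
  expect_equal(stats::median(raw), 5, tolerance = 0.2)
  model <- fit_recalibration(pairs)
  rate_at <- function(scans, tol) {
    r <- purrr::map_dbl(seq_len(nrow(scans)), function(i) {
      prec <- scans$precursor_mz[[i]]
      hit <- which.min(abs(adduct_mz(d$compounds$mass, "[M+H]+") - prec))
      assignment_rate(annotate_spectrum(scans[i, ], d$compounds[hit, ],
                                        tol_ppm = tol))
    })
    mean(r)
  }
  before <- rate_at(ms2, 2.5)
  after <- rate_at(apply_recalibration(ms2, model), 2.5)
  expect_gte(after, before)
  expect_gt(after, 0.9)
})

test_that("clean_spectrum drops failpeaks, applies floors and merges", {
  ann <- tibble::tibble(
    mz = c(91.0542, 91.0546, 120.0808, 130.1),
    intensity = c(5e5, 3e5, 8e5, 1e5),
    status = c("assigned", "assigned", "assigned", "failpeak"),
    formula = c("C7H7", "C7H7", "C8H10N", NA)
  )
  cs <- clean_spectrum(ann, clean_policy(merge_ppm = 5))
  # failpeak gone, close centroids merged with summed intensity
  expect_equal(nrow(cs), 2)
  expect_equal(cs$intensity[[1]], 8e5)
  expect_equal(cs$mz[[1]], (91.0542 * 5e5 + 91.0546 * 3e5) / 8e5, tolerance = 1e-9)
  # all assigned and well separated -> identical peak set
  ann2 <- ann[c(1, 3), ]
  cs2 <- clean_spectrum(ann2, clean_policy())
  expect_equal(cs2$mz, ann2$mz)
  # failpeaks retained under the permissive policy
  cs3 <- clean_spectrum(ann, clean_policy(keep_failpeaks = TRUE, merge_ppm = 5))
  expect_equal(nrow(cs3), 3)
  # relative-intensity floor
  ann4 <- tibble::tibble(mz = c(100, 200), intensity = c(1e6, 10),
                         status = "assigned", formula = c("C5H8", "C10H16"))
  cs4 <- clean_spectrum(ann4, clean_policy(min_rel = 1e-3))
  expect_equal(nrow(cs4), 1)
})
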