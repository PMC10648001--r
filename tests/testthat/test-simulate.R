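# Synthetic design and DDA run generator.

test_that("small designs honor sizes, replicates and isobar plans", {
  d1 <- generate_design(sizes = 2, mix_names = "only", seed = 3)
  expect_equal(nrow(d1$design), 2)
  expect_equal(unique(d1$design$mix), "only")

  d2 <- generate_design(sizes = c(8, 8, 8), mix_names = c("a", "b", "c"),
                        isobar_plan = 3, seed = 3)
  same_formula <- d2$compounds |>
    dplyr::count(formula) |>
    dplyr::filter(n > 1)
  expect_equal(nrow(same_formula), 3)
  expect_equal(nrow(d2$isobar_pairs), 3)
  # pair members share the formula but not the structure
  for (i in 1:3) {
    a <- d2$compounds[d2$compounds$id == d2$isobar_pairs$id_a[[i]], ]
    b <- d2$compounds[d2$compounds$id == d2$isobar_pairs$id_b[[i]], ]
    expect_equal(a$formula, b$formula)
    expect_false(a$smiles == b$smiles)
    # separated in RT by more than twice the anchoring tolerance
    expect_gt(abs(a$rt - b$rt), 1)
  }
  # no accidental isobars: within a mix, non-pair ions are > 1 Da apart
  g <- group_isobars(d2$design, d2$compounds)
  multi <- g |> dplyr::filter(n_members > 1)
  expect_true(all(multi$id %in% c(d2$isobar_pairs$id_a, d2$isobar_pairs$id_b)))
})

test_that("the default design reproduces the ten-mix trial layout", {
  d <- generate_design(seed = 1)
  sizes <- d$design |> dplyr::count(mix)
  expect_equal(sizes$n[match(as.character(499:508), sizes$mix)],
               c(95, 95, 95, 95, 185, 185, 365, 365, 95, 365))
  # replicate sets: mixes 503 and 505 contain all of mix 499
  m499 <- d$design$id[d$design$mix == "499"]
  expect_true(all(m499 %in% d$design$id[d$design$mix == "503"]))
  expect_true(all(m499 %in% d$design$id[d$design$mix == "505"]))
  # identifiers unique, SMILES parseable by construction
  expect_false(any(duplicated(d$compounds$id)))
})

test_that("simulated runs carry the planted chromatography and are seeded", {
  d <- generate_design(sizes = 1, mix_names = "solo", seed = 17)
  p <- sim_params(seed = 17, noise_rate = 0)
  sim <- simulate_run(d, "solo", "+", 45, p)
  cmp <- d$compounds
  eic <- extract_eic(sim$run, adduct_mz(cmp$mass, "[M+H]+"), ppm = 2.5)
  expect_equal(max(eic$intensity), cmp$apex, tolerance = 0.01)
  expect_equal(eic$rt[which.max(eic$intensity)], cmp$rt, tolerance = 0.011)

  f1 <- tempfile(fileext = ".mzML"); f2 <- tempfile(fileext = ".mzML")
  on.exit(unlink(c(f1, f2)))
  simulate_run(d, "solo", "+", 45, p, path = f1)
  simulate_run(d, "solo", "+", 45, p, path = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("a planted mass-error curve appears in the raw annotations", {
  d <- generate_design(sizes = 3, mix_names = "m", seed = 23)
  sim <- simulate_run(d, "m", "+", 45, sim_params(seed = 23, mass_error = c(5, 0)))
  ms2 <- sim$run[sim$run$ms_level == 2, ]
  errs <- purrr::map(seq_len(nrow(ms2)), function(i) {
    hit <- which.min(abs(adduct_mz(d$compounds$mass, "[M+H]+") - ms2$precursor_mz[[i]]))
    ann <- annotate_spectrum(ms2[i, ], d$compounds[hit, ], tol_ppm = 10)
    ann$error_ppm[ann$status == "assigned"]
  }) |> unlist()
  expect_gt(length(errs), 10)
  expect_equal(stats::median(errs), 5, tolerance = 0.25)
})

test_that("ground truth matches the emitted scans", {
  d <- generate_design(sizes = 4, mix_names = "m",
                       violations = c("none", "ms2_absent", "none", "none"),
                       seed = 29)
  sim <- simulate_run(d, "m", "+", 30, sim_params(seed = 29))
  truth <- sim$truth
  absent <- truth$id[truth$violation == "ms2_absent"]
  prec <- sim$run$precursor_mz[sim$run$ms_level == 2]
  absent_mz <- truth$ion_mz[truth$id == absent]
  expect_false(any(abs(prec - absent_mz) < 0.01))
  # every detectable compound triggered at least one MS2
  for (i in which(truth$violation == "none")) {
    expect_true(any(abs(prec - truth$ion_mz[[i]]) < 0.01))
  }
  # planted fragments annotate their own spectra
  i <- which(truth$violation == "none")[[1]]
  scan <- sim$run[sim$run$ms_level == 2 &
                    abs(sim$run$precursor_mz - truth$ion_mz[[i]]) < 0.01, ][1, ]
  ann <- annotate_spectrum(scan, d$compounds[d$compounds$id == truth$id[[i]], ],
                           tol_ppm = 5)
  expect_true(all(truth$fragments[[i]] %in% ann$formula))
})

test_that("the two-mix worked fixture reproduces the published geometry", {
  fx <- fig4_scenario()
  expect_equal(sort(unique(fx$design$design$mix)), c("503", "508"))
  expect_equal(fx$design$compounds$rt, c(12.3, 14.4))
  expect_equal(adduct_mz(fx$design$compounds$mass[[1]], "[M+H]+"), 164.1070,
               tolerance = 5e-5)
})
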