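# SPLASH hashes, record assembly, serialization and validation.

make_clean_spectrum <- function(mz = c(91.0542, 120.0808, 164.1070),
                                intensity = c(5e5, 8e5, 3e5),
                                formula = c("C7H7", "C8H10N", "C10H14NO")) {
  structure(tibble::tibble(mz = mz, intensity = intensity, formula = formula),
            class = c("clean_spectrum", class(tibble::tibble())),
            base_peak = max(intensity))
}

fig4_entry <- function() {
  tibble::tibble(id = "ENT-AMINE",
                 name = "2,2-dimethyl-2,3-dihydro-1-benzofuran-7-amine",
                 smiles = "CC1(C)Cc2cccc(N)c2O1",
                 formula = "C10H13NO",
                 mass = monoisotopic_mass("C10H13NO"))
}

test_that("relative intensities follow the 999 scale with floor 1", {
  one <- relative_intensities(cbind(100, 5e5))
  expect_equal(one$rel_intensity, 999L)
  two <- relative_intensities(cbind(c(100, 200), c(1e6, 5e5)))
  expect_equal(two$rel_intensity, c(999L, 500L))
  tiny <- relative_intensities(cbind(c(100, 200), c(1e6, 1)))
  expect_equal(tiny$rel_intensity[[2]], 1L)
  expect_error(relative_intensities(cbind(numeric(), numeric())),
               class = "mixlib_record_error")
})

test_that("SPLASH is scale-invariant and matches the bundled oracle", {
  spectra <- random_spectra(25)
  for (s in spectra[1:5]) {
    scaled <- s; scaled[, 2] <- scaled[, 2] * 7.3
    expect_equal(compute_splash(s), compute_splash(scaled))
  }
  mine <- vapply(spectra, compute_splash, character(1))
  expect_true(all(startsWith(mine, "splash10-")))
  oracle <- splash_oracle(spectra)
  expect_equal(mine, oracle)
  # different spectra hash differently
  expect_gt(dplyr::n_distinct(mine), 20)
})

test_that("build_record populates mandatory fields and the worked accession", {
  rec <- build_record(fig4_entry(), make_clean_spectrum(),
                      assignment = tibble::tibble(level = "1", rt = 12.3),
                      settings = test_settings(), serial = "LU109201",
                      ce = 45, date = "2023.05.01")
  expect_equal(mb_field(rec, "ACCESSION"), "MSBNK-LCSB-LU109201")
  expect_equal(mb_field(rec, "CH$FORMULA"), "C10H13NO")
  expect_equal(as.integer(mb_field(rec, "PK$NUM_PEAK")), 3L)
  expect_equal(mb_field(rec, "MS$FOCUSED_ION", "PRECURSOR_M/Z"), "164.1070")
  expect_equal(mb_field(rec, "MS$FOCUSED_ION", "PRECURSOR_TYPE"), "[M+H]+")
  expect_equal(nrow(validate_record(rec)), 0)

  # integer serials are zero-padded under the accession prefix
  rec2 <- build_record(fig4_entry(), make_clean_spectrum(),
                       assignment = NULL, settings = test_settings(),
                       serial = 7L, ce = 30)
  expect_equal(mb_field(rec2, "ACCESSION"), "MSBNK-LCSB-LU000007")
})

test_that("spectra below the base-peak threshold are rejected", {
  weak <- make_clean_spectrum(intensity = c(5e4, 9e4, 3e4))
  expect_error(build_record(fig4_entry(), weak, NULL, test_settings(), 1L),
               class = "mixlib_basepeak_error")
  entry <- fig4_entry(); entry$smiles <- ""
  expect_error(build_record(entry, make_clean_spectrum(), NULL,
                            test_settings(), 1L),
               class = "mixlib_record_error")
})

test_that("records round-trip through text serialization bit-exactly", {
  settings <- test_settings()
  settings$solvent_a <- "water + 0.1% formic acid"
  settings$solvent_b <- "acetonitrile + 0.1% formic acid"
  specs <- list(
    make_clean_spectrum(),
    make_clean_spectrum(mz = c(53.0386, 288.2894), intensity = c(2e5, 7e6),
                        formula = c("C4H5", NA)),
    make_clean_spectrum(mz = 164.1070, intensity = 1.23e6, formula = "C10H14NO")
  )
  for (i in seq_along(specs)) {
    rec <- build_record(fig4_entry(), specs[[i]],
                        assignment = tibble::tibble(level = "1", rt = 12.3),
                        settings = settings, serial = i, ce = 45)
    # multi-line chromatography block present
    expect_gte(length(mb_field(rec, "AC$CHROMATOGRAPHY")), 3)
    f <- tempfile(fileext = ".txt")
    lines <- write_record(rec, f)
    back <- parse_record(f)
    expect_identical(back$fields, rec$fields)
    expect_equal(back$peaks, rec$peaks)
    # re-serialization is byte-identical
    expect_identical(write_record(back), readLines(f))
    unlink(f)
  }
})

test_that("parsing rejects truncated or malformed records", {
  rec <- build_record(fig4_entry(), make_clean_spectrum(), NULL,
                      test_settings(), 1L)
  lines <- write_record(rec)
  expect_error(parse_record(lines = utils::head(lines, -1)),
               class = "mixlib_record_error")
  expect_error(parse_record(lines = c("garbage", lines)),
               class = "mixlib_record_error")
})

test_that("validation flags the classic defects", {
  rec <- build_record(fig4_entry(), make_clean_spectrum(), NULL,
                      test_settings(), 1L)
  expect_equal(nrow(validate_record(rec)), 0)

  off <- rec
  off$fields$value[off$fields$key == "PK$NUM_PEAK"] <- "4"
  expect_true("peak_count" %in% validate_record(off)$rule)

  wrong_mass <- rec
  wrong_mass$fields$value[wrong_mass$fields$key == "CH$EXACT_MASS"] <- "163.2100"
  expect_true("mass_consistency" %in% validate_record(wrong_mass)$rule)

  bad_acc <- rec
  bad_acc$fields$value[bad_acc$fields$key == "ACCESSION"] <- "LU109201"
  expect_true("accession_format" %in% validate_record(bad_acc)$rule)

  nofield <- rec
  nofield$fields <- nofield$fields[nofield$fields$key != "CH$FORMULA", ]
  expect_true("missing_field" %in% validate_record(nofield)$rule)

  unsorted <- rec
  unsorted$peaks <- unsorted$peaks[rev(seq_len(nrow(unsorted$peaks))), ]
  expect_true("peak_order" %in% validate_record(unsorted)$rule)
})

test_that("summarize_records extracts the requested fields per file", {
  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  for (i in 1:3) {
    rec <- build_record(fig4_entry(), make_clean_spectrum(), NULL,
                        test_settings(), i, ce = 15 * i)
    write_record(rec, file.path(dir, paste0(mb_field(rec, "ACCESSION"), ".txt")))
  }
  tab <- summarize_records(dir, c("ACCESSION", "CH$FORMULA"))
  expect_equal(dim(tab), c(3L, 2L))
  expect_equal(unique(tab$`CH$FORMULA`), "C10H13NO")
  tab2 <- summarize_records(dir, c("ACCESSION",
                                   "AC$MASS_SPECTROMETRY: COLLISION_ENERGY"))
  expect_equal(tab2[[2]], sprintf("%d %% (nominal)", c(15, 30, 45)))
  # empty directory -> zero-row table with the requested header
  empty <- tempfile(); dir.create(empty)
  tab3 <- summarize_records(empty, c("ACCESSION", "CH$NAME"))
  expect_equal(nrow(tab3), 0)
  expect_equal(names(tab3), c("ACCESSION", "CH$NAME"))
})
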