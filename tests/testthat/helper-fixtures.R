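# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures are stored.

make_settings_ini <- function(path = tempfile(fileext = ".ini"),
                              license = "CC BY", contributor = "LCSB") {
  writeLines(c(
    "[record]",
    "authors=A. Tester, B. Checker",
    paste0("license=", license),
    "publication=internal test set",
    "[instrument]",
    "instrument=Q Exactive HF Orbitrap",
    "instrument_type=LC-ESI-QFT",
    "ionization=ESI",
    "fragmentation_mode=HCD",
    "[chromatography]",
    "column_name=C18 core-shell 2.1x100 mm",
    "[accession]",
    paste0("contributor=", contributor),
    "accession_prefix=LU"
  ), path)
  path
}

test_settings <- function() read_settings(make_settings_ini())

# a small in-memory run: one Gaussian MS1 profile plus optional MS2 scans
make_gaussian_run <- function(rt_apex = 12.3, apex = 2e6, sigma = 0.05,
                              target_mz = 164.1070, rt_range = c(10, 16),
                              dt = 0.01, ms2_rt = rt_apex,
                              ms2_precursor = target_mz,
                              extra_apexes = NULL, mix = "m1", ce = 45) {
  rt1 <- seq(rt_range[[1]], rt_range[[2]], by = dt)
  profile <- apex * exp(-(rt1 - rt_apex)^2 / (2 * sigma^2))
  for (ex in extra_apexes %||% list()) {
    profile <- profile + ex$apex * exp(-(rt1 - ex$rt)^2 / (2 * sigma^2))
  }
  peaks1 <- lapply(profile, function(i) {
    if (i >= 1) cbind(mz = target_mz, intensity = i)
    else cbind(mz = 100.0, intensity = 10)
  })
  scans <- tibble::tibble(
    rt = rt1, ms_level = 1L, polarity = "+",
    precursor_mz = NA_real_, iso_width = NA_real_, ce = NA_real_,
    peaks = peaks1
  )
  if (!is.null(ms2_rt)) {
    ms2 <- tibble::tibble(
      rt = ms2_rt, ms_level = 2L, polarity = "+",
      precursor_mz = ms2_precursor, iso_width = 1, ce = ce,
      peaks = lapply(seq_along(ms2_rt), function(i) {
        cbind(mz = c(91.0542, 120.0808), intensity = c(5e5, 8e5))
      })
    )
    scans <- dplyr::bind_rows(scans, ms2) |> dplyr::arrange(rt)
  }
  scans$scan <- seq_len(nrow(scans))
  ms_run(scans, mix = mix, mode = "+", ce_tag = ce)
}

# random centroid spectra for SPLASH cross-checks
random_spectra <- function(n = 20, seed = 421) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- sample(3:40, 1)
    cbind(mz = sort(round(runif(k, 50, 900), 4)),
          intensity = round(runif(k, 1, 1e6)))
  })
}

splash_oracle <- function(spectra) {
  script <- system.file("splash", "splash_oracle.py", package = "mixlib")
  lines <- vapply(spectra, function(s) {
    paste(sprintf("%.10g:%.10g", s[, 1], s[, 2]), collapse = " ")
  }, character(1))
  system2("python", shQuote(script), input = lines, stdout = TRUE)
}

# exhaustive subformula search used as the independent oracle; masses typed
# from the IUPAC monoisotopic table, electron mass from CODATA
oracle_masses <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, S = 31.97207069, Cl = 34.96885271)
oracle_valence <- c(C = 4, H = 1, N = 3, O = 2, S = 2, Cl = 1)
oracle_electron <- 0.00054857990946

brute_subformulas <- function(counts, fragment_mz, tol_ppm, charge = 1L) {
  syms <- names(counts)
  grid <- do.call(expand.grid, lapply(as.integer(counts), function(k) 0:k))
  names(grid) <- syms
  mass <- as.matrix(grid) %*% oracle_masses[syms]
  mz <- (mass - charge * oracle_electron)
  err <- abs(mz - fragment_mz) / mz * 1e6
  rd <- 1 + as.matrix(grid) %*% (oracle_valence[syms] - 2) / 2
  keep <- err <= tol_ppm & rd >= -0.5 & rowSums(grid) > 0
  if (!any(keep)) return(character())
  hits <- grid[keep, , drop = FALSE]
  apply(hits, 1, function(v) {
    format_formula(element_counts(stats::setNames(as.integer(v), syms)))
  })
}
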