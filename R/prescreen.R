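# Extracted-ion-chromatogram quality control: per compound x mix x mode x
# collision energy, decide whether clean MS2 spectra can be harvested.

#' Quality-control thresholds
#'
#' Defaults follow routine Orbitrap screening practice for complex mixtures:
#' minimum MS1 apex intensity 1e5 counts, minimum signal-to-noise 3, m/z
#' tolerance +/-2.5 ppm, retention-time tolerance +/-0.5 min.
#'
#' @param min_intensity Minimum chromatographic apex intensity (counts).
#' @param min_snr Minimum apex signal-to-noise ratio.
#' @param ppm m/z matching tolerance (ppm).
#' @param rt_tol Retention-time tolerance (minutes) between the MS1 apex and
#'   a matched MS2 scan.
#' @return List of thresholds (class `qc_thresholds`).
#' @export
qc_thresholds <- function(min_intensity = 1e5, min_snr = 3, ppm = 2.5, rt_tol = 0.5) {
  stopifnot(min_intensity > 0, min_snr > 0, ppm > 0, rt_tol > 0)
  structure(list(min_intensity = min_intensity, min_snr = min_snr,
                 ppm = ppm, rt_tol = rt_tol), class = "qc_thresholds")
}

#' Extract an ion chromatogram
#'
#' For every MS1 scan, sums the intensities of centroids within `ppm` of the
#' target m/z (zero when none match). Aggregation by sum (rather than max)
#' is the default and can be changed.
#'
#' @param run `ms_run`.
#' @param target_mz Target m/z (Da).
#' @param ppm Tolerance in ppm.
#' @param agg `"sum"` (default) or `"max"` aggregation of in-window centroids.
#' @return Tibble (`eic`): `rt` (minutes), `intensity`; attributes
#'   `target_mz`, `ppm`.
#' @export
extract_eic <- function(run, target_mz, ppm = 2.5, agg = c("sum", "max")) {
  agg <- match.arg(agg)
  ms1 <- run[run$ms_level == 1L, , drop = FALSE]
  if (!nrow(ms1)) abort("run has no MS1 scans", class = "mixlib_prescreen_error")
  tol <- target_mz * ppm * 1e-6
  f <- if (agg == "sum") sum else max
  intensity <- vapply(ms1$peaks, function(p) {
    sel <- abs(p[, "mz"] - target_mz) <= tol
    if (any(sel)) f(p[sel, "intensity"]) else 0
  }, numeric(1))
  structure(tibble(rt = ms1$rt, intensity = intensity),
            class = c("eic", class(tibble())),
            target_mz = target_mz, ppm = ppm)
}

# Robust noise level of an EIC: MAD (scaled to sigma) of the points outside
# the given peak bounds; falls back to the MAD of the lower half of all
# points when peaks cover everything.
eic_noise <- function(eic, bounds = NULL) {
  y <- eic$intensity
  outside <- rep(TRUE, length(y))
  if (!is.null(bounds) && nrow(bounds)) {
    for (i in seq_len(nrow(bounds))) {
      outside[eic$rt >= bounds$rt_left[i] & eic$rt <= bounds$rt_right[i]] <- FALSE
    }
  }
  base <- y[outside]
  if (length(base) < 5) base <- y[y <= stats::median(y)]
  noise <- stats::mad(base, center = stats::median(base))
  max(noise, 1)
}

#' Detect chromatographic peaks in an EIC
#'
#' Local-maximum search (via `pracma::findpeaks`) above a noise floor, with
#' MAD-based signal-to-noise estimation using the points outside all peak
#' bounds as the noise baseline.
#'
#' @param eic EIC from [extract_eic()].
#' @param noise_mult Peaks must exceed `noise_mult` x the initial noise
#'   estimate. The default (2) sits below the downstream S/N threshold so
#'   that peaks in the S/N 2..3 band are still detected and can be failed
#'   for low signal-to-noise rather than silently missed.
#' @return Tibble of peaks sorted by retention time: `rt_apex`,
#'   `intensity_apex`, `snr`, `rt_left`, `rt_right`.
#' @export
detect_peaks <- function(eic, noise_mult = 2) {
  stopifnot(nrow(eic) > 0)
  y <- eic$intensity
  empty <- tibble(rt_apex = numeric(), intensity_apex = numeric(),
                  snr = numeric(), rt_left = numeric(), rt_right = numeric())
  if (all(y <= 0)) return(empty)
  noise0 <- eic_noise(eic)
  # zero = "+" so flat-topped (plateau) peaks are still recognised
  pk <- pracma::findpeaks(y, minpeakheight = noise_mult * noise0, nups = 1,
                          zero = "+")
  if (is.null(pk)) return(empty)
  out <- tibble(
    rt_apex = eic$rt[pk[, 2]],
    intensity_apex = pk[, 1],
    rt_left = eic$rt[pk[, 3]],
    rt_right = eic$rt[pk[, 4]]
  )
  noise <- eic_noise(eic, bounds = out)
  out$snr <- out$intensity_apex / noise
  out |> select("rt_apex", "intensity_apex", "snr", "rt_left", "rt_right") |>
    arrange(.data$rt_apex)
}

# MS2 scans of a run whose precursor matches a target m/z within ppm.
matching_ms2 <- function(run, target_mz, ppm) {
  ms2 <- run[run$ms_level == 2L, , drop = FALSE]
  if (!nrow(ms2)) return(ms2)
  tol <- target_mz * ppm * 1e-6
  ms2[abs(ms2$precursor_mz - target_mz) <= tol, , drop = FALSE]
}

#' Quality-control verdict for one compound in one run
#'
#' A compound passes when some chromatographic peak has (a) apex intensity at
#' or above the threshold, (b) signal-to-noise at or above the threshold, and
#' (c) at least one MS2 scan whose precursor matches the target m/z within
#' the ppm tolerance and whose retention time lies within the RT tolerance of
#' that apex. MS2 scans outside the tolerance are excluded from the matches.
#' When no peak satisfies all three, the failed checks of the best candidate
#' peak (fewest violations, then highest apex) are reported; with no peak at
#' all every check fails.
#'
#' @param run `ms_run` (MS1 + MS2 scans of one mix/mode/CE file).
#' @param entry One-row compound tibble (`id`, `mass`, ...).
#' @param adduct Adduct name or object; must match the run polarity.
#' @param thresholds [qc_thresholds()].
#' @return One-row tibble: compound id, mix, polarity, ce, verdict
#'   (`"pass"`/`"fail"`), `failed` (list-column of failed check names among
#'   intensity, snr, ms2_present, rt_shift), `rt_apex`, `intensity_apex`,
#'   `snr`, `ms2_scans` (list-column of matched MS2 scan numbers, nearest
#'   the apex first), and `peaks` (list-column of all detected peaks).
#' @export
qc_compound <- function(run, entry, adduct = "[M+H]+", thresholds = qc_thresholds()) {
  if (is.character(adduct)) adduct <- adduct(adduct)
  pol <- unique(run$polarity)
  if ((adduct$charge > 0) != (pol == "+")) {
    abort("adduct polarity does not match run polarity", class = "mixlib_prescreen_error")
  }
  target <- adduct_mz(entry$mass, adduct)
  eic <- extract_eic(run, target, ppm = thresholds$ppm)
  peaks <- detect_peaks(eic)
  ms2 <- matching_ms2(run, target, thresholds$ppm)

  evaluate <- function(i) {
    p <- peaks[i, ]
    failed <- character()
    if (p$intensity_apex < thresholds$min_intensity) failed <- c(failed, "intensity")
    if (p$snr < thresholds$min_snr) failed <- c(failed, "snr")
    near <- if (nrow(ms2)) abs(ms2$rt - p$rt_apex) <= thresholds$rt_tol else logical()
    if (!nrow(ms2)) {
      failed <- c(failed, "ms2_present")
    } else if (!any(near)) {
      failed <- c(failed, "rt_shift")
    }
    scans <- if (nrow(ms2) && any(near)) {
      m <- ms2[near, , drop = FALSE]
      m$scan[order(abs(m$rt - p$rt_apex))]
    } else integer()
    list(failed = failed, scans = scans)
  }

  if (!nrow(peaks)) {
    failed <- c("intensity", "snr", if (nrow(ms2)) "rt_shift" else "ms2_present")
    best <- list(failed = failed, scans = integer())
    best_peak <- tibble(rt_apex = NA_real_, intensity_apex = NA_real_, snr = NA_real_)
  } else {
    evals <- lapply(seq_len(nrow(peaks)), evaluate)
    nfail <- vapply(evals, function(e) length(e$failed), integer(1))
    ord <- order(nfail, -peaks$intensity_apex)
    best <- evals[[ord[[1]]]]
    best_peak <- peaks[ord[[1]], ]
  }
  src <- run_source(run)
  tibble(
    id = entry$id,
    mix = src$mix %||% NA_character_,
    polarity = pol,
    ce = src$ce_tag %||% NA_real_,
    verdict = if (length(best$failed)) "fail" else "pass",
    failed = list(best$failed),
    rt_apex = best_peak$rt_apex,
    intensity_apex = best_peak$intensity_apex,
    snr = best_peak$snr,
    ms2_scans = list(best$scans),
    peaks = list(peaks)
  )
}

#' Prescreen many compounds against a set of runs
#'
#' @param runs List of `ms_run` objects (one per mix/mode/CE file).
#' @param compounds Compound tibble ([read_compound_list()]).
#' @param design Mix design tibble (`id`, `mix`) from [read_setid()].
#' @param adduct Adduct applied to every compound (chosen per run polarity
#'   when `NULL`: `[M+H]+` for positive, `[M-H]-` for negative runs).
#' @param thresholds [qc_thresholds()].
#' @return QC result tibble, one row per compound x run.
#' @export
prescreen <- function(runs, compounds, design, adduct = NULL,
                      thresholds = qc_thresholds()) {
  res <- purrr::map(runs, function(run) {
    src <- run_source(run)
    ids <- design$id[design$mix == src$mix]
    add <- adduct %||% (if (unique(run$polarity) == "+") "[M+H]+" else "[M-H]-")
    purrr::map(ids, function(i) {
      qc_compound(run, compounds[compounds$id == i, ], adduct = add,
                  thresholds = thresholds)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  res
}

#' Flatten QC results to a summary table and write it as CSV
#'
#' One row per compound x mix x mode x collision energy, with the verdict and
#' comma-joined failure reasons; suitable for per-CE pass tallies.
#'
#' @param results QC tibble from [prescreen()] / [qc_compound()].
#' @param path Optional CSV output path.
#' @return The flat summary tibble (invisibly written to `path` if given).
#' @export
prescreen_table <- function(results, path = NULL) {
  flat <- if (nrow(results)) {
    results |>
      mutate(failed = vapply(.data$failed, paste, character(1), collapse = ","),
             n_ms2 = vapply(.data$ms2_scans, length, integer(1))) |>
      select("id", "mix", "polarity", "ce", "verdict", "failed",
             "rt_apex", "intensity_apex", "snr", "n_ms2")
  } else {
    tibble(id = character(), mix = character(), polarity = character(),
           ce = numeric(), verdict = character(), failed = character(),
           rt_apex = numeric(), intensity_apex = numeric(), snr = numeric(),
           n_ms2 = integer())
  }
  if (!is.null(path)) readr::write_csv(flat, path, progress = FALSE)
  flat
}
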