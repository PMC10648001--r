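# Fragment sub-formula annotation, m/z recalibration and spectrum cleaning.
#
# Tolerances follow a staged scheme: a wide first-pass annotation tolerance
# (default 10 ppm) feeds the recalibration fit; after correction the spectra
# are re-annotated at the screening tolerance (2.5 ppm). Both stages are
# reconstructions of common practice and are exposed as parameters.

#' Enumerate sub-formulas of a precursor ion matching a fragment m/z
#'
#' Finds all element-count subsets of the precursor ion formula whose ion m/z
#' (electron mass included) lies within the ppm tolerance of the fragment
#' m/z, subject to a ring-plus-double-bond-equivalent bound of >= -0.5
#' (allowing even-electron fragment ions). The element set is restricted to
#' the precursor's own elements. Candidates are sorted by absolute ppm error.
#'
#' @param precursor_ion Ion formula (e.g. `adduct_formula("C10H13NO", "[M+H]+")`).
#' @param fragment_mz Observed fragment m/z (Da).
#' @param tol_ppm Matching tolerance in ppm.
#' @param charge Ion charge sign (+1 or -1).
#' @param rdbe_min Lower RDBE bound.
#' @return Tibble: `formula`, `mass`, `mz`, `error_ppm`, `rdbe`.
#' @export
enumerate_subformulas <- function(precursor_ion, fragment_mz, tol_ppm = 10,
                                  charge = 1L, rdbe_min = -0.5) {
  counts <- as_element_counts(precursor_ion)
  stopifnot(length(counts) > 0, fragment_mz > 0, tol_ppm > 0, charge %in% c(-1L, 1L))
  syms <- names(counts)
  maxc <- as.integer(counts)
  masses <- .element_masses[syms]
  # neutral-formula mass window implied by the ion m/z tolerance
  lo <- fragment_mz * (1 - tol_ppm * 1e-6) + charge * .electron_mass
  hi <- fragment_mz * (1 + tol_ppm * 1e-6) + charge * .electron_mass
  # descending element mass gives the strongest pruning
  ord <- order(-masses)
  syms <- syms[ord]; maxc <- maxc[ord]; masses <- masses[ord]
  k <- length(syms)
  max_tail <- rev(cumsum(rev(maxc * masses)))   # max mass attainable from i..k
  acc <- vector("list", 64); nacc <- 0L
  cur <- integer(k)
  dfs <- function(i, mass_so_far) {
    if (mass_so_far > hi) return()
    tail_max <- if (i > k) 0 else max_tail[i]
    if (mass_so_far + tail_max < lo) return()
    if (i > k) {
      if (mass_so_far >= lo) {
        nacc <<- nacc + 1L
        if (nacc > length(acc)) acc[[2L * nacc]] <<- NULL
        acc[[nacc]] <<- cur
      }
      return()
    }
    for (n in 0:maxc[i]) {
      cur[i] <<- n
      dfs(i + 1L, mass_so_far + n * masses[i])
    }
    cur[i] <<- 0L
  }
  dfs(1L, 0)
  if (!nacc) {
    return(tibble(formula = character(), mass = numeric(), mz = numeric(),
                  error_ppm = numeric(), rdbe = numeric()))
  }
  cand <- purrr::map(acc[seq_len(nacc)], function(v) {
    ec <- element_counts(stats::setNames(v, syms))
    if (!length(ec)) return(NULL)
    r <- rdbe(ec)
    if (r < rdbe_min) return(NULL)
    m <- monoisotopic_mass(ec)
    mz <- (m - charge * .electron_mass) / 1
    tibble(formula = format_formula(ec), mass = m, mz = mz,
           error_ppm = ppm_error(fragment_mz, mz), rdbe = r)
  }) |> purrr::list_rbind()
  cand |> arrange(abs(.data$error_ppm))
}

#' Annotate an MS2 spectrum with precursor sub-formulas
#'
#' Every centroid receives the candidate sub-formulas of the precursor ion
#' within tolerance; the candidate with the smallest absolute ppm error is
#' the best assignment. Peaks with no candidate are marked `failpeak`.
#'
#' @param scan One-row `ms_run` slice or a list with a `peaks` matrix.
#' @param entry One-row compound tibble with `formula` (neutral).
#' @param adduct Adduct of the precursor ion.
#' @param tol_ppm Annotation tolerance (ppm).
#' @return Tibble (`annotated_spectrum`): `mz`, `intensity`, `status`
#'   (`assigned`/`failpeak`), `formula`, `theo_mz`, `error_ppm`,
#'   `n_candidates`, `candidates` (list); attribute `assignment_rate`.
#' @export
annotate_spectrum <- function(scan, entry, adduct = "[M+H]+", tol_ppm = 10) {
  if (is.character(adduct)) adduct <- adduct(adduct)
  peaks <- if (is.matrix(scan)) scan else scan$peaks[[1]]
  if (is.null(peaks) || !nrow(peaks)) {
    abort("empty peak list", class = "mixlib_annotate_error")
  }
  ion <- adduct_formula(entry$formula, adduct)
  charge <- if (adduct$charge > 0) 1L else -1L
  rows <- purrr::map(seq_len(nrow(peaks)), function(i) {
    cand <- enumerate_subformulas(ion, peaks[i, "mz"], tol_ppm = tol_ppm,
                                  charge = charge)
    if (nrow(cand)) {
      tibble(mz = peaks[i, "mz"], intensity = peaks[i, "intensity"],
             status = "assigned", formula = cand$formula[[1]],
             theo_mz = cand$mz[[1]], error_ppm = cand$error_ppm[[1]],
             n_candidates = nrow(cand), candidates = list(cand))
    } else {
      tibble(mz = peaks[i, "mz"], intensity = peaks[i, "intensity"],
             status = "failpeak", formula = NA_character_,
             theo_mz = NA_real_, error_ppm = NA_real_,
             n_candidates = 0L, candidates = list(cand))
    }
  }) |> purrr::list_rbind()
  structure(rows, class = c("annotated_spectrum", class(rows)),
            assignment_rate = mean(rows$status == "assigned"),
            precursor_formula = format_formula(ion), charge = charge)
}

#' Assignment rate of an annotated spectrum
#' @param annotated Result of [annotate_spectrum()].
#' @return Fraction of peaks assigned.
#' @export
assignment_rate <- function(annotated) attr(annotated, "assignment_rate")

#' Fit an m/z recalibration model from assigned fragments
#'
#' Models the mass error (ppm) as a smooth function of observed m/z using
#' local regression (span 0.75); with fewer than `min_train` training pairs
#' a linear fit is used instead. Predictions outside the fitted m/z range
#' are clamped to the boundary values.
#'
#' @param pairs Tibble/data.frame with columns `observed` and `theoretical`
#'   (m/z in Da).
#' @param min_train Minimum pairs for the local-regression fit.
#' @param span Loess span.
#' @return `recal_model` object; see [predict.recal_model()].
#' @export
fit_recalibration <- function(pairs, min_train = 20, span = 0.75) {
  stopifnot(all(c("observed", "theoretical") %in% names(pairs)))
  pairs <- as_tibble(pairs) |> filter(!is.na(.data$observed), !is.na(.data$theoretical))
  if (nrow(pairs) < 2) {
    abort("need at least 2 (observed, theoretical) pairs", class = "mixlib_recal_error")
  }
  err <- ppm_error(pairs$observed, pairs$theoretical)
  kind <- if (nrow(pairs) >= min_train) "local-regression" else "linear-fallback"
  fit <- if (kind == "local-regression") {
    stats::loess(err ~ mz, data = tibble(err = err, mz = pairs$observed),
                 span = span, degree = 2, surface = "direct")
  } else {
    stats::lm(err ~ mz, data = tibble(err = err, mz = pairs$observed))
  }
  rng <- range(pairs$observed)
  model <- structure(
    list(fit = fit, kind = kind, range = rng, n = nrow(pairs),
         raw_error_ppm = err, train_mz = pairs$observed),
    class = "recal_model"
  )
  model
}

#' Predicted mass error (ppm) at given m/z values
#'
#' @param object `recal_model`.
#' @param newdata Numeric vector of m/z values (clamped to the fitted range).
#' @param ... Unused.
#' @return Predicted error in ppm.
#' @export
predict.recal_model <- function(object, newdata, ...) {
  mz <- pmin(pmax(as.numeric(newdata), object$range[[1]]), object$range[[2]])
  as.numeric(stats::predict(object$fit, tibble(mz = mz)))
}

#' @export
print.recal_model <- function(x, ...) {
  cat("<recal_model>", x$kind, "fit on", x$n, "pairs;",
      sprintf("m/z range %.4f-%.4f\n", x$range[[1]], x$range[[2]]))
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the training residuals of a recalibration model
#' @param x `recal_model`.
#' @param ... Unused.
#' @return Tibble: `mz`, `raw_error_ppm`, `fitted_ppm`, `residual_ppm`.
#' @export
tidy.recal_model <- function(x, ...) {
  fitted <- predict(x, x$train_mz)
  tibble(mz = x$train_mz, raw_error_ppm = x$raw_error_ppm,
         fitted_ppm = fitted, residual_ppm = x$raw_error_ppm - fitted)
}

#' One-row summary of a recalibration model
#' @param x `recal_model`.
#' @param ... Unused.
#' @return Tibble: `kind`, `n`, `mz_min`, `mz_max`, `median_raw_ppm`,
#'   `median_residual_ppm`.
#' @export
glance.recal_model <- function(x, ...) {
  td <- tidy(x)
  tibble(kind = x$kind, n = x$n, mz_min = x$range[[1]], mz_max = x$range[[2]],
         median_raw_ppm = stats::median(abs(td$raw_error_ppm)),
         median_residual_ppm = stats::median(abs(td$residual_ppm)))
}

#' Collect (observed, theoretical) pairs from annotated spectra
#'
#' @param annotated_list List of [annotate_spectrum()] results.
#' @return Tibble with `observed`, `theoretical` from all assigned peaks.
#' @export
recalibration_pairs <- function(annotated_list) {
  purrr::map(annotated_list, function(a) {
    a <- a[a$status == "assigned", , drop = FALSE]
    tibble(observed = a$mz, theoretical = a$theo_mz)
  }) |> purrr::list_rbind()
}

#' Apply a recalibration model to a scan or run
#'
#' Corrects every peak m/z (and MS2 precursor m/z) by the predicted ppm
#' error: `corrected = observed * (1 - pred_ppm * 1e-6)`. Out-of-range m/z
#' receive the boundary correction (clamping contract of the model).
#'
#' @param x One-row scan slice, a peaks matrix, or an `ms_run`.
#' @param model `recal_model`.
#' @return Object of the same shape with corrected m/z.
#' @export
apply_recalibration <- function(x, model) {
  correct <- function(mz) mz * (1 - predict(model, mz) * 1e-6)
  if (is.matrix(x)) {
    x[, "mz"] <- correct(x[, "mz"])
    return(x)
  }
  x$peaks <- lapply(x$peaks, function(p) {
    if (nrow(p)) p[, "mz"] <- correct(p[, "mz"])
    p
  })
  if ("precursor_mz" %in% names(x)) {
    sel <- !is.na(x$precursor_mz)
    x$precursor_mz[sel] <- correct(x$precursor_mz[sel])
  }
  x
}

#' Cleaning policy for annotated spectra
#'
#' @param keep_failpeaks Retain unannotated peaks (default drop).
#' @param min_rel Relative-intensity floor (fraction of the base peak).
#' @param merge_ppm Centroids closer than this (ppm) are merged
#'   (intensity-weighted m/z, summed intensity); default twice the
#'   post-recalibration tolerance.
#' @return Policy list.
#' @export
clean_policy <- function(keep_failpeaks = FALSE, min_rel = 1e-3, merge_ppm = 5) {
  list(keep_failpeaks = keep_failpeaks, min_rel = min_rel, merge_ppm = merge_ppm)
}

#' Clean an annotated spectrum
#'
#' Drops failpeaks (configurable), applies the relative-intensity floor, and
#' merges duplicate centroids within the merge width.
#'
#' @param annotated [annotate_spectrum()] result.
#' @param policy [clean_policy()].
#' @param precursor Optional list of precursor metadata to carry along
#'   (`precursor_mz`, `ce`, `polarity`, ...).
#' @return `clean_spectrum`: tibble `mz`, `intensity`, `formula`, sorted by
#'   m/z, intensities > 0; attributes `base_peak`, `precursor`, `provenance`.
#' @export
clean_spectrum <- function(annotated, policy = clean_policy(), precursor = list()) {
  pk <- as_tibble(annotated)[, c("mz", "intensity", "formula", "status")]
  if (!policy$keep_failpeaks) pk <- pk[pk$status == "assigned", , drop = FALSE]
  pk <- pk[pk$intensity > 0, , drop = FALSE]
  pk <- pk[order(pk$mz), , drop = FALSE]
  # single-linkage merge of centroids within the merge width
  if (nrow(pk) > 1) {
    gap_ppm <- diff(pk$mz) / pk$mz[-nrow(pk)] * 1e6
    grp <- cumsum(c(1, gap_ppm > policy$merge_ppm))
    pk <- pk |>
      mutate(.grp = grp) |>
      group_by(.data$.grp) |>
      summarise(
        formula = .data$formula[which.max(.data$intensity)],
        mz = sum(.data$mz * .data$intensity) / sum(.data$intensity),
        intensity = sum(.data$intensity),
        .groups = "drop"
      ) |>
      select("mz", "intensity", "formula")
  } else {
    pk <- pk[, c("mz", "intensity", "formula")]
  }
  if (nrow(pk)) {
    base <- max(pk$intensity)
    pk <- pk[pk$intensity >= policy$min_rel * base, , drop = FALSE]
  }
  structure(as_tibble(pk), class = c("clean_spectrum", class(tibble())),
            base_peak = if (nrow(pk)) max(pk$intensity) else 0,
            precursor = precursor,
            provenance = policy)
}
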