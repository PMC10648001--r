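# Cross-mix disambiguation of isobaric compounds.
#
# Compounds of one mix whose adduct ions fall within the precursor isolation
# window form an isobar group; their EICs are indistinguishable, so a DDA
# spectrum near a shared chromatographic peak cannot be attributed to one
# compound from that mix alone. Mixes where only one group member is present
# anchor that compound's retention time; anchors propagate across mixes and
# may leave a single member/peak pair that is then assigned by elimination.
# Anything still ambiguous is reported at confidence level 3 and excluded
# from record generation.

#' Group mix members that share the precursor isolation window
#'
#' Within each mix, compounds are grouped by single-linkage on
#' `|delta ion m/z| <= window_da` (transitive closure), so in one dimension a
#' group is a chain of consecutive gaps at most the window width. Singletons
#' form their own groups.
#'
#' @param design Mix design tibble (`id`, `mix`).
#' @param compounds Compound tibble with `id`, `mass`.
#' @param adduct Adduct used for ion m/z.
#' @param window_da Isolation window width (Da), default 1.
#' @return Tibble: `mix`, `group` (id within mix), `id`, `ion_mz`,
#'   `mz_min`, `mz_max`, `n_members`.
#' @export
group_isobars <- function(design, compounds, adduct = "[M+H]+", window_da = 1.0) {
  if (is.character(adduct)) adduct <- adduct(adduct)
  df <- design |>
    inner_join(compounds[, c("id", "mass")], by = "id") |>
    mutate(ion_mz = adduct_mz(.data$mass, adduct))
  if (!nrow(df)) {
    return(tibble(mix = character(), group = integer(), id = character(),
                  ion_mz = numeric(), mz_min = numeric(), mz_max = numeric(),
                  n_members = integer()))
  }
  df |>
    group_by(.data$mix) |>
    arrange(.data$ion_mz, .by_group = TRUE) |>
    mutate(group = cumsum(c(1, diff(.data$ion_mz) > window_da))) |>
    group_by(.data$mix, .data$group) |>
    mutate(mz_min = min(.data$ion_mz), mz_max = max(.data$ion_mz),
           n_members = dplyr::n()) |>
    ungroup() |>
    select("mix", "group", "id", "ion_mz", "mz_min", "mz_max", "n_members")
}

# Deduplicate the chromatographic peaks seen by the members of one
# mix-group: members of an isobar group share (nearly) the same EIC window,
# so their detected peaks coincide; peaks are clustered on RT.
collect_group_peaks <- function(detections, ids, mix, rt_cluster_tol) {
  pk <- detections |>
    filter(.data$mix == !!mix, .data$id %in% ids) |>
    select("id", "mix", "peaks") |>
    tidyr::unnest("peaks")
  if (!nrow(pk)) {
    return(tibble(peak = integer(), rt = numeric(), intensity = numeric()))
  }
  pk <- pk |> arrange(.data$rt_apex)
  cl <- cumsum(c(1, diff(pk$rt_apex) > rt_cluster_tol))
  pk |>
    mutate(.cl = cl) |>
    group_by(.data$.cl) |>
    summarise(rt = stats::median(.data$rt_apex),
              intensity = max(.data$intensity_apex), .groups = "drop") |>
    mutate(peak = dplyr::row_number()) |>
    select("peak", "rt", "intensity")
}

#' Resolve isobar groups across mixes by retention-time anchoring
#'
#' Implements the cross-mix logic: (i) a compound alone in its group with a
#' detected peak is anchored at that peak's RT (level 1, `alone_in_mix`);
#' (ii) anchors propagate -- in multi-member groups, peaks within `rt_tol`
#' of an anchored compound's RT are claimed by it (level 1,
#' `anchored_elsewhere`); (iii) when exactly one unclaimed peak and one
#' unanchored member remain in a group, the pair is assigned by elimination
#' (level 1, `by_elimination`) and becomes a new anchor; propagation iterates
#' to a fixpoint across mixes; (iv) any remaining many-to-many case is
#' reported at level 3 (`ambiguous`); (v) members with no peak are
#' `not_detected`. Two anchored compounds claiming one peak (co-elution)
#' are both demoted to level 3.
#'
#' @param groups Output of [group_isobars()].
#' @param detections QC tibble from [prescreen()] (needs `id`, `mix`,
#'   `peaks` list-column of detected chromatographic peaks). Only passing
#'   detections should normally be supplied.
#' @param rt_tol RT anchoring tolerance in minutes (> 0).
#' @return Assignment tibble: `id`, `mix`, `rt`, `intensity`, `level`
#'   (`"1"`, `"3"`, `"not_detected"`), `rationale` (`alone_in_mix`,
#'   `anchored_elsewhere`, `by_elimination`, `ambiguous`, `coelution`,
#'   `no_peak`).
#' @export
resolve_isobars <- function(groups, detections, rt_tol = 0.5) {
  if (rt_tol <= 0) abort("rt_tol must be > 0", class = "mixlib_isobar_error")
  # deterministic iteration order
  keys <- groups |> distinct(.data$mix, .data$group) |> arrange(.data$mix, .data$group)
  state <- purrr::pmap(keys, function(mix, group) {
    members <- groups |> filter(.data$mix == !!mix, .data$group == !!group) |>
      arrange(.data$id)
    peaks <- collect_group_peaks(detections, members$id, mix, rt_cluster_tol = rt_tol / 2)
    list(mix = mix, members = members$id, peaks = peaks,
         assigned = tibble(id = character(), peak = integer(),
                           rt = numeric(), intensity = numeric(),
                           rationale = character()))
  })
  anchors <- tibble(id = character(), rt = numeric())
  add_anchor <- function(id, rt) {
    if (!id %in% anchors$id) anchors <<- bind_rows(anchors, tibble(id = id, rt = rt))
  }

  # pass 0: singleton groups
  for (i in seq_along(state)) {
    st <- state[[i]]
    if (length(st$members) == 1 && nrow(st$peaks) >= 1) {
      # all peaks belong to the lone member; anchor at the most intense
      best <- st$peaks[which.max(st$peaks$intensity), ]
      state[[i]]$assigned <- tibble(id = st$members, peak = best$peak,
                                    rt = best$rt, intensity = best$intensity,
                                    rationale = "alone_in_mix")
      add_anchor(st$members, best$rt)
    }
  }

  # fixpoint propagation over multi-member groups
  repeat {
    changed <- FALSE
    for (i in seq_along(state)) {
      st <- state[[i]]
      if (length(st$members) < 2) next
      open_members <- setdiff(st$members, st$assigned$id)
      open_peaks <- st$peaks |> filter(!.data$peak %in% st$assigned$peak)
      if (!length(open_members) || !nrow(open_peaks)) next
      # anchored members claim nearby peaks; two anchors claiming the same
      # peak is co-elution and demotes both (safety over coverage)
      claims <- purrr::map(open_members, function(m) {
        a <- anchors |> filter(.data$id == m)
        if (!nrow(a)) return(NULL)
        near <- open_peaks |> filter(abs(.data$rt - a$rt[[1]]) <= rt_tol)
        if (!nrow(near)) return(NULL)
        best <- near[which.min(abs(near$rt - a$rt[[1]])), ]
        tibble(id = m, peak = best$peak, rt = best$rt,
               intensity = best$intensity)
      }) |> purrr::list_rbind()
      if (!is.null(claims) && nrow(claims)) {
        claims <- claims |>
          group_by(.data$peak) |>
          mutate(rationale = if (dplyr::n() > 1) "coelution" else "anchored_elsewhere") |>
          ungroup()
        st$assigned <- bind_rows(st$assigned, claims)
        open_peaks <- open_peaks |> filter(!.data$peak %in% claims$peak)
        changed <- TRUE
      }
      open_members <- setdiff(st$members, st$assigned$id)
      # elimination: one member, one peak left
      if (length(open_members) == 1 && nrow(open_peaks) == 1) {
        st$assigned <- bind_rows(st$assigned,
          tibble(id = open_members, peak = open_peaks$peak,
                 rt = open_peaks$rt, intensity = open_peaks$intensity,
                 rationale = "by_elimination"))
        add_anchor(open_members, open_peaks$rt)
        changed <- TRUE
      }
      state[[i]] <- st
    }
    if (!changed) break
  }

  # co-elution safety: within a group, two assigned compounds whose anchored
  # RTs both lie within rt_tol of the same peak are demoted
  out <- purrr::map(state, function(st) {
    asg <- st$assigned
    if (nrow(asg) > 1) {
      dup <- asg |> count(.data$peak) |> filter(.data$n > 1)
      if (nrow(dup)) {
        demote <- asg$peak %in% dup$peak
        asg$rationale[demote] <- "coelution"
      }
    }
    level1 <- asg |>
      mutate(level = as.character(ifelse(.data$rationale == "coelution", "3", "1")),
             mix = rep(st$mix, dplyr::n()))
    open_members <- setdiff(st$members, asg$id)
    open_peaks <- st$peaks |> filter(!.data$peak %in% asg$peak)
    rest <- if (length(open_members)) {
      if (nrow(open_peaks)) {
        tibble(id = open_members, mix = st$mix, peak = NA_integer_,
               rt = NA_real_, intensity = NA_real_,
               rationale = "ambiguous", level = "3")
      } else {
        tibble(id = open_members, mix = st$mix, peak = NA_integer_,
               rt = NA_real_, intensity = NA_real_,
               rationale = "no_peak", level = "not_detected")
      }
    } else NULL
    bind_rows(level1, rest)
  }) |> purrr::list_rbind()
  out |>
    select("id", "mix", "rt", "intensity", "level", "rationale") |>
    arrange(.data$mix, .data$id)
}

#' Retain only spectra of unambiguous (level-1) assignments
#'
#' @param spectra Tibble of extracted spectra with `id` and `mix` columns
#'   (e.g. one row per clean spectrum).
#' @param assignments Output of [resolve_isobars()].
#' @return List with `retained` (spectra of level-1 assignments) and
#'   `excluded` (dropped rows joined with the exclusion level/rationale).
#' @export
filter_records <- function(spectra, assignments) {
  keep <- assignments |> filter(.data$level == "1") |> select("id", "mix")
  retained <- spectra |> inner_join(keep, by = c("id", "mix"))
  excluded <- spectra |>
    anti_join(keep, by = c("id", "mix")) |>
    left_join(assignments |> select("id", "mix", "level", "rationale"),
              by = c("id", "mix"))
  list(retained = retained, excluded = excluded)
}
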