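# Synthetic multi-mix DDA fixtures with known ground truth.
#
# The generator emulates the screening study's input shape: ten mixes of
# 95/185/365 compounds (two of the larger mixes carrying the replicate set
# of the first mix), positive/negative runs per collision energy, Gaussian
# chromatographic peaks, an inclusion-list DDA duty cycle, a planted
# mass-error curve, baseline noise, and optional planted isobar pairs and
# QC violations. Fragment spectra are random sub-formula draws with a
# CE-dependent intensity shift -- deliberately non-physical, but exactly
# reproducible and annotatable.

.sim_families <- list(
  alkanol  = function(n) list(smiles = paste0(strrep("C", n), "O"),
                              counts = c(C = n, H = 2 * n + 2, O = 1),
                              name = sprintf("n-alkan-1-ol C%d (synthetic)", n)),
  alkan2ol = function(n) list(smiles = paste0("CC(O)", strrep("C", n - 2)),
                              counts = c(C = n, H = 2 * n + 2, O = 1),
                              name = sprintf("alkan-2-ol C%d (synthetic)", n)),
  amine    = function(n) list(smiles = paste0(strrep("C", n), "N"),
                              counts = c(C = n, H = 2 * n + 3, N = 1),
                              name = sprintf("n-alkylamine C%d (synthetic)", n)),
  acid     = function(n) list(smiles = paste0(strrep("C", n - 1), "C(=O)O"),
                              counts = c(C = n, H = 2 * n, O = 2),
                              name = sprintf("n-alkanoic acid C%d (synthetic)", n)),
  ketone   = function(n) list(smiles = paste0("CC(=O)", strrep("C", n - 2)),
                              counts = c(C = n, H = 2 * n, O = 1),
                              name = sprintf("methyl ketone C%d (synthetic)", n)),
  diol     = function(n) list(smiles = paste0("O", strrep("C", n), "O"),
                              counts = c(C = n, H = 2 * n + 2, O = 2),
                              name = sprintf("alkane diol C%d (synthetic)", n)),
  amide    = function(n) list(smiles = paste0(strrep("C", n - 1), "C(=O)N"),
                              counts = c(C = n, H = 2 * n + 1, N = 1, O = 1),
                              name = sprintf("n-alkanamide C%d (synthetic)", n)),
  nitrile  = function(n) list(smiles = paste0(strrep("C", n - 1), "C#N"),
                              counts = c(C = n, H = 2 * n - 1, N = 1),
                              name = sprintf("n-alkanenitrile C%d (synthetic)", n))
)

#' Simulation parameters
#'
#' Defaults describe a 17-minute gradient sampled every 0.01 min, Gaussian
#' peaks of sigma 0.05 min, apex intensities log-uniform between 3e5 and
#' 3e6 counts, six nominal collision energies (15..90), a 1 Da isolation
#' window, a DDA duty cycle taking one MS2 per listed precursor every 5th
#' MS1 cycle above 1e4 counts, sparse baseline noise and a configurable
#' linear mass-error curve (ppm as a function of m/z).
#'
#' @param rt_range Chromatogram span (minutes).
#' @param scan_interval MS1 sampling interval (minutes).
#' @param sigma_rt Chromatographic peak sigma (minutes).
#' @param apex_range Range of per-compound apex intensities (counts),
#'   sampled log-uniformly.
#' @param ce_levels Nominal collision energies.
#' @param iso_width Precursor isolation window (Da).
#' @param mass_error `c(intercept, slope)`: error in ppm at m/z `mz` is
#'   `intercept + slope * (mz - 100)`.
#' @param noise_rate Expected number of spurious baseline centroids per MS1
#'   scan.
#' @param noise_level Mean intensity of baseline centroids (counts).
#' @param dda_threshold MS1 intensity needed to trigger an MS2.
#' @param dda_period Trigger one MS2 per listed precursor every this many
#'   MS1 cycles while above threshold.
#' @param n_fragments Planted fragments per compound (precursor ion is
#'   always included as well).
#' @param min_frag_mz Smallest allowed fragment m/z.
#' @param seed Random seed; fixed seed gives byte-identical mzML output.
#' @return Parameter list (class `sim_params`).
#' @export
sim_params <- function(rt_range = c(1, 17), scan_interval = 0.01,
                       sigma_rt = 0.05, apex_range = c(3e5, 3e6),
                       ce_levels = c(15, 30, 45, 60, 75, 90),
                       iso_width = 1, mass_error = c(0, 0),
                       noise_rate = 3, noise_level = 200,
                       dda_threshold = 1e4, dda_period = 5,
                       n_fragments = 6, min_frag_mz = 50, seed = 1L) {
  stopifnot(sigma_rt > 0, length(ce_levels) >= 1, iso_width > 0)
  structure(as.list(environment()), class = "sim_params")
}

ppm_curve <- function(params) {
  a <- params$mass_error[[1]]; b <- params$mass_error[[2]]
  function(mz) a + b * (mz - 100)
}

# derive a reproducible sub-seed (< 2^31) for a labelled simulation unit
sub_seed <- function(seed, label) {
  (as.integer(seed) * 1009L +
     sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))) %% 2000000011L
}

#' Generate a multi-mix screening design with ground truth
#'
#' Builds a compound list and setID map emulating a multi-mix trial. The
#' default sizes are the ten-mix design (95, 95, 95, 95, 185, 185, 365,
#' 365, 95, 365) with mixes named 499..508; the replicate plan re-uses the
#' complete first mix inside mixes 503 and 505. Compounds are simple
#' homologous-series structures with analytically known formulas, packed
#' into mixes so that no two ions fall within the isolation window unless
#' an isobar pair is explicitly planted. Each planted pair shares one
#' molecular formula; anchored pairs get a disambiguating mix where one
#' member occurs alone, unanchored pairs always co-occur.
#'
#' @param sizes Mix sizes.
#' @param mix_names Mix names (defaults to 499..508 truncated/extended to
#'   `length(sizes)`).
#' @param replicate_plan List of `c(target=, source=)` pairs: the target mix
#'   includes every compound of the source mix.
#' @param isobar_plan Tibble with column `anchored` (one row per planted
#'   same-formula pair), or an integer count (then all anchored).
#' @param min_separation Minimum ion m/z gap (Da) enforced within a mix for
#'   non-isobar members.
#' @param violations Optional tibble `n` x (`violation`) or character vector
#'   recycled over compounds: planted QC defects among `"none"`,
#'   `"intensity"`, `"snr"`, `"ms2_absent"`, `"ms2_shifted"`.
#' @param seed Random seed.
#' @return List (class `sim_design`): `compounds` (id, name, smiles,
#'   formula, mass, rt, apex, sigma, violation), `design` (id, mix),
#'   `isobar_pairs` (pair, id_a, id_b, anchored).
#' @export
generate_design <- function(sizes = c(95, 95, 95, 95, 185, 185, 365, 365, 95, 365),
                            mix_names = NULL,
                            replicate_plan = NULL,
                            isobar_plan = NULL,
                            min_separation = 1.1,
                            violations = "none",
                            seed = 1L) {
  set.seed(sub_seed(seed, "design"))
  n_mix <- length(sizes)
  if (is.null(mix_names)) mix_names <- as.character(seq(499, by = 1, length.out = n_mix))
  stopifnot(length(mix_names) == n_mix)
  if (is.null(replicate_plan) && n_mix == 10 &&
      identical(sizes, c(95, 95, 95, 95, 185, 185, 365, 365, 95, 365))) {
    replicate_plan <- list(c(target = "503", source = "499"),
                           c(target = "505", source = "499"))
  }
  if (is.numeric(isobar_plan)) {
    isobar_plan <- tibble(anchored = rep(TRUE, isobar_plan))
  }
  n_pairs <- if (is.null(isobar_plan)) 0L else nrow(isobar_plan)

  # pool of candidate structures, mass-sorted (skip the alkan-2-ol family:
  # it is reserved for isobar planting)
  pool_fams <- setdiff(names(.sim_families), "alkan2ol")
  pool <- purrr::map(3:450, function(n) {
    purrr::map(pool_fams, function(f) {
      spec <- .sim_families[[f]](n)
      tibble(family = f, n = n, smiles = spec$smiles, name = spec$name,
             formula = format_formula(element_counts(spec$counts)),
             mass = monoisotopic_mass(element_counts(spec$counts)))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind() |> arrange(.data$mass)

  need <- sizes
  members <- purrr::map(seq_len(n_mix), function(i) character())
  masses <- purrr::map(seq_len(n_mix), function(i) numeric())
  compounds <- list()
  next_id <- 1L
  new_id <- function() {
    id <- sprintf("SIM%05d", next_id); next_id <<- next_id + 1L; id
  }
  add_compound <- function(row) {
    id <- new_id()
    compounds[[length(compounds) + 1L]] <<- tibble(
      id = id, name = row$name, smiles = row$smiles,
      formula = row$formula, mass = row$mass)
    id
  }
  place <- function(mix_i, id, mass) {
    members[[mix_i]] <<- c(members[[mix_i]], id)
    masses[[mix_i]] <<- c(masses[[mix_i]], mass)
    need[mix_i] <<- need[mix_i] - 1L
  }

  # replicate sources are filled first so targets can copy them
  src_names <- unique(vapply(replicate_plan %||% list(), `[[`, character(1), "source"))
  order_mix <- order(!(mix_names %in% src_names))

  # planted isobar pairs (consume the smallest pool masses' alkanol slots)
  pair_rows <- NULL
  if (n_pairs > 0) {
    stopifnot(n_mix >= 2)
    for (p in seq_len(n_pairs)) {
      n_carbon <- 8 + 2 * p
      a_spec <- .sim_families$alkanol(n_carbon)
      b_spec <- .sim_families$alkan2ol(n_carbon)
      a_row <- tibble(name = a_spec$name, smiles = a_spec$smiles,
                      formula = format_formula(element_counts(a_spec$counts)),
                      mass = monoisotopic_mass(element_counts(a_spec$counts)))
      b_row <- a_row; b_row$name <- b_spec$name; b_row$smiles <- b_spec$smiles
      id_a <- add_compound(a_row); id_b <- add_compound(b_row)
      anchored <- isTRUE(isobar_plan$anchored[[p]])
      # both members co-occur in the mix with the most free slots
      co <- which.max(need)
      place(co, id_a, a_row$mass); place(co, id_b, b_row$mass)
      other <- setdiff(order(need, decreasing = TRUE), co)[[1]]
      if (anchored) {
        place(other, id_a, a_row$mass)       # solo occurrence anchors id_a
      } else {
        place(other, id_a, a_row$mass)       # never separated
        place(other, id_b, b_row$mass)
      }
      pair_rows <- bind_rows(pair_rows,
        tibble(pair = p, id_a = id_a, id_b = id_b, anchored = anchored))
      # drop the consumed alkanol from the pool
      pool <- pool |> filter(!(.data$family == "alkanol" & .data$n == n_carbon))
    }
  }

  # greedy fill respecting the within-mix separation; replicate targets are
  # seeded with their source mix first (sources come earlier in order_mix)
  pool_mass <- pool$mass
  pool_used <- rep(FALSE, nrow(pool))
  for (mi in order_mix) {
    for (rp in replicate_plan %||% list()) {
      if (rp[["target"]] == mix_names[[mi]]) {
        si <- match(rp[["source"]], mix_names)
        stopifnot(!is.na(si), length(members[[si]]) > 0)
        fresh <- setdiff(members[[si]], members[[mi]])
        for (id in fresh) {
          place(mi, id, masses[[si]][[match(id, members[[si]])]])
        }
      }
    }
    while (need[mi] > 0L) {
      open <- which(!pool_used)
      if (!length(open)) {
        abort("structure pool exhausted; reduce sizes or separation",
              class = "mixlib_sim_error")
      }
      found <- FALSE
      for (j in open) {
        if (!length(masses[[mi]]) ||
            min(abs(masses[[mi]] - pool_mass[[j]])) > min_separation) {
          id <- add_compound(pool[j, ])
          place(mi, id, pool_mass[[j]])
          pool_used[[j]] <- TRUE
          found <- TRUE
          break
        }
      }
      if (!found) {
        abort("cannot satisfy within-mix mass separation", class = "mixlib_sim_error")
      }
    }
  }

  compounds <- purrr::list_rbind(compounds)
  # chromatography: one true RT per compound, shared across mixes
  rt_lo <- 2; rt_hi <- 15
  compounds$rt <- round(stats::runif(nrow(compounds), rt_lo, rt_hi), 3)
  if (!is.null(pair_rows)) {
    for (p in seq_len(nrow(pair_rows))) {
      ia <- match(pair_rows$id_a[[p]], compounds$id)
      ib <- match(pair_rows$id_b[[p]], compounds$id)
      while (abs(compounds$rt[ia] - compounds$rt[ib]) < 1.5) {
        compounds$rt[ib] <- round(stats::runif(1, rt_lo, rt_hi), 3)
      }
    }
  }
  compounds$apex <- round(exp(stats::runif(nrow(compounds), log(3e5), log(3e6))))
  compounds$sigma <- 0.05
  compounds$violation <- rep_len(violations, nrow(compounds))
  compounds$apex[compounds$violation == "intensity"] <- 5e4
  compounds$apex[compounds$violation == "snr"] <- 1.5e5

  design <- purrr::map2(mix_names, members, function(m, ids) {
    tibble(id = ids, mix = m)
  }) |> purrr::list_rbind()

  structure(list(compounds = compounds, design = design,
                 isobar_pairs = pair_rows %||%
                   tibble(pair = integer(), id_a = character(),
                          id_b = character(), anchored = logical()),
                 seed = seed),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat("<sim_design>", nrow(x$compounds), "compounds in",
      length(unique(x$design$mix)), "mixes;",
      nrow(x$isobar_pairs), "planted isobar pair(s)\n")
  invisible(x)
}

#' Write design CSVs in the pipeline input schema
#'
#' @param design `sim_design`.
#' @param dir Output directory.
#' @return Named paths of `compounds.csv` and `setid.csv`.
#' @export
write_design <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(compounds = file.path(dir, "compounds.csv"),
             setid = file.path(dir, "setid.csv"))
  readr::write_csv(design$compounds[, c("id", "name", "smiles")],
                   paths[["compounds"]], progress = FALSE)
  readr::write_csv(design$design, paths[["setid"]], progress = FALSE)
  paths
}

# planted fragment set for one compound: sub-formulas of the precursor ion
planted_fragments <- function(ion_counts, params) {
  syms <- names(ion_counts)
  prec_mass <- monoisotopic_mass(ion_counts)
  frags <- list()
  tries <- 0L
  while (length(frags) < params$n_fragments && tries < 200L) {
    tries <- tries + 1L
    p <- stats::runif(1, 0.3, 0.9)
    cand <- vapply(as.integer(ion_counts), function(k) stats::rbinom(1, k, p), integer(1))
    ec <- element_counts(stats::setNames(cand, syms))
    if (!length(ec)) next
    m <- monoisotopic_mass(ec)
    if (m < params$min_frag_mz || m >= prec_mass - 0.5) next
    if (rdbe(ec) < -0.5) next
    key <- format_formula(ec)
    if (key %in% names(frags)) next
    frags[[key]] <- ec
  }
  frags
}

# CE-dependent fragment intensity profile: higher collision energy shifts
# weight to lower-mass fragments
fragment_weights <- function(frag_masses, prec_mass, ce) {
  frac <- frag_masses / prec_mass
  target <- 1 - 0.8 * ce / 100
  exp(-(frac - target)^2 / 0.08)
}

#' Simulate one DDA run of a mix
#'
#' Produces MS1 scans with Gaussian extracted-ion profiles plus baseline
#' noise, and inclusion-list DDA MS2 scans near each apex whose fragment
#' peaks are drawn from the compound's planted sub-formulas, with the
#' configured mass-error curve applied to every emitted m/z. Planted QC
#' violations shape the run: `intensity` (weak apex), `snr` (oscillating
#' chemical background in the compound's m/z track), `ms2_absent` (left off
#' the inclusion list), `ms2_shifted` (MS2 triggered 0.7 min after apex).
#'
#' @param design `sim_design`.
#' @param mix Mix name.
#' @param mode `"+"` or `"-"`.
#' @param ce Collision energy (one of `params$ce_levels`).
#' @param params [sim_params()].
#' @param path Optional mzML output path.
#' @return List: `run` (`ms_run`), `truth` (tibble per compound: id, mix,
#'   detectable, rt, apex, violation, ion m/z, fragment formulas), and
#'   `path` when written.
#' @export
simulate_run <- function(design, mix, mode = "+", ce = 45,
                         params = sim_params(), path = NULL) {
  set.seed(sub_seed(params$seed, paste(mix, mode, ce)))
  adduct <- if (mode == "+") adduct("[M+H]+") else adduct("[M-H]-")
  err <- ppm_curve(params)
  obs_mz <- function(mz) mz * (1 + err(mz) * 1e-6)

  cmp <- design$design |> filter(.data$mix == !!mix) |>
    inner_join(design$compounds, by = "id")
  if (!nrow(cmp)) abort(paste0("empty mix: ", mix), class = "mixlib_sim_error")
  cmp$ion_mz <- adduct_mz(cmp$mass, adduct)
  cmp$ion_formula <- vapply(cmp$formula, function(f) {
    format_formula(adduct_formula(f, adduct))
  }, character(1), USE.NAMES = FALSE)

  rt1 <- seq(params$rt_range[[1]], params$rt_range[[2]], by = params$scan_interval)
  n1 <- length(rt1)
  ms1_peaks <- vector("list", n1)  # accumulating [mz, int] rows per scan

  add_points <- function(scan_idx, mz, int) {
    keep <- int >= 1
    if (!any(keep)) return()
    ms1_peaks[[scan_idx]] <<- rbind(ms1_peaks[[scan_idx]],
                                    cbind(mz[keep], int[keep]))
  }

  # compound elution profiles
  for (i in seq_len(nrow(cmp))) {
    sel <- which(abs(rt1 - cmp$rt[[i]]) <= 4 * cmp$sigma[[i]])
    if (length(sel)) {
      int <- cmp$apex[[i]] * exp(-(rt1[sel] - cmp$rt[[i]])^2 / (2 * cmp$sigma[[i]]^2))
      for (k in seq_along(sel)) {
        add_points(sel[[k]], obs_mz(cmp$ion_mz[[i]]), int[[k]])
      }
    }
    if (identical(cmp$violation[[i]], "snr")) {
      # oscillating chemical background over the full run in this m/z track,
      # phase-locked so a crest coincides with the compound's apex: the peak
      # stays detectable but its S/N sinks below the threshold
      ridge <- 2.5 * cmp$apex[[i]] *
        (1 + sin(2 * pi * (rt1 - cmp$rt[[i]]) / 2 + pi / 2)) / 2 *
        stats::runif(n1, 0.95, 1.05)
      for (k in seq_len(n1)) {
        add_points(k, obs_mz(cmp$ion_mz[[i]]) * (1 + stats::runif(1, -2e-7, 2e-7)),
                   ridge[[k]])
      }
    }
  }
  # baseline noise centroids
  for (k in seq_len(n1)) {
    nn <- stats::rpois(1, params$noise_rate)
    if (nn > 0) {
      add_points(k, stats::runif(nn, 50, 600),
                 stats::rexp(nn, 1 / params$noise_level))
    }
  }

  # planted fragment sets (shared across CE levels via a per-compound seed)
  truth_frags <- purrr::map(seq_len(nrow(cmp)), function(i) {
    set.seed(sub_seed(params$seed, paste0("frag-", cmp$id[[i]])))
    planted_fragments(parse_formula(cmp$ion_formula[[i]]), params)
  })

  # DDA schedule: inclusion list of mix precursors, one MS2 per compound
  # every dda_period-th MS1 cycle while the profile is above threshold
  charge <- if (adduct$charge > 0) 1L else -1L
  ms2 <- list()
  set.seed(sub_seed(params$seed, paste(mix, mode, ce, "dda")))
  for (i in seq_len(nrow(cmp))) {
    if (identical(cmp$violation[[i]], "ms2_absent")) next
    shift <- if (identical(cmp$violation[[i]], "ms2_shifted")) 0.7 else 0
    profile <- cmp$apex[[i]] * exp(-(rt1 - cmp$rt[[i]])^2 / (2 * cmp$sigma[[i]]^2))
    trigger <- which(profile >= params$dda_threshold)
    trigger <- trigger[seq_along(trigger) %% params$dda_period == 1L]
    frags <- truth_frags[[i]]
    if (!length(trigger) || !length(frags)) next
    frag_mass <- vapply(frags, monoisotopic_mass, numeric(1))
    prec_counts <- parse_formula(cmp$ion_formula[[i]])
    prec_mass <- monoisotopic_mass(prec_counts)
    w <- fragment_weights(frag_mass, prec_mass, ce)
    for (t in trigger) {
      rt2 <- rt1[[t]] + shift + params$scan_interval / 2
      base_int <- 0.5 * profile[[t]]
      ints <- round(base_int * w / max(w) * stats::runif(length(w), 0.85, 1))
      mzs <- obs_mz((frag_mass - charge * .electron_mass) / 1)
      pk <- cbind(c(mzs, obs_mz(cmp$ion_mz[[i]])),
                  c(ints, round(base_int * 0.3)))
      pk <- pk[pk[, 2] >= 1, , drop = FALSE]
      pk <- pk[order(pk[, 1]), , drop = FALSE]
      if (!nrow(pk)) next
      ms2[[length(ms2) + 1L]] <- list(rt = rt2,
                                      precursor = obs_mz(cmp$ion_mz[[i]]),
                                      peaks = pk)
    }
  }

  scans1 <- tibble(
    rt = rt1, ms_level = 1L,
    precursor_mz = NA_real_, iso_width = NA_real_, ce = NA_real_,
    peaks = lapply(ms1_peaks, function(p) {
      if (is.null(p)) p <- matrix(numeric(), ncol = 2)
      colnames(p) <- c("mz", "intensity")
      p[order(p[, 1]), , drop = FALSE]
    })
  )
  scans2 <- if (length(ms2)) {
    tibble(
      rt = vapply(ms2, `[[`, numeric(1), "rt"),
      ms_level = 2L,
      precursor_mz = vapply(ms2, `[[`, numeric(1), "precursor"),
      iso_width = params$iso_width, ce = as.numeric(ce),
      peaks = lapply(ms2, function(s) {
        p <- s$peaks; colnames(p) <- c("mz", "intensity"); p
      })
    )
  } else NULL
  scans <- bind_rows(scans1, scans2) |> arrange(.data$rt)
  # drop empty MS1 scans' all-empty peak matrices? keep (valid empty scans)
  scans$polarity <- mode
  scans$scan <- seq_len(nrow(scans))
  run <- ms_run(scans, mix = mix, mode = mode, ce_tag = as.numeric(ce))

  truth <- cmp |>
    mutate(detectable = .data$violation %in% c("none", "snr"),
           fragments = purrr::map(truth_frags, names)) |>
    select("id", "mix", "detectable", "rt", "apex", "sigma", "violation",
           "ion_mz", "ion_formula", "fragments")
  out <- list(run = run, truth = truth)
  if (!is.null(path)) {
    write_run(run, path)
    out$path <- path
  }
  out
}

#' Simulate and write all runs of a design
#'
#' File names follow `"<mix>_<pos|neg>_ce<CE>.mzML"`.
#'
#' @param design `sim_design`.
#' @param dir Output directory.
#' @param modes Ionization modes to emit.
#' @param ce_levels Collision energies (default from `params`).
#' @param params [sim_params()].
#' @return Tibble: mix, mode, ce, path; attribute `truth` binds all
#'   per-run ground truth.
#' @export
simulate_design <- function(design, dir, modes = "+", ce_levels = NULL,
                            params = sim_params()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ce_levels <- ce_levels %||% params$ce_levels
  grid <- tidyr::expand_grid(mix = unique(design$design$mix),
                             mode = modes, ce = ce_levels)
  truth <- list()
  grid$path <- purrr::pmap_chr(grid, function(mix, mode, ce) {
    tag <- if (mode == "+") "pos" else "neg"
    p <- file.path(dir, sprintf("%s_%s_ce%02d.mzML", mix, tag, as.integer(ce)))
    sim <- simulate_run(design, mix, mode, ce, params, path = p)
    truth[[length(truth) + 1L]] <<- sim$truth |> mutate(mode = mode, ce = as.numeric(ce))
    p
  })
  structure(grid, truth = purrr::list_rbind(truth))
}

#' Two-mix worked isobar fixture
#'
#' Reproduces the cross-mix disambiguation example: mix "503" contains only
#' 2,2-dimethyl-2,3-dihydro-1-benzofuran-7-amine eluting at 12.3 min; mix
#' "508" contains both that amine and N-(2,4-dimethylphenyl)acetamide (same
#' formula, C10H13NO) with peaks at 12.3 and 14.4 min at ion m/z 164.1070.
#'
#' @param dir Optional directory; when given, mzML files and design CSVs are
#'   written there.
#' @param ce Collision energy of the simulated runs.
#' @param params [sim_params()] (seed honoured).
#' @return List: `design` (`sim_design`), and with `dir` also `files`
#'   (simulation table) and `inputs` (design CSV paths).
#' @export
fig4_scenario <- function(dir = NULL, ce = 45, params = sim_params()) {
  compounds <- tibble(
    id = c("ENT-AMINE", "ENT-ACETAMIDE"),
    name = c("2,2-dimethyl-2,3-dihydro-1-benzofuran-7-amine",
             "N-(2,4-dimethylphenyl)acetamide"),
    smiles = c("CC1(C)Cc2cccc(N)c2O1", "CC(=O)Nc1ccc(C)cc1C"),
    formula = "C10H13NO",
    mass = monoisotopic_mass(parse_formula("C10H13NO")),
    rt = c(12.3, 14.4),
    apex = c(2e6, 3e6),
    sigma = 0.05,
    violation = "none"
  )
  design <- structure(list(
    compounds = compounds,
    design = tibble(id = c("ENT-AMINE", "ENT-AMINE", "ENT-ACETAMIDE"),
                    mix = c("503", "508", "508")),
    isobar_pairs = tibble(pair = 1L, id_a = "ENT-AMINE",
                          id_b = "ENT-ACETAMIDE", anchored = TRUE),
    seed = params$seed
  ), class = "sim_design")
  out <- list(design = design)
  if (!is.null(dir)) {
    out$files <- simulate_design(design, dir, modes = "+", ce_levels = ce,
                                 params = params)
    out$inputs <- write_design(design, dir)
  }
  out
}
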