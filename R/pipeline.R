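# End-to-end orchestration: prescreen -> annotate/recalibrate -> isobar
# resolution -> record build -> validation/summary -> deposition, with all
# stage artifacts written to disk and a manifest of what was produced.

#' Pipeline configuration
#'
#' @param mzml_dir Directory of input mzML files named
#'   `"<mix>_<pos|neg>_ce<CE>.mzML"`.
#' @param compounds_csv,setid_csv,settings_ini Input paths.
#' @param out_dir Output directory (created).
#' @param thresholds [qc_thresholds()].
#' @param pre_tol_ppm,post_tol_ppm Annotation tolerance before and after
#'   recalibration.
#' @param rt_tol RT anchoring tolerance for isobar resolution (minutes).
#' @param badlist_csv Optional CSV (column `smiles`) excluded from
#'   deposition.
#' @param min_base_peak Base-peak intensity floor for records.
#' @param date Record date stamp (injectable for reproducible artifacts).
#' @param seed Seed for any stochastic step.
#' @return Config list (class `pipeline_config`).
#' @export
pipeline_config <- function(mzml_dir, compounds_csv, setid_csv, settings_ini,
                            out_dir, thresholds = qc_thresholds(),
                            pre_tol_ppm = 10, post_tol_ppm = 2.5,
                            rt_tol = 0.5, badlist_csv = NULL,
                            min_base_peak = 1e5, date = "2023.01.01",
                            seed = 1L) {
  cfg <- as.list(environment())
  for (p in c("mzml_dir", "compounds_csv", "setid_csv", "settings_ini")) {
    if (!file.exists(cfg[[p]])) {
      abort(paste0("config path does not exist: ", p, " = ", cfg[[p]]),
            class = "mixlib_config_error")
    }
  }
  if (!is.null(cfg$badlist_csv) && !file.exists(cfg$badlist_csv)) {
    abort("badlist_csv does not exist", class = "mixlib_config_error")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `thresholds` may
#' be a nested map of [qc_thresholds()] arguments.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$thresholds)) y$thresholds <- do.call(qc_thresholds, y$thresholds)
  do.call(pipeline_config, y)
}

parse_run_filename <- function(path) {
  b <- sub("\\.mzML$", "", basename(path))
  parts <- strsplit(b, "_", fixed = TRUE)[[1]]
  if (length(parts) != 3 || !grepl("^ce[0-9]+$", parts[[3]])) return(NULL)
  list(mix = parts[[1]], mode = if (parts[[2]] == "pos") "+" else "-",
       ce = as.numeric(sub("^ce", "", parts[[3]])))
}

#' Run the full library-generation pipeline
#'
#' Executes every stage and writes its artifacts under `out_dir`:
#' `prescreen.csv`, `assignments.csv`, `exclusions.csv`, one MassBank
#' record per retained spectrum under `records/`, `validation.csv`,
#' `record_summary.csv`, and the deposition tables under `deposition/`.
#' A failure for one compound is logged and skipped, never fatal.
#'
#' @param config [pipeline_config()].
#' @return Manifest tibble (`stage`, `artifact`, `path`, `n`), with the
#'   per-stage tables attached as attribute `results`.
#' @export
run_pipeline <- function(config) {
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rec_dir <- file.path(config$out_dir, "records")
  dir.create(rec_dir, showWarnings = FALSE)

  compounds <- read_compound_list(config$compounds_csv)
  design <- read_setid(config$setid_csv, compounds)
  settings <- read_settings(config$settings_ini)

  files <- sort(list.files(config$mzml_dir, pattern = "\\.mzML$", full.names = TRUE))
  meta <- purrr::map(files, parse_run_filename)
  keep <- !vapply(meta, is.null, logical(1))
  files <- files[keep]; meta <- meta[keep]
  if (!length(files)) abort("no parseable mzML files found", class = "mixlib_config_error")

  manifest <- list()
  note <- function(stage, artifact, path, n) {
    manifest[[length(manifest) + 1L]] <<- tibble(stage = stage, artifact = artifact,
                                                 path = path, n = n)
  }
  exclusions <- list()
  exclude <- function(stage, id, mix, reason) {
    exclusions[[length(exclusions) + 1L]] <<- tibble(stage = stage, id = id,
                                                     mix = mix, reason = reason)
  }

  # stage 1: prescreen every run
  runs <- purrr::map2(files, meta, function(f, m) {
    read_run(f, mix = m$mix, mode = m$mode, ce_tag = m$ce)
  })
  qc <- prescreen(runs, compounds, design, thresholds = config$thresholds)
  qc_path <- file.path(config$out_dir, "prescreen.csv")
  prescreen_table(qc, qc_path)
  note("prescreen", "qc_table", qc_path, nrow(qc))
  for (i in which(qc$verdict == "fail")) {
    exclude("prescreen", qc$id[[i]], qc$mix[[i]],
            paste0("qc:", paste(qc$failed[[i]], collapse = "+")))
  }
  qc_pass <- qc[qc$verdict == "pass", , drop = FALSE]

  # stage 2: isobar grouping and cross-mix resolution (per mode)
  assignments <- purrr::map(unique(qc_pass$polarity), function(pol) {
    add <- if (pol == "+") "[M+H]+" else "[M-H]-"
    det <- qc_pass[qc_pass$polarity == pol, , drop = FALSE] |>
      distinct(.data$id, .data$mix, .keep_all = TRUE)
    grp <- group_isobars(design |> dplyr::semi_join(det, by = c("id", "mix")),
                         compounds, adduct = add)
    if (!nrow(grp)) return(NULL)
    resolve_isobars(grp, det, rt_tol = config$rt_tol) |>
      mutate(polarity = pol)
  }) |> purrr::list_rbind()
  if (is.null(assignments) || !ncol(assignments)) {
    assignments <- tibble(id = character(), mix = character(), rt = numeric(),
                          intensity = numeric(), level = character(),
                          rationale = character(), polarity = character())
  }
  asg_path <- file.path(config$out_dir, "assignments.csv")
  readr::write_csv(assignments, asg_path, progress = FALSE)
  note("isobar", "assignments", asg_path, nrow(assignments))
  for (i in which(assignments$level != "1")) {
    exclude("isobar", assignments$id[[i]], assignments$mix[[i]],
            paste0("level", assignments$level[[i]], ":", assignments$rationale[[i]]))
  }

  # stage 3: per passing compound x run, annotate, recalibrate, clean, build
  level1 <- assignments[assignments$level == "1", , drop = FALSE]
  records <- list()
  serial <- 0L
  qc_keep <- qc_pass |>
    inner_join(level1[, c("id", "mix", "polarity", "rt")] |>
                 dplyr::rename(rt_assigned = "rt"),
               by = c("id", "mix", "polarity")) |>
    arrange(.data$id, .data$mix, .data$polarity, .data$ce)
  run_index <- purrr::map_chr(runs, function(r) {
    s <- run_source(r); paste(s$mix, s$mode, s$ce_tag)
  })
  for (i in seq_len(nrow(qc_keep))) {
    row <- qc_keep[i, ]
    run <- runs[[match(paste(row$mix, row$polarity, row$ce), run_index)]]
    entry <- compounds[compounds$id == row$id, ]
    add <- if (row$polarity == "+") "[M+H]+" else "[M-H]-"
    result <- tryCatch({
      scan_ids <- row$ms2_scans[[1]]
      if (!length(scan_ids)) stop("no matched MS2 scan")
      scan <- run[run$scan == scan_ids[[1]], ]
      ann <- annotate_spectrum(scan, entry, adduct = add,
                               tol_ppm = config$pre_tol_ppm)
      pairs <- recalibration_pairs(list(ann))
      spectrum <- if (nrow(pairs) >= 2) {
        model <- fit_recalibration(pairs)
        scan2 <- apply_recalibration(scan, model)
        ann2 <- annotate_spectrum(scan2, entry, adduct = add,
                                  tol_ppm = config$post_tol_ppm)
        clean_spectrum(ann2, precursor = list(precursor_mz = scan2$precursor_mz[[1]],
                                              ce = row$ce, polarity = row$polarity))
      } else {
        clean_spectrum(ann, precursor = list(precursor_mz = scan$precursor_mz[[1]],
                                             ce = row$ce, polarity = row$polarity))
      }
      rec <- build_record(entry, spectrum,
                          assignment = tibble(level = "1", rt = row$rt_assigned),
                          settings = settings, serial = serial + 1L,
                          adduct = add, ce = row$ce, date = config$date,
                          min_base_peak = config$min_base_peak)
      serial <- serial + 1L
      rec
    }, error = function(e) e)
    if (inherits(result, "error")) {
      exclude("records", row$id, row$mix, conditionMessage(result))
    } else {
      acc <- mb_field(result, "ACCESSION")
      write_record(result, file.path(rec_dir, paste0(acc, ".txt")))
      records[[length(records) + 1L]] <- result
    }
  }
  note("records", "record_files", rec_dir, length(records))

  # stage 4: validation and summary
  validation <- purrr::map(records, validate_record) |> purrr::list_rbind()
  if (is.null(validation)) {
    validation <- tibble(accession = character(), rule = character(),
                         message = character())
  }
  val_path <- file.path(config$out_dir, "validation.csv")
  readr::write_csv(validation, val_path, progress = FALSE)
  note("validate", "violations", val_path, nrow(validation))
  sum_path <- file.path(config$out_dir, "record_summary.csv")
  summary <- summarize_records(rec_dir,
    fields = c("ACCESSION", "CH$NAME", "CH$FORMULA", "CH$EXACT_MASS",
               "AC$MASS_SPECTROMETRY: COLLISION_ENERGY",
               "AC$CHROMATOGRAPHY: RETENTION_TIME", "PK$SPLASH"),
    path = sum_path)
  note("validate", "record_summary", sum_path, nrow(summary))

  # stage 5: deposition
  badlist <- if (!is.null(config$badlist_csv)) {
    readr::read_csv(config$badlist_csv, show_col_types = FALSE, progress = FALSE)$smiles
  } else character()
  rows <- purrr::map(records, extract_fields) |> purrr::list_rbind()
  if (is.null(rows) || !nrow(rows)) {
    rows <- extract_fields(mb_record(tibble(key = character(), value = character()),
                                     tibble(mz = numeric(), intensity = numeric(),
                                            rel_intensity = integer())))[0, ]
  }
  substance <- build_substance_table(rows, badlist)
  annotation <- build_annotation_table(rows)
  dep_paths <- write_deposition(substance, annotation,
                                file.path(config$out_dir, "deposition"))
  note("deposition", "substance_table", dep_paths[["substance"]], nrow(substance))
  note("deposition", "annotations", dep_paths[["annotations"]],
       nrow(annotation$annotations))

  excl <- if (length(exclusions)) purrr::list_rbind(exclusions) else {
    tibble(stage = character(), id = character(), mix = character(),
           reason = character())
  }
  excl_path <- file.path(config$out_dir, "exclusions.csv")
  readr::write_csv(excl, excl_path, progress = FALSE)
  note("log", "exclusions", excl_path, nrow(excl))

  out <- purrr::list_rbind(manifest)
  structure(out, results = list(qc = qc, assignments = assignments,
                                records = records, validation = validation,
                                substance = substance, exclusions = excl))
}
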