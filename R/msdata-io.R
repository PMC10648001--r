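# Reading and writing the pipeline's inputs: mzML runs (via mzR), compound
# lists and setID maps (CSV), and acquisition settings (INI).

#' Construct a run object from per-scan data
#'
#' A run is a tibble with one row per scan, ordered by retention time:
#' columns `scan`, `ms_level`, `rt` (minutes), `polarity` (`"+"`/`"-"`),
#' `precursor_mz`, `iso_width` (Da), `ce` (NCE), and `peaks` (list of
#' two-column `mz`/`intensity` matrices sorted by m/z).
#'
#' @param scans Tibble with the columns above.
#' @param mix,mode,ce_tag Source tags (mix name, ionization mode, collision
#'   energy of the file).
#' @return `ms_run` tibble.
#' @export
ms_run <- function(scans, mix = NA_character_, mode = NA_character_, ce_tag = NA_real_) {
  stopifnot(all(c("ms_level", "rt", "polarity", "peaks") %in% names(scans)))
  if (is.unsorted(scans$rt)) {
    abort("scan retention times must be non-decreasing", class = "mixlib_io_error")
  }
  if (length(unique(scans$polarity)) > 1) {
    abort("run must have homogeneous polarity", class = "mixlib_io_error")
  }
  if (any(scans$ms_level == 2 & is.na(scans$precursor_mz))) {
    abort("MS2 scan without precursor m/z", class = "mixlib_io_error")
  }
  scans$peaks <- lapply(scans$peaks, function(p) {
    p <- as.matrix(p)
    colnames(p) <- c("mz", "intensity")
    if (nrow(p) > 1 && is.unsorted(p[, "mz"])) p <- p[order(p[, "mz"]), , drop = FALSE]
    p
  })
  structure(as_tibble(scans), class = c("ms_run", class(as_tibble(scans))),
            mix = mix, mode = mode, ce_tag = ce_tag)
}

run_source <- function(run) {
  list(mix = attr(run, "mix"), mode = attr(run, "mode"), ce_tag = attr(run, "ce_tag"))
}

#' Read a centroided mzML run
#'
#' Parses an mzML file into an [ms_run()] tibble. Retention times are
#' normalised to minutes. Profile-mode spectra are rejected; MS2 scans must
#' carry precursor metadata. When the isolation window is absent the default
#' 1 Da total width is assumed.
#'
#' @param path mzML file.
#' @param mix,mode,ce_tag Optional source tags attached to the run.
#' @param default_iso_width Isolation window width (Da) used when the file
#'   does not record one.
#' @return `ms_run` tibble.
#' @export
read_run <- function(path, mix = NA_character_, mode = NA_character_,
                     ce_tag = NA_real_, default_iso_width = 1) {
  if (!file.exists(path)) abort(paste0("no such file: ", path), class = "mixlib_io_error")
  fh <- tryCatch(mzR::openMSfile(path), error = function(e) {
    abort(paste0("cannot open mzML file: ", path, " (", conditionMessage(e), ")"),
          class = "mixlib_io_error")
  })
  on.exit(mzR::close(fh), add = TRUE)
  hdr <- mzR::header(fh)
  if (!nrow(hdr)) abort(paste0("empty mzML file: ", path), class = "mixlib_io_error")
  if (any(!is.na(hdr$centroided) & !hdr$centroided)) {
    abort("profile-mode spectra found: centroid required", class = "mixlib_io_error")
  }
  if (any(hdr$msLevel == 2 & (is.na(hdr$precursorMZ) | hdr$precursorMZ <= 0))) {
    abort("MS2 scan without precursor m/z", class = "mixlib_io_error")
  }
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  iso <- hdr$isolationWindowLowerOffset + hdr$isolationWindowUpperOffset
  scans <- tibble(
    scan = hdr$seqNum,
    ms_level = as.integer(hdr$msLevel),
    rt = hdr$retentionTime / 60,
    polarity = ifelse(hdr$polarity > 0, "+", "-"),
    precursor_mz = ifelse(hdr$msLevel == 2, hdr$precursorMZ, NA_real_),
    iso_width = ifelse(hdr$msLevel == 2,
                       ifelse(is.na(iso) | iso <= 0, default_iso_width, iso),
                       NA_real_),
    ce = ifelse(hdr$msLevel == 2, hdr$collisionEnergy, NA_real_),
    peaks = pk
  )
  ms_run(scans, mix = mix, mode = mode, ce_tag = ce_tag)
}

#' Write a run to mzML
#'
#' Inverse of [read_run()]: serialises an `ms_run` through mzR so that
#' reading the file back reproduces the run field-for-field.
#'
#' @param run `ms_run` object.
#' @param path Output mzML path.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  n <- nrow(run)
  stopifnot(n > 0)
  counts <- vapply(run$peaks, nrow, integer(1))
  tic <- vapply(run$peaks, function(p) sum(p[, "intensity"]), numeric(1))
  bp <- lapply(run$peaks, function(p) {
    if (!nrow(p)) return(c(0, 0))
    p[which.max(p[, "intensity"]), ]
  })
  is2 <- run$ms_level == 2L
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = as.integer(run$ms_level),
    polarity = ifelse(run$polarity == "+", 1L, 0L),
    peaksCount = counts, totIonCurrent = tic,
    retentionTime = run$rt * 60,
    basePeakMZ = vapply(bp, `[`, numeric(1), 1),
    basePeakIntensity = vapply(bp, `[`, numeric(1), 2),
    collisionEnergy = ifelse(is2, run$ce, NA_real_),
    ionisationEnergy = 0,
    lowMZ = vapply(run$peaks, function(p) if (nrow(p)) min(p[, "mz"]) else 0, numeric(1)),
    highMZ = vapply(run$peaks, function(p) if (nrow(p)) max(p[, "mz"]) else 0, numeric(1)),
    precursorScanNum = NA_integer_,
    precursorMZ = ifelse(is2, run$precursor_mz, NA_real_),
    precursorCharge = ifelse(is2, ifelse(run$polarity == "+", 1L, -1L), NA_integer_),
    precursorIntensity = ifelse(is2, 0, NA_real_),
    mergedScan = NA_integer_, mergedResultScanNum = NA_integer_,
    mergedResultStartScanNum = NA_integer_, mergedResultEndScanNum = NA_integer_,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ifelse(is2, run$precursor_mz, NA_real_),
    isolationWindowLowerOffset = ifelse(is2, run$iso_width / 2, NA_real_),
    isolationWindowUpperOffset = ifelse(is2, run$iso_width / 2, NA_real_),
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_
  )
  pks <- lapply(run$peaks, function(p) {
    m <- unname(as.matrix(p))
    storage.mode(m) <- "double"
    m
  })
  mzR::writeMSData(pks, path, header = hdr)
  invisible(path)
}

# ---- tabular inputs ----------------------------------------------------

default_aliases <- function() {
  list(
    identifier = c("identifier", "id", "ID", "Identifier"),
    name = c("name", "Name", "compound_name"),
    smiles = c("smiles", "SMILES", "ms_ready_smiles", "SMILES_MS_Ready"),
    mix = c("mix", "set", "Set", "mix_name")
  )
}

pick_column <- function(df, aliases, what, path) {
  hit <- intersect(aliases, names(df))
  if (!length(hit)) {
    abort(paste0("no ", what, " column in ", path,
                 " (expected one of: ", paste(aliases, collapse = ", "), ")"),
          class = "mixlib_io_error")
  }
  hit[[1]]
}

#' Read a compound list CSV
#'
#' Expects identifier, name and (MS-ready) SMILES columns; header names are
#' matched against configurable aliases. The molecular formula and neutral
#' monoisotopic mass are derived from the SMILES. Rows whose SMILES cannot be
#' parsed are skipped with a warning; duplicate identifiers are an error.
#'
#' @param path CSV file.
#' @param aliases Named list of column-name aliases (see `default_aliases`).
#' @return Tibble: `id`, `name`, `smiles`, `formula`, `mass`.
#' @export
read_compound_list <- function(path, aliases = default_aliases()) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  idc <- pick_column(df, aliases$identifier, "identifier", path)
  nmc <- pick_column(df, aliases$name, "name", path)
  smc <- pick_column(df, aliases$smiles, "SMILES", path)
  out <- tibble(id = as.character(df[[idc]]), name = as.character(df[[nmc]]),
                smiles = as.character(df[[smc]]))
  dup <- unique(out$id[duplicated(out$id)])
  if (length(dup)) {
    abort(paste0("duplicate compound identifier(s): ", paste(dup, collapse = ", ")),
          class = "mixlib_io_error")
  }
  out$formula <- smiles_formula(out$smiles)
  bad <- is.na(out$formula)
  if (any(bad)) {
    warn(paste0("skipping ", sum(bad), " row(s) with unparseable SMILES: ",
                paste(out$id[bad], collapse = ", ")))
    out <- out[!bad, , drop = FALSE]
  }
  out$mass <- vapply(out$formula, function(f) monoisotopic_mass(parse_formula(f)),
                     numeric(1), USE.NAMES = FALSE)
  out
}

#' Read a setID CSV mapping compounds to mixes
#'
#' @param path CSV with identifier and set (mix name) columns.
#' @param compounds Compound tibble from [read_compound_list()]; every
#'   referenced identifier must exist there.
#' @param aliases Column-name aliases.
#' @return Tibble `id`, `mix` (a mix design).
#' @export
read_setid <- function(path, compounds = NULL, aliases = default_aliases()) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!nrow(df)) {
    warn(paste0("empty setID file: ", path))
    return(tibble(id = character(), mix = character()))
  }
  idc <- pick_column(df, aliases$identifier, "identifier", path)
  mxc <- pick_column(df, aliases$mix, "mix", path)
  out <- tibble(id = as.character(df[[idc]]), mix = as.character(df[[mxc]]))
  if (!is.null(compounds)) {
    dangling <- setdiff(out$id, compounds$id)
    if (length(dangling)) {
      abort(paste0("setID references unknown identifier(s): ",
                   paste(dangling, collapse = ", ")),
            class = "mixlib_io_error")
    }
  }
  out
}

.allowed_licenses <- c("CC0", "CC BY", "CC BY-SA", "CC BY-NC", "CC BY-NC-SA")

#' Read an acquisition settings INI file
#'
#' Sections are flattened; mandatory keys are `authors`, `license`,
#' `instrument`, `instrument_type`, `ionization`, `contributor` and
#' `accession_prefix`. The license must come from the allowed Creative
#' Commons set.
#'
#' @param path INI file.
#' @return Named list of settings (class `mb_settings`).
#' @export
read_settings <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path), class = "mixlib_io_error")
  raw <- ini::read.ini(path)
  settings <- purrr::list_flatten(raw, name_spec = "{inner}")
  required <- c("authors", "license", "instrument", "instrument_type",
                "ionization", "contributor", "accession_prefix")
  missing <- setdiff(required, names(settings))
  if (length(missing)) {
    abort(paste0("settings file missing mandatory key(s): ",
                 paste(missing, collapse = ", ")),
          class = "mixlib_io_error")
  }
  if (!nzchar(settings$contributor)) {
    abort("contributor code must be non-empty", class = "mixlib_io_error")
  }
  if (!settings$license %in% .allowed_licenses) {
    abort(paste0("license must be one of: ", paste(.allowed_licenses, collapse = ", ")),
          class = "mixlib_io_error")
  }
  structure(settings, class = "mb_settings")
}
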