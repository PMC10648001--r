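# MassBank-format record assembly, text serialization, parsing, validation
# and summarisation.
#
# A record is represented as an ordered key/value table (`fields`, repeated
# keys allowed, unknown keys preserved) plus a peak table. Serialisation is
# canonical -- m/z to 4 decimals, intensities as integer counts, relative
# intensities 1..999 -- so write/parse round-trips are bit-exact.

.mb_format_version <- "2.6"

.mandatory_fields <- c("ACCESSION", "RECORD_TITLE", "DATE", "AUTHORS",
                       "LICENSE", "CH$NAME", "CH$FORMULA", "CH$EXACT_MASS",
                       "CH$SMILES", "AC$INSTRUMENT", "AC$INSTRUMENT_TYPE")

#' Relative intensities for a MassBank peak block
#'
#' `rel = round(999 * I / max(I))`, floored at 1 so every reported peak is
#' visible on the 1..999 scale.
#'
#' @param peaks Matrix/data frame with m/z and intensity columns (>= 1 row).
#' @return Tibble `mz`, `intensity`, `rel_intensity`.
#' @export
relative_intensities <- function(peaks) {
  peaks <- as.matrix(peaks)[, 1:2, drop = FALSE]
  if (!nrow(peaks)) abort("empty peak list", class = "mixlib_record_error")
  rel <- pmax(1, round(999 * peaks[, 2] / max(peaks[, 2])))
  tibble(mz = as.numeric(peaks[, 1]), intensity = as.numeric(peaks[, 2]),
         rel_intensity = as.integer(rel))
}

mb_record <- function(fields, peaks) {
  structure(list(fields = fields, peaks = peaks), class = "massbank_record")
}

#' @export
print.massbank_record <- function(x, ...) {
  cat("<massbank_record>", mb_field(x, "ACCESSION"), "with",
      nrow(x$peaks), "peaks\n")
  invisible(x)
}

#' Get field value(s) from a record
#'
#' @param record `massbank_record`.
#' @param key Field key, e.g. `"CH$FORMULA"`.
#' @param subtag Optional subtag for repeated iterating fields, e.g.
#'   `mb_field(r, "AC$MASS_SPECTROMETRY", "MS_TYPE")`.
#' @return Character vector of values (length 0 when absent); with a subtag,
#'   the value after the subtag word.
#' @export
mb_field <- function(record, key, subtag = NULL) {
  v <- record$fields$value[record$fields$key == key]
  if (is.null(subtag)) return(v)
  hit <- startsWith(v, paste0(subtag, " "))
  sub(paste0("^", gsub("([$\\\\])", "\\\\\\1", subtag), " "), "", v[hit])
}

#' Build the accession string
#' @param contributor Contributor code (e.g. `"LCSB"`).
#' @param serial Full record code (e.g. `"LU109201"`) or an integer serial,
#'   which is prefixed and zero-padded to 6 digits.
#' @param prefix Accession prefix used with integer serials (e.g. `"LU"`).
#' @return Accession such as `"MSBNK-LCSB-LU109201"`.
#' @export
mb_accession <- function(contributor, serial, prefix = "") {
  code <- if (is.numeric(serial)) sprintf("%s%06d", prefix, serial) else as.character(serial)
  paste0("MSBNK-", contributor, "-", code)
}

#' Assemble a MassBank record
#'
#' Builds a complete record for one compound x collision energy x mode from
#' a cleaned spectrum and a level-1 isobar assignment. Spectra whose base
#' peak is below `min_base_peak` are rejected with a classed error
#' (`mixlib_basepeak_error`), implementing the base-peak-intensity filter.
#'
#' @param entry One-row compound tibble (`id`, `name`, `smiles`, `formula`,
#'   `mass`; optional `inchi`, `inchikey` from an offline infolist).
#' @param spectrum [clean_spectrum()] (non-empty).
#' @param assignment One-row assignment (needs `rt`, level `"1"`).
#' @param settings [read_settings()] list.
#' @param serial Record serial (integer or full code, see [mb_accession()]).
#' @param adduct Precursor adduct.
#' @param ce Collision energy (NCE).
#' @param date Record date string (injectable for reproducible output).
#' @param min_base_peak Base-peak intensity threshold (counts).
#' @return `massbank_record`.
#' @export
build_record <- function(entry, spectrum, assignment, settings, serial,
                         adduct = "[M+H]+", ce = NA_real_,
                         date = format(Sys.Date(), "%Y.%m.%d"),
                         min_base_peak = 1e5) {
  if (is.character(adduct)) adduct <- adduct(adduct)
  if (!nrow(spectrum)) abort("empty spectrum", class = "mixlib_record_error")
  base_peak <- max(spectrum$intensity)
  if (base_peak < min_base_peak) {
    abort(sprintf("base peak intensity %.3g below threshold %.3g",
                  base_peak, min_base_peak),
          class = "mixlib_basepeak_error")
  }
  if (is.na(entry$smiles) || !nzchar(entry$smiles)) {
    abort("missing structure (SMILES)", class = "mixlib_record_error")
  }
  if (!is.null(assignment) && !identical(assignment$level, "1")) {
    abort("record generation requires a level-1 assignment",
          class = "mixlib_record_error")
  }
  ion_mode <- if (adduct$charge > 0) "POSITIVE" else "NEGATIVE"
  precursor_mz <- adduct_mz(entry$mass, adduct)
  rt <- if (!is.null(assignment)) assignment$rt else NA_real_
  inchi <- entry[["inchi"]]
  if (is.null(inchi) || is.na(inchi)) inchi <- smiles_inchi(entry$smiles)
  inchikey <- entry[["inchikey"]]
  if (is.null(inchikey) || is.na(inchikey)) inchikey <- smiles_inchikey(entry$smiles)
  accession <- mb_accession(settings$contributor, serial,
                            prefix = settings$accession_prefix)
  instrument_type <- settings$instrument_type
  title <- paste(entry$name, instrument_type, "MS2",
                 sprintf("CE: %s", format_num(ce)), adduct$name, sep = "; ")

  fields <- tibble(key = character(), value = character())
  add <- function(key, value) {
    value <- as.character(value)
    value <- value[!is.na(value) & nzchar(value)]
    if (length(value)) {
      fields <<- bind_rows(fields, tibble(key = key, value = value))
    }
  }
  add("ACCESSION", accession)
  add("RECORD_TITLE", title)
  add("DATE", date)
  add("AUTHORS", settings$authors)
  add("LICENSE", settings$license)
  add("PUBLICATION", settings$publication %||% NA)
  add("COMMENT",
      paste0("Record generated by mixlib; MassBank record format ",
             .mb_format_version))
  add("CH$NAME", entry$name)
  add("CH$COMPOUND_CLASS", entry[["compound_class"]] %||% "N/A")
  add("CH$FORMULA", entry$formula)
  add("CH$EXACT_MASS", format_num(entry$mass, 4))
  add("CH$SMILES", entry$smiles)
  add("CH$IUPAC", inchi)
  add("CH$LINK", paste("INCHIKEY", inchikey))
  add("AC$INSTRUMENT", settings$instrument)
  add("AC$INSTRUMENT_TYPE", instrument_type)
  add("AC$MASS_SPECTROMETRY", paste("MS_TYPE", "MS2"))
  add("AC$MASS_SPECTROMETRY", paste("ION_MODE", ion_mode))
  add("AC$MASS_SPECTROMETRY", paste("IONIZATION", settings$ionization))
  add("AC$MASS_SPECTROMETRY",
      paste("FRAGMENTATION_MODE", settings$fragmentation_mode %||% "HCD"))
  if (!is.na(ce)) {
    add("AC$MASS_SPECTROMETRY",
        paste("COLLISION_ENERGY", format_num(ce), "% (nominal)"))
  }
  add("AC$CHROMATOGRAPHY",
      if (!is.null(settings$column_name)) paste("COLUMN_NAME", settings$column_name))
  add("AC$CHROMATOGRAPHY",
      if (!is.null(settings$solvent_a)) paste("SOLVENT A", settings$solvent_a))
  add("AC$CHROMATOGRAPHY",
      if (!is.null(settings$solvent_b)) paste("SOLVENT B", settings$solvent_b))
  if (!is.na(rt)) {
    add("AC$CHROMATOGRAPHY", paste("RETENTION_TIME", format_num(rt, 3), "min"))
  }
  add("MS$FOCUSED_ION", paste("BASE_PEAK", format_num(base_peak)))
  add("MS$FOCUSED_ION", paste("PRECURSOR_M/Z", format_num(precursor_mz, 4)))
  add("MS$FOCUSED_ION", paste("PRECURSOR_TYPE", adduct$name))

  peaks <- relative_intensities(spectrum[, c("mz", "intensity")])
  # canonical numeric formatting so serialization round-trips bit-exact
  peaks$mz <- round(peaks$mz, 4)
  peaks$intensity <- round(peaks$intensity)
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  add("PK$SPLASH", compute_splash(cbind(peaks$mz, peaks$intensity)))
  add("PK$NUM_PEAK", nrow(peaks))
  mb_record(fields, peaks)
}

format_num <- function(x, digits = NULL) {
  if (is.null(x) || all(is.na(x))) return(NA_character_)
  if (is.null(digits)) {
    # integer-like values without decimals, otherwise up to 6 significant
    if (isTRUE(all.equal(x, round(x)))) sprintf("%d", as.integer(round(x)))
    else format(x, trim = TRUE)
  } else {
    sprintf(paste0("%.", digits, "f"), x)
  }
}

#' Serialise a record to MassBank text format
#'
#' @param record `massbank_record`.
#' @param path Output file; when `NULL` the lines are returned.
#' @return Character lines (invisibly when written to `path`).
#' @export
write_record <- function(record, path = NULL) {
  lines <- c(
    paste0(record$fields$key, ": ", record$fields$value),
    "PK$PEAK: m/z int. rel.int.",
    sprintf("  %.4f %d %d", record$peaks$mz,
            as.integer(round(record$peaks$intensity)),
            as.integer(record$peaks$rel_intensity)),
    "//"
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Parse a MassBank record text file
#'
#' Inverse of [write_record()]: unknown fields are preserved in order.
#'
#' @param path Record file (or a character vector of lines via `lines`).
#' @param lines Record lines; overrides `path`.
#' @return `massbank_record`.
#' @export
parse_record <- function(path = NULL, lines = NULL) {
  if (is.null(lines)) lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || utils::tail(lines, 1) != "//") {
    abort("truncated record: missing '//' terminator", class = "mixlib_record_error")
  }
  lines <- utils::head(lines, -1)
  ipk <- which(startsWith(lines, "PK$PEAK:"))
  if (length(ipk) != 1) {
    abort("record must contain exactly one PK$PEAK block", class = "mixlib_record_error")
  }
  head_lines <- lines[seq_len(ipk - 1)]
  peak_lines <- if (ipk < length(lines)) lines[(ipk + 1):length(lines)] else character()
  m <- regexpr(": ", head_lines, fixed = TRUE)
  if (any(m < 0)) {
    abort("malformed field line in record", class = "mixlib_record_error")
  }
  fields <- tibble(
    key = substr(head_lines, 1, m - 1),
    value = substr(head_lines, m + 2, nchar(head_lines))
  )
  pk <- strsplit(trimws(peak_lines), " +")
  if (any(lengths(pk) != 3)) {
    abort("malformed peak line in record", class = "mixlib_record_error")
  }
  peaks <- tibble(
    mz = as.numeric(vapply(pk, `[`, character(1), 1)),
    intensity = as.numeric(vapply(pk, `[`, character(1), 2)),
    rel_intensity = as.integer(vapply(pk, `[`, character(1), 3))
  )
  mb_record(fields, peaks)
}

#' Validate a MassBank record
#'
#' Pre-submission checks: mandatory fields, peak-count consistency, relative
#' intensity scale (1..999 with max 999), peak ordering, accession format,
#' formula/exact-mass consistency (5 ppm) and SPLASH integrity.
#'
#' @param record `massbank_record`.
#' @return Tibble of violations (`accession`, `rule`, `message`); zero rows
#'   means the record passes.
#' @export
validate_record <- function(record) {
  acc <- mb_field(record, "ACCESSION")
  acc1 <- if (length(acc)) acc[[1]] else NA_character_
  v <- list()
  bad <- function(rule, message) {
    v[[length(v) + 1]] <<- tibble(accession = acc1, rule = rule, message = message)
  }
  missing <- setdiff(.mandatory_fields, unique(record$fields$key))
  for (f in missing) bad("missing_field", paste("missing mandatory field", f))
  if (!length(acc) || !grepl("^MSBNK-[A-Za-z0-9_]+-[A-Za-z0-9_]+$", acc1)) {
    bad("accession_format", paste("malformed accession:", acc1))
  }
  np <- suppressWarnings(as.integer(mb_field(record, "PK$NUM_PEAK")))
  if (!length(np) || is.na(np[[1]])) {
    bad("missing_field", "missing PK$NUM_PEAK")
  } else if (np[[1]] != nrow(record$peaks)) {
    bad("peak_count", sprintf("PK$NUM_PEAK %d but %d peaks", np[[1]], nrow(record$peaks)))
  }
  if (nrow(record$peaks)) {
    if (is.unsorted(record$peaks$mz, strictly = FALSE)) {
      bad("peak_order", "peaks not sorted by m/z")
    }
    rel <- record$peaks$rel_intensity
    if (any(rel < 1 | rel > 999)) bad("rel_intensity", "relative intensity outside 1..999")
    else if (max(rel) != 999) bad("rel_intensity", "maximum relative intensity must be 999")
  } else {
    bad("peak_count", "record has no peaks")
  }
  formula <- mb_field(record, "CH$FORMULA")
  exact <- suppressWarnings(as.numeric(mb_field(record, "CH$EXACT_MASS")))
  if (length(formula) && length(exact) && !is.na(exact[[1]])) {
    m <- tryCatch(monoisotopic_mass(parse_formula(formula[[1]])),
                  error = function(e) NA_real_)
    if (is.na(m)) {
      bad("formula", paste("unparseable CH$FORMULA:", formula[[1]]))
    } else if (abs(ppm_error(exact[[1]], m)) > 5 &&
               abs(exact[[1]] - m) > 5e-4) {
      bad("mass_consistency",
          sprintf("CH$EXACT_MASS %.4f vs formula mass %.4f (> 5 ppm)", exact[[1]], m))
    }
  }
  splash <- mb_field(record, "PK$SPLASH")
  if (length(splash) && nrow(record$peaks)) {
    expected <- compute_splash(cbind(record$peaks$mz, record$peaks$intensity))
    if (splash[[1]] != expected) bad("splash", "SPLASH does not match the peak list")
  }
  if (!length(v)) {
    return(tibble(accession = character(), rule = character(), message = character()))
  }
  purrr::list_rbind(v)
}

#' Summarise MassBank records in a directory
#'
#' Extracts the requested fields from every `.txt` record in `dir` into a
#' table with one row per record; fields may address subtags as
#' `"AC$MASS_SPECTROMETRY: MS_TYPE"`. Multiple values are joined with `"; "`.
#'
#' @param dir Directory of record files.
#' @param fields Character vector of field selectors.
#' @param path Optional CSV output.
#' @return Tibble, one row per record file.
#' @export
summarize_records <- function(dir, fields = c("ACCESSION", "CH$NAME",
                                              "CH$FORMULA", "PK$SPLASH"),
                              path = NULL) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  rows <- purrr::map(files, function(f) {
    rec <- parse_record(f)
    vals <- purrr::map_chr(fields, function(sel) {
      parts <- strsplit(sel, ": ", fixed = TRUE)[[1]]
      v <- if (length(parts) == 2) mb_field(rec, parts[[1]], parts[[2]])
           else mb_field(rec, sel)
      if (length(v)) paste(v, collapse = "; ") else NA_character_
    })
    stats::setNames(as.list(vals), fields) |> as_tibble()
  }) |> purrr::list_rbind()
  if (!nrow(rows)) {
    rows <- as_tibble(stats::setNames(rep(list(character()), length(fields)), fields))
  }
  if (!is.null(path)) readr::write_csv(rows, path, progress = FALSE)
  rows
}
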