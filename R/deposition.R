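# PubChem deposition artifacts: the cleaned substance table and the MS/MS
# annotation table with Top-5 peaks.

.deposition_fields <- c(
  "accession", "authors", "instrument", "instrument_type", "ms_level",
  "ionization_mode", "ionization", "collision_energy", "fragmentation_mode",
  "column_name", "retention_time", "precursor_mz", "precursor_adduct",
  "license", "publication", "splash", "top5_peaks",
  "name", "smiles", "inchi", "inchikey"
)

#' Top-5 peaks of a spectrum for display
#'
#' The five highest-intensity peaks in descending intensity; ties are broken
#' by the lower m/z first.
#'
#' @param peaks Matrix/data frame with m/z and intensity columns.
#' @return Tibble `mz`, `intensity` with at most 5 rows.
#' @export
top5_peaks <- function(peaks) {
  pk <- as.data.frame(as.matrix(peaks[, 1:2]))
  names(pk) <- c("mz", "intensity")
  pk <- pk[order(-pk$intensity, pk$mz), , drop = FALSE]
  as_tibble(utils::head(pk, 5))
}

format_top5 <- function(top5) {
  paste(sprintf("%.4f:%d", top5$mz, as.integer(round(top5$intensity))),
        collapse = " ")
}

#' Flatten a MassBank record into a deposition row
#'
#' Projects a record onto the agreed PubChem display field list. Missing
#' optional fields are left empty; the accession and SPLASH carry the
#' hyperlinks on the PubChem side and are marked as link-bearing.
#'
#' @param record `massbank_record`.
#' @return One-row tibble with the agreed deposition fields; attribute
#'   `link_fields` names the hyperlinked columns.
#' @export
extract_fields <- function(record) {
  g <- function(key, subtag = NULL) {
    v <- mb_field(record, key, subtag)
    if (length(v)) v[[1]] else NA_character_
  }
  inchikey <- mb_field(record, "CH$LINK")
  inchikey <- inchikey[startsWith(inchikey, "INCHIKEY ")]
  row <- tibble(
    accession = g("ACCESSION"),
    authors = g("AUTHORS"),
    instrument = g("AC$INSTRUMENT"),
    instrument_type = g("AC$INSTRUMENT_TYPE"),
    ms_level = g("AC$MASS_SPECTROMETRY", "MS_TYPE"),
    ionization_mode = g("AC$MASS_SPECTROMETRY", "ION_MODE"),
    ionization = g("AC$MASS_SPECTROMETRY", "IONIZATION"),
    collision_energy = g("AC$MASS_SPECTROMETRY", "COLLISION_ENERGY"),
    fragmentation_mode = g("AC$MASS_SPECTROMETRY", "FRAGMENTATION_MODE"),
    column_name = g("AC$CHROMATOGRAPHY", "COLUMN_NAME"),
    retention_time = g("AC$CHROMATOGRAPHY", "RETENTION_TIME"),
    precursor_mz = g("MS$FOCUSED_ION", "PRECURSOR_M/Z"),
    precursor_adduct = g("MS$FOCUSED_ION", "PRECURSOR_TYPE"),
    license = g("LICENSE"),
    publication = g("PUBLICATION"),
    splash = g("PK$SPLASH"),
    top5_peaks = if (nrow(record$peaks)) {
      format_top5(top5_peaks(record$peaks[, c("mz", "intensity")]))
    } else NA_character_,
    name = g("CH$NAME"),
    smiles = g("CH$SMILES"),
    inchi = g("CH$IUPAC"),
    inchikey = if (length(inchikey)) sub("^INCHIKEY ", "", inchikey[[1]]) else NA_character_
  )
  structure(row, link_fields = c("accession", "splash"))
}

#' Build the cleaned PubChem substance table
#'
#' Clean-up steps, applied in order with per-reason accounting: rows whose
#' structure fields are `"N/A"` (or missing), SMILES containing wildcard
#' atoms (`*`), bad-list SMILES (exact string membership), and duplicate
#' structure triples (SMILES + InChI + InChIKey after whitespace
#' normalisation; the first row survives).
#'
#' @param rows Deposition rows ([extract_fields()] output, row-bound).
#' @param badlist Character vector of excluded SMILES.
#' @return The cleaned tibble; attribute `removals` is a tibble of
#'   per-reason counts (`na_entry`, `wildcard`, `badlist`, `duplicate`).
#' @export
build_substance_table <- function(rows, badlist = character()) {
  rows <- as_tibble(rows)
  norm <- function(x) trimws(gsub("[[:space:]]+", " ", ifelse(is.na(x), "", x)))
  removals <- c(na_entry = 0L, wildcard = 0L, badlist = 0L, duplicate = 0L)

  na_bad <- norm(rows$smiles) %in% c("", "N/A", "NA")
  removals[["na_entry"]] <- sum(na_bad)
  rows <- rows[!na_bad, , drop = FALSE]

  wc <- grepl("*", rows$smiles, fixed = TRUE)
  removals[["wildcard"]] <- sum(wc)
  rows <- rows[!wc, , drop = FALSE]

  bl <- rows$smiles %in% badlist
  removals[["badlist"]] <- sum(bl)
  rows <- rows[!bl, , drop = FALSE]

  key <- paste(norm(rows$smiles), norm(rows$inchi), norm(rows$inchikey), sep = "\r")
  dup <- duplicated(key)
  removals[["duplicate"]] <- sum(dup)
  rows <- rows[!dup, , drop = FALSE]

  structure(rows, removals = tibble(reason = names(removals),
                                    n = as.integer(removals)))
}

#' Build the MS/MS annotation table and its mapping entry
#'
#' One annotation row per record plus a mapping entry naming the annotation
#' file version; rerunning on identical input yields identical output.
#'
#' @param rows Deposition rows.
#' @param version Annotation file version label.
#' @param file Annotation file name recorded in the mapping.
#' @return List with `annotations` (tibble) and `mapping` (tibble; zero rows
#'   for empty input).
#' @export
build_annotation_table <- function(rows, version = "1", file = "massbank_annotations.csv") {
  rows <- as_tibble(rows)
  annotations <- rows[, intersect(.deposition_fields, names(rows)), drop = FALSE]
  mapping <- if (nrow(rows)) {
    tibble(file = file, version = version, n_annotations = nrow(rows))
  } else {
    tibble(file = character(), version = character(), n_annotations = integer())
  }
  list(annotations = annotations, mapping = mapping)
}

#' Write deposition artifacts to disk
#'
#' @param substance Substance tibble ([build_substance_table()]).
#' @param annotation List from [build_annotation_table()].
#' @param dir Output directory.
#' @return Named vector of written paths.
#' @export
write_deposition <- function(substance, annotation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    substance = file.path(dir, "pubchem_substances.csv"),
    annotations = file.path(dir, "massbank_annotations.csv"),
    mapping = file.path(dir, "annotation_mapping.csv")
  )
  readr::write_csv(substance, paths[["substance"]], progress = FALSE)
  readr::write_csv(annotation$annotations, paths[["annotations"]], progress = FALSE)
  readr::write_csv(annotation$mapping, paths[["mapping"]], progress = FALSE)
  paths
}
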