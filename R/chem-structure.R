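# Structure standardisation: MS-ready forms and stereochemistry restoration.
#
# All SMILES-level chemistry (canonicalisation, neutralisation, InChI) is
# delegated to OpenBabel through the `obabel` command-line tool; this module
# adds the mixture-curation logic on top: component selection, charge
# neutralisation policy, stereo stripping and stereo restoration against the
# original mixture SMILES.

have_obabel <- function() nzchar(Sys.which("obabel"))

assert_obabel <- function() {
  if (!have_obabel()) {
    abort("OpenBabel ('obabel') is required on the PATH for structure handling",
          class = "mixlib_obabel_error")
  }
}

# Run obabel over a vector of SMILES; returns a character vector aligned with
# the input, NA where OpenBabel could not parse/convert a molecule.
# `out` is an obabel output format; `args` extra command-line options.
ob_convert <- function(smiles, out = "can", args = character()) {
  assert_obabel()
  n <- length(smiles)
  if (n == 0) return(character())
  infile <- tempfile(fileext = ".smi")
  outfile <- tempfile(fileext = ".txt")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(paste(smiles, seq_len(n)), infile)
  if (out %in% c("smi", "can")) {
    run_args <- c(paste0("-ismi"), infile, paste0("-o", out), args, "-e",
                  "-O", outfile)
    sep <- "\t"
  } else {
    # txt output: "title appended-property"
    run_args <- c("-ismi", infile, "-otxt", "--append", out, "-e", "-O", outfile)
    sep <- " "
  }
  suppressWarnings(system2("obabel", shQuote(run_args, type = "sh"),
                           stdout = FALSE, stderr = FALSE))
  res <- rep(NA_character_, n)
  if (file.exists(outfile)) {
    lines <- readLines(outfile, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    for (ln in lines) {
      parts <- strsplit(trimws(ln), sep, fixed = TRUE)[[1]]
      if (length(parts) < 2) next
      if (sep == "\t") { value <- parts[[1]]; idx <- suppressWarnings(as.integer(parts[[2]])) }
      else { idx <- suppressWarnings(as.integer(parts[[1]])); value <- parts[[2]] }
      if (!is.na(idx) && idx >= 1 && idx <= n) res[idx] <- value
    }
  }
  res
}

#' Canonical SMILES via OpenBabel
#'
#' @param smiles Character vector of SMILES.
#' @param stereo Keep stereo descriptors (default) or strip them.
#' @return Canonical SMILES; `NA` for unparseable input.
#' @export
smiles_canonical <- function(smiles, stereo = TRUE) {
  ob_convert(smiles, out = "can", args = if (stereo) character() else "-xi")
}

#' Neutralise formal charges where chemically possible
#'
#' Protonates/deprotonates charged sites (e.g. carboxylates, ammoniums).
#' Charges that cannot be neutralised, such as quaternary nitrogen, are
#' retained; see [net_formal_charge()].
#'
#' @param smiles Character vector of SMILES.
#' @return Neutralised SMILES (stereo preserved); `NA` on parse failure.
#' @export
smiles_neutralize <- function(smiles) {
  ob_convert(smiles, out = "smi", args = "--neutralize")
}

#' InChI / InChIKey via OpenBabel
#' @param smiles Character vector of SMILES.
#' @return Character vector, `NA` on failure.
#' @export
smiles_inchikey <- function(smiles) ob_convert(smiles, out = "inchikey")

#' @rdname smiles_inchikey
#' @export
smiles_inchi <- function(smiles) ob_convert(smiles, out = "inchi")

#' Molecular formula of a SMILES
#' @param smiles Character vector of SMILES.
#' @return Hill-order formula strings (`NA` on failure); any trailing charge
#'   annotation (e.g. `"Na+"`) is stripped.
#' @export
smiles_formula <- function(smiles) {
  f <- ob_convert(smiles, out = "formula")
  sub("[+-]+[0-9]*$", "", f)
}

#' Net formal charge read off a SMILES string
#'
#' Sums the charge annotations of bracket atoms (`[O-]`, `[N+]`, `[Fe+2]`...).
#'
#' @param smiles Character vector of SMILES.
#' @return Integer net charge per input.
#' @export
net_formal_charge <- function(smiles) {
  vapply(smiles, function(s) {
    atoms <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
    if (!length(atoms)) return(0L)
    chg <- vapply(atoms, function(a) {
      m <- regmatches(a, gregexpr("[+-][0-9]*", a))[[1]]
      if (!length(m)) return(0L)
      sum(vapply(m, function(x) {
        sgn <- if (substr(x, 1, 1) == "+") 1L else -1L
        num <- substr(x, 2, nchar(x))
        sgn * (if (nzchar(num)) as.integer(num) else 1L)
      }, integer(1)))
    }, integer(1))
    sum(chg)
  }, integer(1), USE.NAMES = FALSE)
}

# Split a mixture SMILES into its dot-separated components.
smiles_components <- function(smiles) strsplit(smiles, ".", fixed = TRUE)[[1]]

heavy_atom_count <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f)) return(NA_integer_)
    counts <- tryCatch(parse_formula(f), error = function(e) NULL)
    if (is.null(counts)) return(NA_integer_)
    sum(counts[setdiff(names(counts), c("H", "D"))])
  }, integer(1), USE.NAMES = FALSE)
}

# Pick the index of the "largest organic" component: contains carbon, most
# heavy atoms; ties broken by monoisotopic mass, then canonical SMILES order.
select_main_component <- function(components) {
  formulas <- smiles_formula(components)
  canon <- smiles_canonical(components)
  info <- tibble(
    idx = seq_along(components),
    formula = formulas,
    canon = canon,
    heavy = heavy_atom_count(formulas),
    mass = vapply(formulas, function(f) {
      if (is.na(f)) return(NA_real_)
      tryCatch(monoisotopic_mass(parse_formula(f)), error = function(e) NA_real_)
    }, numeric(1), USE.NAMES = FALSE),
    # carbon-containing: a 'C' not starting a two-letter symbol (Cl, Ca, ...)
    organic = !is.na(formulas) & grepl("C(?![a-z])", formulas, perl = TRUE)
  )
  info <- info |>
    filter(.data$organic) |>
    arrange(desc(.data$heavy), desc(.data$mass), .data$canon)
  if (!nrow(info)) return(NA_integer_)
  info$idx[[1]]
}

#' MS-ready form of a structure
#'
#' Produces the neutral, desalted, stereo-stripped SMILES that represents the
#' species entering the mass spectrometer: the largest organic component is
#' retained, formal charges are neutralised where chemically possible, and
#' stereo descriptors are removed. Charges that cannot be neutralised
#' (e.g. quaternary ammonium) are kept and flagged via the
#' `residual_charge` attribute.
#'
#' @param smiles A single SMILES string (may contain counter-ions, charges
#'   and stereochemistry).
#' @return Canonical MS-ready SMILES with attribute `residual_charge`
#'   (integer net charge remaining after neutralisation).
#' @examples
#' \dontrun{ms_ready("[Na+].OC[C@@H](O)[C@H]1OC(=O)C(O)=C1[O-]")}
#' @export
ms_ready <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  comps <- smiles_components(smiles)
  main <- select_main_component(comps)
  if (is.na(main)) {
    abort(paste0("no organic component in SMILES: ", smiles),
          class = "mixlib_structure_error")
  }
  neutral <- smiles_neutralize(comps[[main]])
  if (is.na(neutral)) {
    abort(paste0("unparseable SMILES component: ", comps[[main]]),
          class = "mixlib_structure_error")
  }
  # neutralisation of a single component must not re-introduce '.' pieces
  neutral <- smiles_components(neutral)[[1]]
  out <- smiles_canonical(neutral, stereo = FALSE)
  resid <- net_formal_charge(out)
  if (resid != 0L) {
    warn(paste0("charge could not be fully neutralised (net ", resid, "): ", smiles))
  }
  structure(out, residual_charge = resid)
}

#' Restore stereochemistry from the original mixture SMILES
#'
#' Given an MS-ready (stereo-stripped) SMILES and the original mixture SMILES
#' it was derived from, finds the component of the original with the same
#' constitution and returns its desalted, neutralised form with the original
#' stereo descriptors reinstated. Stripping stereo from the result reproduces
#' the MS-ready input (canonical comparison).
#'
#' @param ms_ready_smiles MS-ready SMILES (no stereo, neutral, single
#'   component).
#' @param original_smiles Original mixture SMILES (may contain counter-ions,
#'   charges, stereo).
#' @return Canonical desalted neutral SMILES with stereo retained.
#' @export
restore_stereo <- function(ms_ready_smiles, original_smiles) {
  stopifnot(length(ms_ready_smiles) == 1, length(original_smiles) == 1)
  target <- smiles_canonical(ms_ready_smiles, stereo = FALSE)
  if (is.na(target)) {
    abort("unparseable MS-ready SMILES", class = "mixlib_structure_error")
  }
  comps <- smiles_components(original_smiles)
  neutral <- smiles_neutralize(comps)
  neutral <- vapply(neutral, function(s) {
    if (is.na(s)) NA_character_ else smiles_components(s)[[1]]
  }, character(1), USE.NAMES = FALSE)
  skeleton <- smiles_canonical(neutral, stereo = FALSE)
  hit <- which(!is.na(skeleton) & skeleton == target)
  if (!length(hit)) {
    abort("no component of the original SMILES matches the MS-ready constitution",
          class = "mixlib_structure_error")
  }
  smiles_canonical(neutral[[hit[[1]]]], stereo = TRUE)
}

#' Compare two SMILES for identical constitution (stereo ignored)
#' @param a,b SMILES strings.
#' @return Logical.
#' @export
same_constitution <- function(a, b) {
  ca <- smiles_canonical(a, stereo = FALSE)
  cb <- smiles_canonical(b, stereo = FALSE)
  !is.na(ca) && !is.na(cb) && ca == cb
}
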