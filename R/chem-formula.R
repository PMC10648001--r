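#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Pinned IUPAC monoisotopic masses (Da) of the most abundant isotope.
# Kept as a package constant so mass arithmetic is bit-stable.
.element_masses <- c(
  H  = 1.0078250319, D = 2.0141017780,
  B  = 11.0093055,  C  = 12.0000000,   N  = 14.0030740052, O = 15.9949146221,
  F  = 18.9984032,  Na = 22.98976928,  Mg = 23.9850417,    Al = 26.98153863,
  Si = 27.9769265327, P = 30.97376151, S  = 31.97207069,   Cl = 34.96885271,
  K  = 38.96370668, Ca = 39.96259098,  Fe = 55.93493743,   Ni = 57.9353429,
  Cu = 62.9295975,  Zn = 63.9291422,   As = 74.9215964,    Se = 79.9165213,
  Br = 78.9183376,  I  = 126.904473,   Li = 7.01600455
)

# Standard valences used for ring-plus-double-bond equivalents.
.element_valences <- c(
  H = 1, D = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Na = 1, Mg = 2, Al = 3,
  Si = 4, P = 3, S = 2, Cl = 1, K = 1, Ca = 2, Fe = 2, Ni = 2, Cu = 2,
  Zn = 2, As = 3, Se = 2, Br = 1, I = 1, Li = 1
)

#' Physical constants for ion mass arithmetic
#'
#' Electron and proton rest masses in Da, pinned so that ion m/z values are
#' reproducible to the sub-ppm level expected of Orbitrap data.
#' @name mass-constants
#' @keywords internal
.electron_mass <- 0.00054857990946
.proton_mass <- 1.00727646688

#' Parse a molecular formula into element counts
#'
#' Parses a Hill-order (or arbitrary-order) molecular formula string such as
#' `"C10H13NO"` into a named integer vector of element counts.
#'
#' @param formula Non-empty formula string, e.g. `"C6H12O6"`.
#' @return Named integer vector of counts (class `element_counts`), one entry
#'   per element symbol, each count >= 1.
#' @examples
#' parse_formula("C10H13NO")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  formula <- trimws(formula)
  if (!nzchar(formula)) abort("empty formula string", class = "mixlib_parse_error")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    abort(paste0("malformed formula: '", formula, "'"), class = "mixlib_parse_error")
  }
  sym <- sub("[0-9]*$", "", toks)
  num <- sub("^[A-Za-z]+", "", toks)
  bad <- setdiff(sym, names(.element_masses))
  if (length(bad)) {
    abort(paste0("unknown element symbol(s): ", paste(bad, collapse = ", ")),
          class = "mixlib_parse_error")
  }
  n <- ifelse(num == "", 1L, suppressWarnings(as.integer(num)))
  if (anyNA(n)) abort("malformed count in formula", class = "mixlib_parse_error")
  counts <- tapply(n, sym, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  element_counts(out)
}

#' Construct an element-counts object
#'
#' @param x Named integer vector (element symbol -> count). Zero counts are
#'   dropped; negative counts are an error.
#' @return `element_counts` object.
#' @export
element_counts <- function(x = integer()) {
  if (length(x)) {
    stopifnot(!is.null(names(x)), all(nzchar(names(x))))
    bad <- setdiff(names(x), names(.element_masses))
    if (length(bad)) {
      abort(paste0("unknown element symbol(s): ", paste(bad, collapse = ", ")),
            class = "mixlib_parse_error")
    }
    x <- as.integer(round(x)) |> stats::setNames(names(x))
    if (any(x < 0)) abort("negative element count", class = "mixlib_parse_error")
    x <- x[x > 0]
    x <- x[hill_order(names(x))]
  }
  structure(as.integer(x) |> stats::setNames(names(x)), class = "element_counts")
}

# Hill order: C first, then H, then the rest alphabetically; if no carbon,
# everything alphabetical.
hill_order <- function(symbols) {
  if ("C" %in% symbols) {
    order(match(symbols, c("C", "H"), nomatch = 3L), symbols)
  } else {
    order(symbols)
  }
}

#' Format element counts as a Hill-order formula string
#'
#' @param counts `element_counts` or named integer vector.
#' @return Formula string, `""` for the empty formula.
#' @export
format_formula <- function(counts) {
  counts <- as_element_counts(counts)
  if (!length(counts)) return("")
  paste0(names(counts), ifelse(counts > 1L, counts, ""), collapse = "")
}

#' @export
format.element_counts <- function(x, ...) format_formula(x)

#' @export
print.element_counts <- function(x, ...) {
  cat("<formula>", format_formula(x), "\n")
  invisible(x)
}

as_element_counts <- function(x) {
  if (inherits(x, "element_counts")) x
  else if (is.character(x)) parse_formula(x)
  else element_counts(x)
}

# Element-wise sum of two count vectors (deltas may be negative); errors if
# the result would go negative.
counts_add <- function(a, b) {
  syms <- union(names(a), names(b))
  out <- stats::setNames(rep(0L, length(syms)), syms)
  out[names(a)] <- out[names(a)] + as.integer(a)
  out[names(b)] <- out[names(b)] + as.integer(b)
  if (any(out < 0)) abort("element count would become negative", class = "mixlib_parse_error")
  element_counts(out)
}

#' Monoisotopic mass of a formula
#'
#' Sum of pinned most-abundant-isotope masses over the element counts.
#'
#' @param counts `element_counts`, named integer vector, or formula string.
#' @return Mass in Da (0 for the empty formula).
#' @examples
#' monoisotopic_mass(parse_formula("H2O"))
#' @export
monoisotopic_mass <- function(counts) {
  counts <- as_element_counts(counts)
  if (!length(counts)) return(0)
  sum(.element_masses[names(counts)] * as.numeric(counts))
}

#' Ring-plus-double-bond equivalents of a formula
#'
#' RDBE = 1 + sum over elements of n_i (v_i - 2) / 2 with standard valences.
#' Even-electron fragment ions can have half-integral RDBE down to -0.5.
#'
#' @param counts formula in any accepted representation.
#' @return RDBE (can be half-integral or negative).
#' @export
rdbe <- function(counts) {
  counts <- as_element_counts(counts)
  if (!length(counts)) return(1)
  1 + sum(as.numeric(counts) * (.element_valences[names(counts)] - 2)) / 2
}

# ---- adducts -----------------------------------------------------------

.adduct_table <- list(
  "[M+H]+"   = list(delta = c(H = 1L),          charge = +1L),
  "[M+Na]+"  = list(delta = c(Na = 1L),         charge = +1L),
  "[M+K]+"   = list(delta = c(K = 1L),          charge = +1L),
  "[M+NH4]+" = list(delta = c(N = 1L, H = 4L),  charge = +1L),
  "[M-H]-"   = list(delta = c(H = -1L),         charge = -1L),
  "[M+Cl]-"  = list(delta = c(Cl = 1L),         charge = -1L),
  "[M+HCOO]-" = list(delta = c(C = 1L, H = 1L, O = 2L), charge = -1L)
)

normalize_adduct_name <- function(name) {
  # accept the typographic minus sign used in print
  gsub("−", "-", name)
}

#' Look up a known adduct
#'
#' @param name Adduct name such as `"[M+H]+"` or `"[M-H]-"` (a Unicode minus
#'   is accepted and normalised).
#' @return List with `name`, `delta` (element_counts-style named vector, may
#'   contain negative entries) and `charge`.
#' @export
adduct <- function(name) {
  key <- normalize_adduct_name(name)
  if (!key %in% names(.adduct_table)) {
    abort(paste0("unknown adduct: ", name), class = "mixlib_adduct_error")
  }
  c(list(name = key), .adduct_table[[key]])
}

#' List known adducts
#' @return Tibble with name, delta formula, charge.
#' @export
known_adducts <- function() {
  tibble(
    name = names(.adduct_table),
    charge = purrr::map_int(.adduct_table, "charge"),
    delta_mass = purrr::map_dbl(.adduct_table, function(a) {
      sum(.element_masses[names(a$delta)] * as.numeric(a$delta))
    })
  )
}

#' m/z of an adduct ion
#'
#' Computes `(M + delta - z * m_e) / |z|` where `delta` is the adduct's atom
#' gain/loss and `m_e` the electron rest mass. The electron-mass correction
#' matches what high-resolution instruments actually measure; it can be
#' disabled for comparison with legacy tables that ignore it.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (>= 0).
#' @param adduct Adduct name or object from [adduct()].
#' @param electron_correction Apply the electron-mass term (default `TRUE`).
#' @return m/z in Da.
#' @examples
#' adduct_mz(monoisotopic_mass(parse_formula("C10H13NO")), "[M+H]+")
#' @export
adduct_mz <- function(neutral_mass, adduct = "[M+H]+", electron_correction = TRUE) {
  if (is.character(adduct)) adduct <- adduct(adduct)
  stopifnot(all(neutral_mass >= 0))
  delta <- sum(.element_masses[names(adduct$delta)] * as.numeric(adduct$delta))
  e <- if (electron_correction) .electron_mass else 0
  (neutral_mass + delta - adduct$charge * e) / abs(adduct$charge)
}

#' Formula of an adduct ion
#'
#' Element counts of the ion, e.g. C10H14NO for C10H13NO + `[M+H]+`.
#'
#' @inheritParams adduct_mz
#' @param counts Neutral formula in any accepted representation.
#' @return `element_counts` of the ion.
#' @export
adduct_formula <- function(counts, adduct = "[M+H]+") {
  if (is.character(adduct)) adduct <- adduct(adduct)
  counts_add(as_element_counts(counts), adduct$delta)
}

# m/z of an ion given its formula and charge (electron book-keeping included).
ion_mz <- function(counts, charge) {
  stopifnot(charge != 0)
  (monoisotopic_mass(counts) - charge * .electron_mass) / abs(charge)
}

ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}
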