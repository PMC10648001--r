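---
title: "From mixture screening runs to a curated spectral library: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From mixture screening runs to a curated spectral library: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixlib)
```

## The problem

High-resolution tandem mass spectra of authentic standards are the backbone
of compound identification in non-targeted screening. When standards are
measured not one-by-one but as *designed mixtures* -- tens to hundreds of
compounds per injection, acquired in data-dependent mode at several nominal
collision energies (NCE) and in both ionization modes -- turning the raw
runs into a trustworthy open library requires a chain of curation steps:

1. **Prescreening / QC**: for every compound expected in a mix, extract its
   ion chromatogram, find the chromatographic peak, and demand a minimum
   apex intensity, a minimum signal-to-noise ratio, and at least one MS2
   scan whose precursor matches the target and whose retention time (RT)
   sits close to the MS1 apex.
2. **Annotation and recalibration**: assign sub-formulas of the precursor
   ion to fragment peaks, fit a smooth m/z-error model from the assigned
   peaks, correct the spectra and re-annotate at a tighter tolerance.
3. **Isobar disambiguation**: compounds of one mix whose precursor ions fall
   inside the same isolation window produce indistinguishable DDA spectra;
   their identities must be resolved *across* mixes by RT anchoring, and
   anything still ambiguous excluded.
4. **Record generation and validation**: assemble MassBank-format text
   records (with SPLASH hashes and 1--999 relative intensities), validate
   them, and summarize the collection.
5. **Deposition**: project the records onto the field list agreed for
   PubChem display (including Top-5 peaks) and build a cleaned substance
   table.

`mixlib` implements this chain end to end, and ships a seeded synthetic
fixture generator so each stage -- and the whole pipeline -- can be
exercised against known ground truth without any external data.

## Core quantities and conventions

**Masses.** Monoisotopic atomic masses are pinned in an internal IUPAC
table so that all arithmetic is bit-stable. Ion m/z includes the
electron-mass correction,
$$ m/z = \frac{M + \Delta_{\mathrm{adduct}} - z\, m_e}{|z|}, $$
which is what an Orbitrap actually measures; a flag
(`electron_correction = FALSE`) reproduces legacy tables that neglect
$m_e$. With this convention the protonated ion of C~10~H~13~NO computes to
164.1070 (4 decimals):

```{r}
adduct_mz(monoisotopic_mass(parse_formula("C10H13NO")), "[M+H]+")
```

**Sub-formulas.** A fragment candidate is any element-count subset of the
precursor *ion* formula whose ion m/z lies within tolerance and whose
ring-plus-double-bond equivalent is at least $-0.5$ (allowing even-electron
fragment ions). The element set is restricted to the precursor's own
elements, so no adducted Na/K fragments are invented. The enumeration is an
exact depth-first search with mass pruning; the test suite checks it
against a brute-force subset enumeration.

**MS-ready structures.** Mixture SMILES may carry counter-ions, charges and
stereochemistry. The MS-ready form keeps the largest organic component
(most heavy atoms; ties by monoisotopic mass, then canonical SMILES order),
neutralises charges where chemically possible (quaternary nitrogen is kept
and flagged), and strips stereo descriptors. Because databases often
register only the stereo-bearing form, `restore_stereo()` re-derives the
stereochemistry by matching the MS-ready constitution against the
components of the original mixture SMILES and returning the matching
component desalted, neutralised, and with its stereo centres intact.
OpenBabel performs the SMILES-level chemistry (canonicalisation,
neutralisation, InChI/InChIKey); the component-selection and matching rules
are this package's own, since no published rule exists for them.

## Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| QC minimum apex intensity | 1e5 | counts | below this, fragment spectra are too sparse to be library-grade |
| QC minimum S/N | 3 | -- | standard detection limit convention |
| EIC / precursor match tolerance | 2.5 | ppm | routine Orbitrap screening tolerance |
| RT tolerance (MS2 vs apex; isobar anchoring) | 0.5 | min | matches typical peak widths and gradient reproducibility |
| Pre-recalibration annotation tolerance | 10 | ppm | wide first pass to gather training pairs |
| Post-recalibration tolerance | 2.5 | ppm | screening tolerance re-applied after correction |
| Recalibration fit | loess, span 0.75, degree 2 | -- | smooth error-vs-m/z curves; linear fallback under 20 pairs |
| Centroid merge width | 5 (2 x post tol) | ppm | duplicated centroids from the writer/reader cycle collapse to one |
| Isolation window | 1 | Da | grouping window for isobars |
| Base-peak floor for records | 1e5 | counts | records below this are rejected at build time |

The intensity threshold is applied twice on purpose: at QC to the MS1 apex
and at record build to the MS2 base peak. The two stages catch different
failure modes (weak elution vs weak fragmentation), and published
descriptions of this workflow state both without saying which one governs;
we therefore enforce both.

## The S/N estimator

Only the criterion "signal-to-noise >= 3" is standard; the estimator is
not. `mixlib` defines noise as the MAD (scaled to sigma) of the EIC points
*outside* all detected peak bounds, falling back to the lower half of the
trace when peaks cover everything, and never below 1 count. Peak detection
itself uses `pracma::findpeaks` with a floor of twice the initial noise
estimate -- deliberately *below* the S/N-3 rule, so that peaks in the
S/N 2..3 band are detected and failed for low S/N rather than silently
missed. Flat-topped (plateau) maxima are accepted (`zero = "+"`), since a
true apex falling exactly between two scan times otherwise disappears.

## Isobar resolution

Within each mix, compounds are grouped by single-linkage on
|Delta m/z| <= 1 Da (in one dimension this is chaining of consecutive
gaps). Resolution then iterates to a fixpoint:

* a compound alone in its group with a peak anchors its RT (level 1);
  with several peaks the most intense is taken, because every peak in the
  window belongs to the only candidate;
* anchored compounds claim peaks within the RT tolerance in other mixes;
  if two anchors claim the same peak, both are demoted to level 3
  (co-elution: safety over coverage);
* if exactly one unanchored member and one unclaimed peak remain in a
  group, they are paired *by elimination* (level 1) -- and this new anchor
  can unlock other mixes, hence the fixpoint iteration;
* remaining many-to-many cases are level 3 and their spectra are excluded;
  members with no peak are `not_detected`.

Iteration order is fixed (sorted mixes, groups, ids), so the result is
independent of input order. Fragment-spectrum similarity is *not* used to
break ties; that requires individual standards and is out of scope.

## SPLASH

Records carry a SPLASH spectral hash with four blocks: the `splash10`
prefix; a 10-bin wrapped 5-Da intensity histogram encoded base-3 and
re-encoded base-36 (4 characters); a 10-bin wrapped 100-Da histogram as
base-10 digits; and the first 20 hex characters of the SHA256 over
`round(mz*1e6):round(999*I/Imax)` pairs sorted by m/z (ties by descending
intensity). All intensities enter after normalisation, so the hash is
invariant under intensity scaling. The same protocol is implemented twice,
independently -- in R inside the package and in Python
(`inst/splash/splash_oracle.py`, hashlib only) -- and the test suite
requires the two to agree on randomly generated spectra.

## The synthetic fixture generator

`generate_design()` emulates a ten-mix trial: sizes
(95, 95, 95, 95, 185, 185, 365, 365, 95, 365) for mixes named 499--508,
with mixes 503 and 505 carrying the complete replicate set of mix 1
(mix 499), so 505 is 270 new substances plus those 95. Compounds are
homologous-series structures (alkanols, amines, acids, ketones, diols,
amides, nitriles) whose formulas are known analytically; mixes are packed
so that no two ions fall within the isolation window unless an isobar pair
is planted. Planted pairs share a molecular formula (1-alkanol vs
alkan-2-ol), elute >= 1.5 min apart (three times the anchoring tolerance),
and come in two flavours: *anchored* (one member also occurs alone in
another mix) and *unanchored* (always co-occurring, hence unresolvable by
design).

`simulate_run()` emits Gaussian elution profiles (sigma 0.05 min) sampled
every 0.01 min over a 17-minute gradient, apex intensities log-uniform in
3e5..3e6 counts, sparse Poisson baseline noise, and an inclusion-list DDA
duty cycle (one MS2 per listed precursor every 5th MS1 cycle above 1e4
counts). Fragment peaks are random sub-formula draws with a CE-dependent
intensity shift toward low-mass fragments at high NCE. A configurable
linear mass-error curve (ppm as a function of m/z) is applied to every
emitted m/z. Planted QC violations shape the run: a weak apex (5e4), an
oscillating chemical background phase-locked to the compound's apex (S/N
sinks below 3 while the peak stays detectable and above 1e5), omission
from the inclusion list, or MS2 triggered 0.7 min late.

What the generator does **not** emulate: physically meaningful
fragmentation chemistry, isotope patterns, RT drift between runs, detector
saturation, chimeric MS2 from co-isolated *non-listed* background, and
profile-mode peak shapes. Green tests therefore demonstrate that the
curation logic is correct under its stated assumptions -- not that the
thresholds are optimal for any particular instrument.

## Numerical choices and degenerate inputs

* Retention times are minutes everywhere; mzML I/O converts on read/write.
* The loess recalibration uses the standard (least-squares) family: with
  synthetic training pairs the residuals can be *exactly* zero, which
  breaks the re-descending weights of the robust variant. Predictions are
  clamped to the fitted m/z range.
* Peak blocks are serialised with m/z at 4 decimals and integer
  intensities; records store all field values as formatted text, which is
  what makes `parse_record(write_record(r))` bit-exact.
* Relative intensities are `round(999 I / I_max)` floored at 1.
* Empty EICs, empty mixes, empty record directories and empty deposition
  inputs all return typed empty tables rather than errors; empty peak
  lists in spectra are errors, because a record without peaks is invalid.
* Config files are YAML; record dates are injectable so that pipeline
  artifacts are byte-reproducible under a fixed seed.
* Accession serials are allocated in sorted (compound, mix, polarity, CE)
  order under the contributor's prefix, e.g. `MSBNK-LCSB-LU000001`; the
  scheme within a prefix is a package choice.

## Problem sizes in the shipped tests

The test-suite fixtures are sized for completeness, not throughput: QC
exactness uses a 50-compound mix with planted violations; the
sub-formula oracle runs 50 random fragment cases over precursors with at
most 12 heavy atoms; recalibration recovery uses six-compound runs under
constant (+5 ppm) and linear planted error curves; record integrity uses a
two-mix, eight-compound pipeline at two collision energies; the
determinism check runs a three-mix pipeline twice and compares every
artifact byte by byte. The full ten-mix design is generated once to verify
its layout.

## Known limitations

* Identification beyond RT anchoring (e.g. spectral similarity between
  mixes) is not attempted; unresolvable isobars stay level 3 and out of
  the library, which is conservative by construction.
* Compound names, synonyms and database identifiers come from the input
  compound list (an offline "infolist"); no web services are queried.
  InChI/InChIKeys are generated with OpenBabel when not supplied.
* The SPLASH implementation follows the published protocol with the
  constants documented above; its byte-level agreement with other SPLASH
  libraries should be re-verified before cross-library joins.
* Only one chromatographic peak per compound is carried into a record;
  multiple passing peaks are retained through QC and handed to the isobar
  resolver, but a compound ultimately yields one RT per mix.
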