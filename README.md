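# mixlib

Curated open mass-spectral libraries from LC-HRMS/MS runs of **known
chemical mixtures**.

When reference standards are measured as designed mixtures (tens to
hundreds of compounds per injection, data-dependent MS2 at several nominal
collision energies, positive and negative mode), building a library out of
the raw runs is mostly a curation problem. `mixlib` implements that
curation chain as composable, pipe-friendly functions over data frames:

* **Prescreening / QC** — per compound × mix × mode × collision energy,
  extract the ion chromatogram and demand apex intensity ≥ 10⁵ counts,
  signal-to-noise ≥ 3, and an MS2 scan whose precursor matches within
  ±2.5 ppm and whose RT lies within ±0.5 min of the MS1 apex. Every
  failure carries its reason set.
* **Fragment annotation + recalibration** — assign sub-formulas `c ⊆`
  precursor ion formula with RDBE ≥ −0.5 and ion m/z
  `(m(c) − z·mₑ)/|z|` within tolerance; fit a loess mass-error curve
  error(m/z) from assigned peaks (linear fallback below 20 pairs), correct
  by `m/z·(1 − ê·10⁻⁶)` and re-annotate at 2.5 ppm.
* **Isobar disambiguation** — compounds of one mix within the 1 Da
  isolation window form groups; identities are resolved across mixes by RT
  anchoring with propagation to a fixpoint and assignment *by elimination*;
  what stays ambiguous is confidence level 3 and excluded.
* **MassBank records** — assembly, bit-exact text serialization, parsing,
  validation (peak counts, 1–999 relative intensities, accession format,
  formula/mass consistency, SPLASH integrity) and directory summaries.
* **PubChem deposition** — the agreed display field list with Top-5 peaks,
  plus a substance table cleaned of `N/A` structures, wildcard SMILES,
  bad-list entries and duplicates, with per-reason accounting.
* **Synthetic fixtures** — a seeded generator for multi-mix designs
  (default: ten mixes of 95/185/365 compounds with replicate subsets),
  Gaussian chromatography, inclusion-list DDA, planted mass-error curves,
  planted QC violations and planted isobar pairs, so the whole pipeline is
  testable offline with known ground truth.

MS-ready structure handling (desalting, charge neutralisation, stereo
stripping and *stereo restoration* from the original mixture SMILES) is
built on OpenBabel, which must be on the `PATH` (`obabel`).

## Worked example

The classic two-mix isobar situation: mix 503 contains only
2,2-dimethyl-2,3-dihydro-1-benzofuran-7-amine; mix 508 contains both that
amine and *N*-(2,4-dimethylphenyl)acetamide — the same formula
C₁₀H₁₃NO, so inside one mix their DDA spectra are indistinguishable.

```r
library(mixlib)

adduct_mz(monoisotopic_mass(parse_formula("C10H13NO")), "[M+H]+")
#> [1] 164.107   # 164.1070 at 4 decimals

fx    <- fig4_scenario("fixtures", params = sim_params(seed = 1))
runs  <- purrr::pmap(fx$files, function(mix, mode, ce, path)
           read_run(path, mix = mix, mode = mode, ce_tag = ce))
comp  <- read_compound_list(fx$inputs[["compounds"]])
design <- read_setid(fx$inputs[["setid"]], comp)

qc <- prescreen(runs, comp, design)
prescreen_table(qc)[, c("id", "mix", "verdict", "rt_apex", "snr")]
#> # A tibble: 3 × 5
#>   id            mix   verdict rt_apex     snr
#> 1 ENT-AMINE     503   pass       12.3 2000000
#> 2 ENT-AMINE     508   pass       14.4 3000000
#> 3 ENT-ACETAMIDE 508   pass       14.4 3000000

resolve_isobars(group_isobars(design, comp), qc)
#>              id mix   rt intensity level          rationale
#> 1     ENT-AMINE 503 12.3     2e+06     1       alone_in_mix
#> 2 ENT-ACETAMIDE 508 14.4     3e+06     1     by_elimination
#> 3     ENT-AMINE 508 12.3     2e+06     1 anchored_elsewhere
```

Reading the output: in mix 503 the amine is alone in its isolation-window
group, so its retention time is anchored at 12.3 min (level 1). In mix 508
two peaks (12.3 and 14.4 min) share the window; the anchor claims 12.3 for
the amine, and the single remaining peak/compound pair — the acetamide at
14.4 min — is assigned *by elimination*, also at level 1. Without mix 503
both compounds would stay at confidence level 3 and be excluded from the
library.

The full pipeline (QC → annotation/recalibration → isobar resolution →
record build → validation → deposition tables) runs from one config:

```r
cfg <- pipeline_config(mzml_dir = "fixtures", compounds_csv = "fixtures/compounds.csv",
                       setid_csv = "fixtures/setid.csv", settings_ini = "settings.ini",
                       out_dir = "out", seed = 1)
run_pipeline(cfg)       # manifest of stage artifacts; records under out/records/
```

A thin CLI wraps the same functions: `inst/scripts/mixlib run --config
config.yml`, `mixlib fixtures --preset fig4 --out fixtures --seed 1`,
`mixlib prescreen --mzml-dir … --compounds … --setid …`.

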