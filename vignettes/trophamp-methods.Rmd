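---
title: "Methods: quantifying trophic amplification in gridded ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying trophic amplification in gridded ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis

`trophamp` implements a per-cell comparison of two climate-change signals
on a regular latitude–longitude grid: the relative change in net primary
production (NPP, the forcing from an Earth-system model) and the relative
change in total consumer biomass (TCB, the response of a marine ecosystem
model), both between a reference window and an end-of-century target
window. Every diagnostic in the package derives from the three per-cell
change statistics

- `ΔNPP% = 100 (NPP_fut − NPP_ref)/NPP_ref`,
- `ΔB%   = 100 (B_fut − B_ref)/B_ref`,
- `ΔSST  = SST_fut − SST_ref` (°C),

where `_ref`/`_fut` are per-cell arithmetic means over the two windows.

**Response types.** A cell where biomass changes in the same direction as
NPP but by more is an *amplification*; by less, an *attenuation*; in the
opposite direction, an *inversion*. The sign prefix (positive/negative)
records the direction of the biomass change itself, giving six types. The
ratio `R = ΔB%/ΔNPP%` carries the same information quantitatively:
`R > 1`, `0 < R < 1`, `R < 0` for the three base types.

**Assumptions.** The comparison is purely local (no spatial smoothing, no
wrap-around neighbourhoods) and assumes both fields live on one shared
grid and land/ocean mask; mask mismatches are treated as errors rather
than being reconciled silently. Time axes are annual and contiguous;
sub-annual inputs are rejected rather than averaged, to keep the
provenance of every number obvious.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `reference_window` | 1995–2014 | years | baseline climatology (the usual IPCC reference period) |
| `target_window` | 2090–2099 | years | end-of-century window |
| `npp_exclusion_pct` | 1 | % | cells/samples with smaller `abs(ΔNPP%)` are excluded from R summaries and warming curves (an R computed on a near-zero denominator is noise) |
| `trim` | (2.5, 97.5) | percentiles | symmetric trim of the retained R sample before averaging, per member analysis |
| `agreement_votes` | 4 (of 5) | members | absolute vote threshold for the agreement map |
| `sst_bin_width` | 0.1 | °C | width of the warming bins |
| `weighted` | TRUE | — | cosine-latitude area weighting of global statistics |

The 1 % exclusion and the 2.5/97.5 trim are applied to R *summaries*
(mean R by type, warming curves) but **not** to the type maps: a map
classifies every cell, while a ratio statistic needs protection from
near-zero denominators. The trim is computed per member analysis over its
own retained cells; a pooled-ensemble trim would let one extreme member
shift every other member's cut-offs.

## Weighting

Global means and "percent of ocean area" statistics weight each cell by
`cos(latitude)`, the relative area of a cell on a regular grid. Because
the source analyses of this kind rarely state their weighting, every
area-weighted function takes `weighted = FALSE` for plain cell counting as
a sensitivity mode. Global change series default to the *change of the
area-weighted global mean* rather than the global mean of per-cell
changes; the per-cell variant is available (`per_cell = TRUE`), and the
two differ by a Jensen gap that the tests bound on the synthetic world.

Per-cell changes are computed as the *ratio of window means* (climatology
first, then ratio), which is stable for noisy annual data; the windowed
mean of annual ratios is not offered as a default anywhere.

## The synthetic pseudo-ensemble

Real multi-model archives are far too large to ship or regenerate in a
test suite, so the package carries a seeded generator whose statistics are
known in closed form. It emulates the *layout and statistical structure*
of an ISIMIP-like ensemble, not the Earth:

- **Forcings.** `SST(t) = SST0 + trend·s(t) + ε` and
  `NPP(t) = NPP0·(1 + g·s(t))·(1 + η)`, with `s(t)` a piecewise-linear
  ramp that is exactly 0 across the reference window and exactly 1 across
  the target window. Keeping `s` constant within each window is essential:
  the biomass response is exponential in `s`, so window means equal the
  closed form exactly (to float precision) only when `s` does not vary
  inside a window. The exact ramp shape between the windows is otherwise
  immaterial to window statistics.
- **Members.** Per class `c` with trophic distance `d_c`,
  `B_c(t) = B0_c · [NPP(t)/NPP0] · exp(−λ d_c (SST(t) − SST0)) · (1+ν)`,
  and `tcb = Σ_c B_c`. λ (per °C) is the member's transfer-efficiency
  sensitivity: warming by ΔT multiplies the energy reaching a class by
  `exp(−λ d_c ΔT)`, the cumulative-losses mechanism hypothesised to drive
  trophic amplification. λ = 0 gives a temperature-neutral member whose
  biomass tracks NPP exactly (`R ≡ 1`). The default ensemble spans
  λ ∈ {0, 0.05, 0.1, 0.15, 0.2} °C⁻¹ over six weight classes with
  `d_c = 1…6`, on a 45×90 grid over 1950–2099.
- **Noise.** One knob, `noise_sd` (default 0.05): the relative standard
  deviation of mean-one lognormal multiplicative noise on NPP and on each
  class biomass (independent streams split deterministically from the
  master seed, so any member/class is reproducible in isolation). For SST
  the same value is used as an absolute standard deviation in °C, since
  relative noise is meaningless for a temperature. Five percent
  interannual variability is a realistic order of magnitude for annual
  NPP anomalies.
- **Class baselines.** `B0_c` defaults to a geometric spectrum with ratio
  0.5 per class — between a pure transfer-efficiency decay (~0.1, far too
  steep for biomass) and a flat Sheldon spectrum (biomass roughly equal
  per logarithmic size class). This also means TCB is not dominated by a
  single class's noise stream. `baseline_te` (TE₀ = 0.1) is retained as
  the member's energy-flux property and validated to keep
  `TE₀·exp(−λΔT)` inside (0, 1) over the simulated warming range.

### The default trend geometry is stylised, deliberately

The default `sst_trend_field` / `npp_trend_field` are **not** Earth-like;
they are constructed so that the qualitative regimes the diagnostics are
designed to detect are realised robustly on the default grid:

- In the low/mid latitudes (|lat| ≤ 72°), warming decreases linearly from
  ~4.4 °C at the equator to ~0.35 °C at the band edge (with a smooth zonal
  ripple that de-quantises the discrete latitude rows), while NPP declines
  uniformly by 1.02 % — just above the standard 1 % exclusion. Retained
  decrease-direction samples are therefore end-of-century ones, and the
  binned mean R traces the closed form `exp(−λ d̄ ΔT) + (1−exp(−λ d̄ ΔT))/|n|`
  as a strictly increasing function of warming. With smooth "Earth-like"
  gradients instead, each bin mixes cells whose `ΔSST`-to-`ΔNPP` ratios
  differ by orders of magnitude, and the binned curve is provably
  non-monotone for this response model — the stylised geometry is what
  makes "R increases with warming" a property of the generator rather
  than an accident of binning.
- In the polar band (|lat| > 72°), NPP increases by 25 %. Most of the band
  warms by only 0.35 °C, where the NPP gain outpaces the
  transfer-efficiency losses (positive response); a sharp-edged "warm
  inflow" sector warms by 1.8 / 3.2 °C, where the same gain is overwhelmed
  (negative response). This produces the positive-to-negative crossing of
  R with warming in the NPP-increase subset, and a population of strongly
  responding, sign-safe cells (|ΔNPP| = 25 %) for classification-recovery
  tests. The two warming plateaus are placed away from every default
  member's zero-biomass-change contour so that no grid cell sits on a
  classification boundary within noise reach.
- No default cell has |ΔNPP| between ~1.1 % and 25 %. Under the default
  noise, the measured ΔNPP of a cell with a true change of 2–6 % flips
  sign with non-negligible probability, which would make "recover the
  true type" an ill-posed request for exactly the cells a test would
  query. The stated world simply does not pose that ill-posed question.

What a green test on this world establishes: the pipeline's arithmetic,
masking, exclusion and trimming rules, its classifier, and its binning
reproduce known ground truth, including under realistic noise. What it
does **not** establish: anything about real oceans, real ecosystem models,
spatially correlated noise, drifting baselines, or coastal mask mismatch
between members — none of which the generator emulates.

## Numerical choices

- **Boundary ties.** `R` exactly 1 (analytically possible: the λ = 0
  member) classifies as attenuation; the comparison `|ΔB| ≤ |ΔNPP|` is
  made with a 10⁻⁹ relative tolerance so that both the measured path and
  the closed-form path resolve the tie identically under float roundoff.
  `ΔB = 0` is `undefined`; `ΔNPP = 0` with `ΔB ≠ 0` is an inversion with
  the sign of ΔB and a ±Inf sentinel R that every summary excludes.
- **Degenerate references.** Cells with reference climatology ≤ 10⁻¹²
  (in data units) are masked from ratio statistics, counted, and logged.
- **Missing years.** A cell enters a window climatology only if every
  year of the window is present (all-or-nothing); the NetCDF reader
  rejects files with partially missing years rather than guessing.
- **Agreement ties.** Two types tied at or above the vote threshold →
  `no_agreement` (conservative; thresholds above half make this
  impossible, but lower configured thresholds need the rule). Members
  with no defined type at a cell do not vote; the threshold stays
  absolute, as in a fixed 6-of-7 rule.
- **Shapiro diagnostic.** The normality statistic on the retained R
  sample subsamples deterministically (evenly spaced indices) to the
  test's 5000-observation limit.
- **Warming-curve samples** are (cell, year) pairs of annual changes
  versus the reference climatology, pooled regardless of year; each
  sample counts once (no area weight), since pooling over years has no
  natural area–time measure. The end-of-century spatial alternative and
  an area-weighted mode exist behind flags because the convention is
  genuinely ambiguous in this literature.
- **TL→weight conversion.** The default map assumes
  `TL(w) = TL₀ + log(w/w₀)/log(PPMR)` with PPMR = 100 (one trophic level
  per two decadal weight bins), discretised to bin-overlap fractions with
  open outer edges, rows summing to 1. It is an explicit stand-in: users
  with a model-specific conversion table supply it via `mapping=`.
  Conversion acts on biomass fields *before* changes are computed —
  biomass is conserved under the linear reallocation, relative changes
  are not, so the order is fixed.
- **Length-based schemes** stay on their own axis; they are never
  force-converted to weight. Cross-scheme comparison is by rank
  (small/medium/large).

## Configuration and reproducibility

A run is a serialisable key/value tree (JSON always; YAML accepted when
the `yaml` package is available — JSON is the guaranteed path because the
supported R stack pins it). The same config and seed reproduce
byte-identical artifacts; every run writes a manifest with a config hash
and per-artifact MD5 checksums so reproducibility is checkable from the
outside. Sub-seeds for every noise stream are split deterministically
from the master seed, and the generator restores the caller's RNG state.

## Limitations

- NetCDF support is classic NetCDF-3 only (64-bit-offset files read,
  record variables read, classic written). netCDF-4/HDF5 inputs must be
  converted externally.
- The generator's world is stylised (see above); it validates the
  pipeline, not ecological realism. Production-forced versus
  biomass-forced member variants, seasonal cycles, ocean transport and
  species-level structure are out of scope.
- Single-cell classifications carry no uncertainty estimate; the package
  deliberately reports deterministic per-cell types plus ensemble
  agreement, not per-cell probabilities.
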