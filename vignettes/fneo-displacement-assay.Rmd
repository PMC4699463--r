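---
title: "Models and methods behind the F-neo displacement pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the F-neo displacement pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fneoscreen)
```

## The assay

F-neo is a fluorescein–neomycin conjugate whose fluorescence is quenched when
the neomycin moiety docks into an RNA groove. The quench is not a stacking
artifact: the negative electrostatic potential of the groove shifts the
fluorescein monoanion/dianion equilibrium toward the weakly emitting
monoanion. That gives the probe three distinct uses, and this package models
all three:

1. **Affinity**: titrating an RNA into the probe produces a saturation curve
   whose shape gives the dissociation constant and, through the saturation
   point, the number of probe binding sites per RNA.
2. **Electrostatics**: titrating pH in the free and bound states gives two
   pKa values; their difference converts directly into an apparent potential
   of the binding site.
3. **Screening**: an unlabelled compound that competes the probe out of the
   RNA restores fluorescence, so a single-concentration read per compound,
   normalized to a neomycin control on the same plate, ranks a whole library.

miRNAs — mature ~22-nt duplexes and their ~65–85-nt hairpin precursors — are
the RNA substrates of interest here; their bulges and internal loops are the
candidate aminoglycoside sites, which is why the package also ships a
dot-bracket bulge counter (`count_bulge_regions()`) to set the expected site
multiplicity.

## Binding model

Probe affinities are in the low-nM range while the assay runs at 100 nM
probe, so free and total ligand cannot be equated. The forward model is the
ligand-depletion ("tight-binding") quadratic isotherm,

$$F(\Psi) = F_0 + \frac{F_b - F_0}{2P}\Big(S - \sqrt{S^2 - 4 \Psi P}\Big),
\qquad S = \Psi + P + K_D,$$

with $P$ the total probe, $\Psi$ the total concentration of *binding sites*
(RNA concentration × integer site multiplicity $n$), and $F_0$, $F_b$ the
free/bound fluorescence plateaus. All concentrations in the public interface
are nM, because every published affinity in this assay family is printed in
nM. We parameterize by $K_D = 1/K_a$.

Two numerical points:

- The discriminant $S^2 - 4\Psi P$ touches zero at stoichiometric
  equivalence in the tight-binding limit; round-off can push it slightly
  negative. We clamp negatives smaller than $10^{-9} S^2$ and raise a domain
  error for anything larger — the former is round-off, the latter is a
  corrupt input.
- At $\Psi = 0$ the closed form is returned exactly as $F_0$ rather than
  through the square root, so the free-probe anchor point is exact.

### Competitive equilibrium

Displacement by an unlabelled competitor is a two-ligand, one-site-class mass
balance. All sites are treated as equivalent — the same simplification the
assay itself rests on (the saturation curves show a single transition). With
free-site concentration $s$,

$$g(s) = s + \frac{P\,s}{s + K_D^{probe}} + \frac{C\,s}{s + K_D^{comp}}
 - S_{tot} = 0 .$$

$g$ is strictly increasing on $[0, S_{tot}]$, so the physical root is unique
and bracketed. We solve by 64 bisection steps followed by a Newton polish
(the derivative is $\ge 1$, so Newton is safe once bracketed), vectorized
across conditions; residuals land at machine precision, far inside the
$10^{-9}$ relative tolerance the container type asserts. We deliberately do
not use the closed-form cubic: branch selection near degenerate corners
(zero competitor, zero sites, near-stoichiometric points) is where cubic
solutions go wrong, and a bracketed monotone root-find has no branches.

`kd_competitor = Inf` encodes an inert compound, which makes "no competitor"
a smooth special case rather than an API branch.

## Protonation and the electrostatic potential

The fluorescein reporter is a two-state (monoanion/dianion) single-proton
system: the dianion fraction at pH $x$ is $1/(1 + 10^{pK_a - x})$ and the
optical signal interpolates linearly between the two species' signals.
Binding shifts the pKa; the shift maps to an apparent potential

$$\varphi = -2.303\,\Delta pK_a \quad [kT/e],$$

reported both in $kT/e$ and in volts at the assay temperature. The physical
constants used for the volt conversion are the ones conventional for this
assay's literature ($R = 8.312$ J mol$^{-1}$ K$^{-1}$, $T = 298.2$ K,
$N_A = 6.023\times10^{23}$, $e = 1.602\times10^{-19}$ C) — note the slightly
non-CODATA $R$; at four significant figures the difference is irrelevant and
consistency with the source convention matters more. For the canonical free
(6.37) and bound (7.45) pKa pair the potential computes to $-2.487\,kT/e$;
the value usually quoted alongside those inputs is $-2.46$, consistent with
unrounded pKa estimates having been used upstream. We compute, we do not
force agreement; the acceptance tolerance is ±0.05.

## Fitting

All four estimators are plain nonlinear least squares (`stats::nls`, `port`
algorithm with a positivity bound on $K_D$, falling back to `optim`/L-BFGS-B
if the line search dies). Starting values are data-driven and deterministic:
plateaus from the extremes of $y$, midpoints from the half-range crossing of
the sorted data, and for $K_D$ the half-saturation point corrected for
depletion ($\Psi_{1/2} \approx P/2 + K_D$). Identical inputs give identical
fits; there is no per-dataset tuning anywhere.

- `fit_kd()` fits $(F_0, F_b, K_D)$ at a fixed site multiplicity.
- `estimate_site_multiplicity()` scans an integer candidate set (default
  1–8, covering the published range up to six sites per precursor hairpin),
  refits per candidate, and keeps the smallest-RSS candidate, breaking ties
  toward the smaller $n$ (parsimony). If even the winner explains the data
  poorly ($R^2 < 0.995$) the estimate carries a `large_residual` flag —
  in practice this means the generating multiplicity was outside the
  candidate set.
- `fit_pka()` fits the two-state ionization model; it accepts increasing or
  decreasing series (the asymptotes swap, the pKa is invariant — this is a
  tested reflection property). A fitted pKa outside the observed pH range is
  an identifiability error, not a result.
- `fit_ic50()` is a four-parameter logistic in $\log_{10}$ concentration.
  The published analysis says only "sigmoidal fit"; the 4PL is the HTS
  convention, reduces to the same 50%-displacement midpoint definition, and
  leaves the Hill slope free (whether the original fits floated it is
  unstated — floating it is the conservative choice). Two identifiability
  gates protect against extrapolated transitions: the fitted midpoint must
  lie within two decades of the titrated range, and the observed signal span
  must cover at least half of the fitted top–bottom window.

## Plate statistics

Assay quality is the Z′-factor,
$Z' = 1 - 3(\sigma_p + \sigma_n)/|\mu_p - \mu_n|$, computed from replicate
positive (probe + RNA + neomycin) and negative (probe + RNA) wells with
*sample* standard deviations (the source does not specify the estimator;
sample SD is the convention for small control sets). Verdicts follow the
standard scale: > 0.5 excellent, 0–0.5 marginal, < 0 unacceptable. Z′ is
affine-invariant in the signals, which the tests assert directly.

Compound activity is percent binding,
$100\,(F_{drug} - F_{baseline}) / (F_{neo} - F_{baseline})$, with both
control means taken **from the same plate** as the compound well — per-plate
normalization is the load-bearing design of the screen and is observable in
the tests (same raw signals, different plate baselines, different percents).
Deltas are signed: values below 0% or above 100% are reported untouched,
because the published per-compound tables report sub-neomycin binders without
truncation. Probe-only wells are carried for QC but never enter the percent
computation. The default hit threshold is 110% — at least ten percent more
displacement than the parent neomycin — and is configurable.

## The sigma ledger

Per miRNA, each library compound's percent binding is expressed in library
standard deviations from the library mean ("σ"). Two deliberate choices,
both places where the source is ambiguous:

- **Sample SD**, consistent with the plate statistics.
- **Neomycin is excluded** from the library statistics. It is the
  normalization anchor, fixed at 100% by construction; letting the anchor
  shrink the library SD would bias every σ.

Class averages aggregate σ over positional patterns: `NeoRX` (arginine at
position 1, *any or no* amino acid at position 2 — the "any or no" reading
follows the source's own definition of the pattern), `NeoXS` (any amino acid
at position 1, serine at position 2), `NeoX` (mono-conjugates). Members
weight equally; the size-weighted average of disjoint position-1 classes
reconstructs the library mean (≈ 0), which is a tested invariant.
Beta-alanine is a distinct two-character token (`βA`, ASCII `bA`), never
collapsed to alanine. `specificity_delta()` reports pairwise σ differences
of one compound across miRNAs — the quantity used to argue that a
conjugation buys specificity rather than blanket affinity.

## The synthetic world

No raw plate data were published for this assay family, so the package ships
seeded generators for every input, and the generators' zero-noise output *is*
the corresponding forward model — that identity is tested, which is what
makes the generators usable as oracles for the fitting layer.

Stated-world defaults, chosen once:

- **Assay presets** carry the four published configurations: mature hsa-miR
  504 (100 nM probe / 50 nM RNA / 300 nM compound, 2 sites, probe $K_D$
  1.5 nM), pre-hsa-miR 504 (100 / 16.7 / 300, 6 sites, 0.5 nM), hsa-miR 142
  (100 / 100 / 500, 1 site, 2.0 nM), hsa-miR 335 (100 / 100 / 500, 1 site,
  2.2 nM), plus the neomycin IC50 measured under each.
- **Well noise** is multiplicative Gaussian with CV 2% by default. The
  source prints no plate-reader noise figure; 2% is a typical fluorescence
  plate-reader CV and is a simulation default, not a measured value. Plate
  spatial effects (edges, drift) are deliberately not modelled — the source
  applies no spatial correction either, so simulating one would test code
  that does not exist.
- **Fluorescence plateaus** default to $F_0 = 1000$, $F_b = 250$ AU, a ~75%
  quench consistent with the strong quench reported for the best substrate.
- **Competitor affinities are calibrated from IC50s.** The competitor $K_D$
  values behind published IC50s are not printed, so
  `calibrate_competitor_kd()` root-finds the $K_D$ whose noiseless
  displacement curve crosses 50% of the zero-competitor bound probe exactly
  at the target IC50. One real consequence: at the mature-504 condition
  (100 nM sites against 100 nM probe) the one-site competitive model has a
  *stoichiometric floor* — even an infinitely tight 1:1 competitor cannot
  halve the bound probe until its total concentration reaches ~55 nM, so a
  target IC50 of 51.4 nM (the best published compound) is unreachable within
  the model and raises a domain error rather than a silently wrong number.
  The rank-order tests assign that compound a $K_D$ log-scaled from the
  nearest feasible one, preserving the published ordering.
- **The ground-truth library** draws
  $\log_{10} K_D = \log_{10} K_D^{neo} + \alpha(\text{pos1}) +
  \beta(\text{pos2}) + \varepsilon$ over the default 215-compound roster
  (15 mono-conjugates including lysine; di-conjugates with position 2 in
  S/T/Y/V over 15 position-1 codes and in D/W/βA/H/R/L/F/C/A/N over 14).
  Effect signs follow the published preference directions (arginine at
  position 1 stabilizes, aspartate destabilizes at either position,
  tryptophan destabilizes, serine at position 2 stabilizes); magnitudes were
  fixed once so that a simulated mature-504 screen lands in the published
  regime (library mean percent binding in the low 70s, library SD ≈ 20
  percentage points), with $\varepsilon \sim N(0, 0.15)$ in decades.
- **Plate layout**: each simulated 96-well plate carries two probe-only, two
  negative and two positive (neomycin) wells plus 45 compounds in duplicate,
  mirroring the published duplicate-with-on-plate-neomycin design.

### The supplementary stand-in

The per-compound supplementary tables behind the published class averages
were distributed as document attachments and are not available as data.
`synthetic_supplementary_table()` therefore constructs a *labelled-synthetic*
215-compound percent table whose library mean, SD and anchored class
averages are pinned (by a small fixed-point adjustment) to the published
summary numbers. A green test on it establishes that the σ-ledger machinery
recovers known summary statistics from per-compound data — it does **not**
establish agreement with the unpublished per-compound values, which remain
unreproducible. The same honesty applies to the published Z′ values and
per-compound percent-binding table: raw plates were never deposited, so
those numbers are covered by property tests (affine invariance, noise
monotonicity, sign recovery of generating effects) rather than by value
reproduction.

## Bulge counting

`count_bulge_regions()` pairs a dot-bracket string with a stack (reporting
the position of any unbalanced bracket), then walks the loop closed by each
pair: a loop containing at least one unpaired base *and* at least one child
helix counts once — that covers bulges, internal loops (two-sided loops count
once) and multibranch spacers, while hairpin loops, exterior dangling ends
and the `&` strand break of a duplex never count. The `&` is a region
terminator, not an unpaired base, so the UU overhangs of annealed mature
duplexes read as dangling ends. Published secondary-structure figures are not
printed as dot-bracket strings, so the counter is validated on constructed
examples; the published counts (2, 6, 1, 2 for the four constructs) are
expected outputs only for user-supplied structures that match those figures.

## Known limitations

- One equivalent site class; no cooperativity, no heterogeneous sites, no
  probe–probe interactions, no ionic-strength corrections.
- IC50s are reported as-is; no Cheng–Prusoff conversion to $K_i$ (not
  performed in the source analysis either).
- The σ ledger carries no significance testing or multiple-testing control,
  matching the source's usage; treat class averages as descriptive.
- The synthetic generators emulate well noise only; real screens add plate
  drift, edge effects, compound autofluorescence and pipetting error, so a
  green simulation test bounds algorithmic correctness, not assay ruggedness.
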