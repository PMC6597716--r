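---
title: "Models and methods behind thermokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thermokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermokin)
```

thermokin analyses the classic trade-off of enzyme temperature adaptation:
thermophilic enzymes are stable but slow at moderate temperature, their
mesophilic homologues fast but fragile. The package covers the five stages
of a comparative engineering study on an enzyme pair such as the
3-isopropylmalate dehydrogenases (IPMDH) of *Thermus thermophilus* and
*Escherichia coli*: structure-guided selection of candidate substitutions,
Michaelis–Menten kinetics, transition-state-theory energy profiles, thermal
unfolding, and the stability–activity regression. This vignette explains
the models, the defaults, and the choices that were genuinely open.

## Kinetic model

Initial velocities of a single-ligand titration are fitted to

$$v = \frac{V_{\max} S}{K_m + S}, \qquad k_{cat} = V_{\max} / [E]_0,$$

by unweighted nonlinear least squares (`fit_mm()`, Levenberg–Marquardt via
minpack.lm). Unweighted residuals match the common practice for
steady-state data where no error model is reported; an optional `1/v^2`
weighting is available for data spanning many decades. Starting values are
$V_{\max,0} = 1.2\max(v)$ and $K_{m,0}$ the concentration nearest
half-maximal velocity; both parameters are bounded positive, and a $K_m$
estimate collapsing onto the bound is flagged rather than reported as
converged. Standard errors come from the local covariance of the fit. At
least five concentrations are required; fewer is a precondition error, not
a warning, because two-parameter saturation fits on sparser designs are
unidentifiable in practice.

Fold-change tables (`relative_table()`) report each enzyme's constant
divided by the reference enzyme's, rounded to two significant figures —
the convention used in published kinetic tables for this enzyme family.
`check_relative_consistency()` recomputes every ratio from the printed
constants; the shipped table contains a few cells whose printed
parenthesised values disagree with their own printed constants (they were
evidently derived from unrounded raw data). The package flags those cells
instead of asserting either number.

## Transition-state energetics

With $k_B$, $h$, $R$ the Boltzmann, Planck and gas constants
(`physical_constants()`: $R = 8.314\,\mathrm{J\,K^{-1}mol^{-1}}$,
$h = 6.626\times10^{-34}\,\mathrm{J\,s}$,
$k_B = 1.381\times10^{-23}\,\mathrm{J\,K^{-1}}$), the three-state profile
along initial state (IS), Michaelis complex (MS) and transition state (TS)
is built from

$$\Delta G^\ddagger = -RT\ln\!\frac{k_{cat}h}{k_B T}, \qquad
\Delta G_m = RT\ln\!\frac{K_m}{c^\circ}, \qquad
\Delta G_T = \Delta G^\ddagger + \Delta G_m,$$

$$\Delta H^\ddagger = -R\,\frac{d\ln k_{cat}}{d(1/T)} - RT_{ref}, \qquad
\Delta H_m = R\,\frac{d\ln (K_m/c^\circ)}{d(1/T)}, \qquad
-T\Delta S_X = \Delta G_X - \Delta H_X .$$

Slopes are ordinary least squares over all supplied temperatures (studies
of this kind typically use three or four); two points are allowed with a
warning. $K_m$ is non-dimensionalised by $c^\circ = 1$ M before any
logarithm, the $-RT$ term uses $T_{ref} = 298.15$ K, and all energies are
in kJ/mol.

### The sign convention

The enzymology literature sometimes prints the binding step as
$\Delta G_m = -RT\ln K_m$ and $\Delta H_m = -R\,d\ln K_m/d(1/T)$ with
$K_m$ in molar units. Taken literally, those signs make a *weaker* binder
(larger $K_m$) look *more* stable at the Michaelis complex, and for the
IPMDH pair they would put the thermophile and mesophile barriers
$\Delta G_T$ more than 15 kJ/mol apart — contradicting the observed
behaviour that the two enzymes share the same IS→TS barrier at 25 °C while
the mesophile's Michaelis complex is the less stable one. thermokin
therefore defaults to the association convention
($\Delta G_m = RT\ln(K_m/c^\circ)$, $\Delta H_m = +R \cdot$ slope), which
reproduces that narrative, and exposes `convention = "as_printed"` for the
literal form. The sign audit is a regression test: under association the
Tt/Ec barrier gap is below 1 kJ/mol, under the printed signs it exceeds
15 kJ/mol, and profiles refuse to mix conventions.

`compare_profiles()` summarises two profiles' similarity as the
root-mean-square difference over the nine state quantities. On the shipped
constants the combined mutants sit several-fold closer to the mesophilic
enzyme than to their thermophilic parent — the quantitative form of
"mesophilic-like catalysis".

## Mutant design rules

`select_shell_sites()` implements the comparative rule set: a position is
a candidate when (i) the thermophile and mesophile residues differ in the
pairwise alignment and (ii) the residue lies within a shell radius
(8 or 12 Å in typical use) of any heavy atom of any copy of the bound
substrate or coenzyme, in any chain — cross-subunit proximity counts,
because in a homodimer a residue can contact the ligand bound to the
partner subunit. Distances are minima over heavy atoms; hydrogens are
ignored.

Three points were genuinely open and are decided as follows:

* **"Structurally close" grouping.** Candidates are merged into one
  construct by single-linkage clustering on the minimum inter-residue
  heavy-atom distance, default threshold 6 Å (`group_sites()`). This
  reproduces the natural behaviour that adjacent-residue pairs such as
  272/273 become one construct without merging distant shells; the
  threshold is a parameter, not a constant.
* **Insertion rule.** A residue run inserted in the mesophilic sequence is
  added to a construct when the aligned residue immediately flanking the
  insertion on either side is one of the construct's substitutions; an
  insertion flanked by substitutions of two different constructs is
  attached to both with a warning (`apply_insertion_rule()`).
* **Aligner and tie-breaks.** `align_global()` delegates to
  `Biostrings::pairwiseAlignment` (BLOSUM62, gap open 11, gap extend 1).
  Its traceback is deterministic, and the package treats that determinism —
  rather than a particular tie-break rule — as the contract; a published
  reference alignment can always be supplied directly
  (`read_alignment_fasta()`) and takes precedence. Alignment positions map
  to structure residue numbers through a configurable integer offset
  (default 0), 1-based throughout.

The package does not attempt to reproduce any particular study's exact
construct list: published groupings depend on unpublished criteria, so the
partition property (every candidate in exactly one construct), shell
nesting, and oracle equality of the distance map are what the tests
guarantee.

## Thermal unfolding

`fit_melt()` fits the two-state van't Hoff model with linear baselines,

$$\theta(T) = (1-f)(a_N + b_N T) + f(a_U + b_U T), \qquad
f = \frac{1}{1 + e^{\Delta G_{unf}/RT}}, \qquad
\Delta G_{unf} = \Delta H_{vH}\Big(1 - \frac{T}{T_m}\Big),$$

with temperatures in Kelvin inside $f$ and °C at the interface. The heat
capacity change of unfolding is fixed at zero (so $\Delta G_{unf}$ is
linear in $T$) — the minimal two-state model, appropriate when the
experiment reports a midpoint rather than a full stability curve. A
visible transition is required (signal range at least 5 times a local
noise estimate from second differences); flat traces return an explicit
no-transition result. Because thermophilic protein melts are frequently
irreversible, a model-free fallback (`method = "derivative"`: midpoint of
a smoothed-derivative extremum) is provided; its $T_m$ carries no standard
error. `delta_tm()` differences two midpoints with errors propagated in
quadrature.

## Stability–activity trade-off

`fit_tradeoff()` regresses $\log_{10}$(specific activity at 25 °C) on the
unfolding midpoint, reporting the slope, intercept and Pearson $r$. The
logarithm is base-10 (the axis convention of this literature); $r$ and the
deviations are base-invariant. The trade-off line is defined by wild-type
enzymes only, and engineered mutants are scored by
`deviation_from_line()` — positive deviations mean more activity than the
wild-type trade-off allows at that stability, the signature of a mutant
escaping the trade-off. Published correlation coefficients for such plots
depend on figure-only coordinates, so the package validates this module by
construction (collinear data, known-line recovery, residual identities)
rather than against literature values.

## The synthetic generator, and what passing tests mean

`enzyme_truth()` fixes an idealised enzyme: activation enthalpy/entropy
(Eyring law for $k_{cat}(T)$), binding enthalpy/entropy (van't Hoff law
for $K_m(T)$, association convention), melting midpoint, van't Hoff
unfolding enthalpy and four baseline coefficients.
`truth_preset("thermophile-like")` and `"mesophile-like"` are calibrated
at load time from the shipped kinetic constants of TtIPMDH and EcIPMDH
(anchored exactly at 25 °C, enthalpies from the three printed
temperatures), so the generator's defaults *are* the study conditions of
the shipped tables; their unfolding parameters ($T_m$ 88 and 63 °C,
$\Delta H_{vH}$ 600 and 450 kJ/mol, CD-scale baselines around −16 mdeg)
are typical literature values for a thermophilic versus mesophilic
homodimer of this size, chosen once.

Noise is multiplicative Gaussian on velocities and ellipticities
(default studies use 1%): velocities span orders of magnitude across
temperatures, so a relative error model is the sensible default where no
error model is reported. Seeded generation is bit-reproducible.

Toy structures (`make_toy_structure()`) place each residue as a backbone
plus one side-chain pseudo-atom on a ray pointing away from the ligand
clusters, solving the placement by 1-d root finding so the minimum
heavy-atom distance to the ligand set equals the target to 0.01 Å; the
achieved distance is verified and clashes are errors. This gives exact
control of the quantity the shell rules consume while keeping fixtures
human-readable.

What the generator does *not* emulate: correlated/heteroscedastic
instrument noise, substrate inhibition or bi-substrate kinetics, curved
Arrhenius plots ($\Delta C_p^\ddagger \ne 0$), irreversible or aggregating
melts, and real side-chain geometry. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated models, not
robustness to every pathology of real data.

## Problem sizes and numerical choices

The recovery suites use 8-concentration titrations spanning
$0.25$–$32\times K_m$ at $10^{-8}$ M enzyme, four temperatures
(25/40/55/70 °C), 100 noise seeds at 1% noise, and 0.5 °C melt grids from
60–100 °C — sizes at which the estimators' sampling error is far smaller
than the acceptance tolerances while a full run of the suite stays
interactive. Noiseless round-trips are asserted to six or more significant
digits; Arrhenius recovery of a known activation enthalpy tolerates
0.5 kJ/mol of curvature from the $T$ prefactor (the van't Hoff line is
exactly linear by construction, so it is recovered to machine precision).
Ties and degenerate inputs: identical alignment columns are never
candidates; empty candidate sets give empty design lists; `relative_table`
requires a positive reference; regression helpers refuse a single
temperature and warn at two.

## Limitations

* The energy profiles inherit every limitation of transition-state theory
  with a transmission coefficient of 1; absolute barrier heights should be
  read comparatively.
* $\Delta H$ estimates from three temperatures carry the usual small-n
  regression fragility; the functions report $r^2$ and slope so users can
  judge.
* The melt model assumes reversible two-state unfolding; for irreversible
  melts the fitted $\Delta H_{vH}$ is an apparent value and only the
  midpoint is meaningful (use the derivative method there).
* `run_pipeline()`'s synthetic mode exercises every stage end-to-end but
  is a demonstration harness, not a substitute for running the individual
  fitters on real data.
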