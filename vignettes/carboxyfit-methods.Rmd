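---
title: "Models and methods in carboxyfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in carboxyfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carboxyfit)
```

# The problem

Transplastomic tobacco lines expressing a cyanobacterial Form-1A Rubisco —
free, or co-expressed with shell proteins so that carboxysomes assemble in
the chloroplast stroma — are a stepping stone toward installing a bacterial
CO₂-concentrating mechanism in a C3 crop. Their phenotype is extreme: about
a tenth of the wild-type Rubisco content, an enzyme with high turnover but
a CO₂ affinity an order of magnitude poorer, and consequently growth only
at elevated CO₂. Interpreting such plants requires a consistent chain from
in vitro enzyme assays, through unit conventions, to a leaf-level
assimilation model and its inversion, plus morphometry of the assembled
particles. `carboxyfit` implements that chain.

# Unit conventions

Enzyme assays measure dissolved CO₂ (µM); leaf gas exchange measures
partial pressures (µbar). The two are linked by Henry's law at 25 °C with
the conventional CO₂ solubility of 0.0334 M bar⁻¹, so that
µbar × (M bar⁻¹) = µM directly. The Rubisco specificity factor
$S_{C/O}$ carries the same duality: its molar basis (M M⁻¹) and pressure
basis (bar bar⁻¹) differ by the CO₂/O₂ solubility ratio. No O₂ solubility
is part of the measurement convention, so the package adopts
0.001259 M bar⁻¹, the 25 °C literature value; the implied ratio of 26.53
reproduces the dual-basis specificity pairs in the packaged parameter sets
to within 1.5%, and the constant is configurable through
`gas_conditions()`. All interfaces accept mbar and %(v/v) (2% v/v ≡ 20 mbar
at 1 bar total) and convert on ingest; all internal model math is in µbar.

A small residual discrepancy is expected for one packaged pair
(55 M M⁻¹ ↔ 1445 bar bar⁻¹, where the default ratio gives 1459): the
pressure-basis value was evidently derived from an unrounded molar mean.
The package converts from the rounded molar value and documents the ~1%
slack rather than back-inferring hidden digits.

# Rubisco kinetics

`fit_michaelis_menten()` estimates $(V_{max}, K_m)$ of
$v = V_{max} S/(K_m+S)$ by Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) with the analytic Jacobian. Starting values come
from a Hanes–Woolf linearization ($S/v$ on $S$); four further starts
jittered uniformly within ±50% (fixed seed 101) make the fit robust on
small noisy designs such as the 8-point, 30–440 µM carboxylation grid.
Standard errors are asymptotic, from the Jacobian at the optimum. A fit
that fails to converge raises an error carrying the best attempt rather
than returning silently.

Derived quantities are deliberately minimal algebra kept in one place:
$k_{cat} = V_{max}/E_{sites}$; $K_O$ from paired Michaelis constants under
N₂ and 21% O₂ via the competitive model $K_C^{app} = K_C(1 + O/K_O)$ (the
no-inhibition case returns `Inf` as an explicit sentinel); and $S_{C/O}$
from the labelled-product ratio of a specificity assay. For the latter the
conversion from a 3-PGA/2-PG signal ratio to the velocity ratio $v_c/v_o$
depends on product stoichiometry, which the assay description leaves
implicit; the package exposes `stoichiometry_mode` with default
"2PGA+1PGA/1PG" (carboxylation → 2 PGA; oxygenation → 1 PGA + 1 2-PG, so
$v_c/v_o = (R-1)/2$) and a "direct" alternative, rather than hard-coding a
guess. Activation-state treatments (pre-activation, carbonic-anhydrase
inhibitors) are wet-lab conditions and appear only as metadata tags.

Rates may be supplied per leaf area or per site; when a site content is
attached the per-replicate series is fitted first and site-normalization
applied afterwards, i.e. per-replicate-then-average, since the alternative
ordering is indistinguishable for the packaged summaries.

# The leaf assimilation model

Net assimilation is the minimum of two limiting rates:

$$A_c = \frac{k_{cat} E\,(C_c - \Gamma^*)}{C_c + K_C^{21\%O_2}} - R_d,
\qquad
A_j = \frac{(C_c - \Gamma^*)\,J}{4\,(C_c + O/S_{C/O})} - R_d,
\qquad \Gamma^* = \frac{0.5\,O}{S_{C/O}}.$$

The working constants are $R_d = 1$ µmol m⁻² s⁻¹, $J = 140$ µmol m⁻² s⁻¹
and $O = 200$ mbar at 25 °C, with measured $C_i$ standing in for $C_c$ (no
mesophyll-conductance term; the curve object records which was supplied).
The electron-transport constant is called $J$ throughout; source
descriptions sometimes label the same 140 µmol m⁻² s⁻¹ figure $J_{max}$,
and the package treats the two as one constant in $A_j$. There is no TPU
limitation and no temperature response — the model is used strictly at
25 °C.

The CO₂ compensation point on the Rubisco-limited branch has the closed
form

$$\Gamma = \frac{V_{cmax}\Gamma^* + R_d K_C}{V_{cmax} - R_d},
\qquad V_{cmax} = k_{cat}E,$$

finite only when $V_{cmax} > R_d$. `compensation_point()` evaluates the
closed form and checks which branch is operative at the root; for every
packaged parameter set the Rubisco branch limits there (low-$C_c$
assimilation at these parameterizations is far below $J/4$), and if a
parameter combination ever makes the electron branch operative the
function warns and returns the bracketed numeric root of the full minimum
model instead. The test suite verifies closed form against bisection to
10⁻⁶ µbar across a sweep of $k_{cat} \in [1,12]$, $E \in [1,30]$,
$K_C \in [300, 10000]$ µbar, $S_{C/O} \in [1000,3000]$.

With the packaged parameters this machinery yields Γ ≈ 56 µbar for
wild-type tobacco and ≈ 493 µbar for the CyLS line — the computed values
the acceptance tests compare against their published counterparts (55 ± 1
and 503 ± 69 µbar).

# Inversion

`fit_leaf_parameters()` minimizes
$\sum_i (A_i^{obs} - \min(A_c, A_j)(C_{c,i}))^2$ over a declared free set
⊆ {E, kcat}. The minimum is evaluated exactly — no soft-min smoothing —
because the phenotype predictions use the literal kink; the optimizer is
therefore derivative-free: golden-section/parabolic search
(`stats::optimize`, tolerance 10⁻¹⁰) for one free parameter, Nelder–Mead
with five seeded starts (seed 202) for two. Default bounds are
E ∈ [0.01, 50] µmol sites m⁻² and kcat ∈ [0.1, 20] s⁻¹ — generous brackets
around the physiological range. Standard errors come from a central-
difference Jacobian of the model at the optimum.

E and kcat enter the model only through their product $V_{cmax}$ (and the
electron branch through neither), so a single curve can never separate
them: the joint fit always warns, and when the curve is Rubisco-limited at
every point it aborts with an unidentifiability error instead of
returning an arbitrary point on the ridge. In the low-$C_c$ regime the
question of whether fits should use the Rubisco branch alone or the full
minimum is immaterial at these parameter values — $A_j$ never limits
there — and the package always uses the full minimum.

Because no raw curve data are published for these lines, the reproduction
of the fitted site contents (1.8 and 1.7 µmol sites m⁻²) and the
leaf-disc turnover estimate (6.46 s⁻¹) is posed as synthetic parameter
recovery: generate curves at the published fitted value under the stated
constants, refit, and require the ensemble mean to sit within Monte-Carlo
error of the generating value. That demonstrates the estimator is
consistent and unbiased under the model's own assumptions; it cannot
validate the model against instrument artifacts (leaks, Rubisco
deactivation at low CO₂) that the real measurements face.

# Morphometry

Elongated rods — the aberrant morphology of incompletely closed shells —
are defined by width < 75 nm combined with "disproportionate" length. The
aspect-ratio floor that operationalizes the latter is set to 2.0
(configurable): observed rods average about 7:1 and intact carboxysomes
1:1, so any threshold in (1.5, 5) yields the same partition of realistic
data. Width/length are canonicalized (length ≥ width) so classification is
invariant to column order. Proportions are reported both exactly and
rounded to whole percent, the convention used for such counts; counts are
always retained.

Size-distribution modes mimic nanoparticle-tracking reporting: each
replicate's mode is the argmax of a Gaussian-kernel density (Silverman's
rule bandwidth) on a 0.5 nm grid — the instrument's internal algorithm is
proprietary, so a standard KDE is used — and the reported value is the
mean of replicate modes ± s.e.m. No correction is applied for the
geometry of random thin sections, which under-detects rods in situ; the
section-based proportion is therefore reported as observed.

# Synthetic data

The generators define the study conditions for every test:

* **Assays**: exact Michaelis–Menten rates on an 8-point geometric grid
  spanning the documented ranges (30–440 µM CO₂, 10–800 µM RuBP), with
  multiplicative Gaussian noise (default CV 5%, a typical radiolabel assay
  precision).
* **Curves**: the minimum model evaluated on a 12-point C_i grid
  (50–1500 µbar, the attached-leaf measurement window) with additive
  Gaussian noise of s.d. 0.25 µmol m⁻² s⁻¹ — a free knob chosen to
  resemble attached-leaf scatter, explicitly not a measured value. MIMS
  mode extends the grid to 20 mbar, the leaf-disc instrument's range.
* **Particles**: a lognormal isometric population parameterized by its
  target mode (100.3 nm, shape 0.08) plus a rod population with
  width ~ N(59, 5²) and length ~ N(437, 190²) nm truncated positive by
  resampling; rod fraction per-particle Bernoulli. Tracking replicates add
  a 6% between-replicate location jitter representing independent
  preparations, chosen so the s.e.m. of the mean mode over 19 replicates
  is of order 1.5 nm, the precision at which such modes are customarily
  reported.

All generators take an integer seed, restore the caller's RNG state, and
are bit-reproducible on a given platform. What passing tests show is that
the pipeline recovers what it assumes — noise is Gaussian, the model is
the generator. Real data add drift, leak artifacts and progressive enzyme
deactivation at low CO₂, none of which are simulated.

# Numerical choices and problem sizes

Tolerances: unit round trips and algebraic identities are tested to
10⁻¹²; closed-form vs numeric compensation points to 10⁻⁶ µbar; noiseless
fit recovery to 10⁻⁶ relative. Monte-Carlo checks use 200-replicate
ensembles (curves or assays) with acceptance at 2–3 Monte-Carlo standard
errors — sizes chosen to make bias detectable at the few-percent level
while keeping the full suite interactive (a few minutes on one CPU).
Degenerate inputs fail loudly: empty batches warn and return empty
tables, per-item failures in batch reports are recorded without aborting,
and sentinel infinities (K_O with no detectable inhibition) are explicit.

# Limitations

The model omits mesophyll conductance, TPU limitation and temperature
response by design. The O₂ solubility and the product stoichiometry of
the specificity assay are conventions adopted here, not measured inputs.
Synthetic-recovery results certify the estimators, not the biology; and
the packaged parameter sets are rounded published summaries, so derived
quantities carry their rounding (visible as the ~1% specificity-basis
slack and the 493-vs-503 µbar compensation-point offset).
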