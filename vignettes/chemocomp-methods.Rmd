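---
title: "Models and methods behind chemocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chemocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemocomp)
library(dplyr)
```

chemocomp implements the quantitative chain used to analyse chemostat
competition experiments between two ciliate consumers (*Euplotes
octocarinatus* and clones of *Coleps hirtus*) sharing two microalgal prey
(*Cryptomonas* sp., "Cry", and *Navicula pelliculosa*, "Nav") and the
accompanying bacteria, under nitrogen limitation and continuous dilution.
This vignette is the package's own account of the models, the parameters
that matter, the numerical choices, and the limits of what the bundled
synthetic-data generator can and cannot show.

## Allometric carbon conversion

All biomass bookkeeping is done in carbon units. A taxon's carbon content
per cell follows an allometric law

$$C\,[\mathrm{pg}] = m \cdot a \cdot V^{\,b},$$

with $V$ the mean cell volume in µm³. The multiplier $m$ (default 1) houses
laws stated on another currency first; the bacterial law uses $m = 0.5$ for
the dry-weight-to-carbon step ($C = 0.5\,DW$). The derived carbon density
$C/V$ is stored at full precision; rounding to the 2–3 significant figures
conversion factors are conventionally reported with happens only at
formatting time, so no rounding error compounds downstream.

The bundled trait table carries the study system's values: Cry
($V = 664$ µm³, $a = 0.216$, $b = 0.939$, density 0.145 pg C/µm³), Nav
($V = 100$, $a = 0.288$, $b = 0.811$, density 0.121), ciliates (linear law
$0.14 \cdot V$) and bacteria ($V = 0.05$, $0.5 \cdot 0.435 \cdot V^{0.86}$,
density 0.33). Maximum ingestion rates measured in prey cells per ciliate
per day convert to pg C per ciliate per day by multiplying with the prey's
carbon per cell; `diet_share()` turns per-prey carbon rates into diet
fractions.

```{r}
profs <- taxon_profiles()
carbon_per_cell(664, allometric_law(0.216, 0.939))
diet_share(c(Cry = imax_to_carbon(18.6, profs$Cry),
             Nav = imax_to_carbon(12.1, profs$Nav)))
```

## Grazing and ingestion estimation

Bottle grazing experiments pair an ungrazed control with a grazed bottle.
The estimators are the standard Frost (1972) form with the
Heinbokel-style time-averaged grazer correction:

* control growth coefficient $k = \ln(C^*_2/C^*_1)/T$;
* grazing coefficient $g = k - \ln(C_2/C_1)/T$;
* time-averaged prey density
  $\bar{C}_p = C_1\,(e^{(k-g)T} - 1)/((k-g)T)$;
* time-averaged grazer density $\bar{N} = (N_2 - N_1)/(\ln N_2 - \ln N_1)$
  (the logarithmic mean, shared with `time_averaged_density()`);
* clearance $F = g/\bar{N}$ and ingestion $I = F \cdot \bar{C}_p$.

Negative $g$ (grazed bottle outgrowing its control) is reported and
flagged, never clamped; such bottles are excluded from functional-response
fits by default because negative ingestion has no mechanistic reading and
destabilises the fit.

`fit_functional_response()` fits the Michaelis–Menten response
$I(C) = I_{\max} C/(K + C)$ by nonlinear least squares
(Levenberg–Marquardt), initialised from a reciprocal (Lineweaver–Burk)
regression, with $K$ bounded to $(0, 10 \cdot \max C]$. Where the
Levenberg–Marquardt step encounters a singular gradient (noisy, nearly flat
responses), a Nelder–Mead search on log-parameters minimising the same sum
of squares takes over; the `converged` flag reports whichever route ran.
The package supports both ways of obtaining $I_{\max}$: the fit across
densities (default), or reading ingestion at a single saturating density —
`grazing_rates()` on one saturating bottle gives the latter directly.

Degenerate-limit handling: the $k \to g$ limit of $\bar{C}_p$ and the
$N_2 \to N_1$ limit of the logarithmic mean switch to their analytic limits
below an absolute tolerance of $10^{-9}$ on the exponent/log-difference.

## Censored population statistics

Counts below a taxon's detection limit are substituted by half the limit
and flagged (`censored`), never silently imputed: for ciliates counted in a
2-ml subsample the limit is 0.5 cells/ml and the substitute 0.25 cells/ml,
which in carbon units puts the floor at $10^{3.3}$ pg C/ml for *Euplotes*
and $10^{2.8}$ for *Coleps*. The policy is applied to any observation
strictly below the limit (zero counts included), which is how a continuous
latent state must be censored and subsumes the zero-count convention.

Net growth rate between two observations is the two-point log-linear rate
$r = (\ln B_2 - \ln B_1)/(t_2 - t_1)$; `growth_rates()` applies it to the
first and last uncensored points inside a window (default days 0–5, the
initial growth phase, configurable). Multi-point phase rates
(`phase_rate()`) use the OLS slope of $\ln B$ versus time and require at
least three uncensored points; both conventions are deliberate and
documented rather than interchangeable. The population filtration rate is
$F = I_{\max} \cdot \bar{C}$ with $\bar{C}$ the logarithmic-mean density
over the window; `rate_table()` reports it as log10 and flags windows with
negative mean growth (lag phases), since inactive ciliates need not filter
at $I_{\max}$ — the flag is reported rather than the value suppressed.

The competition response variable is the log biomass ratio
$\log_{10}(\text{Coleps BM}/\text{Euplotes BM})$; `log_ratio_table()`
emits the tidy (day, treatment, replicate, response) table ready for any
mixed-model ANOVA tool. The inference itself is out of scope here.

## The microbial-loop carbon budget

At stationary phase the dominant alga's net primary production only
compensates washout, $\mathrm{NPP} = \delta B_N$. With a fraction $f$ of
gross primary production exuded, $E_A = \frac{f}{1-f}\,\mathrm{NPP}$.
Bacteria consume exudates plus the carbon ciliates excrete after grazing
them, so at equilibrium production satisfies

$$P_B = e_B\left(E_A + (1 - e_C)P_B - D\right), \qquad D = \delta B,$$

with closed form

$$P_B = \frac{e_B (E_A - D)}{1 - e_B(1 - e_C)}.$$

The same number is the limit of the production → consumption → partial
excretion cycle summed as a geometric series with ratio $e_B(1-e_C)$;
`bacterial_production_iterative()` keeps that recursion as an independent
oracle, and the two agree to $10^{-12}$ relative across the admissible
parameter space ($e_B(1-e_C) < 1$, enforced at construction). Defaults are
$e_B = e_C = 0.5$ (so $P_B = \tfrac{2}{3}(E_A - D)$ exactly),
$\delta = 0.1\,d^{-1}$, consumer gross growth efficiency 25% and maximum
growth rate 0.4 d⁻¹, giving a maximum consumer demand of $1.6\,B_E$ per
day.

Negative $P_B$ (exudation below bacterial washout) is returned flagged
rather than clamped: this preserves the strict monotonicity of
$f \mapsto P_B$, so `critical_exudation()` can invert it in closed form;
the round trip through `bacterial_production()` is exact to $10^{-10}$.
"Maximal amount the consumer can ingest" is interpreted as
$\mu_{\max}/GE \cdot B_E$ (the intake sustaining maximum growth at the
stated efficiency); the washout-compensating intake $\delta/GE \cdot B_E$
is provided as a third documented `kind`. Extra carbon sources (e.g. dying
diatom biomass) are not modelled separately: `bacterial_production()` takes
the total flux $E_A$ as an argument, so any additive source can be included
by adding it there. The diagnostic `implied_growth_rate()` returns
$\ln(1 + P/B)$; nothing downstream depends on it, because no stated
convention links the two quantities.

Reproducing the study's reported bound P/B ≤ 2.6 d⁻¹ requires the deposited
final-day counts; the machinery (`pb_ratio()`, `budget_sweep()`) accepts
them as an ordinary `community_state` but the package asserts nothing about
numbers it cannot compute from bundled inputs.

## The synthetic community generator

`sim_config()`/`simulate_chemostat()` provide a seeded, deterministic
chemostat community emulating the study conditions: dilution 0.1 d⁻¹,
120 µmol N/L inflow, 33 days sampled every second day, initial ciliate and
algal biovolumes 1.3×10⁶ and 14.4×10⁶ µm³/ml split equally among the taxa
present. Mechanisms:

* **Algae**: Monod growth on dissolved N, $\mu_i = \mu_{\max,i} N/(K_{N,i}+N)$,
  with a fraction $f$ of gross production exuded as DOC. Defaults
  $\mu_{\max} = 0.6$ (Cry) and 1.1 d⁻¹ (Nav), $K_N = 2.0$ and 0.8 µmol/L:
  Nav's lower $R^* = \delta K_N/(\mu_{\max}-\delta)$ makes it the better
  nitrogen competitor, as observed.
* **Grazing**: multi-prey type-II response; consumer $c$'s intake of prey
  $i$ is $I_{\max,ci}\,P_i/(K_c + \sum_j P_j)$ in carbon-specific units, so
  saturated intake on a single prey matches the measured per-prey
  $I_{\max}$ from the trait table. Half-saturation 2×10⁵ pg C/ml (about
  2000 Cry cells/ml).
* **The filter feeder** additionally takes bacteria at a low
  carbon-specific rate (0.5 d⁻¹) and assimilation (0.25 — bacteria are poor
  food), and starts with a 9-day lag of zero ingestion and growth, the
  simplest mechanism consistent with the observed lag phase.
* **Food-quality decline**: once dissolved N falls below 2 µmol/L,
  assimilation on Nav is multiplied by `nav_quality_decline` (default 0:
  N-starved diatoms support no consumer growth; their ingested carbon is
  excreted to DOC).
* **Bacteria** grow on DOC with efficiency 0.5, Monod in both DOC and N.
* **Nitrogen closure**: every pool carries a fixed N quota per unit carbon;
  ingested N not built into consumer biomass is remineralised immediately,
  exudates and excreta are N-free DOC, and respiration releases no N. Total
  N therefore obeys $dT/dt = \delta(N_{in} - T)$ exactly, and the
  integrated trajectory is tested against that closed form to $10^{-6}$
  relative.

The quotas are *effective* values (5×10⁻⁵ µmol N L⁻¹ per pg C ml⁻¹ for
eukaryotes, 10⁻⁴ for bacteria), chosen once so that the 120 µmol N/L inflow
supports standing algal stocks of the order the experiment reports
(~2×10⁶ pg C/ml). Literal Redfield stoichiometry would cap biomass two
orders of magnitude below the experimental inoculum — the real populations
were inoculated N-rich and ran far above Redfield C:N under severe
N-limitation, which a fixed-quota model can only represent through an
effective quota.

Integration is fixed-step 4th-order Runge–Kutta at 0.01 d (via deSolve):
reproducibility across platforms is worth more here than adaptive-step
speed, and the nitrogen-conservation test bounds the global error.

`observe()` emulates sampling: every second day, per replicate, the latent
carbon pools are multiplied by mean-one lognormal noise (CV configurable,
default 10%), converted to abundances through the taxon profiles, and
censored at the detection limits. Lognormal noise is the natural choice for
positive, multiplicative count error. All randomness flows from one seed;
identical config and seed give byte-identical output.

`generate_bottle_experiment()` forward-simulates the Frost bottle dynamics
with a constant grazing coefficient, either imposed directly (for exact
round-trips) or derived from a Michaelis–Menten clearance at the realised
mean prey density by fixed-point iteration, so that the estimated ingestion
equals the functional response evaluated at $\bar{C}_p$.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: demographic stochasticity (noise is observational
only), flexible stoichiometry and the physiology behind food-quality
decline (imposed as a threshold switch), the unexplained synchronized crash
of one clone (no mortality-pulse mechanism is included, since the source
observations identify none; a crash can be emulated by splitting a run and
zeroing a pool), benthic/wall populations, and any fit of the dynamic model
to the real deposited time series.

### Problem sizes used in the checks

The bundled tests run the default 33-day community at step 0.01 d, one
300-day grazer-free run for the analytic steady-state comparison, one
150-day washout run, 30 observation-noise draws for the growth-rate
coverage check, and 200 replicate fits of 8-point functional responses.
Washout deserves a note: decline toward the detection limit is exponential
at roughly $\delta - \mu$, so from experiment-scale inocula
(10⁵–10⁶ pg C/ml, 50–500× the detection limits) crossing the limit takes
several washout time scales; the check therefore runs 150 days rather than
the experiment's 33.

## The marker assay, in silico

The computable parts of the clone-discrimination assay are reproduced:
IUPAC-aware reverse complement, primer-site search (primer ambiguity codes
match their expansions; template letters are literal, appropriate for
primers designed on known templates; default zero mismatches for the same
reason), amplicon prediction pairing forward-strand forward-primer sites
with minus-strand reverse-primer sites within 5 kb, and pairwise divergence
as the p-distance over gap-free columns of a global alignment (match +1,
mismatch −1, gap −2 — stated defaults, exposed as arguments, since no
alignment convention is fixed by the assay).

Coordinates are 1-based inclusive throughout, the R/Bioconductor
convention, so `end - start + 1 = length` and amplicon lengths include both
primer footprints — the convention under which Sanger-verified product
sizes are reported. The bundled primer FASTA carries ITS F/R, 3770F, 2104R
and 3770F with the 40-nt GC clamp. The deposited clone sequences themselves
are *not* bundled (they live in GenBank under MW929305, MW929304 and
MW929302); with those sequences downloaded, `in_silico_pcr()` predicts the
~510–527 bp ITS products directly. The test suite instead forces a 143 bp
product from a constructed synthetic template (21 nt forward primer +
100 N spacer + 22 nt reverse-complemented reverse primer).

## Known limitations

* The generator's trajectories match the study qualitatively (Cry declines
  below detection while Nav rises and plateaus; N is depleted below
  1.7 µmol/L; bacteria stay abundant), not quantitatively; no parameter
  was fitted to the deposited data.
* Replicated treatment tables come from observation noise around one latent
  trajectory; real replicate chemostats diverge dynamically.
* `rate_table()`'s filtration rates assume grazing at $I_{\max}$ throughout
  the window, an upper bound that overestimates F for populations that
  crashed mid-window.
* Divergence values depend on the alignment scoring; the assay's published
  intraspecific range (2.7–4.9%) was obtained with unstated alignment
  settings, so agreement should be read as approximate.
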