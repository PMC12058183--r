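---
title: "Dynamic polygenic models of insecticide-resistance management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic polygenic models of insecticide-resistance management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irmsim)
```

# The problem

Insecticide-treated nets (ITNs) and indoor residual spraying (IRS) drive
strong selection for insecticide resistance in malaria vectors.
Resistance-management (IRM) strategies — deploying insecticides in
sequences, rotations, mixtures, household micro-mosaics or ITN+IRS
combinations — are evaluated almost exclusively with computational models,
and most of those models assume resistance is monogenic. Genome-wide
association studies suggest mosquito resistance is substantially polygenic.
`irmsim` implements a dynamic quantitative-genetics simulator in which
resistance to each insecticide is a normally distributed polygenic trait,
and the strength of selection is recomputed every generation from the
current resistance level, the insecticide's decaying efficacy, and how
mosquitoes encounter deployments over space and over their gonotrophic
cycles.

# The resistance scale

Resistance to insecticide $i$ is quantified by a polygenic resistance score
(PRS) $z_I$, an arbitrary quantitative scale. A Hill curve (the
Michaelis–Menten variant with exponent $n = 1$) converts a PRS to the
proportion surviving a standardised discriminating-dose bioassay:

$$K^B_i = K_{max}\frac{z_I^n}{z_{50} + z_I^n},$$

with $K_{max} = 1$ and, throughout the package's defaults, $z_{50} = 900$:
a PRS of 100 then corresponds to 10% bioassay survival, the conventional
"confirmed resistance" criterion used as the withdrawal threshold. Scores
at or below zero denote fully susceptible mosquitoes (zero bioassay
survival). Bioassay survival is converted to survival of a real field
encounter through a regression estimated from experimental-hut data,
modulated by the insecticide's current efficacy $\omega$:

$$K^F_i = (\varphi_1 K^B_i + \varphi_2)^{\omega},$$

with $\varphi_1 = 0.48$, $\varphi_2 = 0.15$. The efficacy enters as an
exponent: at full efficacy ($\omega = 1$) the map is the plain regression;
a fully decayed insecticide ($\omega = 0$) kills nothing (survival 1); and
over-spraying ($\omega > 1$) depresses survival at every resistance level.
A multiplicative reading of the efficacy term cannot reproduce either
limit, which is why the power form is used.

Efficacy itself decays after deployment in two phases, a slow basal phase
up to a longevity threshold $\tau_b$ (generations since deployment) and a
rapid phase after it:

$$\omega_\tau = \omega_0\, e^{-\tau^{p}\,\delta_b}\ (\tau \le \tau_b),
\qquad
\omega_\tau = \omega_0\, e^{-\tau_b^{p}\,\delta_b}\,
  e^{-(\tau-\tau_b)^{p}\,\delta_r}\ (\tau > \tau_b).$$

The exponent $p$ is configurable (`decay_profile(exponent = )`). The
default is $p = 1$: with the reference rates $\delta_b = 0.015$,
$\delta_r = 0.08$, $\tau_b = 20$, simple exponential decay loses roughly a
quarter of the initial efficacy over the two-year basal phase, which is
what a "slow basal decay, then rapid degradation" profile describes. With
$p = 2$ the same rates would annihilate the insecticide within 15
generations, making the basal phase the fast one and erasing any
difference between deployment strategies once decay is switched on; we
therefore treat the quadratic reading as a typographical artefact and keep
it available as an option rather than the default. `omega0` doubles as the
dose: half-dose mixture constituents are modelled with $\omega_0 = 0.5$.

The PRS standard deviation $\sigma_I$ is either fixed (default 30, a
deliberately moderate spread for low-resistance scenarios; the package's
sensitivity sweep varies it from 5 to 100) or linear in the mean,
$\sigma_I = \varphi_3 \bar z_I + \varphi_4$, evaluated separately per site.
No field-validated values for $\varphi_3, \varphi_4$ are shipped — the
defaults (0.1, 20) are illustrative placeholders and the linear mode should
be parameterised from bioassay data before quantitative use.

# Selection within a generation

Each generation a cohort hatches with PRS $\sim N(\bar z_I, \sigma_I)$,
split 1:1 between sexes. A fraction $x$ of females (and $mx$ of males,
$m$ being the male:female exposure ratio) encounters the deployed
insecticide(s). Survivors of the encounter and those who avoided it form
the breeding parents; the insecticide selection differential is the
difference between the parental mean and the hatching mean, per sex. Two
mechanisms for who survives the encounter are implemented.

**Truncation selection** (`polytruncate` branch): only mosquitoes above a
threshold survive. If the population mean field survival is $\bar K^F$,
the survivors are the top $\bar K^F$ of the distribution and their mean
exceeds the population mean by $\sigma_I\,\phi(q)/\bar K^F$, where $q$ is
the standard-normal point with upper-tail mass $\bar K^F$ — the classical
intensity-of-selection formula. Survivor counts scale the exposed numbers
by $\bar K^F$ (and by the mixture partner's mean survival, since mixture
contact is simultaneous and survival multiplicative).

**Probabilistic selection** (`polysmooth` branch): each individual survives
with its own field survival probability $K^F_i(z)$. The population is
discretised into a grid of PRS bins (mean ± 6σ, 2001 bins by default) with
per-sex frequency vectors; exposure and per-bin survival multiply the
frequencies, and survivor counts and means are sums over the grid. For
mixtures the partner insecticide enters as its population mean survival:
the model carries no individual-level correlation between the two traits,
so an individual's survival of the partner cannot depend on its focal-trait
score. A hard step-function survival recovers the truncation result as the
grid refines, which the test suite verifies.

Population mean survival ($\bar K^F$, also the mixture partner term) is by
convention evaluated at the population mean PRS, not as the expectation of
survival over the distribution; `mean_survival(mode = "integrated")`
offers the expectation for sensitivity analysis.

**Fitness costs** enter as a separate, non-positive selection differential
per sex: a fixed magnitude in PRS units when $\sigma_I$ is fixed, or a
fixed fraction of $\sigma_I$ when $\sigma_I$ tracks the mean. Costs are
applied with a negative sign — they reduce resistance — and in the refugia
and for undeployed insecticides they are the only selection acting.

**Response.** The between-generation change in the mean follows the
sex-specific Breeder's equation,
$R = h^2\,\tfrac{S_{\mathrm{f}} + S_{\mathrm{m}}}{2}\,\beta$, with $h^2$ the trait
heritability and $\beta$ the exposure scaling factor (below). By default
$\beta$ rescales only the insecticide-selection component:

$$R = h^2\frac{S^S_{\mathrm{f}} + S^S_{\mathrm{m}}}{2}\beta
    + h^2\frac{S^\varphi_{\mathrm{f}} + S^\varphi_{\mathrm{m}}}{2}.$$

This is a deliberate design choice (`scenario(beta_scales_costs = )`).
$\beta$ exists to calibrate the uncertain strength of insecticide
selection — exposure, contact time, heritability — against an operational
timescale, whereas the fitness-cost differentials are specified directly on
the PRS scale. Because the calibrated $\beta$ of the probabilistic branch
is of order 10, letting it multiply the cost differentials (0.04–0.58 PRS
units in the standard operational ranges) would make costs dominate the
insecticide differential at low resistance across most of that range, and
resistance would simply never evolve there; the truncation branch, whose
raw differentials are an order of magnitude larger, would be almost
unaffected, and the two branches would disagree over half the parameter
space. Setting `beta_scales_costs = TRUE` restores the alternative
reading.

# The two-patch landscape

The world is an intervention site (a fraction $C$ of the population, where
insecticides are deployed) and an untreated refugia. Events in a
generation are ordered: selection, mating, dispersal, egg laying. After
selection and mating, per-trait responses update each site's mean —
deployed traits get the full selection-plus-cost response, undeployed
traits and the refugia get the cost-only response, and cross resistance
adds $\alpha_{\Gamma I} R_\Gamma$ for every *deployed* partner trait
$\Gamma$ ($\alpha$ a genetic correlation in $[-1, 1]$). Site means are
floored at zero: costs cannot push the mean PRS negative.

Dispersal then mixes the two means. With $\theta$ the proportion of
females dispersing, the exchange rates are $r_{Int} = \theta C$ (females
moving from the intervention site into the refugia) and
$r_{Ref} = (1-C)\theta$ (the reverse). The default update is

$$\bar z_{Int}'' = \bar z_{Int}'(1 - r_{Ref}) + \bar z_{Ref}'\,r_{Ref},
\qquad
\bar z_{Ref}'' = \bar z_{Ref}'(1 - r_{Int}) + \bar z_{Int}'\,r_{Int},$$

which is what global dispersal redistributed in proportion to patch size
yields: each site keeps $(1 - \text{immigrant rate})$ of its own mean, and
the weights sum to one identically. Two alternative modes are provided:
`"literal"` pairs $(1-r_{Int})$ with $r_{Ref}$ (and vice versa), exactly
as the source equations are printed; its weights sum to
$1 - \theta C + \theta(1-C)$, so away from $C = 0.5$ it contracts or
inflates both means every generation regardless of selection — at
$C = \theta = 0.9$ the intervention mean would lose 72% per generation,
which would prevent resistance from ever evolving across much of the
operational coverage/dispersal space. We read that pairing as a transposed
subscript and default to the conserving form; `"normalised"` rescales the
literal weights to sum to one. All three coincide at $C = 0.5$.

# Multiple gonotrophic cycles

A female needs a blood meal for every egg batch, so each ~3-day
gonotrophic cycle brings a fresh chance of encountering an insecticide.
Micro-mosaics and ITN+IRS combinations only make sense in this frame: a
mosquito surviving insecticide $i$ in one cycle may meet $j$ in the next
(a "temporal mixture"). The multi-cycle extension applies to the
probabilistic branch only — after the first round of selection the PRS
distribution is no longer normal, so the truncation formula has no valid
second application.

House-level deployment is described by coverages $c_i, c_j, c_{ij}$ (houses
with only $i$, only $j$, both; summing to one) and, within dual-treated
houses, sex-specific encounter splits $\Lambda_{i|ij}, \Lambda_{j|ij},
\Lambda_{ij|ij}$. Setting $c_i = 1$ recovers a monotherapy, $c_{ij} = 1$
with $\Lambda_{ij|ij} = 1$ a mixture, $c_{ij} = 0$ a micro-mosaic. Between
cycles a fraction $\rho = d^g$ of females survives natural (non-insecticidal)
mortality, with $d$ the daily survival and $g$ the cycle length in days
($d = 0.9, g = 3 \Rightarrow \rho = 0.729$).

Within a generation, the female frequency vector is carried across cycles
(the warped, post-selection distribution persists; a fresh normal is drawn
only at each new generation). Encounters with the focal product select per
bin; encounters with the partner product scale all bins by the partner's
mean survival; unexposed females pass through; and from the second cycle
on every term is multiplied by $\rho$ — so $\rho$ scales counts but never
within-cycle means. Survivor counts are computed as the sums of the
corresponding frequency components, which keeps the per-cycle bookkeeping
identity (parents = $i$-survivors + $j$-survivors + dual survivors +
unexposed) exact to machine precision and makes a one-cycle run reproduce
the single-generation probabilistic branch bit-for-bit.

Males get one round of selection, before mating, built as the male
analogue of the female first-cycle equations with exposure $mx$ and the
male encounter split; because females mate once, the male differential is
held constant across cycles. (The source's explicit male equations are in
supplementary material we could not consult; this operation is
reconstructed from the stated constraints and marked as such.) Each
cycle's response from the Breeder's equation is weighted by the number of
females laying eggs in that cycle, so later, more-resistant cycles
contribute less; the weighted total updates the next generation's mean.
Fitness costs enter once (they act mostly before or at the first cycle)
and are carried unchanged to every cycle. Insecticide decay is frozen
within a generation and advances between generations.

An optional reconstructed mode (`scenario(per_cycle_dispersal = TRUE)`)
mixes the female cohorts of the two sites after every cycle instead of
once per generation, using patch-size-weighted mixing of the frequency
vectors on a shared grid; it is off by default and reduces to the default
machinery when nobody disperses.

**Age profiles.** Because the cycle loop tracks how many females complete
each cycle, a single-generation snapshot (full coverage, no evolution)
yields the population's age distribution under an intervention, next to
the geometric no-intervention profile scaled to 100,000 females completing
their first cycle. Females surviving ≥ 4 cycles (≈ 10 days) proxy for
surviving the extrinsic incubation period of *Plasmodium falciparum* — the
fraction that can ever transmit malaria.

# Strategies and thresholds

Deployment decisions are taken at deployment-interval boundaries, at the
start of a generation, from the intervention-site female mean converted to
bioassay survival. An insecticide at or above the withdrawal threshold
(default 10%) is failed; a failed insecticide becomes eligible again only
below the return threshold (default 8%) — the hysteresis prevents
thrashing between the two levels. An insecticide crossing the threshold
mid-interval stays deployed until the next decision point (a strict
immediate-withdrawal mode is available and off by default). Whatever is
deployed at a decision point is freshly applied: its decay clock resets,
so efficacy is sawtooth-shaped over a long run.

* **sequence** — keep the current insecticide until it fails, then the
  next eligible one in arsenal order;
* **rotation** — switch to the next eligible insecticide (cyclic arsenal
  order) at every interval;
* **mixture** — deploy the first two insecticides together, at configured
  doses; the product requires both constituents, so it is unavailable once
  either is failed;
* **micromosaic** — deploy the pair as a household mosaic with a coverage
  split (default 50/50); availability as for mixtures;
* **combination** — ITN and IRS products with independent interval clocks
  (e.g. 3 years and 1 year); a failed product is withdrawn at its own next
  boundary and the deployment degrades to a monotherapy of the survivor;
* **continuous** — deploy the first insecticide indefinitely, ignoring
  thresholds (used for calibration and sensitivity runs).

A run ends when no insecticide is available at a decision point or at the
cap (500 generations ≈ 50 years at the default 10 generations per year);
the elapsed years are the strategy's operational lifespan. The
mixture/mosaic availability rule (either constituent failing retires the
product) is a package choice — the source only states that simulations end
when no insecticide is available.

# Calibration and experiments

**The exposure scaling factor.** A novel insecticide is conventionally
expected to survive about ten years of continuous deployment before
resistance reaches the 10% withdrawal threshold. `calibrate_beta()`
bisects on $\beta$ until the first-crossing generation of a reference
scenario — fixed $\sigma = 30$, starting mean PRS 0, no decay, no fitness
costs, exposure $x = m = 0.7$, heritability 0.2 — matches the
100-generation target within one generation. The reference landscape is
the representative operational setting (coverage 0.7, dispersal 0.3)
rather than an isolated site, so the calibrated factor already absorbs the
susceptible influx from the refugia that every strategy run experiences;
calibrating against an isolated site produces a $\beta$ too weak for
resistance to evolve under realistic dispersal. The crossing time is
monotone decreasing in $\beta$, so bisection is exact up to the integer
plateau. Each branch is calibrated separately (the truncation branch's raw
differentials are ~30-fold larger, and its calibrated $\beta$
correspondingly smaller).

**Parameter sweeps.** `lhs_sample()` draws Latin-hypercube samples
(via the `lhs` package) over the standard operational ranges: coverage
0.1–0.9, dispersal 0.1–0.9, fitness costs 0.04–0.58 per sex, female
exposure 0.4–0.9, male exposure 0–1, heritability 0.05–0.3.
`compare_strategies()` runs each strategy on identical parameter sets and
scores pairwise wins, losses and draws by operational lifespan; runs in
which both strategies hit the cap are draws flagged *censored*, since
either might prove superior on a longer horizon.
`classify_agreement()` grades two branches' outcomes on the same sets into
full agreement / agreement / partial disagreement / full disagreement.
`sigma_sensitivity()` sweeps the fixed $\sigma$ from 5 to 100 under
continuous deployment at full coverage, and `showcase_feature_toggles()`
ranks five strategies under all eight on/off permutations of decay, cross
resistance and multiple cycles.

**What the reproductions show.** With calibrated $\beta$, the package
reproduces the qualitative behaviour expected of these models: full-dose
mixtures rank first on mean bioassay survival in every feature-toggle
permutation; over a 200-set Latin-hypercube sweep mixtures beat or draw
sequences and rotations in the overwhelming majority of sets, their
advantage grows with positive cross resistance, and the sequence-rotation
comparison flips with the sign of cross resistance (sequences ahead under
positive, rotations under negative). Time to the withdrawal threshold is
monotone non-increasing in $\sigma$ for every tested parameter set in both
branches. One comparison behaves differently here than reported for the
original models: in this implementation a 50/50 micro-mosaic already
matches or outperforms a rotation of the same two insecticides under a
single cycle, and adding cycles and natural mortality strengthens the
mosaic further — the direction of the multi-cycle shift reproduces, but
the single-cycle ordering does not, and we have not found a reading of the
published equations that produces it; the corresponding check in the test
suite documents the discrepancy rather than papering over it.

# Numerical choices and problem sizes

* PRS grid: hatching mean ± 6σ, 2001 bins by default. The discretised
  mean is accurate to ~10⁻¹⁵σ and doubling the bin count changes recovered
  means by < 10⁻⁸. Sweep-style tests and experiments use 501 bins (301 for
  the longest sweeps), which changes long-run trajectories imperceptibly
  but cuts runtime several-fold; exactness tests use the default grid.
* Test-suite problem sizes: the strategy-comparison sweep uses 200
  parameter sets at cross-resistance −0.3 and +0.3 with the full
  500-generation cap; the rotation-vs-mosaic comparison uses 200 sets at a
  150-generation horizon; the σ sweep uses 20 σ values × 5 parameter sets
  per branch; the truncation oracle uses 10⁶ Monte-Carlo draws.
* Calibration bisects on a multiplicative (log-scale) midpoint over an
  auto-expanding bracket, stopping when the crossing lands within one
  generation of the target.
* Degenerate cohorts (all exposed dead, or no parents) raise errors in the
  low-level operations; the simulation loop catches them, warns, and
  treats the generation as having only unexposed parents.
* Proportions are clamped to [0, 1] after the field-survival map; site
  means are floored at 0 after every response.

# Limitations

The model tracks population mean traits, not individuals or population
sizes: there is no density dependence, no explicit demography (the
age-profile snapshot is a survivorship calculation, not a dynamic age
structure), no linkage disequilibrium or individual-level correlation
between resistance traits, and no sub-lethal effects of exposure. The
synthetic scenarios the tests run are internally consistent — normal trait
distributions, error-free bioassays, fixed coverages — so passing tests
demonstrate the machinery computes the stated model correctly, not that
the model predicts any particular field outcome. Parameters with no
published estimates ($\varphi_3$, $\varphi_4$, the encounter splits
$\Lambda$) ship as documented placeholders.
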