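---
title: "Methods: size-spectrum communities and maximum nutrient yield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: size-spectrum communities and maximum nutrient yield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mnyield` asks a management question: if a multispecies fishery were managed
for the yield of a *nutrient* (calcium, iron, zinc, selenium, vitamins A and
D, omega-3) rather than for catch weight, would the optimal fishing pressure
differ, and in which direction? The package answers it three ways: by
simulation (yield curves from a dynamic multispecies size-spectrum model), by
optimisation (per-species fishing mortalities maximising one nutrient's
equilibrium yield under a no-collapse constraint), and by a data-facing
screening framework (evenness and fishing vulnerability of nutrient catches
in regional catch tables).

## The community model

The simulator is a trait-based multispecies size-spectrum model. Each species
$i$ is described by an abundance density $N_i(w)$ over body mass $w$ obeying

$$\frac{\partial N_i}{\partial t} + \frac{\partial (g_i N_i)}{\partial w}
  = -\mu_i N_i,$$

with a recruitment flux boundary condition at the offspring mass. All
individual rates scale allometrically:

* **Encounter and feeding.** A predator of mass $w$ searches volume
  $\gamma w^q$ and prefers prey a factor $\beta$ smaller, with lognormal
  width $\sigma$: $\varphi(w_p, w) = \exp[-\ln^2(w_p/(\beta w)) / 2\sigma^2]$.
  Encountered prey biomass (interaction-matrix-weighted fish plus background
  resource) saturates intake at $h w^n$, giving a feeding level
  $f = E_{enc}/(E_{enc} + h w^n) \in [0, 1]$.
* **Energy budget.** Assimilated intake $\alpha f h w^n$ pays standard
  metabolism $k_s w^p$ first; the non-negative remainder is split between
  somatic growth and reproduction by a maturity ogive
  $\psi(w) = [1 + (w/w_{mat})^{-10}]^{-1} (w/w_\infty)^{1-n}$, clamped to 1,
  so growth stops exactly at $w_\infty$.
* **Mortality.** Predation mortality integrates each predator's
  $(1-f)\gamma w^q N$ through the same kernel; a constant background
  mortality $\mu_{b,0} w_\infty^{n-1}$ and fishing mortality add to it.
* **Recruitment.** Egg production (reproductive output over twice the
  offspring mass, times an efficiency $\epsilon_{repro}$) is capped by a
  Beverton-Holt form $R = R_{max} R_{di}/(R_{max} + R_{di})$.
* **Resource.** A semi-chemostat background spectrum with capacity
  $\kappa w^{-\lambda}$ up to `w_res_max`, regenerating at
  $r_0 w^{n_r - 1}$.

Fishing mortality is $F_{g,i}(w) = S_{g,i}(w)\, Q_{g,i}\, E_g$ per gear:
a sigmoid trawl ogive on log mass ($S = [1+e^{-\text{slope}(\ln w - \ln
w_{50})}]^{-1}$), catchability $Q$, and relative effort $E$.

### Numerics

The default grid has 100 log-spaced mass bins from the smallest offspring
mass to the largest asymptotic mass, with the resource grid continuing three
decades below; the default step is $dt = 0.1$ yr. Each step is
operator-split: mortality is applied **exactly** as $e^{-\mu\, dt}$, growth
transport uses an implicit first-order upwind sweep (unconditionally stable),
and the resource relaxes exactly towards its frozen-rate equilibrium. The
exact mortality factor is deliberate: a semi-implicit decay $(1+\mu\,dt)^{-1}$
accumulates a ~13% error over 10 years at $\mu = 0.5\,\mathrm{yr}^{-1}$,
while the split scheme keeps pure-decay trajectories on $e^{-\mu t}$ to
machine precision — a property the test suite checks directly. The cost is a
first-order splitting error between growth and mortality, shared by standard
implementations of this model class.

Equilibrium is declared when the maximum relative biomass change per year
across species, averaged over a 10-year trailing window, falls below
$10^{-5}$ (default horizon 300 yr). Inner loops of the reference-point search
and optimiser use a relaxed tolerance ($10^{-4}$, 150 yr, 5-yr window), which
moves equilibrium yields by far less than the 1-2% tolerances those searches
are tested against.

## Reference points

`estimate_fmsy()` finds each species' fishing mortality at maximum
equilibrium yield *inside* the community: species are maximised one at a time
(coarse scan plus golden-section refinement) with all other species held at
their current estimates, iterating across species until the vector changes by
under 1% between rounds. `sweep_effort()` then fishes every species at
$E \times F_{MSY,i}$ for an effort grid $E = 0, 0.05, \dots, 4$, recording
equilibrium catches, nutrient yields (catch × concentration per 100 g ×
$10^4$, summed over species), community and fishable biomass, mean maximum
size, exploitation rate (total catch / total biomass) and stock-collapse
flags (biomass below 10% of unfished). The sweep truncates after the first
effort at which community biomass falls below 10% of unfished or more than
half the stocks are collapsed. `summarise_curve()` locates mMSY and each
nutrient's mMNY with a 3-point quadratic refinement of the grid argmax
(clamped to one grid step — a coarse grid alone cannot resolve ratios a few
percent from 1), and classifies each nutrient as overfished
($F_{mMNY} < F_{mMSY}$), underfished ($>$), or neutral within a 5% ratio
tolerance.

Both the effort-multiplier value and the exploitation rate at each reference
point are reported; ratios are taken on the multiplier axis, which is the
controlled variable.

## What the generic community is - and what it shows

`make_generic_community()` builds the standard study condition: 15
interacting species, asymptotic masses log-spaced from 10 g to 100 kg, one
trawl per species ($w_{50} = 0.05\,w_\infty$, $Q = 1$), all-ones interaction
matrix, and lognormal nutrient concentrations that by default load
*negatively* on size (small forage fish are the nutrient-dense ones, the
empirical pattern that makes nutrient and catch objectives diverge).
Life-history defaults follow trait-based conventions: $w_{mat} =
0.25\,w_\infty$, $n = p = 0.75$, $q = 0.8$, $\beta = 100$, $h = 40$,
$\alpha = 0.6$, critical feeding level 0.25, $R_{max} \propto
w_\infty^{-1.5}$. The remaining free scales ($\sigma = 2.2$,
$\mu_{b,0} = 2$, $\epsilon_{repro} = 0.002$, $R_{max}$ magnitude, resource
$r_0 = 10$ and `w_res_max` = 100 g) were chosen once so that the community
(a) coexists and converges to equilibrium under the default numerics, (b)
has substantial predation coupling rather than 15 de-facto independent
stocks, and (c) shows interior single-species yield maxima and stock
collapses within the scanned effort range — the qualitative features real
calibrated systems show.

A finding worth stating plainly: because the sweep scales each species by its
*self-consistent in-model* $F_{MSY}$, every species' own yield peaks near
$E = 1$ by construction, and mMNY/mMSY ratios on this symmetric community
stay within a few percent of 1. Large published ratios arise when the
reference $F_{MSY}$ values come from external assessments (and so differ from
the conditional in-model optima) or when the community has strongly
asymmetric trophic structure. The directional phenomenon is therefore
exercised on a purpose-built fixture.

`make_nutrient_loading_fixture()` is that fixture: one small, highly
productive forage species plus four piscivores whose preferred prey mass sits
on the forage adults (explicit chain interaction matrix; zooplankton-sized
resource so the piscivores genuinely depend on the forage stock). Loading a
nutrient on the forage species (highest $F_{MSY}$) yields
$F_{mMNY}/F_{mMSY} \approx 1.14$ — nutrient underfishing driven by predation
release — while loading it on the largest predator (lowest $F_{MSY}$) yields
$\approx 0.94$, nutrient overfishing. The same construction drives the
cross-check against the catch-composition framework below.

## The optimiser

`optimise_nutrient()` maximises one nutrient's equilibrium yield over the
per-species fishing mortality box $[0.01, 2]$ with L-BFGS-B (finite-difference
gradients, step $10^{-3}$). Evaluations that collapse any stock are penalised
smoothly — yield minus $M \sum_i \max(0, 0.1 - B_i/B_{0,i})$ with $M$ ten
times the baseline yield scale — because a hard discard would break the
quasi-Newton line search; the returned optimum is re-verified against the
hard constraint with no penalty, and only feasible optima are reported.
Multi-start (baseline policy plus a seeded Latin hypercube, default 5 starts)
guards against local maxima. For generic fixtures the baseline policy is
"every species at its $F_{MSY}$"; historic effort reconstructions, where
available, can be passed instead. Deltas against the baseline are plain
relative changes in nutrient yield, total catch and fishable biomass.

## The evenness-vulnerability framework

For tabular catch data (region × taxon × catch × intrinsic vulnerability
index 0-100), the framework computes, per region: Pielou's evenness
$J = (-\sum p \ln p)/\ln S^+$ of catch and of each nutrient catch (weights =
catch × concentration), the catch-weighted mean vulnerability $V$, the
relative vulnerability $\Delta V = V_{nutrient} - V_{total}$, and region
means across six nutrients with twice the standard error (vitamin D is
excluded in catch-table mode for lack of concentration data in such
databases). Conventions decided here: a single-taxon catch has $J = 0$
(dominance by one stock is maximally uneven, and Pielou's index is 0/0
there); zero-weight taxa do not count toward richness; genus- and
family-rank records receive the unweighted mean concentration of their member
species, and unresolvable records are excluded with a logged count; SEM uses
$n = 6$ nutrient values. In model mode the same weighted mean is taken over
per-species $F_{MSY}$, and a nutrient is resilient (underfished at mMSY) when
its weighted $F_{MSY}$ exceeds the total catch's, vulnerable when below.

`make_catch_table()` emulates the statistical structure this framework
consumes: lognormally skewed catch shares, a configurable fraction of records
demoted to genus/family rank, and vulnerability scores tied to asymptotic
length by a Gaussian copula. It reproduces none of the real-world taxonomic
or regional composition; conclusions about real fisheries require real catch
tables.

## Problem sizes and determinism

The shipped tests and the acceptance script use the 15-species community for
curve-level results, 1-5 species fixtures for oracle comparisons
(dense-grid $F_{MSY}$ search at $\Delta F = 0.01$; $10^4$ random policies
against the optimiser), and 20 synthetic regions for the framework. All
randomness — concentration draws, catch tables, optimiser starts — is
governed by explicit integer seeds, and every generator restores the
caller's RNG state; identical seeds give byte-identical CSV outputs.

## Known limitations

* Equilibrium analysis only: no seasonality, spatial structure, temperature
  effects, or transient dynamics.
* The synthetic communities are illustrative, not calibrated to any real
  system; absolute yields are in model units set by the resource magnitude.
* The first-order splitting error means very large $dt$ shifts equilibria
  slightly; the defaults keep this well below the tolerances used anywhere.
* Nutrient concentrations are inputs; no attempt is made to predict them
  from traits.
* One métier per gear: technical interactions between fleets are out of
  scope.
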