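# mnyield

Multispecies size-spectrum simulation and **maximum nutrient yield** (mMNY)
reference points for nutrient-sensitive fisheries management.

Fish species differ widely in how much calcium, iron, zinc, selenium,
vitamin A, vitamin D and omega-3 they put on a plate per tonne landed.
Fisheries, however, are managed for catch weight: single-species or
multispecies maximum sustainable yield (MSY / mMSY). `mnyield` is for
quantitative fisheries scientists who want to ask the complementary
question — at what fishing pressure is the yield of a *nutrient* maximised,
and does that pressure sit above or below the catch optimum?

The package provides:

* a dynamic **trait-based multispecies size-spectrum model** (abundance
  density `N_i(w)` under `∂N/∂t + ∂(gN)/∂w = −μN`, with allometric intake
  `h w^n`, lognormal predator–prey size preference `φ(w_p/w) =
  exp[−ln²(w_p/(βw))/2σ²]`, Beverton–Holt capped recruitment, semi-chemostat
  resource, and per-gear fishing mortality `F_{g,i}(w) = S_{g,i}(w) Q_{g,i}
  E_g`);
* **yield curves and reference points**: per-species `F_MSY` by iterated
  within-community search, effort sweeps fishing every species at
  `E × F_MSY_i`, nutrient yields (catch × concentration per 100 g × 10⁴),
  stock-collapse rules, and the mMSY / mMNY / `F_mMSY` / `F_mMNY` summary
  with an over-/under-/neutral classification per nutrient;
* a **constrained optimiser** finding the per-species fishing-mortality
  vector (box `[0.01, 2]`, quasi-Newton, multi-start) that maximises one
  nutrient's equilibrium yield without collapsing any stock below 10% of its
  unfished biomass;
* the **evenness–vulnerability framework** for regional catch tables:
  Pielou's evenness and catch-weighted fishing vulnerability of each
  nutrient catch, relative vulnerability `ΔV = V_nutrient − V_total`, and
  per-region / global summaries, with taxonomic fallback for genus- and
  family-rank records;
* **synthetic-data generators** for interacting communities, nutrient
  concentration tables and reconstructed-catch style regional tables, so the
  whole pipeline runs and is tested without any external data.

## Worked example

Build a five-species community, estimate each species' in-community F_MSY,
sweep the exploitation gradient, and summarise the reference points:

```r
library(mnyield)

com <- make_generic_community(n_species = 5, w_inf_range = c(10, 1e4), seed = 1)
m   <- nym_model(com$species, com$gears)

rp <- estimate_fmsy(m)
print(rp, digits = 3)
#>      species F_MSY yield_at_FMSY    B0
#> 1 species_01 1.573         15879 26087
#> 2 species_02 1.451          7659 16700
#> 3 species_03 0.981          3104 10489
#> 4 species_04 0.603          1224  6690
#> 5 species_05 0.382           463  4070

curve <- sweep_effort(m, rp, com$nutrients)
#> Yield curve: 56 effort levels (0 - 2.75), 5 species, 7 nutrients
#> [truncated by collapse rule]
summarise_curve(curve)
#> mMSY 2.856e+04 t/yr at community fishing level 1.160 (exploitation rate 1.423)
#>   nutrient      mMNY F_mMNY exploitation_at_mMNY  ratio classification
#>    calcium 1.953e+10  1.151                1.413 0.9923        neutral
#>       iron 4.014e+08  1.161                1.424 1.0007        neutral
#>       zinc 7.058e+08  1.125                1.382 0.9697        neutral
#>   selenium 1.848e+10  1.147                1.408 0.9885        neutral
#>  vitamin_a 1.855e+10  1.135                1.394 0.9784        neutral
#>  vitamin_d 2.106e+09  1.136                1.395 0.9791        neutral
#>     omega3 3.329e+08  1.127                1.384 0.9709        neutral
```

Reading this: `F_MSY` declines steeply with asymptotic size — the 10 g forage
species tolerates four times the fishing mortality of the 10 kg apex species.
Total catch peaks at 1.16× the F_MSY-balanced effort (`mMSY` ≈ 2.9 × 10⁴
t/yr); the sweep stops at E = 2.75 where the collapse rule triggers. Every
nutrient's `F_mMNY/F_mMSY` ratio sits within 3% of 1 here, because the sweep
scales each species by its own self-consistent F_MSY; directional divergence
appears when nutrients concentrate in species with asymmetric trophic roles
(see `make_nutrient_loading_fixture()` and the methods vignette).

The catch-table framework runs on tabular data alone:

```r
ct  <- make_catch_table(n_regions = 5, seed = 3)
rec <- resolve_profiles(ct$catch, ct$profiles)
fw  <- regional_summary(rec)
global_deviation_summary(fw)
#>            nutrient n_regions frac_negative frac_positive frac_zero
#> calcium     calcium         5           1.0           0.0         0
#> iron           iron         5           0.4           0.6         0
#> omega3       omega3         5           1.0           0.0         0
#> selenium   selenium         5           0.8           0.2         0
#> vitamin_a vitamin_a         5           0.8           0.2         0
#> zinc           zinc         5           0.6           0.4         0
```

`frac_negative` is the fraction of regions whose nutrient catch is *less*
vulnerable to fishing than their total catch (potential nutrient
underfishing at current patterns); `frac_positive` the reverse.

A command-line interface wraps the same functions
(`inst/scripts/mnyield`): subcommands `simulate-data`, `yield-curves`,
`optimise` and `framework`, all deterministic under a fixed `--seed`.

## Learn more

The methods vignette (`vignettes/mnyield-methods.Rmd`) documents the model
equations and assumptions, the numerical scheme (exact-decay operator
splitting, implicit upwind transport), every tunable parameter with its
default and rationale, what the synthetic generators do and do not emulate,
and the package's known limitations.
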