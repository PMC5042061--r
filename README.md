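# lakesize

Statistical analysis of shell-size predictors in gastropod faunas of
long-lived ("ancient") lakes.

Long-lived lakes — systems persisting for 10⁵–10⁶ years or more, such as
Lake Pannon, the Caspian Sea or Lake Ohrid — act as evolutionary islands:
they accumulate species-rich, highly endemic gastropod faunas, including
some of the most spectacular cases of shell gigantism in the freshwater
fossil record. This package asks which properties of a lake and of its
fauna predict the shell sizes found there, and whether apparent
correlations are artifacts of species richness.

It is aimed at palaeobiologists and macroecologists working with
species-level occurrence tables (one shell size per species) and
lake-level physiographic data.

## The analysis

**Size estimator.** Each species' shell height *h* and width *w* (mm) are
reduced to a single size,

&nbsp;&nbsp;&nbsp;&nbsp;*S* = √(*h·w*),

the side of the square with the same area as the *h* × *w* rectangle,
making planispiral and turriform shells comparable.

**Fauna-level measures.** Each lake's fauna is summarised by four
log₁₀-transformed measures: *S*ₘₑₐₙ = log₁₀(mean *S*),
*S*ₘₐₓ = log₁₀(max *S*), *S*ₘᵢₙ = log₁₀(min *S*), and the size range
*S*ᵣₐₙgₑ = log₁₀(max *S* − min *S*).

**Regression battery.** Each measure is regressed on seven lake- and
fauna-specific predictors — log₁₀ surface area (km²), mean family-level
β-Jaccard dissimilarity, log₁₀ distance to the closest coeval lake (km),
percent endemism, centroid latitude and longitude, and log₁₀ species
richness — as one multiple regression plus seven simple regressions.
Multicollinearity is screened with variance inflation factors
(VIFⱼ = 1/(1 − R²ⱼ)), and each predictor's independent contribution *I* is
obtained by hierarchical partitioning (the average R² gain over all *k*!
orderings of predictor entry; ΣI equals the full-model R²).

**Resampling null.** To test whether size–area and size–endemism
correlations are driven by species richness, 25% of every lake's species
are resampled without replacement (minimum two), the measures recomputed
and the simple regression refitted, 1000 times; the test *P* is the
proportion of resampled slopes greater than the observed slope.

**Stratified and temporal views.** The same regressions run within
gastropod families (families in more than five lakes; cells with ≥ 2
species), on faunas at stratigraphic horizons against lake age, on species
longevity (oldest minus youngest occurrence, records dated to ≤ 3 Myr
uncertainty), and along clade ranks within phylogenetic lineages.

**Synthetic data.** `simulate_lakesize()` generates seeded lake/species
tables with the assumed structure — a power-law species–area relationship,
a right-skewed global log₁₀ size distribution, endemism rising with
richness — in a *sampling-null* mode (sizes i.i.d. everywhere; extremes
track richness through order statistics alone) or a *structured* mode
(size-spectrum scale widening with log₁₀ area), with ground truth attached
for parameter-recovery scoring.

## Worked example

```r
library(lakesize)

# the bundled 23-lake study table: endemism rises with log10 richness
lakes <- study_lakes()
cor(lakes$pct_endemism, log10(lakes$n_species))
#> 0.5136978

# a seeded synthetic dataset with a planted area effect, analysed end to end
sim <- simulate_lakesize(sim_config(mode = "structured"), seed = 11)
fit <- lakesize_fit(sim$species, sim$lakes)
fit
#> Shell-size predictor analysis
#>   23 lakes, 957 measured species
#> size distribution (n = 957): G1 = 0.360, Shapiro-Wilk W = 0.989, P = 1.54e-06
#>   max VIF = 9.35 (richness)
#>  measure  n adj_r_squared f_statistic        p r_squared
#>  S_range 23         0.903       30.36 9.31e-08     0.934
#>    S_max 23         0.896       28.21 1.54e-07     0.929
#>    S_min 23         0.589        5.51 2.74e-03     0.720
#>   S_mean 23         0.705        8.53 2.82e-04     0.799

resampling_test(sim$species, sim$lakes, "area", "S_range",
                lakesize_config(repetitions = 1000), seed = 11)
#> Resampling null test: S_range ~ area
#>   observed slope 0.2684; 1000 replicates at fraction 0.25 (0 discarded)
#>   P (literal) = 0.622
```

Reading: the size-range and maximum-size models are strongly explained
(adjusted R² ≈ 0.90 here, where an area effect was planted); the pooled
log₁₀ size distribution is weakly right-skewed (G1 = 0.36) and
significantly non-normal at this sample size; and the resampling test does
not reject its null (P = 0.62) — the size-range–area slope is compatible
with being carried by species richness, which in this generator mode it
partly is. `summary(fit)` prints the full 4 × 7 battery with
hierarchical-partitioning contributions; `coef(fit)` returns it as a
data.frame; `write_lakesize_results(fit, dir)` writes the result CSVs and
a seeded JSON run log.

Empirical species/lake tables are read with `read_species_table()` /
`read_lake_table()` (column schemas in their help pages) and filtered with
`apply_inclusion_filters()` (species without sizes excluded and counted;
lakes with fewer than four measured species dropped).

A thin command-line interface is installed at `exec/lakesize.R`
(`run`, `simulate`, `report` subcommands).

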