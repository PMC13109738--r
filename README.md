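# dietniche

Quantitative trophic ecology of stomach-flushed predators. `dietniche`
implements the standard dietary-composition and niche statistics used to
compare syntopic species — here shaped around a three-species assemblage of
small frogs (*Microhyla heymonsi*, *M. mukhlesuri*, *Occidozyga
lingnanica*; 26, 42 and 48 stomachs, 1659 prey items) — together with a
seeded synthetic stomach-content generator, so the entire pipeline is
testable without raw field data.

## What it computes

For each prey item the volume is the prolate spheroid
`V = 4π/3 · (L/2) · (W/2)²` (mm³) from its measured length `L` and width
`W`. Per species and prey taxon the composition table reports the
frequency of occurrence, numeric and volumetric proportions and the index
of relative importance:

    IRI_i = (%F_i + %N_i + %V_i) / 3

with `%F` normalized over occurrence records so each column sums to 100
(the conventional per-stomach occurrence fraction is kept alongside).
Diet-wide statistics:

* Simpson heterogeneity (finite-sample): `D = Σ n_i(n_i−1) / N(N−1)`,
  reported as `1 − D`;
* Shannon diversity `H' = −Σ p_i ln p_i` and evenness `J' = H'/ln S`;
* Levins standardized niche breadth `B = 1/Σ p_i²`,
  `B_sta = (B−1)/(n−1)` over the `n` prey taxa registered in the diet;
* Pianka pairwise niche overlap
  `O_jk = Σ P_ij P_ik / √(Σ P_ij² · Σ P_ik²)` on the union of the two
  species' prey taxa.

Community-level comparison works on per-stomach abundance or volume
matrices: Bray-Curtis dissimilarity, ANOSIM (rank-based, mid-rank ties,
`r = (mean between-rank − mean within-rank)/(M/2)`, permutation p with the
+1 correction and a recorded seed) and non-metric multidimensional scaling
minimizing Kruskal stress-1 with pool-adjacent-violators monotone
regression, a principal-coordinate start plus seeded random restarts, and
a per-iteration stress trace.

## Worked example

```r
library(dietniche)
d <- generate_diet_data(default_study_config(seed = 42))
d
#> Stomach-content diet dataset
#>   116 stomachs, 1724 prey items, 3 species
#>   - Microhyla heymonsi: 26 stomachs (0 empty), 460 items
#>   - Microhyla mukhlesuri: 42 stomachs (0 empty), 974 items
#>   - Occidozyga lingnanica: 48 stomachs (0 empty), 290 items

diversity_summary(d)
#>                 species one_minus_D   H  S    J    B B_sta
#> 1    Microhyla heymonsi        0.13 0.3  6 0.17  1.2  0.03
#> 2  Microhyla mukhlesuri        0.39 0.7  7 0.36  1.6  0.11
#> 3 Occidozyga lingnanica        0.91 2.7 24 0.85 10.9  0.43

dd <- bray_curtis(build_taxon_matrix(d, "abundance"))
anosim_test(dd, n_permutations = 999, seed = 42)
#> ANOSIM (Bray-Curtis ranks)
#>   groups: Microhyla heymonsi (n=26), Microhyla mukhlesuri (n=42), Occidozyga lingnanica (n=48)
#>   r = 0.4938, p = 0.001 (999 permutations, seed 42)

nmds_ordination(dd, dims = 2, seed = 42)
#> NMDS ordination: 116 samples in 2 dimension(s)
#>   stress = 0.0907 (not converged, 4 starts, seed 42)
```

The diversity table reads as in any diet study: the two *Microhyla* are
termite/ant specialists (low `1 − D`, `B_sta` near 0) while *Occidozyga
lingnanica* is a generalist (`1 − D` ≈ 0.9, high evenness). The global
ANOSIM `r` ≈ 0.49 with `p` = 0.001 says the three diets differ overall —
driven by the generalist — and the NMDS stress below 0.2 indicates an
adequate two-dimensional representation of the Bray-Curtis structure.

A thin command-line wrapper over the same functions lives at
`inst/cli/dietniche.R` (subcommands `validate`, `summarize`, `compare`,
`simulate`); every output file carries a provenance header with the seed
and run configuration.

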