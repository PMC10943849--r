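# pcbdechlor

Analysis of microbial reductive dechlorination of polychlorinated
biphenyls (PCBs) in anaerobic microcosms — for environmental
microbiologists running incubation assays of PCB-spiked inocula (sewage
sludge, sediments, soils) and the bioinformaticians processing their
congener tables, qPCR panels and 16S community profiles.

Organohalide-respiring bacteria (OHRB) such as *Dehalococcoides*,
*Dehalogenimonas* and *Dehalobacter* gain energy by replacing chlorines
on PCBs with hydrogen. A microcosm study tracks this three ways: the
congener composition of the PCB mixture over time (gas chromatography),
the abundance of OHRB genera and of the characterized PCB reductive
dehalogenase genes *pcbA1/pcbA4/pcbA5* (qPCR), and the surrounding
microbial community (amplicon sequencing). pcbdechlor implements the
full computational chain over those three inputs.

## What it computes

**Congener accounting.** The 209 PCB congeners in canonical
chlorophenyl-ring notation (`"2345-245"`), with *ortho*/*meta*/*para*
classification (ring positions 2,6 / 3,5 / 4), chlorine flanking
context, and single-dechlorination product sets with symmetry
multiplicities.

**Dechlorination statistics.** The activity statistic is the average
number of chlorines per biphenyl,
`Cl/PCB = Σᵢ xᵢ·nᵢ` (mole fraction xᵢ, chlorine count nᵢ), and its
decrease from day 0, ΔCl/PCB, decomposed exactly into ortho/meta/para
components. Microcosms are called active at ΔCl/PCB ≥ 0.05 (the abiotic
control level), lag times are reported as sampling intervals, para- vs
meta-preference is classified by ANOVA across replicates, and observed
single-dechlorination pathway graphs get non-negative mass-balance flux
attribution.

**qPCR quantification.** Log-linear standard curves (efficiency
`10^(−1/slope) − 1`, acceptability flags), copy-number inversion with a
copies-per-reaction limit of detection, RDase:OHRB abundance ratios with
the 10×/0.1× uncertainty band (ratios < 0.1 flag undescribed
dehalogenases), and > 90% single-genus dominance calls.

**Community ecology.** OHRB screening (including the uncultivated
Dehalococcoidia lineages S085, vadinBA26, GIF9, DscP2, t0.6.f), alpha
diversity, Bray–Curtis/PCoA, prevalence-filtered (> 50%) Spearman
co-occurrence networks with Benjamini–Hochberg control (|ρ| > 0.6,
adjusted p < 0.01), and a normalized stochasticity ratio (NST) null
model with the 50% stochastic/deterministic boundary.

**Synthetic data.** Seeded generators for every input: first-order
sequential dechlorination kinetics on the congener graph (with ground
truth fluxes), log-linear qPCR forward models, and community tables
assembled stochastically or from templates with planted
abundance–activity coupling.

## Worked example

Simulate a para-preferential microcosm (3:1 para:meta rate ratio,
5% measurement noise) and analyse it:

```r
library(pcbdechlor)

rates <- default_rate_table()
rates["para", ] <- 3 * rates["meta", ]
sim <- simulate_microcosm(rates = rates, seed = 1, replicates = 4,
                          noise_cv = 0.05, id = "FS-demo")

dechlor_stats(sim$series[[1]])
#>        id replicate delta_cl_total delta_ortho delta_meta delta_para active
#> 1 FS-demo         1       0.634259   0.0182949  0.2132833  0.4026808   TRUE
#>   lag_lower lag_upper threshold
#> 1         0        30      0.05

preference_class(sim$series)
#> [1] "para-preferential"
```

The microcosm removed 0.63 chlorines per biphenyl in 180 days, mostly
from para positions (0.40 of the 0.63), was active from the first
sampling interval (lag in (0, 30] days), and the replicate ANOVA calls
it para-preferential.

```r
fit_standard_curve(data.frame(copies = 10^(2:8),
                              Cq = 39.8 - 3.32 * (2:8)), target = "pcbA4")
#> standard_curve 'pcbA4': Cq = 39.8000 + -3.3200 log10(copies),
#>   r2 = 1.0000, efficiency = 100.1% [acceptable]

comm <- simulate_communities(n_samples = 21, coupling_slope = 5, seed = 2)
nst(comm$counts, B = 1000, seed = 3)
#>   group      nst                label n_samples n_pairs    B seed
#> 1   all 92.42353 stochastic-dominated        21     210 1000    3
```

Communities drawn from the null model itself score NST ≈ 92% —
stochastic-dominated, as they should; templated near-replicate
communities (deterministic mode) score ≈ 20%.

`run_pipeline(study_config(...))` ties the stages together over a study
directory and writes CSV/JSON results plus a manifest (seed, thresholds,
input checksums, filter counts). `write_fixture_study()` emits a
complete miniature study in the package's input dialects. A thin CLI
with `simulate` / `dechlor` / `qpcr` / `network` / `nst` / `screen-ohrb`
/ `report` subcommands is installed at `inst/scripts/pcbdechlor-cli`.

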