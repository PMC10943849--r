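---
title: "Methods: congener accounting, dechlorination statistics and community ecology in pcbdechlor"
author: "pcbdechlor authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: congener accounting, dechlorination statistics and community ecology in pcbdechlor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcbdechlor)
```

# Scope

pcbdechlor analyses microbial reductive dechlorination of polychlorinated
biphenyls (PCBs) in anaerobic microcosm incubations, of the kind used to
assay whether an environmental inoculum (e.g. sewage sludge) attenuates a
spiked commercial PCB mixture. The package covers four analysis layers —
congener structural accounting, dechlorination statistics over congener
time series, qPCR quantification of organohalide-respiring bacteria
(OHRB) and reductive dehalogenase (RDase) genes, and community ecology on
taxon-by-sample tables — plus seeded synthetic generators that emulate
each input, so the full pipeline is testable without laboratory data.

# The congener model

A PCB congener is a chlorine substitution pattern on the biphenyl
scaffold. Each phenyl ring is described by the set of substituted carbons
from {2,3,4,5,6} (carbon 1 carries the ring–ring bond); positions 2/6 are
*ortho*, 3/5 *meta* and 4 *para*. Rotating a ring about the ring–ring
bond maps 2↔6, 3↔5, 4→4, and the two rings are interchangeable, giving a
symmetry group of order 8. Labels are canonicalized under that group:
each ring takes its flip-minimal digit string, and the two strings are
ordered lexicographically (the unsubstituted ring, rendered `"0"`, always
second). Deduplicating the 32 × 32 ring-pair patterns under this group
and removing unchlorinated biphenyl yields exactly 209 congeners with the
familiar homolog distribution (3, 12, 24, 42, 46, 42, 24, 12, 3, 1 for
mono through deca); the test suite re-derives this with an independent
brute-force oracle. Ring notation is the canonical key throughout; we do
not ship a mapping to the historical congener numbering, whose ordering
rules contain irregularities that ring notation avoids.

A chlorine's *flanking context* (unflanked, singly- or doubly-flanked)
counts chlorinated neighbours within its ring (adjacency 2–3, 3–4, 4–5,
5–6). Flanking matters because the characterized dechlorinases
preferentially attack flanked *meta* and *para* chlorines.
`dechlorination_products()` removes each chlorine in turn, canonicalizes
the product, and merges symmetry-equivalent channels with an integer
multiplicity — the multiplicity is what keeps kinetic channels from
being double-counted. Removing the last chlorine yields biphenyl, kept
as a distinguished terminal node rather than a 210th congener so the
209-set invariants stay clean.

# Dechlorination statistics

The central statistic is the average number of chlorines per biphenyl,

$$\mathrm{Cl/PCB} = \sum_i x_i \, n_i,$$

with $x_i$ the mole fraction of congener $i$ among detected congeners
and $n_i$ its chlorine count. Activity is the decrease
$\Delta\mathrm{Cl/PCB}(t) = \mathrm{Cl/PCB}(0) - \mathrm{Cl/PCB}(t)$,
decomposed identically per *ortho*/*meta*/*para* class so the three
components sum to the total at machine precision. Mole fractions are
computed over detected congeners only; congeners below detection are
treated as absent rather than censored, matching GC reporting practice
(a documented limitation: heavy losses to below-detection products bias
Cl/PCB upward).

A microcosm is called *active* when $\Delta\mathrm{Cl/PCB}$ reaches
0.05 at any sampled day — the decrease observed in abiotic controls —
with an inclusive comparison (the threshold is stated as a value, not a
strict bound, and inclusivity is reproducible); the threshold can also be
taken from a linked abiotic-control series. Because sampling is roughly
monthly, lag time is reported as the interval (previous sample, onset
sample] rather than a spuriously precise point estimate, and no temporal
interpolation of Cl/PCB is performed.

Preference classification compares final *para*- vs *meta*-position
decreases across replicate microcosms by one-way ANOVA at α = 0.05:
significant with the larger mean on one side gives para- or
meta-preferential, otherwise "comparable". The ANOVA-across-replicates
variant is used because that is the stated statistical test for the
positional comparison; statistics are computed per replicate and then
aggregated.

## Pathway graphs and flux attribution

`build_pathway_graph()` connects every observed congener to every
observed single-dechlorination daughter, annotated by removed-position
class and flanking context; daughters that appear after day 0 with no
observed parent are flagged orphans (their source fell below detection).
`attribute_fluxes()` then solves, per consecutive timepoint pair, a
non-negative least-squares mass balance: each node's concentration
change must equal inflow minus outflow over the edges. The solver
minimises the squared residual with a tiny L1 term (weight 1e-6)
breaking degeneracy toward fewer active edges, implemented as
box-constrained quadratic minimisation (L-BFGS-B with analytic
gradient). Two caveats are inherent to mass-balance attribution and are
reported rather than hidden: flux through congeners below detection
appears as residual (warned above 5% of the interval's total absolute
change), and parallel routes through "diamonds" (two parents reaching
one daughter via different intermediates) are not identifiable from node
balances alone — on such graphs the attributed split between equivalent
routes is one valid solution among many, while path-independent totals
remain well determined. On cascade topologies the attribution is exact:
the flux-recovery checks use a single-congener cascade
(`"2345-25"` → `"245-25"` → `"25-25"`) where the solution is unique,
and recover simulator ground truth to well below 1%.

# qPCR quantification

Standard curves are ordinary least squares of Cq on $\log_{10}$(copies)
over a plasmid dilution series spanning $10^2$–$10^8$ copies/mL;
amplification efficiency is $E = 10^{-1/\text{slope}} - 1$ (slope
−3.3219 ⇔ 100%). Curves are flagged unacceptable outside configurable
bounds (defaults $r^2 \ge 0.99$, efficiency 90–110%; the study-grade
band 92.0–101.9% can be configured). Quantification inverts the curve,
`copies/mL = dilution × 10^{(Cq − intercept)/slope}`; the below-LOD flag
compares copies per *reaction* — copies/mL times the template volume per
reaction (default 0.02 mL) — against a configurable LOD scalar whose
default, 6 copies/reaction, is the conservative end of the 6–9 band
typically computed for these assays. Genus-level 16S copies are treated
as cells 1:1 (single-copy assumption appropriate for Dehalococcoidia-type
genomes), configurable per genus.

The RDase:OHRB ratio sums the three characterized PCB-RDase genes
(*pcbA1*, *pcbA4*, *pcbA5*) over the three OHRB genera
(*Dehalococcoides*, *Dehalogenimonas*, *Dehalobacter*). A 10-fold band
around the 1:1 line represents the maximum plausible qPCR quantification
uncertainty; ratios strictly above 10 flag quantification bias (usually
low OHRB denominators), ratios strictly below 0.1 flag RDase genes not
covered by the assay panel, i.e. undescribed dehalogenases. Dominance is
called when a single genus strictly exceeds 90% of summed OHRB
abundance. Both thresholds are strict bounds by design.

# Community ecology

OHRB screening matches taxonomy labels (fixed substrings) against a
configurable list: the three genera plus the uncultivated Dehalococcoidia
lineages S085, vadinBA26, GIF9, DscP2 and t0.6.f, which carry putative
RDase genes. Alpha diversity reports richness, Shannon entropy (natural
log, via vegan) and Pielou evenness together, since "diversity" in
biodiversity–function comparisons can mean any of the three. Bray–Curtis
dissimilarity and classical-scaling principal coordinates use the
standard definitions; negative eigenvalues are reported, not corrected.

Co-occurrence networks follow the conventional recipe: per activity
group, genera detected in strictly more than 50% of samples (singletons
excluded; "singleton" read strictly as total count 1) are tested
pairwise by Spearman correlation on relative abundances (average ranks
for ties; t-approximation p-values for n ≥ 10, exact permutation
enumeration below), p-values are Benjamini–Hochberg adjusted over all
tested pairs, and an edge requires |ρ| > 0.6 and adjusted p < 0.01.
Groups are formed by ranking microcosms on ΔCl/PCB and splitting into
equal quartiles. Topology is summarised by n, L and average degree 2L/n
over all tested genera.

## The stochasticity ratio

The normalized stochasticity ratio (NST) family of estimators varies in
its exact normalization; this package's contract is the magnitude-ratio
variant, stated here explicitly. Per group, a regional pool is the
taxon-wise sum of counts; each sample is replaced by B (default 1000)
multinomial null draws of its observed depth with probabilities
proportional to regional relative abundance. For each sample pair,

$$r_{ij} = \frac{\min(D_{ij}, \bar E_{ij})}{\max(D_{ij}, \bar E_{ij})},
\qquad \mathrm{NST} = 100\% \times \overline{r_{ij}},$$

where $D_{ij}$ is the observed Bray–Curtis dissimilarity and
$\bar E_{ij}$ the null mean. Pairs whose observed dissimilarity matches
the null expectation score near 1 (assembly indistinguishable from
random draws from the pool); strong departures in either direction score
near 0. NST > 50% is labelled stochastic-dominated, < 50%
deterministic-dominated. The variant is validated behaviourally:
communities generated by the null model itself score ≈ 90%, templated
near-replicate communities score ≈ 20%. One exactness caveat: observed
dissimilarities are invariant to taxon relabelling and sample order, but
the null draws consume random numbers in taxon order, so under a fixed
seed the null side is reproducible bit-for-bit only for a fixed table
layout; across layouts it is equal in distribution.

# Synthetic generators

`simulate_microcosm()` integrates first-order sequential dechlorination
on the congener graph: each chlorine of each congener is removed at rate
$k[\text{position}][\text{flank}] \times m \times C$ (with $m$ the
symmetry multiplicity), products routed per
`dechlorination_products()`, rates zero before a configurable lag. The
system is linear, so it is integrated with deSolve (lsoda, analytic
Jacobian, rtol 1e-10); per-edge cumulative fluxes ride along as
auxiliary states, giving ground truth that satisfies node-wise mass
balance to integrator tolerance and conserves total biphenyl skeletons.
Measurement noise is multiplicative lognormal (unit mean), applied per
congener per timepoint; observed series contain congeners only, as a GC
congener table would.

Generator defaults are fixed once and document the emulated conditions:
a synthetic hexa/hepta-dominated 10-congener mixture with initial
Cl/PCB ≈ 6.1 standing in for the commercial Aroclor 1260 composition
(not tabulated in the public record at congener resolution); total
spike 26.9 µM, the nominal microcosm spiking level; sampling days 0–180
in 30-day steps, matching a 180-day incubation with roughly monthly
sampling; and rate constants ordered doubly-flanked > singly-flanked >
unflanked with para ≳ meta ≫ ortho, sized so the default microcosm
decreases Cl/PCB by ~0.3–0.5 over 180 days, the magnitude reported for
active sludge microcosms. What the generator does *not* emulate —
congener co-elution, detection-limit censoring, inoculum carry-over PCBs,
community succession — bounds what passing tests show about real data:
they validate the statistical machinery, not chromatography.

`simulate_qpcr()` is the log-linear forward model with Gaussian Cq noise;
non-positive copies emit non-detects. `simulate_communities()` draws
samples either as multinomials from a lognormal rank-abundance pool
(stochastic mode) or as near-replicates of a fixed group template with
small multiplicative noise (deterministic mode); designated OHRB taxa
are scaled by $1 + a\,\Delta\mathrm{Cl/PCB}$ per sample, planting the
abundance–activity correlation that the quantification layer is expected
to recover. `simulate_cooccurrence_table()` plants Spearman correlations
through a Gaussian copula (monotone lognormal quantile maps preserve rank
correlations). All generators are bit-reproducible under a fixed seed.

# Numerical choices and problem sizes

* Mole-fraction invariants are asserted at 1e-9; PCoA Euclidean
  reconstruction at 1e-8; exact identities (positional sums, homolog
  counts) exactly.
* The NNLS tie-break weight is 1e-6, small enough to leave well-posed
  solutions unchanged at the tolerances above.
* Ties in Spearman ranks use average ranks; the permutation branch is
  capped at n = 9 (9! = 362,880 permutations, vectorised).
* Degenerate inputs error early with specific messages: all-zero
  profiles, unsampled days, inactive series passed to lag/preference,
  zero-variance correlation inputs, non-integer counts passed to NST,
  asymmetric dissimilarity matrices.
* Default problem sizes in the shipped tests and acceptance script — 100
  seeded control and preference studies, 21-sample groups, B = 1000 NST
  randomizations, a 16-sample fixture study — were chosen as the
  smallest sizes at which the statistical contracts are sharp.

# Known limitations

* Flux attribution is mass-balance-based: splits across
  balance-equivalent parallel routes are reported as one valid solution,
  and flux through undetected intermediates surfaces as residual, not as
  inferred edges.
* Cl/PCB over detected congeners only is biased when substantial mass
  reaches unmeasured light products; the terminal biphenyl row is
  accepted (with 0 chlorines) when a table provides it.
* The NST variant is one member of a family; values should be compared
  across groups within one analysis, not against estimates from other
  normalizations.
* OHRB screening is label matching, not phylogenetic placement; its
  accuracy is bounded by the input taxonomy's.
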