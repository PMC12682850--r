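---
title: "Methods: growth rates, the Water Recovery Index, GWAS co-location and root architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth rates, the Water Recovery Index, GWAS co-location and root architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootshift)
```

rootshift analyses how rice plants re-balance shoot and root growth when a
drought episode ends and water returns. This vignette explains the models and
procedures the package implements, the tunable parameters and their defaults,
what the synthetic-data generators do and do not emulate, and the numerical
and design choices that were genuinely open.

## Growth rates

Two kinds of rate are computed from longitudinal phenotype tables.

**Relative growth rate (RGR).** From shoot dry weights harvested at the end
of drought (SDW1) and after re-watering (SDW2):

$$\mathrm{RGR} = \frac{\ln(\mathrm{SDW}_2) - \ln(\mathrm{SDW}_1)}{\Delta t}$$

in g of new growth per g of existing plant per day. Zero or negative weights
are rejected rather than clamped: the logarithm is undefined there and such
values indicate data errors, not biology. Negative RGR (mass loss) is valid.

**Trait growth rates.** Shoot growth is proxied by total leaf length (cm/d)
and root growth by crown-root number (roots/d), as the simple difference
between two measurement timepoints divided by the elapsed days. Because
destructive sampling measures *different* plants at the two endpoints,
negative rates occur and are retained.

Elapsed time always comes from the treatment's own measurement calendar
(`measurement_schedule()`): field logistics commonly shift control sampling
by a day relative to drought sampling, and using a shared calendar would bias
every control rate. Aggregation follows the field design: plants are averaged
within plot, then plot means within genotype, both unweighted.

For multi-block trials, `block_center()` removes each block's deviation from
the grand mean before genotype means are formed. This additive
block-centring is exact on balanced designs, conserves the grand mean to
1e-12, and is a deliberately simple, reproducible alternative to a
mixed-model least-squares-means fit; outputs are labelled "block-adjusted"
to keep the distinction visible.

## The Water Recovery Index

The WRI ranks genotypes by how strongly they shift investment towards crown
roots during recovery, relative to their own well-watered behaviour:

1. compute line-level shoot and root growth rates over the recovery window
   (default M2→M3, end of drought to early recovery — the window where the
   recovery contrast lives; configurable);
2. rescale the vector of line means linearly onto [1, 100], separately per
   (treatment, compartment) — rates can be negative, and the rescaling makes
   the following log-ratio well defined;
3. form the shoot-to-root growth-rate ratio
   $\mathrm{SRGR} = \ln(\text{rescaled shootGR}/\text{rescaled rootGR})$;
4. $\mathrm{WRI} = \mathrm{SRGR}_{\text{drought}} - \mathrm{SRGR}_{\text{well-watered}}$.

More negative WRI = stronger root-biased regrowth under drought recovery
("conservative"); values near zero = little treatment contrast
("less-conservative"). Ranking sorts ascending with lexicographic
tie-breaking for determinism; the lower half of the ranking is labelled
conservative, the upper half less-conservative.

Numerical choices: the rescale endpoints are exactly 1 and 100; a constant
input vector maps to the interval midpoint 50.5 so the SRGR stays defined;
the affine map is clamped so floating-point round-off cannot push values
outside [1, 100]. Rescaling operates on genotype-level means (the order of
steps puts averaging first) and keeps shoot and root compartments separate —
pooling both compartments into one vector per treatment was evaluated and
recovers planted orderings distinctly worse, so the separate reading is
implemented.

The WRI is a *within-experiment* ranking tool. It depends on plant age and
growth stage, and no cross-experiment normalisation is attempted.

### A known fragility

Because the rescale pins the group minimum at 1, the logarithm strongly
amplifies any noise affecting genotypes near the bottom of a rescaled
group. Genotypes at the low end of either compartment's distribution
therefore carry the least reliable SRGR values. This is intrinsic to the
index definition; it is the main reason the simulation studies below
recover planted orderings imperfectly, and a practical argument for using
the WRI to select extremes rather than to interpret mid-rank differences.

## GWAS peak co-location

Per-season association summaries (SNP, chromosome, position, p-value,
optional MAF) are filtered at $-\log_{10} p \ge 3$ (boundary inclusive) and
MAF ≥ 0.05; a separate flag marks $p < 10^{-4}$ (strict, no multiple-testing
correction, matching how such single-season scans are conventionally
reported). "logP" is $-\log_{10} p$ throughout.

Co-location is single-linkage clustering of filtered hit positions per
chromosome with linkage distance ≤ 100 kb (inclusive); on a line this
reduces to splitting sorted positions at gaps larger than the window, which
is what the implementation does, and what the brute-force all-pairs +
connected-components oracle in the test suite verifies. Clusters are
retained only when members span at least two distinct seasons — the
signature of a reproducible peak. Both member hits must pass the filter (no
single-anchor relaxation). Candidate genes are all annotation features whose
closed interval overlaps the cluster interval padded by ±100 kb; single SNPs
can be queried the same way. Coordinates are 1-based inclusive (GFF3
convention) end to end.

## Root architecture

Scanned root systems arrive as segment tables with diameter, length and a
parent link (a forest; cycles are rejected). Diameter classes follow the
standard rice classification: S-type lateral roots (d ≤ 0.15 mm), L-type
(0.15 < d ≤ 0.37 mm), axial — seminal and crown — roots (d > 0.37 mm).
Boundaries are closed above at both cut points (a 0.37 mm segment is L-type)
and configurable.

Class lengths per plant are sums over a partition, so they reproduce the
reported total exactly (the total is defined as the sum of the class sums,
making the identity independent of floating summation order); proportions
sum to 1 within 1e-9 and are flagged undefined for empty groups.

**Link analysis.** External links are tips (segments with no children),
internal links are branch-bearing segments. Mean S-type lateral length is
estimated as total S-class length divided by the number of S-class tips.
When every S lateral is a single unbranched segment — the biological norm,
since S-type laterals are determinate and unbranched — the estimator is the
exact mean; it is a documented stand-in for the proprietary external-link
statistic of scanner software, validated against the synthetic generator.

**Lateral order.** A lateral is first-order when its ancestor chain reaches
an axial segment without passing an L-class segment of another lateral, and
second-order when it branches off an L-type lateral. Ancestors of the
segment's own class are treated as the same lateral (laterals may be chains
of segments). A vectorized walk implements this; tests verify it against an
independent recursive path-walk oracle on generated systems.

**Longevity scores.** Staining intensities are integers 0–5 (six classes)
per photo; aggregation is photos-within-root then roots-within-group,
unweighted, with sample sizes reported at both levels. The visual scoring
rubric itself is out of scope.

## Synthetic data: what it emulates, and what it does not

The generators exist so every pipeline stage can be tested against known
truth; they emulate the *structure* of the study designs, not absolute trait
magnitudes.

**Field experiment** (`field_sim_config()`, `gen_field_phenotypes()`):
20 genotypes × 2 treatments × 4 plots × 2 plants, measured at M1–M4
(drought 29/34/37/42 DAS; control 29/35/38/42 — M2/M3 delayed one day).
Each genotype carries a latent strategy in [0, 1]:

* strategy 0 ("conservative"): shoot rate × 0.5 under drought and early
  recovery; crown-root rate × 1.5 after re-watering;
* strategy 1 ("less-conservative"): no treatment effect;
* intermediate strategies interpolate linearly.

Crown-root production is halved under drought before re-watering for all
strategies. A per-genotype vigor multiplier (lognormal, CV 0.2) scales all
rates in both treatments, representing genetic size variation — without it
the well-watered genotype means are pure sampling noise, and rescaling a
near-constant vector onto [1, 100] amplifies that noise pathologically; a
CV of 0.2 is modest for a diversity panel deliberately selected for
contrasting growth. Plot (CV 10%) and plant (CV 15%) noise are lognormal
multipliers on rates, shared across shoot and root within a plant and
window — the standard field-trial decomposition into soil-patch and
plant-vigour effects. Trait-specific error enters through integer rounding
of crown-root counts. Leaf length at M1 starts at 30 cm × vigor and crown
roots at 8 × vigor, growing 2 cm/d and 2 roots/d respectively when
unstressed — mid-range values for rice at these stages.

What this generator does *not* emulate: tillering dynamics, SES visual
scores, genotype × plot interactions, measurement error on leaf length,
destructive-sampling plant turnover (plants are persistent identities), or
any soil-water physics. Passing recovery tests therefore shows the index
arithmetic and averaging chain are correct under a plausible noise
decomposition — not that the WRI is robust to every real field artefact.

Simulation studies with this generator recover the planted strategy order
(Spearman |ρ| ≥ 0.9 against planted strategy) in roughly 80–85% of
replicates at the design's replication; failures concentrate in replicates
where a genotype lands at the bottom of a rescaled group (see "A known
fragility" above). Removing crown-root quantization entirely raises this
only to ~88%, confirming the rescale-log amplification, not the rounding,
as the dominant cause.

**GWAS tables** (`gwas_sim_config()`, `gen_gwas_tables()`): three seasons,
uniform background p-values (optionally capped below the filter threshold),
planted peaks shared across chosen seasons at $-\log_{10}p$ ≥ the stated
magnitude, with positional jitter capped at window/4 so planted clusters are
always linkable; planted peaks on a chromosome must be separated by more
than 2× the window when exact recovery is asserted. No kinship, LD or
genotype matrices are simulated.

**Root systems** (`root_sim_config()`, `gen_root_system()`): five axial
roots, 32 first-order S laterals and 4 L laterals each, 2 second-order S
laterals per L (200 S laterals in total); lognormal lengths (S: meanlog
log 7 mm, sdlog 0.2 — S-type laterals are short and determinate, hence the
modest dispersion; L: log 40 mm, 0.3; axial: log 150 mm, 0.2); uniform
diameters strictly inside each class band. Drought halves the S-lateral
count and multiplies the L count by 1.5; the recovered condition reuses
well-watered parameters with the same seed, so architectural reversal after
re-watering holds by construction.

All generators are pure functions of (config, seed) via seed-scoped RNG:
identical seeds give bitwise-identical outputs and the caller's RNG state
is untouched.

## Treatment statistics

`one_sample_t()` implements the classical two-sided one-sample t from its
closed form (zero variance yields an NA marker, not an error).
`two_way_anova_typeII()` assembles Type II sums of squares from residual
sums of nested `lm()` fits — each main effect adjusted for the other,
ignoring the interaction; the interaction adjusted for both — and reduces to
sequential sums of squares on balanced designs (verified to 1e-9 in tests).
`tukey_hsd()` computes studentized-range adjusted p-values from group means,
MSE and group sizes, with a compact letter display built by the
insert-and-absorb algorithm. All three are cross-checked in the test suite
against independent references (`t.test`, `car::Anova`, `stats::TukeyHSD`)
to 1e-8 or better, and the one-sample t's null type-I error is verified to
sit inside the binomial 99% interval around 0.05 over 1000 simulations.
Tests are two-sided throughout; no correction is applied beyond Tukey's.

## Problem sizes and runtime choices

The simulation studies shipped with the package use 100 replicates of the
full field design for WRI recovery, 200 random instances for the
co-location oracle comparison, and 50 seeds each for planted-peak recovery,
length conservation, link-analysis recovery and the statistics
cross-checks. These sizes give stable fractions (binomial s.e. ≤ 5%) while
keeping the whole suite comfortably under a few minutes on one CPU.

## Limitations

* Block adjustment is additive centring, not a mixed model; with strong
  genotype × block structure the two differ.
* The WRI's rescale-log construction is noise-fragile at group extremes
  (see above); mid-rank comparisons should not be over-interpreted.
* The co-location window and linkage rule are heuristics; no LD information
  is used.
* The link-analysis estimator assumes S-type laterals are tips; heavily
  branched S chains would bias it upward.
* Synthetic phenotypes are structural emulations, not calibrated to any
  field dataset's absolute magnitudes.
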