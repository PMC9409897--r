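---
title: "Methods: footprint-driven model enhancement and DAM analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: footprint-driven model enhancement and DAM analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxprint)
```

fluxprint connects two kinds of evidence about a microbial culture — the
metabolites it leaves in (or depletes from) its medium, and the genes it
expresses — to a genome-scale metabolic model (GSMM) of the organism. The
motivating use case is filamentous fungi such as *Cordyceps militaris* grown
on different carbon sources, where exometabolome profiling reveals
condition-dependent lipid secretion (sphingoid bases in particular) that the
published model did not yet explain. The package covers the full analysis
path: differential accumulated metabolite (DAM) calling from LC-MS feature
tables, incorporation of footprint metabolites into a template model,
gap-filling, flux-balance growth and capability simulation, and overlay of
DAMs and differentially expressed genes (DEGs) onto pathway subnetworks.

## The model container

A `metabolic_model` holds genes, compartmented metabolites and bounded
stoichiometric reactions with gene-protein-reaction (GPR) expressions. Two
representation choices matter downstream:

* **Bounds are decimal strings.** Flux bounds are stored as the shortest
  decimal string that parses back to the identical double, and converted to
  numbers only at solve time. File round-trips are therefore exact — a
  property asserted bitwise in the test suite.
* **"Unconstrained" is ±1000 mmol/gDW/h.** The conventional big-M of
  constraint-based modelling; finite bounds keep every LP bounded, so the
  solver never needs unbounded-ray handling for well-formed models.

Reaction categories (enzymatic, transport, exchange, spontaneous, biomass)
follow the standard rules: an exchange touches exactly one metabolite
(boundary form `met ->`), a transport moves an identical multiset of base
species between compartments, biomass is an explicit flag, spontaneous is an
explicit flag with no gene association, everything else is enzymatic.
Labels present in input files always win; `classify_reaction()` fills gaps
and `audit_categories()` reports label/rule disagreements rather than fixing
them. The same philosophy applies to `audit_declared_counts()`: published
count tables are occasionally internally inconsistent (a category breakdown
that sums to one more than the declared total, say), and the audit reports
the discrepancy as data instead of silently reconciling it.

GPR expressions use a minimal grammar — identifiers, parentheses,
case-insensitive `and`/`or` — because negation does not occur in GSMM gene
associations. Boolean evaluation is the usual complex/isozyme semantics;
numeric overlay mode uses AND = min (a complex is limited by its scarcest
subunit) and OR = max (isozymes act independently). An empty GPR means "no
gene association": present, flagged.

## The LP engine

No linear-programming backend is assumed; the package includes a dense
two-phase simplex with Bland's smallest-index pivoting. Determinism was the
design goal: the same instance always pivots identically, so FBA objective
values are reproducible to the last bit. Bounded variables are handled by
shifting (`x = v - lb`) with explicit upper-bound rows; phase-1 artificials
that remain basic at zero (degenerate or redundant mass-balance rows) are
pinned so they can never re-enter or drift positive. Tolerances: feasibility
and optimality 1e-9. This engine targets desk-scale networks (tens to a few
hundred reactions); it trades speed for auditability and has quadratic-cubic
cost per pivot.

Correctness is established by a dual route: every release of the test suite
solves dozens of random stoichiometric instances with both this engine and
scipy's HiGHS solver (driven through a bundled script) plus `boot::simplex`
where that solver converges, requiring status agreement and relative
objective error below 1e-6 (observed: ~1e-15).

Only the optimal objective value is contract-guaranteed. Flux vectors at
degenerate optima are reported with that caveat — alternate optima are
ubiquitous in FBA and callers should not rely on individual fluxes.

## Media, growth and the capability screen

Exchange fluxes follow the standard sign convention (negative = uptake).
`apply_medium()` implements a single-carbon-source medium: the chosen
source's exchange lower bound becomes `-uptake_rate`, every other
carbon-bearing exchange is closed for uptake (carbon content is read from
elemental formulas; metabolites without a formula are treated as
carbon-free and keep their modelled bounds), and the inorganic nutrients —
ammonium, phosphate, sulphate, water, protons — are unconstrained.
Secretion bounds are never touched. Defaults mirror the usual fungal
simulation setup: glucose at 25 mmol/gDW/h.

`simulate_growth()` maximises the biomass reaction and identifies its flux
with specific growth rate (gDW-normalised convention). Published growth
figures are sometimes given per day, so a ×24 unit flag is provided; the
conversion is a presentation choice, not a model change.

`screen_biosynthetic_capability()` asks whether the model can sustain
nonzero secretion of a target while growing: a demand reaction is
synthesised if absent (flagged `added-for-screen`), the growth requirement
(default 1 h⁻¹) is imposed as a **lower bound** on biomass — a fixed
equality can spuriously render targets infeasible when growth and secretion
trade off — and target secretion is maximised. Rates below 1e-10 mmol/gDW/h
or infeasible problems count as no production. That threshold is a
reporting rule; the gap-filler uses a deliberately larger ε (1e-6) so that
numerical noise is never "repaired into" a model.

## Footprint incorporation and gap-filling

Footprint records are matched to model metabolites by external identifier
with precedence InChI > KEGG > ChEBI > PubChem > case-folded name, first
match wins, all matches logged. Compartment matters: a record matched to a
species in its own (extracellular) compartment is a no-op; a record matched
only to an intracellular species gains a boundary species, an exchange and
a transport reaction, because the observation *is* extracellular; an
unmatched record becomes a new extracellular metabolite with an exchange.
Every addition carries provenance `"footprint"`. Records with no
identifying field at all are rejected with a reason rather than guessed at.

`gap_fill()` makes an unachievable target (metabolite production or biomass)
achievable using a universal candidate set. The default procedure is
deterministic and greedy: open all candidates, verify achievability, then
repeatedly attempt single removals in lexicographic id order until no
candidate can be dropped. The result is irreducible by construction —
removing any returned reaction breaks the target — and the invariant is
re-asserted per run in the tests. `exact = TRUE` switches to
minimum-cardinality search by subset enumeration in increasing size,
practical for universes up to a dozen reactions; the greedy result is never
smaller than the exact one and equals it on all tested instances. The
scoring-based behaviour of published gap-filling tools is deliberately not
imitated: this implementation is its own, chosen for determinism and
auditability.

## DAM statistics

The statistical pipeline runs on feature-intensity tables (features ×
samples, non-negative, with a condition/replicate design; three biological
replicates per condition is the typical design and the generator's
default).

Choices that are genuinely open in this kind of analysis, and what this
package does:

* **Normalisation** (`median-scale`, default): each sample is rescaled so
  its median feature intensity equals the median of per-sample medians.
  Scale factors are logged. Total-intensity scaling is available; the
  choice is recorded in the output.
* **Two statistics layers.** Pairwise tables are driven by a two-sided
  unequal-variance Welch t-test on log2 intensities; a one-way ANOVA with
  Tukey HSD post-hoc (studentized-range adjustment, via `aov`/`TukeyHSD`)
  is available for multi-condition designs. Which of the two a given
  published table used is often ambiguous; both are exposed and neither is
  asserted to be "the" reference computation.
* **Fold change** is the ratio of arithmetic means of normalised,
  untransformed intensities; the test runs on log2-transformed values. A
  pseudo-count of half the smallest nonzero intensity guards zeros in both
  places.
* **Thresholds.** Significance is `|log2 FC| >= 0.5` and `p <= 0.05`, both
  boundaries inclusive. Note the common inconsistency this convention
  inherits: a 1.5-fold cut corresponds to |log2 FC| ≈ 0.585, not 0.5; the
  log2 threshold is operative here and the flag is recorded in the call
  attributes. No multiple-testing correction is applied by default (raw
  p-values are the near-universal practice for these feature tables); a
  Benjamini-Hochberg switch exists but defaults off.
* **Degenerate variance.** Zero within-group variance with equal means is
  maximally unsurprising (p = 1); with unequal means, maximally surprising
  (p = 0). ANOVA features with no within-group variance anywhere are
  flagged `degenerate` with undefined p.

Summaries conserve counts by construction (`n_up + n_down =
n_significant`; class tables sum to the significant count; volcano quadrant
counts sum to the record count) and these conservation laws are tested as
properties, as are direction antisymmetry under reference swapping and
threshold monotonicity.

Clustering uses Euclidean distance with average linkage (configurable) via
`stats::hclust`; the merge heights are cross-checked against a brute-force
nearest-pair agglomeration oracle in the tests. PCA (`stats::prcomp`,
mean-centred, unscaled, on log2 intensities) canonicalises score signs so
the largest-magnitude loading of each component is positive — without this
convention, replicate runs on permuted input could flip axes.

## Omics overlay

`extract_subsystem()` slices a model by pathway label. `overlay_omics()`
attaches DAM log2 fold changes to member metabolites (external-id matching
first, then punctuation-stripped case-folded names; lipid shorthand like
`PA(17:0/14:1(9z))` matches after whitespace normalisation) and computes a
per-reaction expression value by numeric GPR evaluation of gene log2 fold
changes. Missing data stay `NA` — never zero-filled — and every unmatched
input record is returned, so matched + unmatched always equals the input
count. The report flags reactions whose expression direction flips or
weakens (|log2 FC| below the fold-change threshold) across comparisons;
"upregulated" for DEGs is read from the sign of the supplied log2 FC only,
since DEG tables arrive pre-thresholded from upstream pipelines.

## Synthetic data: what it emulates, and what it does not

The generators produce every input type at study-like settings so the whole
pipeline is testable without downloads:

* `make_feature_table()`: log-normal intensities, `log2 I ~ N(μ_f + effect,
  σ)`, with per-feature baselines around a 1e5 median intensity (typical
  LC-MS peak-area magnitude; irrelevant to the statistics but keeps volcano
  and PCA output realistic). Defaults — 3 conditions × 3 replicates, 400
  features, 40 planted effects per condition at |log2 FC| = 2, σ = 0.3 —
  are the package's fixed study conditions for recovery experiments.
  Planted sets are disjoint between conditions, so the non-reference pair
  sees both.
* `make_toy_model()`: four templates with hand-derivable optima, including
  `sphingo-mini`, a minimal de novo sphingolipid pathway (serine +
  palmitoyl-CoA → 3-ketodihydrosphingosine → sphinganine →
  phytosphingosine / ceramide → sphingosine) rooted in glucose uptake with
  per-reaction GPRs and EC numbers, sized so capability optima are exact
  small integers (e.g. sphinganine costs 2 glucose: one for serine, one
  for palmitoyl-CoA, so 25 uptake minus a growth floor of 1 leaves a
  maximal rate of 12).
* `make_gapped_model()`: removes individually essential reactions (so the
  minimal repair is exactly the removed set) and builds a universe of those
  plus decoys over fresh dead-end metabolites; the planted truth —
  gapped model fails, decoys alone fail, repair succeeds — is re-verified
  at generation time.
* `make_deg_table()`: planted up-regulation on a subsystem's genes over
  N(0, 0.1) background.

All generators are bit-reproducible under a seed (`withr::with_seed`; no
global RNG state leaks). What they do **not** emulate: peak-shape and
retention-time artefacts, missing-value structure, correlated features,
isotope/adduct redundancy, heavy-tailed intensity noise, or the biological
covariance of real transcriptomes. Passing the planted-recovery tests
therefore demonstrates the statistical machinery is correctly implemented at
the stated effect size and noise level — not that real LC-MS data of
arbitrary quality will yield 90%+ recall.

## Problem sizes and numerical settings

The test suite and the acceptance script run at deliberate desk scale: 50
random LP instances of ≤ 15 reactions for the oracle equivalence check,
gap-fill universes of ≤ 11 candidates (exhaustive enumeration stays in the
hundreds of LP solves), 20 Monte-Carlo repetitions of the 400-feature
recovery experiment. These sizes give stable statistics while keeping a
full run in well under a minute; they are the package's reference
conditions, stated here so that reproductions know what was actually
computed.

## Known limitations

* The simplex is dense and unfactorised; genome-scale models with thousands
  of reactions will solve, but slowly. The design assumes analysis-scale
  and toy networks for simulation work, with the container and IO able to
  hold full GSMMs.
* XML exchange-format import is best-effort (species, stoichiometry,
  fbc/kinetic-law bounds, gene associations); models relying on exotic
  SBML features should be converted to the native JSON schema.
* Metabolite matching is identifier- and name-based; no structure-aware
  (InChI-key collapsing, tautomer) matching is attempted.
* The capability screen's growth floor is a lower bound, not an equality;
  models whose published screens fixed growth exactly may report slightly
  higher production optima here.
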