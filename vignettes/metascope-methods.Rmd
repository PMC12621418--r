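---
title: "Methods: Boolean scope analysis of community metabolic potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Boolean scope analysis of community metabolic potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metascope)
```

This vignette explains the models and procedures implemented in
`metascope`, the assumptions behind them, the parameters that matter, and
the design decisions taken where the methodology left genuine choices.

## 1. The producibility model

Metabolism is abstracted as a set of Boolean reactions over metabolite
identifiers: a reaction is a pair of non-empty sets (reactants, products)
plus a reversibility flag. Stoichiometric coefficients, fluxes,
thermodynamics and compartments are deliberately out of the model. The
semantics is pure reachability: given *seed* metabolites (the nutrients of
a condition), a reaction *fires* once all of its reactants are available
and makes its products available, and the *scope* is the least fixpoint of
this rule. The engine (`expansion_scope()`) implements the standard
counter-propagation algorithm — each rule keeps a count of unmet inputs and
fires when it reaches zero — which visits each rule input once and is
linear in network size; a naive rescan fixpoint serves as the oracle in the
test suite.

Assumptions worth keeping in mind when interpreting scopes:

* **Cost-free reactions.** Boolean semantics means producibility, not
  yield: a metabolite that requires an enormous flux detour counts the same
  as one a single step away.
* **Reversible reactions fire in either direction independently** (two
  directed rules per reversible reaction). The underlying reconstruction's
  reversibility calls therefore directly shape the scope.
* **Seeds-exclusive reporting.** The returned scope contains synthesized
  compounds only; a seed appears only if some fired reaction regenerates
  it. Both conventions are defensible; the exclusive one makes scope sizes
  count what the network *adds* to the medium, and the inclusive variant is
  exposed via `include_seeds = TRUE`. The producibility matrix records
  which convention produced it.
* **Identifier matching is exact string equality.** Reconciliation across
  namespaces is out of scope; networks and seed files must share a
  vocabulary.

Degenerate inputs are legal by design: a network with zero reactions has an
empty scope, seeds absent from the network are inert, and a reaction with
an empty reactant or product side is rejected at parse time (an
empty-reactant rule would silently behave as an unconditional seed
injection).

## 2. Nutrient conditions

Five nested conditions emulate increasingly rich soil solutions: a basal
medium of 43 seeds (inorganic C/N/S sources, water, oxygen, phosphate,
metal ions, coenzymes) contained in all four extensions — simple sugars
(+7), complex sugars / soil organic matter (+21), the eighteen non-sulfur
amino acids (+18), and all twenty amino acids (+20, adding cysteine and
methionine). `load_condition_library()` validates the sizes
(43/50/64/61/63), the basal-containment nesting, and that the two
amino-acid conditions differ exactly by the two sulfur amino acids.
Compounds whose identity the published summary table elides are shipped as
placeholder identifiers flagged `placeholder: true`; they preserve the
set arithmetic on synthetic universes and should be replaced with the
exact identifiers when simulating real reconstructions. Conditions are
network-independent: seeds missing from a network are simply inert.

## 3. Two scales, one community semantics

Each site is modelled at two scales: a single community-wide *metagenome*
network, and a *genome-resolved* collection of MAG networks. Community
producibility of the collection uses **mixed-bag pooling**: all members'
reactions are merged into one network (duplicate reaction content merges,
with provenance retained), so metabolites cross cell boundaries freely.
This is an upper bound of cross-feeding — no transporter or exchange
gating is modelled. The *cooperation potential* of a site is the community
scope minus the union of individual member scopes: compounds no member can
make alone. It is empty for singleton communities by construction.

## 4. The simulation grid and the producibility matrix

The grid crosses all systems with all conditions (canonically 6 sites × 2
scales × 5 conditions = 60 cells) and assembles the binary matrix whose
rows are the union of all scopes. Three post-processing rules:

* **Gap-fill artifact filter.** Genome-resolved reconstructions are
  routinely gap-filled; a metabolite producible in some genome-resolved
  simulation but in *no* metagenome simulation is treated as such an
  artifact and removed. The filter is idempotent and requires both scales.
* **Metabolite groups.** Rows with identical producibility vectors are
  collapsed; groups are the unit of the downstream regression. Group ids
  (`g0001`, ...) are assigned after sorting by (vector bit-string, first
  member id) and are therefore reproducible for a given matrix; note they
  are *matrix-relative* — permuting columns renumbers groups while leaving
  the partition intact.
* **Core metabolites.** Per scale, the rows producible in every
  site × condition cell of that scale.

A failed simulation aborts the build rather than imputing zeros, because a
zero is a biological statement here, not missing data.

## 5. Environmental association

Per environmental variable (pH, EC, organic matter, and element
concentrations; 17 in the emulated design), the standardized site
measurement is regressed on the groups' binary producibility states with an
elastic net at mixing parameter α = 0.85 (predominantly lasso with a ridge
component that tolerates correlated groups).

**Observation unit.** The methodology leaves open what an observation is;
the default here is one observation per simulation column, with the site's
measurement replicated across its 10 columns, because the regression is
fit "to the dataset" whose columns are the simulations. A site-aggregated
design (one observation per site, mean producibility) is available via
`build_design(..., design = "site")`. Every report records which design
was used.

**Penalty selection.** Replicated site responses would make random-fold
cross-validation leak badly, so folds are the sites themselves. With six
folds the CV error curve has very few effective replicates, and we found
the error-minimizing penalty unstable in a way that matters: under null
responses it frequently admitted nonzero coefficients, and on synthetic
benchmarks it produced several spurious selections per world. The package
therefore defaults to the one-standard-error rule (`penalty = "1se"`),
which restored near-perfect null behaviour at a negligible cost in
sensitivity at the benchmark effect size; `penalty = "min"` is available
for users who prefer the error-minimizing choice.

**Coefficient scale and the 0.3 threshold.** Responses are standardized to
unit variance; predictors are kept on their natural binary scale, so a
coefficient reads "shift of the response, in standard deviations, when the
group becomes producible". This keeps a single threshold meaningful across
variables measured in different units and across groups regardless of
their prevalence. Groups with |coefficient| strictly greater than 0.3 for
at least one variable are selected; the union of their members is the
*key metabolite* set. Selection is monotone in the threshold. No
multiple-testing correction is applied: coefficient magnitudes are
descriptive, not inferential.

**Variable clustering.** Selected-group coefficient profiles (absolute
values) are compared between variables with the Bray–Curtis dissimilarity
and clustered with Ward linkage (`ward.D2`), mirroring the heatmap
column clustering used to delineate groups of environmental variables.

## 6. Minimal communities

For each site's genome-resolved system, the requested targets (the key
metabolites, by default under basal medium) are first partitioned into
producible and unproducible by the full community — no subset can cover
what the whole cannot. The solver then finds the minimum cardinality k of
a member subset whose pooled scope covers the producible targets and
enumerates *all* subsets of size k that do:

1. **Contribution pruning** (sound): members none of whose reactions fire
   in the full-community expansion can never help and are dropped.
2. **Forced members** (sound): a member whose removal from the full
   community breaks coverage belongs to every solution; these are fixed
   and the search runs over the remainder only.
3. **Iterative deepening** over the remaining subset sizes with a compiled
   integer-indexed cover check (early exit once all targets are produced).

The search is exact — the test suite checks it against exhaustive
2^n subset enumeration — and deterministic (sorted member ids). Solutions
define *key species* (union), *essential syntrophic organisms*
(intersection; producibility bottlenecks) and *alternative* ones, with
MC:KS = 100·k/|key species| summarizing rigidity. Alternative members are
further grouped into substitutable classes: connected components of the
pairwise relation "swapping one for the other maps every containing
solution onto another solution" — the "OR" groups of a power-graph
summary, serialized as JSON rather than drawn. Enumeration is capped
(default 10,000 solutions); a truncated result is flagged partial and the
classification suppressed rather than reported from an incomplete set.

## 7. The synthetic-world generator

`generate_world()` builds benchmark datasets whose ground truth is known
by construction and recorded in a manifest. Structure and defaults:

* **Sites and organisms.** 6 sites, 8–20 organisms each.
* **Pathway templates.** 40 linear pathways of 2–6 reactions, rooted in
  basal seeds, with products drawn from a 300-metabolite universe (each
  template owns its products, so planted structures do not interfere).
  Half the templates additionally require one condition-specific
  co-substrate (a sugar or an amino acid, including cysteine/methionine
  for the strictest tier); without this the five conditions would be
  indistinguishable. Templates are present at each site with probability
  0.9 — most metabolism is broadly shared, variation is the exception —
  which also keeps decoy site-patterns from colliding with planted ones.
* **Cross-feeding splits.** With probability 0.3 a template instance is
  split between two organisms at a random cut; the downstream products
  become cooperation-only at that site (the manifest records them with the
  condition tier under which they are observable).
* **Redundancy.** With probability 0.15 an unsplit instance is duplicated
  into 2 organisms, planting an interchangeable-producer class.
* **Metagenome vs MAGs.** The site metagenome is the union of all template
  reactions plus "unbinned" metagenome-only templates (20% extra), so the
  metagenome scope strictly extends the community scope. Five gap-fill
  artifacts per world are injected as single-organism, basal-fed products
  excluded from the metagenome.
* **Environmental associations.** 4 basal-tier templates receive fixed,
  balanced site-presence patterns, pairwise distinguishable (overlap
  strictly between 0 and the pattern size — duplicated or complementary
  patterns would be statistically inseparable at six sites). Their
  variables are set to `sign · 0.6 · z(pattern) + N(0, 0.2)` per site; the
  remaining 13 variables are independent standard normal site noise.
* **Only irreversible reactions** are emitted, so the manifest's reachable
  sets are exactly the template combinatorics; reversibility is exercised
  by the unit and property tests instead.

What the generator does *not* emulate: real biochemistry (identifiers are
abstract), branched or cyclic pathway topologies, abundance-dependent
effects, annotation noise, or correlated environmental gradients. Passing
the benchmark therefore demonstrates algorithmic correctness and the
statistical operating characteristics under the stated conditions — not
robustness to reconstruction error in real data. A caveat specific to few
sites: with six sites, an independent noise variable will occasionally
match *some* site-varying group's pattern almost perfectly; such spurious
associations are genuinely present in the data and no penalty rule can
reject them while keeping true effects of similar strength. Benchmarks
here therefore score false positives on the planted variables; selections
on pure-noise variables are controlled (and tested) under the null design
but cannot be driven to zero at this number of sites.

## 8. Numerical and reproducibility choices

* All orderings use locale-independent radix sorting; artifacts are
  byte-stable across machines.
* Every stochastic stage is seeded from the configuration; identical
  configuration and seed give identical artifact checksums (tested), and
  the run report carries an md5 hash of the canonical configuration
  serialization.
* Ties in group naming are broken by first member id; solver output order
  is lexicographic in member ids.
* Problem sizes in the shipped tests are desk-scale by design: random
  networks up to 200 reactions for the oracle suites, communities up to 12
  members for exhaustive solver verification, and 20 generated worlds for
  the association benchmark; the full suite runs in about a minute.

## 9. Known limitations

* Mixed-bag pooling upper-bounds cross-feeding; compartments, transport
  and exchange costs are not modelled, so cooperation potential is an
  optimistic estimate.
* The elastic-net analysis with six sites is descriptive; coefficients
  carry no significance statements and should be read as ranked
  hypotheses.
* Exact enumeration is exponential in the worst case; the contribution and
  forced-member pruning make planted and typical instances fast, but
  adversarial redundancy structures can still blow up (the cap guards
  against runaway enumeration).
* Real-data headline numbers from any particular study depend on the
  deposited reconstructions and their gap-filling; this package
  reproduces the *procedure*, and its tests certify the procedure against
  synthetic ground truth.
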