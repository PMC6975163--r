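---
title: "Ensemble-driven curation targeting for metabolic models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble-driven curation targeting for metabolic models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemcurate)
```

## The problem

A draft genome-scale metabolic model (GEM) derived from genome annotation
usually cannot grow *in silico* on media where the organism demonstrably
grows: reactions are missing. Gap filling repairs this by selecting
reactions from a universal reaction database, but the selection is rarely
unique — many alternative repairs are equally consistent with the growth
data. Each alternative is a different structural hypothesis about the
organism, and the alternatives disagree about downstream predictions such
as gene essentiality. The question this package answers is: *given that
uncertainty, which single reaction should a curator resolve first to most
reduce the uncertainty of the predictions they care about?*

The strategy is an ensemble sensitivity analysis. We sample many
alternative gap-filled models, simulate genome-wide single-gene knockouts
with each, cluster the members by their simulation profiles, and then ask —
with a supervised classifier — which structural differences (presence or
absence of individual gap-filled reactions) predict cluster membership.
Reactions that do are the reactions whose uncertainty drives simulation
uncertainty, and they are ranked for curation.

## The gap-filling program

For one growth condition the package solves

$$\min \sum_{j \in \text{penalized}} |y_j|
\quad \text{s.t.} \quad S v + U y = 0,\;
v_\text{biomass} \ge 0.05\,\text{hr}^{-1},\;
v_{lb} \le v \le v_{ub},\; y_{lb} \le y \le y_{ub},$$

where $S$ is the draft model's stoichiometric matrix with flux vector $v$
and $U$ is the universal database with flux vector $y$. Only universal
fluxes are penalized; the draft's own reactions are free. The program asks
for the *minimum total absolute universal flux* that lets the model produce
a fixed small amount of biomass — a parsimonious-flux criterion repurposed
as a gap-filling objective. Universal reactions carrying more than the
activation cutoff of absolute flux at the optimum are the condition's
repair set.

Numerical choices:

* $|y_j|$ is linearized by the standard split $y_j = y_j^+ - y_j^-$ with
  $y_j^\pm \ge 0$ and objective $\sum (y_j^+ + y_j^-)$. At any optimum at
  most one of the pair is nonzero for penalized reactions.
* The strict growth inequality is implemented as $\ge$: linear programs
  need closed feasible sets, and at a positive floor the two are
  equivalent at any optimum.
* Knockouts are implemented by zeroing both flux bounds, not by removing
  the reaction, so the matrix shape is stable across repeated solves.

### The LP solver

No linear-programming package is available in this package's dependency
footprint, so the LP backend is a self-contained dense two-phase simplex
(`lp_solve()`, internal) for bounded problems: variables are shifted to
$0 \le y \le u$, upper bounds become explicit slack rows, phase 1
minimizes artificial variables, and phase 2 optimizes the true objective.
Pivoting uses Dantzig's rule with an automatic switch to Bland's rule (which
guarantees termination) after a burn-in, a pivot tolerance of $10^{-9}$, and
a phase-1 feasibility tolerance of $10^{-7}$. This is adequate because
every problem the package solves is small and dense — tens of metabolites
and at most a few hundred variables. The test suite cross-checks the
solver's optima against an independent LP implementation on randomized
problems to $10^{-7}$, and the gap-filling layer is additionally verified
against exhaustive universal-subset enumeration.

## Ensemble generation

One member is built by shuffling the media and gap filling condition by
condition; every reaction activated for an earlier condition becomes
penalty-free for the later ones, so a member tends to reuse its own
repairs. The union of activated reactions across conditions is the
member's recipe, and the draft plus that union reaches the biomass floor
in every input medium (asserted per member in the tests). Repeating with
fresh shuffles and restored penalties, then removing duplicate recipes
(set equality; media order ignored), yields the ensemble. Ensembles with
fewer than `min_unique` (default 3) unique recipes abort with a degenerate-
ensemble error: with one or two hypotheses there is no uncertainty
structure to analyze. The default of 1,000 cycles is the method's standard
operating point; saturation is checked empirically (below) rather than
assumed.

Randomness is controlled by a single master seed; member $i$ reseeds the
generator with `seed + i`, so ensembles are reproducible and individual
members can be regenerated in isolation.

## Ensemble simulations and saturation

Gene essentiality is simulated per member by single-gene knockouts under
FBA in *complete medium* — every exchange open at 1,000 mmol·gDW⁻¹·hr⁻¹ —
with an essentiality threshold of $10^{-6}$ units of biomass/hr. The
threshold is deliberately tiny: it distinguishes "can grow at all" from
"cannot", and the calls are insensitive to its exact value over several
orders of magnitude (asserted between $10^{-10}$ and $10^{-3}$ in the
tests). Because gap-filled reactions carry no gene rules, the gene
universe equals the draft's gene set; gap-filled content influences the
*calls*, not the gene list.

Whether an ensemble is large enough is diagnosed by subsampling: members
are drawn with replacement at sizes `step, 2·step, …` (default step 20,
1,000 draws per size) and the number of variable reactions — or of genes
with non-unanimous essentiality — within the draw is summarized by mean
and standard deviation. Because draws are iid, the expected count for a
feature with presence frequency $f$ at size $s$ is
$1 - f^s - (1-f)^s$, which is monotone non-decreasing in $s$; the tests
compare the empirical curves against this closed form. A plateau well
before the full size indicates the ensemble saturates its solution space.

## Clustering, classification, and the curation metrics

Before clustering, genes with *identical* essentiality patterns across the
ensemble are collapsed to a single variable and constant genes are
dropped. Without the collapse, blocks of perfectly correlated genes
dominate the Euclidean geometry and k-means produces grossly unbalanced
clusters; constant columns are dropped for the same reason (zero variance
cannot influence the partition, and correlation against them is
undefined). "Perfectly correlated" means exact column equality, not
anti-correlation.

k-means uses $k = 2$ — the minimal choice that yields a supervised
learning target — on the binary profiles treated as reals, with 300
maximum iterations and 10 random restarts keeping the best inertia. The
restart policy, rather than a specific acceleration or initialization
scheme, is the contract: on small fixtures the attained inertia is checked
against the exhaustive best two-partition. PCoA on pairwise Hamming
distances is computed for visualization only (double centering of the
squared distance matrix and eigendecomposition, checked against classical
scaling); negative eigenvalues are truncated to zero and excluded from the
explained-variance normalization — a safety net, since Hamming distances
on binary vectors embed in Euclidean space.

The cluster classifier is a random forest with 500 trees, Gini splits, no
depth limit, minimum 2 samples per split and 1 per leaf, $\sqrt{p}$
features per split, and bootstrap resampling. Its input is each member's
binary vector over the *variable* reactions; its target is the k-means
label. Out-of-bag accuracy is reported, with an optional 70/30 holdout as
an overfitting check. Two metrics are then extracted per variable
reaction:

* **Fractional importance** — Gini mean-decrease-in-impurity, normalized
  to sum to 1. High values mark reactions the forest needs, possibly
  through interactions with other reactions.
* **Cluster ratio** — $1 - \min(f_1, f_2)/\max(f_1, f_2)$ with $f_c$ the
  within-cluster presence frequency. The formula is reconstructed from its
  three defining anchors: 1 for a cluster-exclusive reaction, 0 for an
  evenly distributed one, and 0.5 for a reaction twice as frequent in one
  cluster ($1 - \tfrac12$). Reactions present in neither cluster are
  excluded as non-variable. The metric is symmetric under label swap and
  insensitive to member order, and it deliberately ignores the classifier:
  it flags low-abundance but cluster-exclusive reactions whose curation
  value a forest may underrate.

The ranked target table sorts by fractional importance, breaking ties by
cluster ratio and then reaction id.

## Evaluation and meta-analysis

When an experimental essentiality screen is available, each member is
scored by precision and recall over the genes shared between the screen
and the model (experimentally essential = positive class). Members
predicting no essential genes report *undefined* precision (NA) rather
than zero — coercing them to zero would silently distort cluster
comparisons. Cluster-level differences are tested with two-sided
Mann–Whitney U on precision and recall, Benjamini–Hochberg-adjusted across
the tests of one invocation; if a cluster retains fewer than two defined
values, the comparison degrades to NA instead of erroring.

Across species, per-reaction metrics are averaged over only the species in
which the reaction was gap filled, with the contributing species count
retained. Subsystem analysis assigns each reaction's value to every
subsystem it is annotated with (a reaction with two annotations is one
observation in each), keeps subsystems with at least 10 observations, and
applies Kruskal–Wallis followed by pairwise Dunn tests with Bonferroni
correction. Dunn's test is implemented in the package (mean-rank z
statistics with the standard tie correction) since no implementation is
available among the dependencies; for two groups its $z^2$ equals the
Kruskal–Wallis $H$, which the tests exploit as an independent check.

## The synthetic fixture generator

Real inputs to this kind of analysis are draft reconstructions, reaction
databases, and growth phenotype panels. The fixture generator replaces
them with toy universes small enough that ground truth is provable:

* **Pathways** are linear chains (exchange → transporter → precursor) whose
  only repair is a single direct reaction — gap filled in every member.
* **Split motifs** engineer order dependence. On medium B the direct repair
  is cheapest; on medium C a two-reaction route through a recycled cofactor
  is always cheapest and renders the recycling reaction penalty-free.
  If C precedes B in a member's shuffle, the freed recycling reaction tips
  the economics toward a bypass reaction `W_B`; otherwise the member goes
  without it. The bypass short-circuits the only draft reaction producing
  one biomass precursor, so its presence flips that reaction's gene from
  essential to nonessential — exactly the bimodal simulation signal the
  analysis is built to detect. Cost margins between competing routes are
  at least 25% of the optimum, far above all numerical tolerances.
* **Decoys** are dead-end universal reactions that cost flux and deliver
  nothing; no minimal solution ever includes them.

Minimal solutions per medium are written down analytically and, for
universes of at most 8 universal reactions, re-derived at generation time
by exhaustive subset enumeration; generation aborts on any disagreement.
`make_split_ensemble()` builds the 200-member parameter-recovery ensemble:
the bypass and the decoys are assigned to members as independent fair coin
flips (deduplicated; the all-absent and all-present members are forced in
so every feature is variable), and essentiality is then *simulated* by FBA
on each materialized member, never assigned.

What the fixtures do not emulate: genome-scale network size and
connectivity, mass-imbalanced or thermodynamically infeasible reactions,
complex gene rules on gap-filled content, multi-compartment transport, and
media with shared nutrient dependencies. Passing tests therefore certify
the algorithmic machinery — LP correctness, order-dependent ensemble
diversity, recovery of an engineered uncertainty driver — not biological
fidelity on real reconstructions.

## Parameters at a glance

| Parameter | Default | Units | Role |
|---|---|---|---|
| `biomass_floor` | 0.05 | hr⁻¹ | growth demanded during gap filling; represents binary "grows" |
| `activation_cutoff` | 1e-11 | mmol·gDW⁻¹·hr⁻¹ | \|flux\| above which a universal reaction counts as activated |
| `n` (cycles) | 1000 | — | gap-fill cycles before deduplication |
| `min_unique` | 3 | — | smallest admissible unique-member count |
| complete-medium limit | 1000 | mmol·gDW⁻¹·hr⁻¹ | uptake bound for every exchange in rich medium |
| `threshold` | 1e-6 | biomass/hr | knockout optimum below which a gene is essential |
| `step`, `draws` | 20, 1000 | — | subsampling grid and draws per size |
| `k` | 2 | — | number of simulation clusters |
| `ntree` | 500 | — | forest size |

## Problem sizes used in the test suite

The suite exercises the pipeline at deliberately small scale, chosen so
that every expected value is either provable or exhaustively enumerable:
toy universes with 3–8 universal reactions (full subset enumeration),
ensembles of 2–4 unique gap-filled members (all media orders enumerable),
a 200-member synthetic ensemble with 11 variable reactions for parameter
recovery and subsampling, and rank-statistic simulations with hundreds of
replicates. These sizes are the package's own verification design: they
make independent oracles exact rather than approximate.

## Known limitations

* The dense simplex targets small problems; genome-scale models (thousands
  of reactions) would need a sparse revised simplex or interior-point
  backend behind the same interface.
* Only single-gene knockouts are simulated; double-knockout interactions
  are out of scope.
* $k$ is fixed at 2. PCoA plots often suggest finer phenotypic structure;
  re-clustering within clusters, or larger $k$, is deliberately not
  implemented.
* SBML support is read-only (Level 3 FBC); the JSON dialect is the
  canonical interchange format.
* The cluster ratio treats both clusters symmetrically and says nothing
  about *which* cluster is right; it quantifies separation, not accuracy.
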