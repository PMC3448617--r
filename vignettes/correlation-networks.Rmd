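---
title: "Correlation networks of cephalometric features: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation networks of cephalometric features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cephnet)
```

## The problem

Class III malocclusion — protrusion of the lower dental arch relative to
the upper — arises from a tangle of skeletal features (short retrusive
maxilla, excess lower anterior face height, acute cranial base angle) and
compensatory dentoalveolar adaptations (proclined upper incisors,
retroclined lower incisors). Standard orthodontic diagnosis measures 21
cephalometric variables per patient (angles in degrees, distances in mm;
see `ceph_feature_info()`), but univariate summaries hide how the variables
move together. cephnet treats the variables as nodes of a network and their
sample correlations as weighted links, then asks structural questions of
that network: which features are hubs, which act as bridges between
subsystems, and which sets behave as a single tightly coupled module.

## The model

For each pair of features $x, y$ within a stratum the sample Pearson
correlation is

$$ r_{xy} = \frac{\langle xy\rangle - \langle x\rangle\langle y\rangle}{s_x\, s_y}, $$

computed with matching denominators so the $n$ vs $n-1$ convention cancels.
The complete weighted graph on the 21 features is then filtered: features
are linked iff $|r_{xy}| > c$ with cutoff $c = 0.40$ by default. Two
contracts matter here:

* **Strict inequality.** A pair at exactly the cutoff is *not* linked. Ties
  at the boundary are measure-zero in real data but the contract must be
  fixed; we read the magnitude filter literally.
* **Signs are kept.** High negative correlations mark negative-feedback
  couplings (e.g. between skeletal divergence and incisor compensation) and
  carry as much structure as positive ones; the graph stores the signed
  $r$ on every edge. All topology, however, is computed on the unsigned
  skeleton — degree, bridges, components and modules are questions about
  which links exist, not their direction of association.

Isolated nodes stay in the graph, so graphs from different strata share a
fixed 21-node set and are directly comparable.

No p-value or multiple-testing filter is applied: edge selection is by
magnitude only. `correlation_pvalues()` emits Fisher-z p-values for
information, never for selection.

### Topology

* **Hubs** are the most-connected nodes: degree ranking, ties broken
  lexicographically, and the top-$k$ cut keeps every node tied with the
  $k$-th degree so no hub is dropped by an arbitrary tie split. The default
  $k = 3$ matches how many hubs a 21-node stratum network typically
  exposes; it is configurable.
* **Bridge nodes** are articulation points: nodes whose removal strictly
  increases the number of connected components among the remaining nodes.
  We formalize "bridge" as a cut *vertex*, not a cut edge, because the
  object of clinical interest is the feature that couples two subsystems.
* **Components** are reported ordered by decreasing size, then by
  lexicographic minimum, for deterministic reports.

### Cliques and power-graph modules

A clique — a feature set in which every pair is linked — is the motif of
interest: such a subsystem tends to act as a whole. `maximal_cliques()`
reports all maximal cliques of at least `min_size = 3` members (the 3–5
node range typical of these networks).

`power_decompose()` compresses the graph losslessly into *power nodes*
(feature sets) and *power edges*: a clique self-edge expands to all
within-set pairs, a biclique edge between two disjoint sets to all cross
pairs. The reference implementations of power-graph analysis are external
plugins with unspecified parameters, so this package fixes a deterministic,
testable procedure instead:

1. **Candidates**: every subtree of a complete-linkage dendrogram over
   Jaccard distance of *closed* neighbourhoods, plus every maximal clique.
   Closed neighbourhoods (node included) make adjacent, similarly wired
   nodes cluster early; candidates only propose, never decide.
2. **Greedy exact cover**: repeatedly select the candidate power edge
   covering the most yet-uncovered source edges, requiring every expanded
   pair to be a real uncovered edge. Ties break by fewer total members,
   then lexicographically. Power-node sets must stay pairwise disjoint or
   nested.
3. **Stop** when no candidate covers at least 2 uncovered edges; leftovers
   become residual edges.

Because every selection covers only uncovered real edges, expansion
reproduces the source graph edge-for-edge — a round-trip the test suite
asserts on hundreds of random graphs. The procedure makes no minimality
claim (minimum power graphs are NP-hard); it is deterministic, exact and
recovers planted block structure, which is what the analysis needs.

`min_module` (default 2) is the minimum size of every power node,
including each side of a biclique. With the default, a star (one hub
against a set of leaves) is left as residual edges rather than compressed
behind a singleton power node; set `min_module = 1` to allow stars. We
chose 2 because a singleton "module" carries no co-occurrence information.

### Stratification

The cohort pipeline stratifies by age into G1 [7, 11), G2 [11, 13),
G3 [13, 15), G4 [15, 18) years — half-open brackets so they tile without
gaps; "7 to 10 years" is read as *through* age 10. Ages outside all
brackets (cohorts of this kind start around 6 y 4 m) are excluded and
counted, not errored. Severity stratification splits a group at the Wits
appraisal: mild > −3 mm, severe ≤ −3 mm, the conventional cut for Class III
anteroposterior dysplasia; by default only the oldest group (G4) is split,
mirroring how severity contrasts are usually examined at the end of growth,
with `severity_group = "all"` available. Strata with fewer than 3 subjects
are skipped with an explicit report entry — a correlation is undefined
there. The analysis pipeline itself contains no randomness; identical
inputs give byte-identical JSON reports.

## The synthetic-data generator

Clinical cephalometric records of this kind are not publicly deposited, so
validation rests on synthetic cohorts with *planted* structure
(`synthetic_config()`, `simulate_cohort()`). The generator states a world
and the tests check the pipeline recovers it:

* **Stratum sizes** default to 240/89/105/98 (G1–G4, total 532), the
  design of the cohort this package emulates.
* **Correlation structure** is a block model: disjoint feature blocks with
  common within-block correlation, individual cross-links (housing the
  negative structural-to-adaptive couplings), and a background correlation
  (default 0) elsewhere. The assembled target matrix is repaired to
  positive semidefinite by eigenvalue clipping at zero followed by
  symmetric rescaling to unit diagonal, iterated to tolerance
  (`nearest_psd()`, `epsilon = 1e-8`) — deterministic and verifiable by
  direct eigendecomposition. A matrix already PSD passes through unchanged,
  so the repair is idempotent.
* **Sampling** is multivariate normal via the symmetric eigen square root.
  Nothing distributional is claimed by the analysis beyond what Pearson
  correlation assumes; the normal is the minimal model consistent with it.
* **Marginals**: feature means/SDs default to clinically plausible Class
  III female values (e.g. SNA 80° ± 3.5°, anterior facial height
  112 ± 7 mm). They only set scales — correlation is affine-invariant, and
  the test suite asserts exactly that invariance.
* **Wits** is both one of the 21 features and the severity variable. Its
  marginal defaults to −3.5 ± 2.5 mm: untreated Class III cohorts centre
  around −4 to −3 mm, and this choice straddles the −3 mm cut so both
  severity classes are populated.
* **Ages** are uniform inside each group's bracket. Only bracket bounds
  are stated for the emulated design; uniform is the least-informative
  choice. The generator does not produce sub-7-year subjects even though
  real cohorts include some — those rows exercise the exclusion path via
  tests instead.
* The shipped default (`default_synthetic_config()`) plants three blocks —
  mandibular-sagittal (SNB, Co-Gn, Go-Pg), maxillomandibular-divergence
  (NS-GoGn, PP-PM, NMe), adaptive-dentoalveolar (IMPA, FMIA, Interincisal,
  Overjet) at within-block r = 0.7 — and two negative cross-links
  (NMe–IMPA, SNB–FMIA at −0.5). These are *synthetic* values chosen for
  testability, named after the qualitative feature groups of the domain;
  they are not estimates from clinical data.

What a green test establishes: the estimator, threshold, topology and
module machinery recover known structure from normal data at the stated
sample sizes. What it does not establish: anything about real craniofacial
growth — real data have nonlinear age trends, heteroscedasticity,
measurement error (≈0.6°/0.9 mm at digitization) and missingness the
generator deliberately omits.

## Numerical choices

* Correlations are clamped to $[-1, 1]$ after computation; the matrix is
  symmetrized by averaging to remove floating-point asymmetry before
  thresholding.
* Strict mode errors on any missing value; opt-in
  `pairwise_complete = TRUE` computes each entry over complete pairs and
  records per-entry `n_used`.
* Degenerate (zero-variance) features are errors that name the offending
  feature — silently emitting `NA` would propagate into the graph stage.
* GraphML is written by the package's own serializer with 17 significant
  digits so a write/read round-trip is exact to the bit; the files remain
  readable by igraph, Cytoscape and yEd.
* All tie-breaks (hubs, components, clique ordering, greedy cover) are
  lexicographic on feature names, making every report deterministic.
* Seeds: `simulate_cohort()` seeds R's RNG from `config$seed` and restores
  the caller's RNG state afterwards; identical configs give bit-identical
  tables.

## Known limitations

* No partial correlations, regularized precision matrices or bootstrap
  edge-stability — edge selection is a plain magnitude threshold by design.
* The power-graph decomposition is greedy; it can differ from a minimum
  power graph and from other tools' outputs on dense, ambiguous graphs.
  Its guarantees are exactness of expansion and determinism, not
  minimality.
* Module detection ignores sign; a module mixing positive and negative
  edges is reported with its sign mix rather than split.
* Weighted or betweenness centralities are out of scope; "hub" means
  degree.
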