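---
title: "Methods: differential phosphoproteomics, motif attribution and network hubs with phosnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential phosphoproteomics, motif attribution and network hubs with phosnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosnet)
```

phosnet implements the quantitative analysis that sits downstream of a
SILAC phosphoproteomic screen comparing the signaling of two receptors —
the motivating use case is an atypical chemokine receptor (ACKR2) against
a conventional one (CCR5), each profiled constitutively and after agonist
stimulation at short and extended times. The package covers four stages:
regulation calling from replicate SILAC ratios, cross-receptor set
summaries, kinase attribution of regulated sites by consensus sequence
motifs, and topology analysis of the protein network spanned by the
differentially phosphorylated proteins (DPPs), with hub selection
validated against degree-preserving random networks.

## The regulation-calling model

Input is a site-level quantification table in the MaxQuant
"Phospho (STY)Sites" tradition: one row per phosphosite, with a protein
accession, the phosphoacceptor residue (S/T/Y), a ±6-residue sequence
window, and per-replicate heavy/light SILAC ratios per condition. In this
design each mixed sample is itself a comparison — the heavy and light
channels carry the two biological states — so a `comparison_design()`
names the condition whose ratio columns it reads and records what the two
channels contained. This is why the package has no separate
numerator/denominator arithmetic: the instrument already measured the
quotient.

Calling proceeds in three steps, each a small pure function:

1. **Normalization** (`normalize_ratios()`): every condition–replicate
   ratio column is divided by $2^{\mathrm{median}(\log_2 r)}$ so its
   median log2 ratio is exactly zero. This mirrors the peptide-level
   median centering performed inside quantification software; our input
   is site-level, so the column-wise analogue is applied and is
   idempotent by construction.
2. **Presence filtering** (`filter_by_presence()`): a site must be
   quantified in at least `min_present` of the replicates (default 2 of
   3) to be considered positively identified; the remainder is routed to
   a `not_quantified` table, never silently dropped.
3. **Geometric-mean thresholding** (`call_regulation()`): the geometric
   mean $\left(\prod_i r_i\right)^{1/n}$ of the present replicate ratios
   is compared against strict thresholds — up-regulated if
   $\bar r_g > 1.5$, down-regulated if $\bar r_g < 0.67$ (a more than
   50% change in either direction), unchanged otherwise. Values equal to
   a threshold are deliberately `unchanged`: the thresholds are quoted as
   strict inequalities, and the boundary case is resolved conservatively.
   The geometric mean uses only the present replicates, since the filter
   has already guaranteed at least two.

No multiple-testing correction is applied: the calls are pure
fold-change thresholds, and identification-level false-discovery control
is the upstream search engine's responsibility, outside this package's
scope.

A protein is differentially phosphorylated when at least one of its
sites is regulated. When a protein carries both up- and down-regulated
sites, both directions are reported (`directions = "up|down"`) rather
than a net call — site-level phosphorylation changes on one protein are
not additive quantities, so no aggregation rule is imposed. Shared
regulation between two receptors is likewise reported both ways:
`summarize_sets()` distinguishes shared-coherent targets (direction sets
intersect) from shared-discordant ones, because requiring or ignoring
direction coherence are both defensible readings of "shared".

## Kinase motif attribution

Regulated sites are attributed to candidate kinases by matching their
13-mer sequence windows (positions −6…+6; windows truncated at protein
termini are padded with `_`, which never matches) against a consensus
motif library. The motif dialect is plain text — `PKA<TAB>R-R-x-S*` —
with offsets inferred from the starred phosphoacceptor and bracketed
residue sets such as `[ST]` for disjunctive positions. Matching is
count-based, not probabilistic: the analysis this package reproduces
works on absolute counts of motif-attributed sites, so position weight
matrices would add parameters without adding fidelity to that statistic.

A site may match several kinases and then contributes one count to each
(deduplicated within a kinase's patterns); the per-receptor total is the
number of (site, kinase) attributions. The cross-receptor statistic is
the **percentage ratio**
$$\frac{a(k)/A}{b(k)/B},$$
the relative attribution of kinase $k$ under receptor A versus receptor
B. A value of 1 means equal relative activity; a kinase attributed only
under A yields `Inf` and one attributed under neither yields `NaN` —
both sentinels are propagated, never dropped, so downstream tallies
(`count_kinases_more_active()`, strict ratio > 1) remain auditable.

The shipped library (`default_motif_library()`) contains twelve widely
cited consensus patterns (basophilic PKA/PKC/CaMKII/AKT, proline-directed
CDK1/MAPK, acidophilic CK2/CK1/PLK1, GSK3, ATM/ATR, and an acidic
tyrosine motif). It is an illustrative default: no public motif source is
canonical for this analysis, and results on real data depend on the
library supplied. Two library-design constraints matter for
benchmarking: no default motif is a structural subset of another (CaMKII
ships as `R-x-x-[ST]*-[ILVF]`, the fuller consensus, precisely so PKA's
`R-R-x-[ST]*` does not nest inside it), and the generator
rejection-samples planted windows until they match only their planted
motif. Together these make noiseless planted-count recovery exact, which
the tests assert.

## Network topology and hub selection

The network stage starts from the DPP list. Edge tables in the STRING
evidence-export tradition are filtered by
`filter_edges()`: an edge survives when its `experiments` channel score
is ≥ 0.15 **or** its `databases` score is ≥ 0.35 (inclusive bounds,
disjunctive channels). `build_network()` then induces the subgraph on
the DPPs — isolated DPPs are kept as nodes; an opt-in
`keep_interactors` flag retains first-shell non-DPP interactors, off by
default since the induced-subgraph reading is the conservative one. Two
modes exist: `ppi_undirected`, and `signaling_mixed` in which
activation/inhibition edges are directed and docking edges undirected;
edge signs carry semantics only and do not alter path topology.

`compute_centralities()` evaluates the full battery — betweenness,
bridging, centroid, closeness, eccentricity, eigenvector, radiality,
stress, in-degree and out-degree — with the formulas stated in its help
page, following the conventions of the CentiScaPe family of tools
(reciprocal eccentricity, centroid as the minimum γ-difference, bridging
as betweenness × bridging coefficient). Numerical conventions worth
stating explicitly:

* Betweenness counts **ordered** source–target pairs and is
  unnormalized. Hub selection by "above the mean" is invariant under any
  uniform scaling, so this choice cannot change hub sets; it is fixed
  for reproducibility of the raw values.
* Path-based sums run over reachable nodes only; isolated nodes take 0
  by convention, and disconnected components can never produce a
  division by zero (tested).
* Radiality and the diameter are computed per connected component
  (weak connectivity defines components in mixed mode).
* The eigenvector centrality is the principal eigenvector of the
  underlying undirected adjacency, scaled to unit maximum — directed
  variants of eigenvector centrality are ill-conditioned on the small,
  frequently non-strongly-connected signaling networks this stage sees.

Hubs are the nodes whose betweenness strictly exceeds the network's
arithmetic mean betweenness (`select_hubs()`). The phrase "mean value of
betweenness above the mean" admits a second reading — a node's
betweenness averaged across several time-point networks, then compared
to the mean — and because the package exposes `select_hubs()` on any
profile table, that reading is available by averaging profiles before
selection; the per-network rule is the default.

Statistical support comes from degree-preserving randomization
(`rewire_network()`): repeated double-edge swaps that exactly conserve
every node's degree (out- and in-degree sequences separately in directed
mode; the directed and undirected edge pools of a mixed network are
rewired separately), rejecting swaps that would create self-loops or
multi-edges. The default of 10 × (edge count) attempted swaps is the
standard mixing heuristic for edge-swap Markov chains.
`null_distribution()` rewires the observed network `n_random` times
(default 1000; smaller values are appropriate for small networks, where
the null is coarse anyway), recomputes betweenness each time, and
reports per node the add-one empirical p-value
$$p = \frac{1 + \#\{\text{replicates} \ge \text{observed}\}}{n_{\text{random}} + 1},$$
which is never zero, together with a long-format table of per-replicate
mean betweenness ready for violin plots.

## What the synthetic-data generator emulates

`simulate_phosphosites()` emulates the experimental design: three
biological replicates per condition, a planted fraction of up/down
regulated sites at chosen true ratios (defaults 2.0 and 0.5), lognormal
multiplicative noise on ratios — normal on the log2 scale, the standard
SILAC error model — missing replicates MCAR, and optional planted
kinase motifs in the sequence windows. The default `noise_sigma = 0.25`
is a free parameter chosen as a realistic replicate spread for SILAC
ratio data, not an estimate from any particular dataset; the
benchmarking runs in the tests use 0.2 at 2,000 sites with 10% planted
in each direction, and report sensitivity and false-discovery proportion
against the recorded ground truth (observed: sensitivity ≈ 0.99, FDP
well below 0.1 under those conditions).

`simulate_network()` draws Erdős–Rényi or Barabási–Albert graphs and can
plant connector nodes: the non-connector nodes are split into
communities, each wired internally, and consecutive communities joined
*only* through their connector, so every inter-community shortest path
passes through it and its betweenness provably exceeds the graph mean.
Edges carry uniform evidence scores and, in signaling mode, random
relations.

What the generator does **not** emulate bounds what green tests mean for
real data: no peptide-level evidence or localization ambiguity, no
ratio compression or intensity-dependent variance, no correlated
missingness (censoring at low intensity), no shared-peptide protein
inference, and planted motifs are unambiguous by construction whereas
real windows match promiscuously. Passing recovery tests therefore
demonstrates the correctness of the arithmetic and the pipeline's
bookkeeping, not the biological error rates to expect on an instrument
run.

## Reproducibility machinery

Every stochastic entry point takes a seed, and the pipeline derives
per-stage seeds deterministically from the single global seed
(`seed × 7919 + stage offset, mod 2^31 − 1`), so any stage can be re-run
in isolation with identical results. Identical configurations produce
byte-identical TSV outputs (numeric columns are written with a fixed
15-significant-digit format); the JSON run report records the
configuration hash, seed, stage counts and, for synthetic runs, the
confusion matrix of calls against ground truth. Problem sizes used in
the test suite (graphs of up to 12 nodes against brute-force oracles,
exhaustive enumeration of all connected graphs of up to 6 nodes for the
betweenness cross-check, 2,000-site recovery runs over 10 seeds,
200-node rewiring checks, 50-replicate nulls on 21-node planted
networks) were chosen so the whole suite documents the method at
laptop scale.

## Known limitations

* The motif library is a stand-in; per-kinase counts on real data are
  only as good as the supplied consensus patterns, and count-based
  attribution ignores site accessibility and kinase expression.
* Protein-level calls inherit the one-regulated-site rule; a single
  noisy site can flag a large protein.
* The all-pairs geodesic engine is exact but dense
  ($O(nm + n^3)$ per network); it is intended for the hundreds-of-nodes
  networks DPP analyses produce, not for proteome-scale graphs.
* Empirical p-values are resolution-limited at $1/(n_{\text{random}}+1)$
  and are not corrected across nodes; they support ranking and sanity
  checks, not strict error control.
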