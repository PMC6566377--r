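---
title: "Phyletic patterns of protein families across the green lineage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phyletic patterns of protein families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogcpipe)
```

## The question and the analysis

Land plants (embryophytes, Emb) arose from within the charophyte green
algae (Cha). Charophytes split into the basal KCM clade
(Klebsormidiophyceae, Chlorokybophyceae, Mesostigmatophyceae) and the ZCC
clade closest to land plants (Zygnematophyceae, Coleochaetophyceae,
Charophyceae); chlorophyte algae (Chl) serve as the outgroup. A protein
family present in charophytes and embryophytes but absent from
chlorophytes most parsimoniously arose in the Cha+Emb common ancestor —
the lineage that adapted to land. The analysis this package implements
turns that idea into counts: cluster all proteins of a species panel into
families, read each family's phyletic pattern, and ask which functions are
over-represented among families of a given evolutionary age.

The pipeline has five stages, each an exported function group, orchestrated
by `run_pipeline()`:

similarity hits → `filter_hits` → `build_similarity_graph` + `mcl` +
`retain_multispecies` → `classify_ogc`/`tabulate_groups` →
`transfer_annotations` → `count_terms` + `enrich_group` + `top_report`.

## Hit filtering

Input is the 14-column tabular similarity format (`qseqid sseqid pident
length mismatch gapopen qstart qend sstart send evalue bitscore qlen
slen`). A hit survives when `evalue < 1e-5` **and** query coverage
`(qend − qstart + 1)/qlen > 0.5`. Both comparisons are strict: a hit at
E = 1e-5 exactly, or at coverage 0.50 exactly, is removed. Coverage is
computed per row (per HSP) with the query length as denominator; subject
coverage plays no role in the default analysis. Self-hits are dropped at
filter time. The same machinery filters HMM domain hits (`evalue < 1e-15`,
HMM coverage > 0.8) for CAZyme-style screens; that filter is exposed but
not part of the clustering path.

## Clustering into orthologous gene clusters

Each unordered protein pair is weighted by the mean of `−log10(E)` over
its surviving directed best rows (one or two; the best row per ordered
pair is the lowest E-value, ties broken by bitscore). E-values of zero are
floored at 1e-200, capping weights at 200. Each node receives a self-loop
equal to its maximum incident weight (1.0 if isolated), which damps
oscillation in the Markov iteration.

The Markov cluster algorithm is implemented from scratch: make the
adjacency matrix column-stochastic, then alternate *expansion* (matrix
squaring) and *inflation* (element-wise power, column renormalisation)
until the matrix stops changing (`max |ΔM| < 1e-6`, at most 100
iterations; non-convergence is a warning, not an error). Entries below
1e-8 are pruned after each inflation — a numerical choice, not a modelling
one. Clusters are the connected components of the attractor support
(attractors = rows with positive diagonal); a non-attractor node joins the
attractor with its largest matrix entry, ties resolved toward the
lexicographically smallest attractor id so the partition is deterministic.
Disconnected components are clustered independently; this is exact, since
expansion and inflation never mix components.

Inflation defaults to 1.5, the convention of orthology pipelines built on
MCL. The species-pair weight normalisation of full orthology suites is
deliberately omitted — the synthetic acceptance world is defined against
this package's own clustering, and the simplification is stated rather
than hidden.

A cluster becomes an **orthologous gene cluster (OGC)** only if it has at
least two proteins from at least two species. Singletons and
single-species clusters are excluded (and counted): with transcriptome-
derived proteomes such proteins are enriched for falsely predicted ORFs.

## Phyletic classification

For each OGC, presence of the three major groups (Chl; Cha = KCM or ZCC;
Emb) determines one of nine mutually exclusive labels:

| label | rule |
|---|---|
| Chl+Cha+Emb | all three major groups present |
| Cha+Emb | Cha and Emb, no Chl |
| Chl+Cha | Chl and Cha, no Emb |
| Chl+Emb | Chl and Emb, no Cha |
| Emb | only embryophytes (≥ 2 species) |
| Cha | only charophytes, both KCM and ZCC present |
| ZCC | only ZCC (≥ 2 species) |
| KCM | only KCM (≥ 2 species) |
| Chl | only chlorophytes (≥ 2 species) |

The implementation evaluates all nine predicates and asserts that exactly
one fires — the partition property is enforced at every call, not assumed.
`classify_ogc()` refuses species sets of size < 2 (retention happens
first) and unknown species or clade strings; clade names are a
case-sensitive controlled vocabulary.

Reports: `tabulate_groups()` (per-group OGC, protein and max-species
counts, with conserved totals), `venn_counts()` (the seven regions of the
Chl/Cha/Emb Venn diagram; the charophyte-only region pools the Cha, ZCC
and KCM groups), and `species_occupancy()` (per species × group, the
number of OGCs containing that species — OGC counts, not protein counts).
The group table's "max species" column reports the *observed* maximum
number of distinct species in an OGC of that group.

## GO annotation transfer

The ontology is read from OBO 1.2 text; only `is_a` edges are used
(`part_of`/`regulates` are out of scope), obsolete stanzas are dropped,
dangling edge targets and cycles are errors. A term's **level** is 1 plus
the length of the shortest `is_a` path to its namespace root. Shortest
path is the more common convention for "GO level"; it is a convention, not
a fact about the ontology, and the level threshold is a parameter
(`go_level`, default 6) rather than a constant.

Transfer: per query protein, hits with `evalue < 1e-10` (strict) whose
reference carries at least one GO term are considered; **all** hits tied
at the minimum E-value contribute, and the query receives the union of
their terms ("the hits with the lowest E-values", read literally, is a set).
GO-less references are ignored *before* taking the minimum, so a GO-less
best hit does not block annotation by the next-best GO-bearing hit.
Unannotated queries are simply absent from the annotation map. Terms are
counted as transferred — there is no true-path propagation to ancestors;
deeper terms are excluded by the level filter rather than mapped up. Both
choices mirror a transfer-based annotation workflow and are the
documented defaults.

Annotation rates per phyletic group are percentages of annotated member
proteins, rounded half-up to two decimals (the convention of the printed
tables; R's own `round()` rounds half to even).

## Enrichment against the control group

The control is the Chl+Cha+Emb group — families conserved across the whole
panel, hence functionally "background". For each tested group and each
term at the chosen GO level carried by at least one annotated protein of
that group:

- `n_T` — GO-annotated proteins in the tested group (unannotated proteins
  are excluded from the trials, not failures);
- `k_T` — those carrying the term;
- `p0 = k_C / n_C` — the control group's fraction for the same term.

The p-value is the exact binomial upper tail
`P = Σ_{j=k_T}^{n_T} C(n_T, j) p0^j (1−p0)^{n_T−j}`, computed in log space
(`lchoose` + log-sum-exp) so deep tails (P ≈ 1e-200) remain accurate. A
two-sided variant (the point-probability method, matching the behaviour of
the standard exact test) is available; the default is one-sided "greater"
with an explicit direction filter, because only over-representation is
reported. Adjustment is Holm step-down by default (the default of the
standard `p.adjust`), BH optional, applied across all terms tested within
one group — the families of tests are per-group, matching per-group
reported term counts. Terms absent from the control (`p0 = 0`, where any
`k_T > 0` is impossible under the null) are computed and flagged
`degenerate`, never silently dropped. `top_report()` sorts significant
terms by adjusted p (ties: larger tested fraction, then term id) and adds
the `−log10(p_adj)` column used for bar-chart reports.

### A calibration caveat

The test treats `p0` as a *known* constant, but it is estimated from the
control sample. When the control dwarfs the tested group the extra
variance is negligible — in the study-scale analysis the control has
80,871 annotated proteins, 13–900× larger than most tested groups. When
tested and control groups are of comparable size, however, the method is
measurably anticonservative: in desk-scale null simulations with
`n_T ≈ n_C` (a few hundred each) the family-wise false-positive rate
reached ~0.5 at a nominal 0.05, driven by terms whose control count was
small by chance. The package's null-calibration acceptance test therefore
evaluates the method in its valid regime (tested group ≈ 170 annotated
proteins vs control ≈ 1,200, the outgroup-group ratio of the real panel),
where the measured family-wise error is 0.090 against a Monte-Carlo bound
of 0.096. Users comparing two groups of similar size should prefer a
two-sample test; for the largest tested group in a study-scale analysis,
enriched-term lists near the significance boundary deserve suspicion.

## The synthetic cohort

The generator states a world and keeps it fixed:

- **Panel**: 2 Chl, 2 KCM, 5 ZCC, 5 Emb species — the shape of the real
  14-species panel.
- **Group mixture**: the nine groups are drawn with probabilities
  proportional to the observed group sizes of the study panel
  (5031 : 4174 : 1221 : 140 : 4849 : 3600 : 3807 : 66 : 2597).
- **Presence sets**: for a family of group *g*, species presence is
  sampled by independent Bernoulli(0.5) draws *within the clades g
  allows*, rejected until the nine-way rule for *g* holds. Conditioning
  independent draws on "forbidden clades absent" is exactly equivalent to
  never drawing them, so this is unbiased uniform-within-rule sampling
  with acceptance probability ≥ 1/4.
- **Proteins**: 1–3 per present species per family; lengths uniform in
  200–1200 residues (typical protein lengths).
- **Hits**: every ordered intra-family pair gets a hit with E log-uniform
  in 1e-180..1e-20 and query coverage realised exactly, uniform in
  0.55–0.95 (safely above the 0.5 filter; real within-family alignments
  rarely sit at the threshold). Self-hits are emitted, as real search
  output contains them, so parsers and filters are exercised against them.
  Poisson-many decoy inter-family hits (mean 1 per family) violate either
  the E-value rule (E in 1e-4..1) or the coverage rule (0.05–0.45), so by
  construction none survives filtering.
- **Ontology**: one full binary tree of depth 6 per namespace (three
  namespaces), so level-6 terms exist in every namespace; 32 level-6 terms
  per namespace.
- **GO reference**: one reference per query with E in 1e-180..1e-20
  (< 1e-10); each reference carries 1–3 background level-6 terms drawn
  uniformly, plus the planted term with probability `p_planted = 0.4` for
  proteins of planted-group (Cha+Emb) families and `p_background = 0.05`
  elsewhere — a strong but not caricatural enrichment effect.
- **Seeding**: each artifact (families, hits, GO reference) uses its own
  RNG stream derived from the master seed by a fixed label hash, so
  adding an artifact never perturbs the others; equal seeds give
  byte-identical TSVs.

What the generator does **not** emulate: sequence-level evolution (E-values
are drawn, not computed from alignments), assembly artifacts beyond decoy
singletons, correlated GO terms (real ontology annotations are strongly
correlated along the DAG), incomplete transcriptomes, and species-specific
protein-count asymmetries. A green end-to-end test therefore establishes
that the *pipeline machinery* — filtering, clustering, classification,
transfer, testing — is correct on data whose truth is known, not that the
biological conclusions of any particular study are right.

## Numerical and degenerate-input choices

- Strict inequalities at every printed threshold (1e-5, 0.5, 1e-10, 1e-15,
  0.8): boundary rows are excluded, and tests pin the boundaries.
- E = 0 hits are legal input; they weight as 200 after flooring.
- MCL pruning (1e-8) and convergence (1e-6) are numerical knobs; on
  clique-structured graphs the output provably equals the components for
  any inflation > 1, which the acceptance suite checks on 50 random
  instances.
- `binomial_test` is validated against brute-force pmf summation for all
  n ≤ 25, k, and p0 ∈ {0.1, 0.3, 0.5, 0.9} (relative error ≤ 1e-12) and
  spot-checked against the standard exact test; Holm/BH are validated
  against the standard adjustment routines. The reference implementations
  are cross-checks only — the package's own code is what runs.
- Empty inputs: empty hit files parse to empty tables; an empty OGC set
  tabulates to zeros; a zero-protein group reports a flagged 0% rate; a
  control with no annotated proteins is an error.

## Pipeline configuration

`validate_config()` accepts a named list or JSON file; unknown keys fail
with a nearest-key suggestion, and every threshold is range-checked before
any stage runs. Defaults: `max_evalue_cluster = 1e-5`, `min_qcov = 0.5`,
`max_evalue_go = 1e-10`, `max_evalue_domain = 1e-15`, `min_hmm_cov = 0.8`,
`inflation = 1.5`, `go_level = 6`, `alpha = 0.05`,
`adjust_method = "holm"`, `alternative = "greater"`, `top_n = 20`,
`control_group = "Chl+Cha+Emb"`. `run_pipeline()` writes every
intermediate artifact plus `manifest.json` (config hash, seed, per-stage
counts and wall times) and enforces protein-count conservation
(excluded + clustered = graph nodes). Identical (config, seed) produce
byte-identical artifacts. The exported functions *are* the command-line
surface: each stage is one call, and `scripts/acceptance.R` shows the
end-to-end invocation.

```{r example, eval = FALSE}
res <- run_pipeline(list(n_families = 300, seed = 1), outdir = "run1")
res$group_table
res$top_reports[["Cha+Emb"]]
```

## Known limitations

- No species-pair weight normalisation in clustering; on panels with very
  uneven proteome sizes, large-proteome species can dominate edge weights.
- No within-cluster ortholog/paralog distinction; OGCs are protein
  families, nothing finer.
- GO levels by shortest path only (longest-path semantics would shift
  which terms sit at level 6); no ancestor propagation before counting.
- The one-sample binomial's anticonservativeness for tested groups
  comparable in size to the control (see the calibration caveat above).
- Dense per-component MCL: components are expected to be family-sized
  (hundreds of nodes at most); a single near-complete component of many
  thousands of nodes would need a sparse implementation.
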