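---
title: "Weighted voting for miRNA-disease association prediction: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted voting for miRNA-disease association prediction: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdvote)
```

## The problem and the modelling assumption

Curated miRNA-disease association databases are sparse binary matrices:
a 1 records an experimentally verified association, a 0 records *absence of
evidence*, not evidence of absence. The prediction task is one-class link
prediction on this bipartite network. The package's core assumption is the
standard one in this field: functionally similar miRNAs tend to associate
with phenotypically similar diseases. Everything in the pipeline is a way of
(a) building similarity networks that are informative despite the sparsity
and (b) propagating the verified associations along them — in a single
weighted-voting pass, with no iteration to convergence.

## Similarity construction

**Credibility similarity.** External similarity sources are incomplete, so
the association matrix itself is recycled as a similarity source. Verified
entries are recoded to a credibility $\delta > 1$ and undetermined entries
to a base code (default $-1$), and the similarity of two miRNAs is the inner
product of their recoded rows (diseases: columns). With the $-1$ base code,
two profiles agree positively both where they share verified partners
($\delta^2$ terms) and where both are undetermined ($+1$ terms), and
disagree ($-\delta$) where exactly one is verified; $\delta$ controls how
strongly shared verified partners dominate. The raw inner products are then
rescaled row-wise to $[0,1]$:
$$CM_{ij} = \frac{(CM1_{ij} - \min_i)(CM1_{ij} - \min_j)}
                 {(\max_i - \min_i)(\max_j - \min_j)},$$
where the extrema of row $i$ *include* its zeroed diagonal entry. The
diagonal is zeroed before rescaling precisely because the huge
self-inner-product would otherwise compress every other entry; including
the zeroed entry in the extrema is the convention under which the package's
worked 3x2 example rescales to the exact values its tests pin (0, 1, 1). A
row with no spread at all carries no information and its rescaling factor is
defined as 0. The rescaling is invariant to positive scaling of the raw
inner products, which the tests assert.

**Semantic similarity.** Each disease is a term in an ontology given as a
flattened child-to-parent edge list. The disease's ancestor graph $T(D)$
contributes $1$ for the disease's own term and, for any ancestor $d$,
$\max\{\omega \cdot c(d')\}$ over its children $d'$ inside the graph —
a geometric decay ($\omega = 0.5$ by default, in $(0,1]$) with the shortest
ancestor distance, which a BFS oracle confirms in the tests. Similarity is
the summed two-sided contribution of shared ancestors normalised by the two
semantic values; it is symmetric, unit-diagonal and in $[0,1]$, and adding a
shared ancestor can only increase it. "Children of $d$" means children
within the disease's own ancestor graph, not the global ontology: the
contribution of a term is defined per disease. A disease whose term is
missing from the ontology falls back to a singleton graph with a warning —
it can then match others only through itself — rather than aborting a whole
run for one unmapped label.

**Integration and filtering.** The external and credibility similarities are
averaged entry-wise, and the diagonal is then forced to 1: the credibility
similarity has a zero diagonal by construction, but voters must keep
self-similarity 1 so that a verified pair's own vote is never discounted.
The integrated matrix is noisy, so each row is sparsified independently:
sort the off-diagonal values descending; take the hypothetical position
$p_h = \mathrm{round}(r k)$ (half-up, clamped to $[1, k-1]$, $k$ = row
length); locate the value $v$ at $p_h$ and its level bin
$[\lfloor 10v \rfloor / 10, \lfloor 10v \rfloor / 10 + 0.1)$; find the
positions of the values closest to the two bin edges (leading point $p_l$ at
the upper edge, following point $p_f$ at the lower; ties go to the smaller
position); and cut at
$$p = \begin{cases} p_f & p_f < 2p_h \\ p_l & p_f \ge 2p_h,\; p_l > p_h/2 \\
2p_h & \text{otherwise,} \end{cases}$$
clamped to $[1, k-1]$. Values before the cut keep their matrix positions;
the rest become 0. Boundary equalities deliberately fall to the fallback
branch $2p_h$ — the branch conditions are strict, and the fallback is the
conservative middle ground. The fixed 0.1 bin width matches similarity
values living in $[0,1]$; bins are half-open with a $10^{-9}$ guard against
floating-point edge values. Because each row cuts independently, the
filtered matrix is generally asymmetric and is *not* re-symmetrised by
default (each row is that entity's own view of its neighbours);
`mdv_params(symmetrize = "max")` restores symmetry for experimentation.

## The voting model

Row and column voter counts $N_{m_i} = \sum_s A_{is}$,
$N_{d_j} = \sum_t A_{tj}$ are the group sizes. Each verified association
votes for every pair in its row and column; the vote received by candidate
$(m_i, d_j)$ from the voter at $(m_i, d_s)$ is
$N_{m_i}^e \, D(d_s, d_j) / (N_{m_i} + N_{d_j} - A_{ij})$, and symmetrically
with $M$ and $N_{d_j}^e$ for column voters. Accumulated over all voters this
gives the closed form implemented in `score_matrix()`:
$$F_{ij} = \frac{N_{m_i}^e \sum_s A_{is} D(d_s, d_j)
               + N_{d_j}^e \sum_t A_{tj} M(m_t, m_i)}
               {N_{m_i} + N_{d_j} - A_{ij}}.$$
The basic weight's denominator is indexed by the *receiving* candidate.
This is the property that makes the design fair and is asserted exactly
(to $10^{-12}$) in the tests: with group influence off and all similarities
equal, every unverified candidate connected to at least one voter receives a
total vote mass of exactly 1, while a voter receives
$(N_{m_i}+N_{d_j})/(N_{m_i}+N_{d_j}-1) > 1$ because its self-vote is counted
once in its row sum and once in its column sum (no deduplication). A pair
connected to no voter has denominator 0 and is defined to score 0 — it
receives no votes, so no division is ever actually needed; the rule only
guards degenerate inputs. Similarity rows index the voter side
($M(m_t, m_i)$ is voter $t$'s filtered row evaluated at candidate $i$),
which matters once filtering has broken symmetry. Scores are not normalised
afterwards: only ranks are interpreted.

The vectorised implementation is tested against a literal vote-casting
triple loop on random instances, and the rank-based AUC used in evaluation
against an exhaustive pairwise-comparison oracle (and `pROC`).

## Tunable parameters

| parameter | default | range | role |
|---|---|---|---|
| `delta` | 2 | $>1$ | credibility of a verified association (dimensionless recode) |
| `base_code` | $-1$ | real | credibility of an undetermined pair; $+1$ available for the alternative convention, but the $-1$ error structure above is the model's native reading |
| `omega` | 0.5 | $(0,1]$ | per-level semantic decay |
| `r` | 0.1 | $(0,1]$ | filter ratio: assumed reliable fraction of each similarity row |
| `e` | 1/3 | $\ge 0$ | group-influence exponent; 0 disables group weight |

`delta` and `r` interact and are dataset-dependent;
`hyperparameter_sweep()` grids both over seeded five-fold CV. The defaults
are sensible centre points, not tuned optima: `delta = 2` keeps the
$\delta^2$ co-association term dominant without drowning the undetermined
agreements, and `r = 0.1` assumes roughly the top tenth of a similarity row
is reliable, which matches the filter's bin heuristic on unit-interval
similarities. `e = 1/3` keeps group influence sub-linear so large groups
speak louder but cannot monopolise the ranking.

## Evaluation protocol

Five-fold CV splits the *positives* into five seeded folds; all negatives
stay in the test side, as the one-class setting dictates. For each fold the
entire downstream model — credibility similarity, integration, filtering,
voter counts, scores — is rebuilt from the masked matrix, and a test
confirms the masked pairs enter the fold's credibility matrix as
undetermined. The external similarities `FM` and `SD` are *not* recomputed
per fold: they derive from independent data sources (expression-based
functional similarity; the ontology), not from the association matrix, so
holding them fixed is the leak-free reading. Held-out positives are ranked
against all zero pairs of the full matrix; AUC uses midrank tie credit.
Five repeats with different splits are averaged by default. Global LOOCV
masks each positive in turn and ranks it against all unknown pairs of the
whole matrix; each trial trains on strictly more positives than a CV fold,
so its AUC is expected at or slightly above the five-fold mean.

## The synthetic generator

`make_network()` plants latent groups shared by all three data sources:
group-structured associations (within-group probability boosted by a factor
of 10 by default, normalised so the expected density is 3% — the sparsity
regime of curated association databases), a group-indicator functional
similarity with ±0.1 uniform jitter, and an ontology hanging each disease
term under its group term (occasionally via a private intermediate level)
below a common root. A cell-wise permutation of the association matrix
serves as the null: it preserves the verified-pair count but destroys group
structure *and* degree identity. Permuting axis labels alone would not be a
valid null, because the credibility similarity learns from the association
matrix itself and would still recover its intact co-association structure.

Default problem sizes were chosen to be the smallest that exhibit the
method's behaviour clearly: 60 x 40 with 4 groups for the standard network
(~72 positives, mean row degree ~1.2), smaller instances (up to 24 x 16)
for protocol tests, and 200-row samples for the filter's sort-oracle
property.

What the generator does *not* emulate: heavy-tailed degree distributions
(real hub diseases have hundreds of associations), block-free similarity
structure, name vocabularies, or ontology DAGs with multiple parents per
term on the disease path (the random tests cover multi-parent graphs; the
generator's ontology is a tree). Under the default conditions roughly a
quarter of planted positives fall outside their group by construction, so
even a perfect group-recovery oracle cannot reach an AUC much above ~0.8;
the planted-versus-null AUC margin the acceptance checks assert (≥ 0.2) is
therefore evidence of signal recovery under deliberately hard, sparse
conditions — not a performance ceiling of the method on real, richer data.
Passing tests show the machinery is correct and recovers planted structure;
they do not certify absolute AUC levels on any real database.

## Numerical conventions collected

* Symmetry of a loaded similarity matrix is recorded at tolerance $10^{-8}$;
  file round-trips are exact to $10^{-12}$ (17 significant digits written).
* `round(r k)` is half-up, not banker's rounding.
* "Closest to a bin edge" ties resolve to the smallest sorted position;
  equal similarity values sort by smaller matrix index first.
* $0^e$ is defined as 0 for every $e \ge 0$ (an empty group has no voice).
* Zero denominators (pair connected to no voter) score 0 by definition.
* Constant credibility rows rescale to factor 0; row extrema include the
  zeroed diagonal.
* The association matrix's first-appearance axis order is canonical; writing
  an association matrix normalises disease order to row-major first
  occurrence, and an edge list cannot represent zero-degree entities — one
  round trip is idempotent, and extra similarity labels are dropped with a
  warning while missing ones are an error.

## Known limitations

* One-class evaluation against "all unknown pairs" treats unverified true
  associations as negatives; reported AUCs are therefore conservative.
* The credibility similarity is powerful on dense rows but nearly
  uninformative at row degree ≤ 1, which is common at 3% density; the
  integration then halves the external similarity's contrast. On very sparse
  matrices a larger `r` (gentler filtering) can help.
* The filter's fixed 0.1 bin width presumes unit-interval similarities;
  feeding unscaled similarity matrices violates that assumption.
* Global LOOCV rebuilds the model once per positive; on a full-scale
  database (hundreds of thousands of pairs, thousands of positives) expect
  runtimes in hours, and prefer the five-fold protocol for exploration.
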