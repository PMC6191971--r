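---
title: "Methods: iterative multiple-model rule extraction for case-control expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iterative multiple-model rule extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camur)
```

## The model

`camur` classifies samples of a labeled FPKM expression matrix (samples in
rows, genes in columns, one class label per sample) with **rule models**:
a model for a positive class is a disjunction of conjunctions of threshold
literals,

$$\bigvee_k \bigwedge_j \; (g_{kj} \lhd_{kj} t_{kj}), \qquad \lhd \in \{<, \ge\},$$

and predicts the positive class iff at least one conjunction covers the
sample, else the default class. `<` is strict and `>=` closed, so a sample
sitting exactly on a threshold is *not* covered by a `<` literal. Rules
are fully human-readable, which is the point: the unit of extracted
knowledge is the gene/threshold pair, not a weight vector.

### The learner

`learn_model()` is an IREP*-style sequential covering learner in the
RIPPER family, with the canonical published settings as defaults (all are
`learner_params()` arguments):

* **grow/prune split**: stratified 2/3–1/3 of the not-yet-covered samples;
* **growing**: greedily append the literal maximizing FOIL information
  gain $p_1(\log_2 \frac{p_1}{p_1+n_1} - \log_2 \frac{p_0}{p_0+n_0})$,
  over candidate thresholds placed at midpoints between consecutive
  distinct sorted values whose flanking label sets differ (only those
  midpoints can change any confusion count);
* **pruning**: repeatedly delete the final literal while the worth metric
  $v = (p-n)/(p+n)$ on the prune set does not decrease, preferring the
  shorter conjunction on ties;
* **MDL gate**: stop adding conjunctions when the total description length
  (ruleset encoding plus exceptions) exceeds the best seen plus 64 bits.
  Only relative description lengths matter; the encoding lives behind one
  function and can be swapped;
* **optimization**: two passes in which each conjunction is re-grown from
  scratch (replacement) and extended (revision) on the samples not covered
  by the other conjunctions, keeping the description-length-best variant,
  followed by a sweep deleting conjunctions whose removal does not
  lengthen the description;
* **positive class**: `"auto"` resolves to the minority class (ties
  lexicographic), overridable because published example rules sometimes
  predict the majority class.

Determinism is a contract: the same matrix, parameters and seed produce a
bit-identical model. All tie-breaks are total orders (lower gene column
index, then `<` over `>=`, then smaller threshold).

### The single-literal floor

One deliberate deviation from canonical RIPPER: after optimization,
`learn_model()` compares the ruleset's training F-measure with the best
single threshold literal (found over all candidate thresholds) and
returns the literal if it is strictly better. On matrices of realistic
size this never triggers — sequential covering wins. On tiny matrices
(a dozen samples), a 2-sample prune set can tie the worth metric and
delete a perfect literal, leaving an empty model; the floor restores the
guarantee that the learner never loses, on training F, to a model it can
trivially represent. The cost is that on pure-noise data the returned
model may carry one overfit literal instead of being empty; the
cross-validated F gate downstream rejects it either way.

### Validation

The reported per-model metric is stratified k-fold cross-validation
(default `k = 10`), pooling confusion counts over held-out folds before
deriving precision, recall, F-measure and accuracy. The engine records
this choice in the run manifest. When a class has fewer samples than `k`
(the 45-sample cohort shape has 9 normals), `k` is shrunk to the smallest
class size, never below 2. Empty models skip CV: they cover nothing, so
recall and F are 0 by the metric conventions (0 on empty denominators).

## The extraction engine

`run_camur()` implements the iterative loop. Iteration 1 learns on the
full matrix. An accepted model (CV F-measure at or above
`min_f_measure`, default 0.8) contributes its genes to the cumulative set
$S$ and spawns new *elimination combinations*; each later iteration
removes one pending combination's columns and re-learns. Rejected models
are recorded for audit but contribute no genes and no knowledge-base
rows.

* **strict mode**: the only pending combination is always $S$ itself —
  each round eliminates every gene seen so far. Linear in the number of
  models; accepted models have pairwise disjoint gene sets.
* **loose mode**: an accepted model with feature set $F$, learned under
  eliminated combination $C$, enqueues $C \cup \{f\}$ for every
  $f \in F \setminus C$, skipping combinations already seen — a
  breadth-first FIFO walk of the combination lattice. Worst-case
  exponential in $|S|$, and by construction the distinct-gene set found
  in loose mode contains the strict-mode set on the same data and seed.

Stopping criteria, checked in fixed order after each iteration:
(i) the iteration cap (default 100); (iii) the pending queue is empty
after having grown at least once (every combination derivable from
accepted models was eliminated); (ii) the queue is empty and never grew —
no model passed the gate, so there was nothing to eliminate. The
published phrasing is ambiguous about what "all current runs below the
threshold" means; this disambiguation reproduces both edge cases the
design fixes (a pure-noise matrix stops at iteration 1 with reason
`f_below_threshold`; a fully redundant 2-feature toy ends with
`combinations_exhausted`). A combination spanning *every* gene column is
skipped, since eliminating it would leave nothing to learn from.

Per-iteration learner seeds are drawn once from the master seed, so runs
are deterministic and manifests byte-identical across repetitions.

## The knowledge base

`kb_create()` holds four relational tables — runs, models, conjunctions,
literals — with referential integrity and per-conjunction correct/
incorrect cover counts on the training matrix. The intended backing store
for this kind of artifact is an embedded relational database; SQLite
bindings are not available in the target environment, so the store is
plain data frames persisted as a single JSON document. The contract is
the schema, not the engine, and the export/import cycle is tested to be a
fixed point for all five queries.

The five queries: **features** (occurrences count a gene once per model,
matching how published occurrence tables count rules containing a gene);
**conjunctions** (per-model rows with cover counts and percentages, plus
an aggregate count of models sharing the identical conjunction);
**rules** (one row per accepted model with stored metrics, F-descending);
**literal statistics** (threshold min/mean/max grouped by gene and
operator); **feature pairs** (unordered gene pairs co-present in the same
model — per model, not per conjunction, because published example pairs
come from OR-rules). All orderings are total (ties broken
lexicographically) so query output is deterministic.

### Numeric round-tripping

Literal thresholds are rounded to 6 significant digits at creation, so
the canonical rule text
`(<gene> < <t>) OR ((<gene> >= <t>) AND (<gene> < <t>)) => <class>`
re-parses to exactly the stored structure. Stored metrics are rounded to
15 significant digits because the JSON serializer emits at most 15, making
the export a bitwise fixed point under re-import. Matrix CSV output
prints full precision (17 digits, trimmed) so write/load is an identity.

## The synthetic generator

`generate_dataset()` emulates the statistical shape of an FPKM matrix at
desk scale, not its biology. Background genes are i.i.d. log-normal
(log-mean 2, log-sigma 1 — non-negative, heavy right tail,
class-independent). Each informative gene shifts its tumoral values on
the log scale by `shift` background standard deviations, up or down; at
shift 6 the class-conditional ranges are disjoint with overwhelming
probability at n = 60, giving single-literal separability. Redundancy is
planted as *independent* shifted genes rather than correlated copies —
the simplest world in which alternative, equivalent models exist, which
is the phenomenon the engine is built to surface. Columns are randomly
permuted so planted genes occupy no fixed positions.

What the generator does **not** emulate: library-size effects, gene–gene
correlation, overdispersion, batch structure, or any count-level noise
model. A green test therefore establishes that the algorithmic machinery
(learning, gating, elimination, bookkeeping) behaves as specified — not
that the learner's thresholds would be biologically meaningful on real
cohorts.

Canonical fixtures (`make_fixture()`): `table1_toy` (a 3x3 worked-example
layout), `chol_shape` (45 samples, 36/9 — the smallest published cohort
shape, exercising the CV fold shrink), `redundant6` (60 samples, 6
independently separating genes — the alternative-model recovery
scenario), `null60` (no informative gene — the immediate-stop scenario).
Generation is seed-deterministic down to the CSV bytes.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_f_measure` | 0.8 | CV F-measure gate for accepting a model |
| `max_iterations` | 100 | cap on learner invocations per run |
| `mode` | loose | elimination strategy (see above) |
| `split_frac` | 2/3 | grow fraction of the grow/prune split |
| `mdl_slack` | 64 bits | description-length slack before rule addition stops |
| `opt_passes` | 2 | ruleset optimization passes |
| `k_folds` | 10 | CV folds (shrunk to the smallest class if needed) |
| `positive_class` | auto | minority class unless overridden |

The engine defaults (loose, 100, 0.8) reproduce the reference run
configuration for the published cohort analyses.

## Known limitations

* Two-class problems only; multi-class rule ordering is out of scope.
* Missing values are rejected, not imputed.
* Loose mode is worst-case exponential in the number of extracted genes;
  the iteration cap is the practical bound.
* The rule-text grammar assumes gene identifiers without spaces or
  parentheses (true of Ensembl-style ids).
* Thresholds at 6 significant digits could, in adversarial data with
  near-identical values, collapse onto a data value; with continuous
  FPKM-like values this has measure zero.
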