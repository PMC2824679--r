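---
title: "Patient active learning for citation screening: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient active learning for citation screening: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palscreen)
```

This vignette is the package's own account of the science it implements:
the screening model and its assumptions, the parameters that matter and
their defaults, what the synthetic benchmark does and does not emulate, and
the numerical choices made where the design was genuinely open.

## The screening model

Level-1 citation screening is cast as pool-based active learning over a
fixed corpus of `N` citations. A reviewer (the oracle) provides labels at a
cost; the goal is not out-of-sample accuracy but *complete recall on this
corpus at minimal reading effort*. The two metrics, Yield and Burden, are
therefore computed over a combined accounting: citations labeled during
training enter with their reviewer labels (the reviewer is assumed never to
erroneously exclude an eligible citation, so training false negatives are
structurally zero), and the final model's predictions cover only the
remainder. A strategy that happens to *find* the difficult eligible
citations during training is rewarded — it no longer has to classify them.

Citations live in four views — title words, abstract words, keyword terms,
concept-identifier terms — with one linear soft-margin SVM per view and the
deliberately cautious aggregation *relevant if any view says relevant*. An
all-zero vector in a view (empty title, no keywords) makes that view
abstain rather than vote irrelevant; a citation empty in every view
defaults to relevant. Ties exactly on a hyperplane classify relevant. All
three choices trade specificity for sensitivity, which is the correct
direction for this application.

## Why "patient": exploration before exploitation

Uncertainty sampling (SIMPLE) queries the unlabeled citation nearest the
current hyperplane. When the relevant class occupies several vocabulary
clusters, SIMPLE can commit to the first cluster's boundary and never
discover the others — hasty generalization. PAL stays in a random
exploration phase until the *diversity* of the labeled relevant citations —
the mean pairwise angle between their unit vectors in kernel space — has
converged, and only then hands control to SIMPLE. Because all vectors are
unit length, the linear kernel is the cosine and the angle is a natural
between-citation dissimilarity.

Two details are underdetermined by that description and are fixed here:

* **which kernel space hosts the angle** — computed per view over the
  labeled relevant citations (zero vectors skipped; a view needs at least
  two non-zero vectors to contribute) and averaged across views. This
  treats the views symmetrically; a single-view variant would privilege one
  representation for no principled reason. With fewer than two usable
  vectors the score is undefined and the loop simply stays in exploration.
* **what "converged" means** — the score is evaluated once per batch, and
  the switch fires when `patience` consecutive batch-to-batch changes are
  all `<= epsilon`. A change exactly equal to `epsilon` counts. The switch
  is one-way by construction.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `batch_size` | 5 | labels | labels acquired between retrainings; the protocol's batch size |
| `eval_interval` | 25 | labels | learning-curve grid; must be a multiple of `batch_size` |
| `epsilon` | 1 | degrees | diversity tolerance; degrees give it an interpretable scale — one degree of mean angular change over a batch is small relative to the 60–90° spread of distinct topics |
| `patience` | 3 | batches | consecutive quiet batches required; guards against a single uninformative batch triggering the switch |
| `stop_fraction` | 0.5 | fraction of N | the half-corpus stopping criterion; `ceiling(stop_fraction * N)` labels, conservatively rounded up |
| `runs` | 10 | — | repeated simulation runs; run `r` uses `seed + r - 1` |
| `cost` | 1 | — | soft-margin C, linear kernel, deliberately untuned |
| `aggressive` | TRUE | — | final undersampling mode |
| `interim_undersample` | TRUE | — | in-loop models train on a randomly balanced subset so early models are not majority-swamped |
| `min_df` | 3 | documents | vocabulary floor for text views, applied per view over the whole corpus |

`epsilon` and `patience` have no canonical values; they are surfaced in
`pal_config()` precisely because any fixed choice is a judgment call. The
defaults above make the switch fire after a handful of quiet batches, which
on the packaged benchmarks leaves the exploration phase long enough to
touch every relevant cluster in almost every run (this is tested).

One consequence of batch-level convergence checking is worth stating
plainly: a batch that adds no new relevant citation leaves the diversity
score exactly unchanged, and that zero change counts toward convergence. At
very low prevalence the switch can therefore fire early during an unlucky
quiet stretch. This is inherent to the convergence rule rather than a bug;
raising `patience` trades label budget for cluster coverage.

## Featurization choices

TF-IDF is fixed as `tf * ln(N/df)` with raw within-document counts,
followed by L2 unit normalization; keyword/concept views use binary
presence in place of `tf` (terms rarely repeat within one record) with the
same idf and normalization. Unit vectors make the SVM's linear kernel a
cosine, keep hyperplane distances comparable across citations of different
lengths, and give the diversity angle its meaning — the three consumers of
the geometry all depend on this normalization. The `min_df` floor applies
to the text views only (its purpose is taming the open vocabulary of free
text; keyword and concept lists are already controlled vocabularies) and is
computed once over the whole corpus, labeled and unlabeled alike, since the
pool is fully available before learning starts. Tokenization is the
simplest reproducible rule — lowercase, split on any non-alphanumeric run,
drop PubMed stopwords — with no stemming, n-grams, or embeddings, and the
four views are never concatenated into one space: uncertainty geometry in a
concatenated space would be dominated by the highest-dimensional view.

## Class imbalance

Before any final (deployable) model is trained, the labeled irrelevant
majority is undersampled to class balance. The standard remedy discards
random majority examples; *aggressive* undersampling instead discards the
majority examples nearest the current hyperplane — exactly `m = #irrelevant
- #relevant` of them, per view, with "nearest" read as smallest *absolute*
signed distance, since an imperfect separator can have majority points on
either side. Ties break toward the lower citation index for determinism.
Dropping the boundary-hugging majority pushes the retrained hyperplane away
from the minority class, converting false negatives into false positives —
the right trade here. The reference hyperplane for choosing removals is
trained on the raw labeled pool; with random undersampling a single shared
balanced draw is used across views (the labeled subset is a
view-independent concept; aggressive removal is necessarily per view).

In-loop models used only to rank candidates for selection present a quieter
version of the same imbalance problem; they train on a randomly balanced
subset (`interim_undersample`). They are also solved at a looser SMO
tolerance (0.01 vs the 0.001 of final models): selection needs only a
distance *ranking*, not a converged decision boundary. During exploration
no model is consulted, so none is fitted.

## Protocol arithmetic

Seeding provides exactly two labels (one per class, drawn at random — in
practice review teams always know at least one relevant citation). The
first batch is truncated so that the labeled count lands on the
`batch_size` grid (3 labels under the defaults), which makes the
learning-curve evaluations fall exactly on multiples of `eval_interval`;
the last batch is truncated at the stop boundary so the budget is hit
exactly. Every source of randomness — seed labels, exploration draws, the
k-sided view coin, undersampling draws — flows from the single run seed, so
a run is exactly reproducible and a multi-run simulation is a deterministic
function of `(seed, runs)`.

## The synthetic benchmark

The generator emulates the *shape* of real screening corpora: a few
thousand citations, 5–12% relevant, the relevant class split across
disjoint-vocabulary topic clusters. Relevant citations draw each token from
their cluster's signature vocabulary with probability `1 - noise` and from
the shared background vocabulary otherwise; irrelevant citations draw
background tokens only; keyword/concept lists follow the same mixture over
their own smaller vocabularies. Defaults: background vocabulary 2,000,
signature 25 terms per cluster, mean title/abstract lengths 10/120 tokens,
`noise = 0.5` — i.e. half of a relevant citation's tokens are topical, a
deliberately realistic middle ground between trivially separable
(`noise = 0`) and signal-free (`noise -> 1`), chosen once and not tuned.
The packaged `benchmark_suite()` mirrors the sizes and prevalences of three
real systematic-review datasets (N = 4,751 at 5.1%, N = 1,606 at 12.2%,
N = 4,010 at 6.4%), each in 1- and 2-cluster variants.

What the generator does *not* model — Zipfian term frequencies, correlated
vocabulary between the classes, MeSH hierarchy, linguistic structure,
near-duplicate citations — bounds what passing tests show: they validate
the *mechanics and ranking* of the strategies (full yield at the stopping
point, PAL at least matching SIMPLE, the U-shaped burden curve), not the
absolute burden reductions a real review would see. Real corpora are
harder; the package's claims about them are the protocol's, not the
benchmark's.

## Numerical and degenerate-input choices

* SVM fits go through one deterministic SMO solver; model orientation is
  normalized post-fit so relevant examples always score positive.
* Gram (linear-kernel) matrices are computed once per corpus per view and
  every in-loop fit and distance evaluation is a submatrix operation; the
  returned models materialize explicit primal weights so
  `signed_distance()` is exact arithmetic, `(w·x + b)/||w||`.
* `acos` arguments are clamped to `[-1, 1]` before angles are taken.
* Diversity with fewer than two usable vectors, Yield with zero
  gold-relevant citations, and selection from an empty pool are all
  explicit signals (stay-in-exploration, `NA` with a warning, and an error,
  respectively) rather than silent numbers.
* Batches, undersampling and selection all break ties toward the lower
  citation index.

## Problem sizes used in the packaged checks

The test suite exercises the full protocol at the benchmark scale the
two-cluster suite defines: the N = 1,606 benchmark end-to-end, and the
N ≈ 4,000–4,751 shapes at N = 1,000 with their prevalences kept (the
generator makes corpus size a free parameter, so the protocol's behaviour —
not the corpus — is what the larger sizes would re-measure). Stochastic
properties average 10 seeded runs, matching the protocol's repeat count.

## Known limitations

* The diversity heuristic measures coverage only through angles among
  *found* relevant citations; a cluster never sampled during exploration is
  invisible to it. The guarantee is statistical, not absolute.
* Aggressive undersampling assumes the labeled irrelevant pool is large
  enough that discarding `m` points leaves a usable majority sample; at
  tiny budgets the final classifiers rest on very few points, which is why
  small-budget burden is high (the model over-flags) — visible as the left
  arm of the U-shaped burden curve.
* Concept extraction is out of scope: the concept view consumes
  pre-extracted identifier lists and is empty (abstaining) without them.
* The interactive screen mode trusts the reviewer's labels absolutely;
  there is no adjudication or noise model for oracle error.
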