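# palscreen

Semi-automated citation screening for systematic reviews with **Patient
Active Learning (PAL)**.

## The problem

Level-1 screening of a systematic review means manually triaging every
title/abstract returned by a broad literature search — typically 2,000 to
5,000 citations of which only 5–12% are relevant — because wrongly excluding
a single eligible study threatens the validity of the review. `palscreen`
trains a classifier interactively with the reviewer and lets it exclude the
clearly irrelevant remainder, so the reviewer screens only the citations
seen during training plus those the model flags as relevant.

Two properties make this harder than ordinary text classification and shape
every design choice in the package:

* **asymmetric costs** — a false negative (a missed eligible citation) is
  far more costly than a false positive, so the whole pipeline is
  sensitivity-first;
* **class imbalance** — relevant citations are rare, so an untreated
  maximum-margin classifier drifts toward the minority class and produces
  false negatives.

## The method

Each citation is represented in *k* = 4 feature spaces (views): title
bag-of-words, abstract bag-of-words, MeSH-like keywords, and pre-extracted
biomedical concept identifiers, each TF-IDF weighted
(`tf · ln(N/df)`, L2-normalized; text tokens appearing in fewer than 3
documents are dropped, as are PubMed stopwords). One linear soft-margin SVM
(C = 1, untuned) is trained per view and the ensemble predicts **relevant
if any view predicts relevant**.

Labels are acquired by pool-based active learning. Plain uncertainty
sampling (SIMPLE: query the unlabeled citation nearest the current
hyperplane) is prone to *hasty generalization* when the relevant class has
several topical clusters: it refines the first boundary it finds and never
discovers the other clusters. PAL is patient instead:

1. **explore** — query citations uniformly at random, tracking the
   *diversity* of the labeled relevant citations (mean pairwise angle
   between their unit vectors, averaged over views); when that score changes
   by ≤ ε for `patience` consecutive batches, the minority class is assumed
   covered;
2. **exploit** — switch (once, irreversibly) to SIMPLE, flipping a fair
   k-sided coin per query slot to pick the view whose hyperplane is used;
3. **finish** — at the stopping criterion (by default, half the corpus
   labeled), *aggressively undersample* — per view, drop the labeled
   irrelevant citations nearest the hyperplane until classes balance, which
   pushes the retrained boundary away from the relevant class — retrain,
   and classify the remaining pool.

Screening approaches are scored on the whole corpus, not a hold-out set:

* **Yield** = (tp_T + tp_U) / (tp_T + tp_U + fn_U) — the fraction of truly
  eligible citations identified, whether discovered during training (T) or
  predicted (U);
* **Burden** = (tp_T + tn_T + fp_T + tp_U + fp_U) / N — the fraction of
  citations a human still reads.

Manual screening is the (100%, 100%) anchor; the aim is Yield = 100% at the
lowest possible Burden.

## Worked example

Real screening corpora are rarely shareable, so the package ships a
generator of synthetic corpora with controllable size, prevalence and
minority cluster structure:

```r
library(palscreen)

spec   <- synthetic_spec(N = 500, prevalence = 0.1, n_clusters = 2, seed = 42)
corpus <- generate_corpus(spec)     # tibble: id, title, abstract, keywords,
                                    # concepts, label, cluster

stp <- apply_stopping_criterion(corpus, "pal_aggressive",
                                pal_config(runs = 3, seed = 0))
tidy(stp)
#> # A tibble: 3 × 5
#>     run  seed labels_used yield burden
#>   <int> <int>       <int> <dbl>  <dbl>
#> 1     1     0         250     1  0.656
#> 2     2     1         250     1  0.684
#> 3     3     2         250     1  0.642
```

Each run seeded the labeled pool with one citation per class, explored
until the relevant-diversity score stabilized, exploited with SIMPLE, and
stopped at 250 labels (half of N). Yield 1 means no eligible citation was
lost; burden ≈ 0.66 means the reviewer read about 34% fewer citations than
manual screening. A single run exposes its full decision trace:

```r
run <- run_pal(corpus, config = pal_config(seed = 0))
glance(run)
#> # A tibble: 1 × 5
#>   n_labeled n_unlabeled n_relevant_found switch_batch final_diversity
#> 1       250         250               25            8            83.0
tidy(run)            # per-batch phase, chosen views, indices, labels
autoplot(run)        # diversity trajectory with the phase switch
```

Learning curves over the full protocol (evaluate the deployable ensemble
every 25 labels until the pool is exhausted, averaged over repeated runs):

```r
curves <- run_simulation(corpus, "pal_aggressive", pal_config(runs = 10))
autoplot(curves)     # yield/burden vs labels; thin runs, thick mean
```

Corpora can also be read from CSV/TSV (canonical dialect:
`id,title,abstract,keywords,concepts,label`, `;`-separated multi-values),
RIS, or MEDLINE files via `read_corpus()`, and a shell entry point wraps
the same functions:

```sh
Rscript inst/cli/palscreen.R generate --spec copdlike --out bench
Rscript inst/cli/palscreen.R simulate --corpus bench/corpus.csv \
    --strategy pal_aggressive --out sim
Rscript inst/cli/palscreen.R screen --corpus mysearch.ris --out session
```

`screen` runs the interactive prompt loop (`r`/`i`/`quit`); every answer is
logged before the next query, and re-running with the same `--out` resumes
the session without re-asking anything.

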