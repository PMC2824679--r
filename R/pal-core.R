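#' Configuration for a screening run
#'
#' Collects the tunable parameters of the active-learning loop. Defaults
#' follow the experimental protocol the package simulates: batches of 5
#' labels, evaluation every 25 labels, stopping once half the corpus is
#' labeled, 10 repeated runs, linear kernel with cost 1 and no tuning.
#'
#' @param batch_size Labels requested per batch (default 5).
#' @param eval_interval Evaluate the deployable classifier every this many
#'   labels (default 25); must be a multiple of `batch_size`.
#' @param epsilon Convergence tolerance for the diversity heuristic, in
#'   degrees of mean pairwise angle (default 1).
#' @param patience Number of consecutive batch-to-batch diversity changes
#'   that must be `<= epsilon` before switching to uncertainty sampling
#'   (default 3).
#' @param stop_fraction Stop label acquisition at the first batch boundary
#'   where the labeled fraction reaches this value (default 0.5, the
#'   half-corpus stopping criterion).
#' @param runs Number of repeated simulation runs (default 10); run `r` uses
#'   `seed + r - 1`.
#' @param seed Base integer seed; all randomness (seed labels, exploration
#'   draws, view coin-flips, undersampling) flows from it.
#' @param cost Soft-margin cost C for every classifier (default 1).
#' @param aggressive Use aggressive (hyperplane-nearest) undersampling before
#'   final training; `FALSE` uses random undersampling.
#' @param interim_undersample Train the in-loop (selection) models on a
#'   randomly balanced subset of the labeled pool so early models are not
#'   majority-swamped (default `TRUE`).
#' @param min_df Document-count floor for text-view vocabularies.
#' @param views Feature spaces to use.
#' @param interim_tol SMO tolerance for in-loop models; they only rank
#'   candidates by distance, so a looser tolerance (default 0.01) suffices.
#'   Final models are solved at the solver default (0.001).
#' @return A `pal_config` list.
#' @export
pal_config <- function(batch_size = 5, eval_interval = 25, epsilon = 1,
                       patience = 3, stop_fraction = 0.5, runs = 10, seed = 0,
                       cost = 1, aggressive = TRUE, interim_undersample = TRUE,
                       min_df = 3,
                       views = c("title", "abstract", "keywords", "concepts"),
                       interim_tol = 0.01) {
  stopifnot(batch_size >= 1, eval_interval >= 1, epsilon > 0, patience >= 1,
            stop_fraction > 0, stop_fraction <= 1, runs >= 1, cost > 0)
  if (eval_interval %% batch_size != 0) {
    abort("eval_interval must be a multiple of batch_size")
  }
  structure(list(batch_size = as.integer(batch_size),
                 eval_interval = as.integer(eval_interval),
                 epsilon = epsilon, patience = as.integer(patience),
                 stop_fraction = stop_fraction, runs = as.integer(runs),
                 seed = as.integer(seed), cost = cost, aggressive = aggressive,
                 interim_undersample = interim_undersample,
                 min_df = as.integer(min_df), views = views,
                 interim_tol = interim_tol),
            class = "pal_config")
}

# ---- diversity heuristic ----------------------------------------------------

#' Mean pairwise angle between unit vectors
#'
#' The diversity score of a set of (unit-normalized) citation vectors: the
#' mean over all unordered pairs of the angle `acos(<u, v>)`, in degrees.
#' Identical vectors score 0, orthogonal vectors 90.
#'
#' @param vectors Matrix (dense or sparse) of unit row vectors.
#' @return Mean pairwise angle in degrees; `NA_real_` with fewer than two
#'   vectors (the undefined-diversity signal — callers stay in exploration).
#' @export
pairwise_diversity <- function(vectors) {
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1)
  n <- nrow(vectors)
  if (n < 2) return(NA_real_)
  G <- as.matrix(Matrix::tcrossprod(vectors))
  G <- pmin(pmax(G, -1), 1)
  ang <- acos(G[upper.tri(G)]) * 180 / pi
  mean(ang)
}

# diversity of the labeled-relevant set, averaged over views (zero vectors
# skipped; a view needs >= 2 non-zero vectors to contribute)
labeled_relevant_diversity <- function(view_set, rel_idx) {
  if (length(rel_idx) < 2) return(NA_real_)
  per_view <- map_dbl(view_set$spaces, function(sp) {
    V <- sp$X[rel_idx, , drop = FALSE]
    V <- V[Matrix::rowSums(V^2) > 0, , drop = FALSE]
    if (nrow(V) < 2) return(NA_real_)
    pairwise_diversity(V)
  })
  if (all(is.na(per_view))) return(NA_real_)
  mean(per_view, na.rm = TRUE)
}

#' Has the diversity score converged?
#'
#' The exploration phase ends when the diversity of the labeled minority
#' examples stabilizes: `TRUE` iff the last `patience` successive absolute
#' changes of `history` are all less than *or equal to* `epsilon`.
#'
#' @param history Numeric vector of diversity scores, one per batch.
#' @param epsilon Tolerance (same units as the scores, degrees).
#' @param patience Number of consecutive small changes required.
#' @return Logical. Short or `NA`-laden histories give `FALSE`.
#' @export
diversity_converged <- function(history, epsilon, patience) {
  d <- abs(diff(history))
  if (length(d) < patience) return(FALSE)
  tail_d <- d[seq.int(length(d) - patience + 1, length(d))]
  all(!is.na(tail_d) & tail_d <= epsilon)
}

# ---- batch selection --------------------------------------------------------

#' Draw a random exploration batch
#'
#' Uniform sampling without replacement from the unlabeled pool; returns all
#' of the pool when fewer than `batch_size` indices remain.
#'
#' @param unlabeled Integer vector of unlabeled citation indices.
#' @param batch_size Number of indices to draw.
#' @param seed Optional seed for a reproducible draw outside a run loop;
#'   `NULL` uses the current RNG stream.
#' @return Integer vector of selected indices.
#' @export
select_exploration_batch <- function(unlabeled, batch_size, seed = NULL) {
  if (length(unlabeled) == 0) abort("unlabeled pool is empty")
  b <- min(batch_size, length(unlabeled))
  draw <- function() unlabeled[sample.int(length(unlabeled), b)]
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# shared slot-by-slot uncertainty selection: `absdist` is a views x candidates
# matrix of |signed distance| (columns aligned with `candidates`), `views` the
# per-slot coin flips. Ties broken by lower citation index.
select_uncertain_slots <- function(candidates, absdist, views) {
  chosen <- integer(0)
  alive <- rep(TRUE, length(candidates))
  for (v in views) {
    if (!any(alive)) break
    d <- absdist[v, alive]
    cand <- candidates[alive]
    pick <- cand[order(d, cand)[1]]
    chosen <- c(chosen, pick)
    alive[match(pick, candidates)] <- FALSE
  }
  chosen
}

#' Select a batch by SIMPLE uncertainty sampling over random views
#'
#' For each of the `batch_size` slots independently, a view is drawn
#' uniformly (the fair k-sided coin) and the not-yet-chosen unlabeled
#' citation with the smallest absolute signed distance to that view's
#' hyperplane is selected; ties go to the lower citation index. All slots
#' use the batch-start models.
#'
#' @param unlabeled Integer vector of unlabeled citation indices.
#' @param models Named list of `margin_model`s, one per view of `view_set`.
#' @param view_set The corpus `view_set`.
#' @param batch_size Number of indices to select (capped at the pool size).
#' @param seed Optional seed for the view coin-flips; `NULL` uses the
#'   current RNG stream.
#' @return Integer vector of selected indices.
#' @export
select_simple_batch <- function(unlabeled, models, view_set, batch_size,
                                seed = NULL) {
  if (length(unlabeled) == 0) abort("unlabeled pool is empty")
  b <- min(batch_size, length(unlabeled))
  vnames <- names(view_set$spaces)
  absdist <- do.call(rbind, lapply(vnames, function(v) {
    abs(signed_distance(models[[v]], view_matrix(view_set, v)[unlabeled, , drop = FALSE]))
  }))
  rownames(absdist) <- vnames
  draw <- function() sample.int(length(vnames), b, replace = TRUE)
  flips <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  select_uncertain_slots(unlabeled, absdist, vnames[flips])
}

# ---- the screening engine ---------------------------------------------------

# Precompute the dense linear-kernel (gram) matrix of every view once per
# corpus; every in-loop fit and distance computation is then a submatrix
# operation.
compute_grams <- function(view_set) {
  lapply(view_set$spaces, function(sp) as.matrix(Matrix::tcrossprod(sp$X)))
}

# one fitted gram-SVM per view, remembering the citation indices it was
# trained on
train_view_models <- function(view_set, grams, labeled, cost, tol = 0.001) {
  lapply(names(view_set$spaces), function(v) {
    K <- grams[[v]][labeled$index, labeled$index, drop = FALSE]
    fit <- fit_gram_svm(K, labeled$label, cost = cost, tol = tol)
    fit$train_index <- labeled$index
    fit
  }) |> setNames(names(view_set$spaces))
}

# |signed distance| of `query_idx` citations under each view's gram fit:
# views x query matrix
absdist_matrix <- function(fits, grams, query_idx) {
  out <- do.call(rbind, lapply(names(fits), function(v) {
    fit <- fits[[v]]
    abs(gram_signed_distance(fit, grams[[v]][query_idx, fit$train_index, drop = FALSE]))
  }))
  rownames(out) <- names(fits)
  out
}

# materialize primal-weight margin models for an ensemble from gram fits
materialize_ensemble <- function(view_set, fits, cost) {
  models <- lapply(names(fits), function(v) {
    fit <- fits[[v]]
    X <- view_set$spaces[[v]]$X
    sv_idx <- fit$train_index[fit$sv]
    w <- as.numeric(Matrix::crossprod(X[sv_idx, , drop = FALSE], fit$coef)) * fit$sign
    new_margin_model(view = v, weights = w, bias = -fit$b * fit$sign, cost = cost)
  }) |> setNames(names(fits))
  structure(list(models = models, k = length(models),
                 aggregation = "relevant-if-any"),
            class = "screening_ensemble")
}

# Final-stage training: per view, fit a reference model on the raw labeled
# pool, undersample (aggressively w.r.t. that view's hyperplane, or randomly
# with one shared draw), and refit on the survivors.
train_final_ensemble <- function(view_set, grams, labeled, cost, aggressive) {
  vnames <- names(view_set$spaces)
  random_subset <- if (!aggressive) undersample_random(labeled) else NULL
  fits <- lapply(vnames, function(v) {
    sub <- if (aggressive) {
      n_rel <- sum(labeled$label == "relevant")
      if (sum(labeled$label == "irrelevant") > n_rel && n_rel > 0) {
        ref <- fit_gram_svm(grams[[v]][labeled$index, labeled$index, drop = FALSE],
                            labeled$label, cost = cost)
        ref$train_index <- labeled$index
        d <- gram_signed_distance(ref, grams[[v]][labeled$index, labeled$index, drop = FALSE])
        undersample_aggressive_idx(labeled, setNames(d, labeled$index))
      } else labeled
    } else random_subset
    fit <- fit_gram_svm(grams[[v]][sub$index, sub$index, drop = FALSE],
                        sub$label, cost = cost)
    fit$train_index <- sub$index
    fit
  }) |> setNames(vnames)
  materialize_ensemble(view_set, fits, cost)
}

# Core loop shared by run_pal(), run_simulation() and
# apply_stopping_criterion(). `strategy` fixes the selection rule:
#   random  - exploration throughout
#   simple  - uncertainty sampling from the start
#   pal     - exploration until diversity convergence, then uncertainty
# `eval_fun(labeled, unlabeled)`, if given, is called at every
# `eval_interval` grid point. Returns the final state and trace; the caller
# decides how to train the final ensemble.
screening_engine <- function(view_set, oracle, config, strategy, grams,
                             gold = NULL, initial = NULL, stop_n = NULL,
                             eval_fun = NULL) {
  n <- view_set$n
  stop_n <- stop_n %||% ceiling(config$stop_fraction * n)
  set.seed(config$seed)

  trace_rows <- list()
  history <- numeric(0)
  phase <- if (strategy == "simple") "exploitation" else "exploration"
  switch_batch <- if (strategy == "simple") 0L else NA_integer_
  labeled <- tibble(index = integer(0), label = character(0))
  evals <- list()
  finish <- function(err = NULL) {
    res <- list(labeled = labeled, unlabeled = setdiff(seq_len(n), labeled$index),
                phase = phase, diversity_history = history,
                switch_batch = switch_batch,
                trace = bind_rows(trace_rows) %||% tibble(),
                evals = evals, error = err)
    res
  }
  ask <- function(idx) {
    vapply(idx, function(i) {
      lab <- tryCatch(oracle(i), error = function(e) {
        if (inherits(e, "palscreen_quit")) rlang::cnd_signal(e)
        abort(paste0("oracle failed on citation ", i, ": ", conditionMessage(e)),
              class = "palscreen_oracle_error", partial = finish(err = e))
      })
      lab <- normalize_labels(lab)
      if (lab == "unknown") {
        abort(paste0("oracle returned \"unknown\" for citation ", i),
              class = "palscreen_oracle_error", partial = finish())
      }
      lab
    }, character(1))
  }

  # seed the labeled pool with one citation per class
  if (!is.null(initial)) {
    labeled <- tibble(index = as.integer(initial$index),
                      label = normalize_labels(initial$label))
  } else if (!is.null(gold)) {
    seed_idx <- c(sample(which(gold == "relevant"), 1),
                  sample(which(gold == "irrelevant"), 1))
    labeled <- tibble(index = as.integer(seed_idx), label = ask(seed_idx))
  } else {
    # no gold knowledge: query random citations until both classes are seen
    perm <- sample.int(n)
    p <- 0L
    while (length(unique(labeled$label)) < 2 && p < n) {
      p <- p + 1L
      labeled <- bind_rows(labeled, tibble(index = perm[p], label = ask(perm[p])))
    }
  }
  if (length(unique(labeled$label)) < 2) {
    abort("need at least one relevant and one irrelevant citation to start")
  }
  unlabeled <- setdiff(seq_len(n), labeled$index)

  maybe_eval <- function() {
    if (is.null(eval_fun)) return()
    nl <- nrow(labeled)
    if (nl %% config$eval_interval == 0 || length(unlabeled) == 0) {
      evals[[length(evals) + 1]] <<- eval_fun(labeled, unlabeled)
    }
  }

  batch_no <- 0L
  while (nrow(labeled) < stop_n && length(unlabeled) > 0) {
    batch_no <- batch_no + 1L

    if (strategy == "pal" && phase == "exploration") {
      rel_idx <- labeled$index[labeled$label == "relevant"]
      history <- c(history, labeled_relevant_diversity(view_set, rel_idx))
      if (diversity_converged(history, config$epsilon, config$patience)) {
        phase <- "exploitation"
        switch_batch <- batch_no
      }
    }

    # truncate the first batch so later pool sizes fall on batch_size
    # multiples (the evaluation grid), and the last so |L| never overshoots
    nl <- nrow(labeled)
    b_nominal <- config$batch_size - (nl %% config$batch_size)
    b <- min(b_nominal, stop_n - nl, length(unlabeled))

    if (phase == "exploration") {
      sel <- select_exploration_batch(unlabeled, b)
      sel_views <- rep(NA_character_, length(sel))
    } else {
      interim <- if (config$interim_undersample) undersample_random(labeled) else labeled
      fits <- train_view_models(view_set, grams, interim, config$cost,
                                tol = config$interim_tol)
      absd <- absdist_matrix(fits, grams, unlabeled)
      vnames <- names(view_set$spaces)
      sel_views <- vnames[sample.int(length(vnames), b, replace = TRUE)]
      sel <- select_uncertain_slots(unlabeled, absd, sel_views)
      sel_views <- sel_views[seq_along(sel)]
    }

    labs <- ask(sel)
    labeled <- bind_rows(labeled, tibble(index = as.integer(sel), label = labs))
    unlabeled <- setdiff(unlabeled, sel)

    trace_rows[[batch_no]] <- tibble(
      batch = batch_no, phase = phase,
      diversity = if (length(history) > 0 && strategy == "pal") history[length(history)] else NA_real_,
      indices = list(as.integer(sel)), views = list(sel_views),
      labels = list(labs), n_labeled = nrow(labeled))
    maybe_eval()
  }
  finish()
}

#' Run Patient Active Learning over a corpus
#'
#' Drives the full PAL loop: the labeled pool is seeded with one randomly
#' chosen citation per class, batches are selected at random during the
#' exploration phase until the diversity of the labeled relevant citations
#' converges, then by SIMPLE uncertainty sampling over a randomly chosen
#' view; labels come from `oracle`. Acquisition stops at the first batch
#' boundary where the labeled pool reaches `ceiling(stop_fraction * N)`
#' citations. Each view's classifier is then retrained after undersampling
#' (aggressive by default) and the ensemble is returned together with the
#' final pool state and the per-batch decision trace.
#'
#' @param corpus A gold-labeled corpus tibble (gold labels are used only to
#'   seed one citation per class; all other labels flow through `oracle`).
#' @param view_set The corpus `view_set` from [build_view_set()]; built from
#'   `corpus` when `NULL`.
#' @param oracle Function mapping a citation index to `"relevant"` /
#'   `"irrelevant"`. Defaults to reading the corpus gold labels (simulation
#'   mode).
#' @param config A [pal_config()].
#' @param initial Optional starting labeled set (tibble with `index`,
#'   `label`), e.g. citations the review team already knows; replaces the
#'   random per-class seeding.
#' @return A `pal_run` object: `ensemble` (the retrained
#'   `screening_ensemble`), `labeled`, `unlabeled`, `diversity_history`,
#'   `switch_batch`, `trace` (one row per batch) and `config`.
#' @export
run_pal <- function(corpus, view_set = NULL, oracle = NULL,
                    config = pal_config(), initial = NULL) {
  view_set <- view_set %||% build_view_set(corpus, views = config$views,
                                           min_df = config$min_df)
  gold <- NULL
  if (is.null(oracle)) {
    validate_corpus(corpus, require_gold = TRUE)
    gold <- corpus$label
    oracle <- function(i) gold[i]
  } else if (is.null(initial) && all(corpus$label != "unknown")) {
    gold <- corpus$label
  }
  grams <- compute_grams(view_set)
  state <- screening_engine(view_set, oracle, config, strategy = "pal",
                            grams = grams, gold = gold, initial = initial)
  ensemble <- train_final_ensemble(view_set, grams, state$labeled, config$cost,
                                   aggressive = config$aggressive)
  structure(list(ensemble = ensemble, labeled = state$labeled,
                 unlabeled = state$unlabeled,
                 diversity_history = state$diversity_history,
                 switch_batch = state$switch_batch, trace = state$trace,
                 config = config, view_set = view_set),
            class = "pal_run")
}

#' @export
print.pal_run <- function(x, ...) {
  cat("<pal_run> ", nrow(x$labeled), " labeled / ", length(x$unlabeled),
      " unlabeled; phase switch at batch ",
      if (is.na(x$switch_batch)) "never" else x$switch_batch, "\n", sep = "")
  invisible(x)
}

# ---- ensemble prediction ----------------------------------------------------

#' Predict relevance with a screening ensemble
#'
#' Applies the sensitivity-first aggregation rule: a citation is predicted
#' `"relevant"` if *any* view's classifier predicts relevant. A view abstains
#' (casts no vote) for a citation whose vector is all-zero in that view — an
#' empty title must not silently exclude a citation — and a citation with no
#' content in any view defaults to `"relevant"`.
#'
#' @param ensemble A `screening_ensemble`.
#' @param view_set The corpus `view_set`.
#' @param citation_index Integer vector of citation indices.
#' @return Character vector of `"relevant"` / `"irrelevant"`.
#' @export
ensemble_predict <- function(ensemble, view_set, citation_index) {
  idx <- as.integer(citation_index)
  if (length(idx) == 0) return(character(0))
  any_rel <- rep(FALSE, length(idx))
  any_vote <- rep(FALSE, length(idx))
  for (v in names(ensemble$models)) {
    X <- view_matrix(view_set, v)[idx, , drop = FALSE]
    nonzero <- Matrix::rowSums(X^2) > 0
    d <- signed_distance(ensemble$models[[v]], X)
    any_rel <- any_rel | (nonzero & d >= 0)
    any_vote <- any_vote | nonzero
  }
  ifelse(any_rel | !any_vote, "relevant", "irrelevant")
}
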