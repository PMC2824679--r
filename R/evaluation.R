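#' Build the combined screening confusion accounting
#'
#' Cross-tabulates a finished (or interim) screening state into the combined
#' training/prediction confusion cells from which Yield and Burden are
#' computed. Citations labeled during training are tallied by their gold
#' labels into the `T` cells; the reviewer is assumed never to erroneously
#' exclude an eligible citation, so `fn_T = 0` by construction (a gold-
#' relevant citation labeled during training is always a training true
#' positive). Model predictions over the remaining unlabeled pool are
#' cross-tabulated against gold into the `U` cells.
#'
#' @param labeled Labeled-set tibble (`index`, `label`) of citations screened
#'   during training.
#' @param predictions Tibble (`index`, `decision`) of model predictions over
#'   the unlabeled pool; together with `labeled` it must partition `1..N`.
#' @param gold Character vector of gold labels, length `N`.
#' @param N Total number of citations.
#' @return A `screening_outcome` with cells `tp_T`, `tn_T`, `fp_T`, `fn_T`
#'   (always 0), `tp_U`, `tn_U`, `fp_U`, `fn_U`, and `N`.
#' @export
build_outcome <- function(labeled, predictions, gold, N) {
  pred_idx <- if (nrow(predictions) > 0) predictions$index else integer(0)
  if (length(intersect(labeled$index, pred_idx)) > 0) {
    abort("labeled set and prediction pool overlap")
  }
  if (length(union(labeled$index, pred_idx)) != N ||
      nrow(labeled) + length(pred_idx) != N) {
    abort("labeled set and prediction pool must partition 1..N")
  }
  g_lab <- gold[labeled$index]
  tp_T <- sum(g_lab == "relevant")
  fp_T <- sum(g_lab == "irrelevant" & labeled$label == "relevant")
  tn_T <- sum(g_lab == "irrelevant" & labeled$label != "relevant")
  g_pred <- gold[pred_idx]
  rel_hat <- predictions$decision == "relevant"
  out <- list(
    tp_T = tp_T, tn_T = tn_T, fp_T = fp_T, fn_T = 0L,
    tp_U = sum(rel_hat & g_pred == "relevant"),
    fp_U = sum(rel_hat & g_pred == "irrelevant"),
    fn_U = sum(!rel_hat & g_pred == "relevant"),
    tn_U = sum(!rel_hat & g_pred == "irrelevant"),
    N = as.integer(N))
  structure(out, class = "screening_outcome")
}

#' @export
print.screening_outcome <- function(x, ...) {
  cat("<screening_outcome> N =", x$N, "\n")
  cat(sprintf("  training:   tp=%d tn=%d fp=%d fn=0\n", x$tp_T, x$tn_T, x$fp_T))
  cat(sprintf("  prediction: tp=%d tn=%d fp=%d fn=%d\n", x$tp_U, x$tn_U, x$fp_U, x$fn_U))
  cat(sprintf("  yield = %.4f, burden = %.4f\n", compute_yield(x), compute_burden(x)))
  invisible(x)
}

#' Yield of a screening outcome
#'
#' The fraction of all truly eligible (gold-relevant) citations identified by
#' the screening process as a whole, whether discovered during training or
#' flagged by the final model:
#' `(tp_T + tp_U) / (tp_T + tp_U + fn_U)`. Fully manual screening has
#' Yield 1.
#'
#' @param outcome A `screening_outcome`.
#' @return Yield in `[0, 1]`; `NA_real_` (with a warning) when the corpus
#'   contains no gold-relevant citation.
#' @export
compute_yield <- function(outcome) {
  denom <- outcome$tp_T + outcome$tp_U + outcome$fn_U
  if (denom == 0) {
    warn("yield is undefined: no gold-relevant citations")
    return(NA_real_)
  }
  (outcome$tp_T + outcome$tp_U) / denom
}

#' Burden of a screening outcome
#'
#' The fraction of all `N` citations a human must screen manually: everything
#' labeled during training plus everything the model flags as relevant:
#' `(tp_T + tn_T + fp_T + tp_U + fp_U) / N`. Fully manual screening has
#' Burden 1.
#'
#' @param outcome A `screening_outcome`.
#' @return Burden in `[0, 1]`.
#' @export
compute_burden <- function(outcome) {
  if (outcome$N == 0) abort("burden is undefined for N = 0")
  (outcome$tp_T + outcome$tn_T + outcome$fp_T + outcome$tp_U + outcome$fp_U) / outcome$N
}

# map a user-facing strategy name to engine selection rule + undersampling
strategy_modes <- function(strategy) {
  strategy <- match.arg(strategy, c("random", "simple", "pal", "pal_aggressive"))
  list(name = strategy,
       engine = switch(strategy, random = "random", simple = "simple",
                       pal = "pal", pal_aggressive = "pal"),
       aggressive = identical(strategy, "pal_aggressive"))
}

# Train the deployable (undersampled) ensemble on the current labeled pool
# and account for the whole corpus. With an empty unlabeled pool everything
# was human-screened and no model is needed.
evaluate_pool <- function(view_set, grams, labeled, unlabeled, gold, cost,
                          aggressive) {
  if (length(unlabeled) == 0) {
    preds <- tibble(index = integer(0), decision = character(0))
  } else {
    ens <- train_final_ensemble(view_set, grams, labeled, cost, aggressive)
    preds <- tibble(index = unlabeled,
                    decision = ensemble_predict(ens, view_set, unlabeled))
  }
  build_outcome(labeled, preds, gold, view_set$n)
}

#' Simulate screening strategies and record learning curves
#'
#' Replays the full experimental protocol on a gold-labeled corpus: for each
#' run, all labels are hidden except one randomly chosen citation per class,
#' the chosen strategy acquires labels in batches, and at every
#' `eval_interval` labels the deployable classifier (trained with the
#' strategy's undersampling mode) is evaluated over the remaining unlabeled
#' pool, recording `(labels used, yield, burden)`. Acquisition continues
#' until the unlabeled pool is exhausted, where every strategy ends at
#' yield 1, burden 1. Run `r` uses seed `config$seed + r - 1`.
#'
#' @param corpus A fully gold-labeled corpus tibble.
#' @param strategy One of `"random"` (passive learning), `"simple"` (pure
#'   uncertainty sampling), `"pal"` (patient active learning, random final
#'   undersampling) or `"pal_aggressive"` (PAL with aggressive
#'   undersampling).
#' @param config A [pal_config()]; `runs`, `seed`, `batch_size` and
#'   `eval_interval` control the protocol.
#' @param view_set Optional prebuilt `view_set`.
#' @return A `pal_curves` object: `points` (tibble `run`, `labels`, `yield`,
#'   `burden`, one row per run and grid point), `mean` (per-grid-point
#'   averages over the runs that reached it), `strategy` and `config`.
#' @export
run_simulation <- function(corpus, strategy = "pal_aggressive",
                           config = pal_config(), view_set = NULL) {
  validate_corpus(corpus, require_gold = TRUE)
  mode <- strategy_modes(strategy)
  view_set <- view_set %||% build_view_set(corpus, views = config$views,
                                           min_df = config$min_df)
  grams <- compute_grams(view_set)
  gold <- corpus$label
  runs <- map(seq_len(config$runs), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    eval_fun <- function(labeled, unlabeled) {
      out <- evaluate_pool(view_set, grams, labeled, unlabeled, gold,
                           cfg$cost, mode$aggressive)
      tibble(labels = nrow(labeled), yield = compute_yield(out),
             burden = compute_burden(out))
    }
    state <- screening_engine(view_set, oracle = function(i) gold[i],
                              config = cfg, strategy = mode$engine,
                              grams = grams, gold = gold, stop_n = view_set$n,
                              eval_fun = eval_fun)
    list(curve = bind_rows(state$evals) %>% mutate(run = r, .before = 1),
         trace = state$trace)
  })
  points <- bind_rows(map(runs, "curve"))
  mean_curve <- points %>%
    group_by(labels) %>%
    summarise(yield = mean(yield), burden = mean(burden), n_runs = n(),
              .groups = "drop")
  structure(list(points = points, mean = mean_curve,
                 traces = map(runs, "trace"), strategy = mode$name,
                 config = config),
            class = "pal_curves")
}

#' @export
print.pal_curves <- function(x, ...) {
  cat("<pal_curves> strategy =", x$strategy, ";",
      length(unique(x$points$run)), "runs,",
      nrow(x$mean), "grid points\n")
  print(utils::tail(x$mean, 3))
  invisible(x)
}

#' Screen with the half-corpus stopping criterion
#'
#' Runs a strategy until the labeled pool reaches
#' `ceiling(stop_fraction * N)` citations, trains the final (undersampled)
#' ensemble, classifies the remainder, and reports the single resulting
#' outcome per run. This is the deployable protocol: the hypothesis behind
#' the default `stop_fraction = 0.5` is that labeling half of the corpus
#' suffices for 100% Yield.
#'
#' @inheritParams run_simulation
#' @return A `screening_stop` object: `results` (tibble `run`, `seed`,
#'   `labels_used`, `yield`, `burden`), the per-run `outcomes`, `strategy`
#'   and `config`.
#' @export
apply_stopping_criterion <- function(corpus, strategy = "pal_aggressive",
                                     config = pal_config(), view_set = NULL) {
  validate_corpus(corpus, require_gold = TRUE)
  mode <- strategy_modes(strategy)
  view_set <- view_set %||% build_view_set(corpus, views = config$views,
                                           min_df = config$min_df)
  grams <- compute_grams(view_set)
  gold <- corpus$label
  stop_n <- ceiling(config$stop_fraction * view_set$n)
  outcomes <- list()
  rows <- map(seq_len(config$runs), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    state <- screening_engine(view_set, oracle = function(i) gold[i],
                              config = cfg, strategy = mode$engine,
                              grams = grams, gold = gold, stop_n = stop_n)
    out <- evaluate_pool(view_set, grams, state$labeled, state$unlabeled,
                         gold, cfg$cost, mode$aggressive)
    outcomes[[r]] <<- out
    tibble(run = r, seed = cfg$seed, labels_used = nrow(state$labeled),
           yield = compute_yield(out), burden = compute_burden(out))
  })
  structure(list(results = bind_rows(rows), outcomes = outcomes,
                 strategy = mode$name, config = config),
            class = "screening_stop")
}

#' @export
print.screening_stop <- function(x, ...) {
  cat("<screening_stop> strategy =", x$strategy, "\n")
  cat(sprintf("  mean yield = %.4f, mean burden = %.4f over %d runs\n",
              mean(x$results$yield), mean(x$results$burden), nrow(x$results)))
  invisible(x)
}
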