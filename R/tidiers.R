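#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a screening outcome into one row per confusion cell
#'
#' @param x A `screening_outcome`.
#' @param ... Unused.
#' @return A tibble with columns `stage` (`training`/`prediction`), `cell`
#'   (`tp`, `tn`, `fp`, `fn`) and `count`.
#' @method tidy screening_outcome
#' @export
tidy.screening_outcome <- function(x, ...) {
  tibble(
    stage = rep(c("training", "prediction"), each = 4),
    cell = rep(c("tp", "tn", "fp", "fn"), 2),
    count = c(x$tp_T, x$tn_T, x$fp_T, x$fn_T, x$tp_U, x$tn_U, x$fp_U, x$fn_U)
  )
}

#' One-row summary of a screening outcome
#'
#' @param x A `screening_outcome`.
#' @param ... Unused.
#' @return A tibble with `N`, `labeled`, `yield`, `burden`.
#' @method glance screening_outcome
#' @export
glance.screening_outcome <- function(x, ...) {
  tibble(N = x$N, labeled = x$tp_T + x$tn_T + x$fp_T,
         yield = suppressWarnings(compute_yield(x)), burden = compute_burden(x))
}

#' Tidy a PAL run into its per-batch trace
#'
#' @param x A `pal_run`.
#' @param ... Unused.
#' @return The trace tibble: one row per batch with `batch`, `phase`,
#'   `diversity`, list-columns `indices`, `views`, `labels`, and the running
#'   label count `n_labeled`.
#' @method tidy pal_run
#' @export
tidy.pal_run <- function(x, ...) x$trace

#' One-row summary of a PAL run
#'
#' @param x A `pal_run`.
#' @param ... Unused.
#' @return A tibble with label counts, the phase-switch batch and the final
#'   diversity score.
#' @method glance pal_run
#' @export
glance.pal_run <- function(x, ...) {
  tibble(
    n_labeled = nrow(x$labeled),
    n_unlabeled = length(x$unlabeled),
    n_relevant_found = sum(x$labeled$label == "relevant"),
    switch_batch = x$switch_batch,
    final_diversity = if (length(x$diversity_history) > 0) {
      x$diversity_history[length(x$diversity_history)]
    } else NA_real_
  )
}

#' Tidy learning curves into a long tibble
#'
#' Binds the per-run grid points with the mean curve (`run = "mean"`),
#' matching the curve CSV written by [cmd_simulate()].
#'
#' @param x A `pal_curves` from [run_simulation()].
#' @param ... Unused.
#' @return A tibble with columns `run`, `labels`, `yield`, `burden`.
#' @method tidy pal_curves
#' @export
tidy.pal_curves <- function(x, ...) {
  bind_rows(
    mutate(x$points, run = as.character(run)),
    mutate(select(x$mean, labels, yield, burden), run = "mean", .before = 1)
  )
}

#' One-row summary of a set of learning curves
#'
#' @param x A `pal_curves`.
#' @param ... Unused.
#' @return A tibble with the strategy, run count, and the mean curve's final
#'   grid point.
#' @method glance pal_curves
#' @export
glance.pal_curves <- function(x, ...) {
  last <- x$mean[nrow(x$mean), ]
  tibble(strategy = x$strategy, runs = length(unique(x$points$run)),
         final_labels = last$labels, final_yield = last$yield,
         final_burden = last$burden)
}

#' Tidy per-run stopping-criterion results
#'
#' @param x A `screening_stop` from [apply_stopping_criterion()].
#' @param ... Unused.
#' @return The per-run results tibble.
#' @method tidy screening_stop
#' @export
tidy.screening_stop <- function(x, ...) x$results

#' One-row summary of stopping-criterion results
#'
#' @param x A `screening_stop`.
#' @param ... Unused.
#' @return A tibble with mean yield/burden and the fraction of runs at full
#'   yield.
#' @method glance screening_stop
#' @export
glance.screening_stop <- function(x, ...) {
  tibble(strategy = x$strategy, runs = nrow(x$results),
         mean_yield = mean(x$results$yield),
         mean_burden = mean(x$results$burden),
         prop_full_yield = mean(x$results$yield == 1))
}
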