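test_that("pairwise diversity is the mean pairwise angle in degrees", {
  u <- c(1, 0)
  expect_equal(pairwise_diversity(rbind(u, u)), 0)
  expect_equal(pairwise_diversity(rbind(c(1, 0), c(0, 1))), 90)
  # vectors at 0, 60, 90 degrees: pairs 60, 90, 30 -> mean 60
  v <- rbind(c(1, 0), c(cos(pi / 3), sin(pi / 3)), c(0, 1))
  expect_equal(pairwise_diversity(v), 60, tolerance = 1e-9)
  expect_true(is.na(pairwise_diversity(rbind(u))))
})

test_that("diversity convergence needs `patience` small successive changes", {
  expect_true(diversity_converged(c(50, 50, 50), epsilon = 0.01, patience = 2))
  expect_false(diversity_converged(c(50, 55, 60), epsilon = 0.01, patience = 2))
  # a change exactly equal to epsilon counts toward convergence
  expect_true(diversity_converged(c(50, 51, 52), epsilon = 1, patience = 2))
  expect_false(diversity_converged(c(50, 51, 52.5), epsilon = 1, patience = 2))
  # short or NA-bearing histories never converge
  expect_false(diversity_converged(c(50), epsilon = 10, patience = 2))
  expect_false(diversity_converged(c(NA, 50, 50), epsilon = 10, patience = 2))
})

test_that("exploration batches are uniform draws without replacement", {
  expect_setequal(select_exploration_batch(c(4L, 9L, 2L), 5), c(4L, 9L, 2L))
  expect_identical(select_exploration_batch(1:100, 5, seed = 8),
                   select_exploration_batch(1:100, 5, seed = 8))
  expect_error(select_exploration_batch(integer(0), 5), "empty")
  # chi-square goodness of fit against the uniform law
  pool <- 1:10
  draws <- withr::with_seed(123, {
    unlist(lapply(1:10000, function(i) select_exploration_batch(pool, 1)))
  })
  p <- stats::chisq.test(table(factor(draws, levels = pool)))$p.value
  expect_gt(p, 0.01)
})

test_that("SIMPLE selection takes the unlabeled point nearest the hyperplane", {
  vs <- manual_view_set(rbind(c(0.4, 0), c(-0.05, 0), c(2.3, 0)))
  models <- list(title = manual_model(c(1, 0), 0))
  expect_equal(select_simple_batch(1:3, models, vs, 1), 2L)
  # a point exactly on the hyperplane is selected first
  vs2 <- manual_view_set(rbind(c(0.4, 0), c(0, 0.7), c(-0.2, 0)))
  expect_equal(select_simple_batch(1:3, models, vs2, 2)[1], 2L)
  # batch_size >= |U| returns all of U
  expect_setequal(select_simple_batch(1:3, models, vs, 7), 1:3)
  expect_error(select_simple_batch(integer(0), models, vs, 1), "empty")
})

test_that("SIMPLE selection matches a brute-force sort oracle", {
  set.seed(99)
  for (trial in 1:40) {
    n <- sample(5:200, 1)
    k <- sample(1:4, 1)
    unlabeled <- sort(sample(500, n))
    absdist <- matrix(round(abs(rnorm(k * n)), 2), k, n,
                      dimnames = list(paste0("v", 1:k), NULL))
    b <- sample(1:min(10, n), 1)
    flips <- paste0("v", sample(k, b, replace = TRUE))
    got <- palscreen:::select_uncertain_slots(unlabeled, absdist, flips)
    want <- oracle_simple(unlabeled, absdist, flips)
    expect_identical(got, want)
  }
})

test_that("run_pal respects the label budget and the one-way phase switch", {
  spec <- synthetic_spec(N = 120, prevalence = 0.15, n_clusters = 2, seed = 2)
  corpus <- generate_corpus(spec)
  run <- run_pal(corpus, config = pal_config(seed = 5))
  # ceil(0.5 * 120) = 60 labels, never more
  expect_equal(nrow(run$labeled), 60)
  expect_equal(sort(c(run$labeled$index, run$unlabeled)), 1:120)
  # no index queried twice
  expect_equal(anyDuplicated(run$labeled$index), 0)
  # conservation at every batch boundary
  expect_equal(run$trace$n_labeled,
               cumsum(purrr::map_int(run$trace$indices, length)) + 2L)
  # exploitation never precedes the recorded switch, and never reverts
  phases <- run$trace$phase
  if (!is.na(run$switch_batch)) {
    expect_true(all(phases[seq_len(run$switch_batch - 1)] == "exploration"))
    expect_true(all(phases[seq(run$switch_batch, length(phases))] == "exploitation"))
  } else {
    expect_true(all(phases == "exploration"))
  }
  # same seed, same run
  run2 <- run_pal(corpus, config = pal_config(seed = 5))
  expect_identical(run$labeled, run2$labeled)
  expect_identical(run$trace$indices, run2$trace$indices)
})

test_that("a 10-citation corpus stops after exactly 5 labels", {
  corpus <- make_tiny_corpus(rep(c("relevant", "irrelevant"), 5))
  run <- run_pal(corpus, config = pal_config(seed = 1, min_df = 1))
  # 2 seed labels + a first batch truncated to 3 at the stop boundary
  expect_equal(nrow(run$labeled), 5)
  expect_equal(nrow(run$trace), 1)
  expect_equal(length(run$trace$indices[[1]]), 3)
})

test_that("exploration covers both relevant clusters before switching", {
  spec <- synthetic_spec(N = 400, prevalence = 0.12, n_clusters = 2, seed = 10)
  corpus <- generate_corpus(spec)
  vs <- build_view_set(corpus)
  covered <- vapply(1:10, function(s) {
    run <- run_pal(corpus, vs, config = pal_config(seed = s))
    n_explored <- if (is.na(run$switch_batch)) {
      nrow(run$labeled)
    } else if (run$switch_batch == 1) {
      2L
    } else {
      run$trace$n_labeled[run$switch_batch - 1]
    }
    explored <- run$labeled[seq_len(n_explored), ]
    rel <- explored$index[explored$label == "relevant"]
    length(unique(corpus$cluster[rel])) == 2
  }, logical(1))
  expect_gte(sum(covered), 8)
})

test_that("ensemble prediction is relevant if any view votes relevant", {
  # two views; citation 1 relevant only in view two; citation 2 in neither;
  # citation 3 empty everywhere -> abstention default
  X1 <- rbind(c(-1, 0), c(-1, 0), c(0, 0))
  X2 <- rbind(c(0.5, 0), c(-0.5, 0), c(0, 0))
  vs <- manual_view_set(X1)
  vs$spaces$abstract <- vs$spaces$title
  vs$spaces$abstract$name <- "abstract"
  vs$spaces$abstract$X <- Matrix::Matrix(X2, sparse = TRUE)
  vs$k <- 2L
  ens <- structure(list(models = list(title = manual_model(c(1, 0), 0, "title"),
                                      abstract = manual_model(c(1, 0), 0, "abstract")),
                        k = 2L, aggregation = "relevant-if-any"),
                   class = "screening_ensemble")
  expect_equal(ensemble_predict(ens, vs, 1:3),
               c("relevant", "irrelevant", "relevant"))
})

test_that("an oracle failure aborts but preserves the partial trace", {
  corpus <- make_tiny_corpus(rep(c("relevant", "irrelevant"), 10))
  vs <- build_view_set(corpus, min_df = 1)
  calls <- 0
  flaky <- function(i) {
    calls <<- calls + 1
    if (calls > 6) stop("reviewer left")
    corpus$label[i]
  }
  err <- tryCatch(
    palscreen:::screening_engine(vs, flaky, pal_config(seed = 3),
                                 strategy = "pal",
                                 grams = palscreen:::compute_grams(vs),
                                 gold = corpus$label),
    palscreen_oracle_error = function(e) e)
  expect_s3_class(err, "palscreen_oracle_error")
  expect_true(nrow(err$partial$labeled) >= 1)
})
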