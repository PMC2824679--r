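test_that("a separable pair is split with opposite signed distances", {
  X <- rbind(c(0, 0), c(2, 0))
  m <- train_margin_classifier(X, c("irrelevant", "relevant"))
  d <- signed_distance(m, X)
  expect_lt(d[1], 0)
  expect_gt(d[2], 0)
  expect_equal(classify(m, X), c("irrelevant", "relevant"))
})

test_that("the fit agrees with the analytic maximum-margin separator", {
  # relevant at y = 2, irrelevant at y = 0 -> hyperplane y = 1, margin 1
  X <- rbind(c(0, 2), c(1, 2), c(0, 0), c(1, 0))
  y <- c("relevant", "relevant", "irrelevant", "irrelevant")
  m <- train_margin_classifier(X, y)
  expect_equal(signed_distance(m, rbind(c(5, 1))), 0, tolerance = 1e-6)
  expect_equal(signed_distance(m, X), c(1, 1, -1, -1), tolerance = 1e-6)
})

test_that("duplicating every training point leaves the boundary unchanged", {
  set.seed(11)
  # well-separated clusters: the solution is the hard-margin separator, so
  # duplicating the data cannot move it
  X <- matrix(rnorm(40, sd = 0.3), 20, 2)
  y <- rep(c("relevant", "irrelevant"), each = 10)
  X[, 1] <- X[, 1] + ifelse(y == "relevant", 2, -2)
  m1 <- train_margin_classifier(X, y)
  m2 <- train_margin_classifier(rbind(X, X), c(y, y))
  grid <- matrix(rnorm(40), 20, 2)
  expect_equal(signed_distance(m1, grid), signed_distance(m2, grid),
               tolerance = 1e-4)
})

test_that("training is deterministic and guards single-class input", {
  set.seed(4)
  X <- matrix(rnorm(60), 30, 2)
  y <- rep(c("relevant", "irrelevant"), 15)
  m1 <- train_margin_classifier(X, y)
  m2 <- train_margin_classifier(X, y)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$bias, m2$bias)
  expect_error(train_margin_classifier(X, rep("relevant", 30)),
               "each class")
})

test_that("signed_distance is the normalized hyperplane distance", {
  m <- manual_model(weights = c(3, 4), bias = -5)
  expect_equal(signed_distance(m, c(1, 1)), 0.4)
  # jointly scaling weights and bias changes nothing
  m2 <- manual_model(weights = c(6, 8), bias = -10)
  expect_equal(signed_distance(m2, c(1, 1)), 0.4)
  # a point on the hyperplane scores 0 and classifies relevant (tie rule)
  expect_equal(signed_distance(m, c(3 / 5, 4 / 5)), 0)
  expect_equal(classify(m, c(3 / 5, 4 / 5)), "relevant")
  expect_error(signed_distance(m, c(1, 2, 3)), "dimension mismatch")
})

test_that("random undersampling balances classes without touching relevants", {
  labeled <- tibble::tibble(index = 1:10,
                            label = c(rep("relevant", 3), rep("irrelevant", 7)))
  out <- undersample_random(labeled, seed = 5)
  expect_equal(sum(out$label == "relevant"), 3)
  expect_equal(sum(out$label == "irrelevant"), 3)
  expect_true(all(1:3 %in% out$index))
  # determinism given seed
  expect_identical(undersample_random(labeled, seed = 5), out)
  # already balanced -> no-op; minority >= majority -> no-op
  bal <- tibble::tibble(index = 1:6, label = rep(c("relevant", "irrelevant"), 3))
  expect_identical(undersample_random(bal, seed = 1), bal)
  inv <- tibble::tibble(index = 1:5, label = c(rep("relevant", 4), "irrelevant"))
  expect_identical(undersample_random(inv, seed = 1), inv)
})

test_that("aggressive undersampling drops the hyperplane-nearest majority", {
  # model with distance = x coordinate; irrelevant at hand-set distances
  m <- manual_model(weights = c(1, 0), bias = 0)
  X <- rbind(c(9, 0), c(9, 0), c(9, 0),            # relevant (far)
             c(0.1, 0), c(0.9, 0), c(0.3, 0), c(2.0, 0), c(0.5, 0))
  labeled <- tibble::tibble(index = 1:8,
                            label = c(rep("relevant", 3), rep("irrelevant", 5)))
  out <- aggressive_undersample(labeled, m, X)
  # m = 5 - 3 = 2: the points at |d| = 0.1 and 0.3 (indices 4, 6) go
  expect_setequal(out$index, c(1:3, 5, 7, 8))
  expect_equal(sum(out$label == "relevant"), sum(out$label == "irrelevant"))
  # balanced input is untouched
  bal <- labeled[c(1:3, 4:6), ]
  expect_identical(aggressive_undersample(bal, m, X), bal)
})

test_that("aggressive undersampling matches the brute-force oracle", {
  set.seed(21)
  for (trial in 1:60) {
    n <- sample(5:50, 1)
    n_rel <- sample(1:max(1, n %/% 3), 1)
    labeled <- tibble::tibble(
      index = sample(200, n),
      label = sample(c(rep("relevant", n_rel), rep("irrelevant", n - n_rel)))
    )
    d <- round(rnorm(200), 2) # rounding forces ties
    m <- manual_model(weights = c(1, 0), bias = 0)
    X <- cbind(d, 0)
    got <- aggressive_undersample(labeled, m, X)
    want <- oracle_aggressive(labeled, d)
    expect_equal(got, want)
  }
})

test_that("aggressive undersampling yields ensembles at least as sensitive as random", {
  # noisy imbalanced corpora; sensitivity on the full corpus, >= 10 seeds
  sens <- function(aggressive, seed) {
    spec <- synthetic_spec(N = 150, prevalence = 0.12, n_clusters = 1,
                           noise = 0.8, seed = seed)
    corpus <- generate_corpus(spec)
    vs <- build_view_set(corpus)
    grams <- palscreen:::compute_grams(vs)
    labeled <- tibble::tibble(index = seq_len(nrow(corpus)),
                              label = corpus$label)
    withr::with_seed(seed, {
      ens <- palscreen:::train_final_ensemble(vs, grams, labeled, cost = 1,
                                              aggressive = aggressive)
    })
    rel <- which(corpus$label == "relevant")
    mean(ensemble_predict(ens, vs, rel) == "relevant")
  }
  seeds <- 1:10
  s_agg <- mean(vapply(seeds, function(s) sens(TRUE, s), numeric(1)))
  s_rnd <- mean(vapply(seeds, function(s) sens(FALSE, s), numeric(1)))
  expect_gte(s_agg, s_rnd)
})
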