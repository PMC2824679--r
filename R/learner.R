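#' Train a linear maximum-margin classifier
#'
#' Fits a soft-margin linear SVM (via the SMO solver in \pkg{kernlab}) on the
#' given citation vectors and binary labels. The returned model exposes the
#' primal weight vector and bias so that [signed_distance()] is the exact
#' signed Euclidean distance to the separating hyperplane, positive on the
#' relevant side. The solver is deterministic given identical inputs.
#'
#' @param vectors A numeric matrix or sparse `Matrix` of training vectors,
#'   one row per example.
#' @param labels Character or factor labels, values `"relevant"` /
#'   `"irrelevant"`; both classes must be present.
#' @param cost Soft-margin cost parameter C (default 1, untuned).
#' @param view Optional name of the feature space the model belongs to.
#' @return A `margin_model` object with fields `view`, `weights`, `bias`,
#'   `cost`.
#' @export
train_margin_classifier <- function(vectors, labels, cost = 1, view = NULL) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    abort("training requires at least one example of each class")
  }
  if (nrow(vectors) != length(labels)) abort("vectors/labels length mismatch")
  K <- as.matrix(Matrix::tcrossprod(vectors))
  fit <- fit_gram_svm(K, labels, cost = cost)
  w <- as.numeric(Matrix::crossprod(vectors[fit$sv, , drop = FALSE], fit$coef)) * fit$sign
  bias <- -fit$b * fit$sign
  new_margin_model(view = view, weights = w, bias = bias, cost = cost)
}

new_margin_model <- function(view, weights, bias, cost) {
  structure(list(view = view, weights = as.numeric(weights), bias = bias,
                 cost = cost, norm_w = sqrt(sum(weights^2))),
            class = "margin_model")
}

#' @export
print.margin_model <- function(x, ...) {
  cat("<margin_model>", if (!is.null(x$view)) paste0(" view=", x$view) else "",
      " dim=", length(x$weights), " ||w||=", signif(x$norm_w, 4), "\n", sep = "")
  invisible(x)
}

# Solve the SVM dual on a precomputed linear-kernel (gram) matrix.
# Returns support-vector indices (into the rows of K), signed dual
# coefficients `coef` (alpha_i y_i in kernlab's internal orientation), the
# offset `b` with decision f(x) = sum coef_i K(x_i, x) - b, and `sign`
# orienting f so that relevant examples score higher than irrelevant ones.
fit_gram_svm <- function(K, labels, cost = 1, tol = 0.001) {
  y <- factor(labels, levels = c("relevant", "irrelevant"))
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "C-svc",
                     C = cost, kernel = "matrix", tol = tol)
  sv <- unlist(kernlab::alphaindex(m))
  cf <- unlist(kernlab::coef(m))
  b <- kernlab::b(m)
  f <- as.numeric(K[, sv, drop = FALSE] %*% cf) - b
  s <- if (mean(f[y == "relevant"]) >= mean(f[y == "irrelevant"])) 1 else -1
  norm_w <- sqrt(max(as.numeric(crossprod(cf, K[sv, sv, drop = FALSE] %*% cf)), 1e-24))
  list(sv = sv, coef = cf, b = b, sign = s, norm_w = norm_w)
}

# Signed distances of rows of a gram block to a fitted gram-SVM hyperplane.
# K_block: rows = query points, columns indexed like the training rows.
gram_signed_distance <- function(fit, K_block) {
  f <- as.numeric(K_block[, fit$sv, drop = FALSE] %*% fit$coef) - fit$b
  fit$sign * f / fit$norm_w
}

#' Signed distance to the separating hyperplane
#'
#' Computes `(w . x + b) / ||w||` for one or more vectors: the signed
#' Euclidean distance to the model's hyperplane, positive on the relevant
#' side. The decision rule is relevant iff the signed distance is `>= 0`
#' (points exactly on the hyperplane classify as relevant — the package is
#' sensitivity-first throughout).
#'
#' @param model A `margin_model`.
#' @param vectors A vector, matrix, or sparse `Matrix` whose columns match
#'   the model's dimension.
#' @return Numeric vector of signed distances, one per row.
#' @export
signed_distance <- function(model, vectors) {
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1)
  if (ncol(vectors) != length(model$weights)) {
    abort(paste0("dimension mismatch: model has ", length(model$weights),
                 " features, vectors have ", ncol(vectors)))
  }
  as.numeric(vectors %*% model$weights + model$bias) / model$norm_w
}

#' Classify vectors with a margin model
#'
#' @param model A `margin_model`.
#' @param vectors Vectors as in [signed_distance()].
#' @return Character vector, `"relevant"` where the signed distance is >= 0.
#' @export
classify <- function(model, vectors) {
  ifelse(signed_distance(model, vectors) >= 0, "relevant", "irrelevant")
}

# ---- undersampling ----------------------------------------------------------

#' Random undersampling of the majority class
#'
#' Removes uniformly random labeled-irrelevant citations until the class
#' counts are equal, the standard remedy for class imbalance prior to
#' training. A no-op when the relevant class is not the minority.
#'
#' @param labeled A labeled-set tibble with columns `index` (citation index)
#'   and `label` (`relevant`/`irrelevant`).
#' @param seed Optional integer seed making the draw reproducible without
#'   touching the global RNG state; with `seed = NULL` the current RNG
#'   stream is used.
#' @return The undersampled labeled-set tibble (original row order).
#' @export
undersample_random <- function(labeled, seed = NULL) {
  n_rel <- sum(labeled$label == "relevant")
  irr <- which(labeled$label == "irrelevant")
  m <- length(irr) - n_rel
  if (m <= 0) return(labeled)
  draw <- function() sample(irr, m)
  drop_rows <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  labeled[-drop_rows, , drop = FALSE]
}

#' Aggressive undersampling of the majority class
#'
#' Removes exactly `m = #irrelevant - #relevant` labeled-irrelevant citations
#' whose vectors lie *nearest* the model's hyperplane (smallest absolute
#' signed distance; ties broken by lower citation index). Discarding the
#' boundary-hugging majority examples pushes the retrained decision boundary
#' away from the minority class, trading specificity for sensitivity. A no-op
#' when `m <= 0`. The removal is per view: each view's model defines its own
#' removals.
#'
#' @param labeled A labeled-set tibble (`index`, `label`).
#' @param model A `margin_model` trained on the labeled set in this view.
#' @param vectors The view's citation-by-term matrix; rows are indexed by
#'   citation index (i.e. `vectors[i, ]` is citation `i`).
#' @return The undersampled labeled-set tibble.
#' @export
aggressive_undersample <- function(labeled, model, vectors) {
  n_rel <- sum(labeled$label == "relevant")
  irr_rows <- which(labeled$label == "irrelevant")
  m <- length(irr_rows) - n_rel
  if (m <= 0) return(labeled)
  idx <- labeled$index[irr_rows]
  d <- abs(signed_distance(model, vectors[idx, , drop = FALSE]))
  drop_rows <- irr_rows[order(d, idx)[seq_len(m)]]
  labeled[-drop_rows, , drop = FALSE]
}

# Gram-space analogue used inside the active-learning loop: drop the m
# labeled-irrelevant citations with smallest |signed distance|, ties by
# lower citation index.
undersample_aggressive_idx <- function(labeled, dist_by_index) {
  n_rel <- sum(labeled$label == "relevant")
  irr_rows <- which(labeled$label == "irrelevant")
  m <- length(irr_rows) - n_rel
  if (m <= 0) return(labeled)
  idx <- labeled$index[irr_rows]
  d <- abs(dist_by_index[as.character(idx)])
  drop_rows <- irr_rows[order(d, idx)[seq_len(m)]]
  labeled[-drop_rows, , drop = FALSE]
}
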