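# Small fixtures and independent oracles shared across the test files.
# Everything is built in code; nothing is read from disk except files the
# tests themselves write to tempdirs.

# a tiny fully-gold-labeled corpus built by hand
make_tiny_corpus <- function(labels = c("relevant", "irrelevant", "irrelevant")) {
  n <- length(labels)
  tibble::tibble(
    id = paste0("d", seq_len(n)),
    title = paste("study number", seq_len(n)),
    abstract = paste("abstract text for record", seq_len(n)),
    keywords = lapply(seq_len(n), function(i) paste0("kw", i)),
    concepts = lapply(seq_len(n), function(i) paste0("C000", i)),
    label = labels
  )
}

# write a corpus CSV literally, bypassing write_corpus(), so reader tests
# do not depend on the writer
write_csv_fixture <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a hand-built view_set with one 2-d "title" view whose rows are given
# directly; lets selection tests pin distances exactly
manual_view_set <- function(X, view = "title") {
  X <- Matrix::Matrix(X, sparse = TRUE)
  spaces <- list(list(name = view, vocabulary = paste0("t", seq_len(ncol(X))),
                      X = X, df = rep(1L, ncol(X))))
  names(spaces) <- view
  structure(list(spaces = spaces, k = 1L, n = nrow(X),
                 ids = paste0("d", seq_len(nrow(X)))),
            class = "view_set")
}

# a margin model with hand-set weights/bias (distance = (w.x + b)/||w||)
manual_model <- function(weights, bias, view = "title") {
  palscreen:::new_margin_model(view = view, weights = weights, bias = bias,
                               cost = 1)
}

# brute-force reference for aggressive undersampling: sort the majority by
# |signed distance| (ties by lower citation index), drop the first m
oracle_aggressive <- function(labeled, dist_by_index) {
  n_rel <- sum(labeled$label == "relevant")
  irr <- labeled[labeled$label == "irrelevant", ]
  m <- nrow(irr) - n_rel
  if (m <= 0) return(labeled)
  ord <- order(abs(dist_by_index[irr$index]), irr$index)
  drop_idx <- irr$index[ord[seq_len(m)]]
  labeled[!(labeled$index %in% drop_idx), ]
}

# brute-force reference for SIMPLE batch selection: for given per-slot view
# flips, repeatedly take the unlabeled index with smallest |distance| in the
# flipped view (full sort, ties by lower index)
oracle_simple <- function(unlabeled, absdist, flips) {
  chosen <- integer(0)
  pool <- unlabeled
  for (v in flips) {
    if (length(pool) == 0) break
    d <- absdist[v, match(pool, unlabeled)]
    ord <- order(d, pool)
    chosen <- c(chosen, pool[ord[1]])
    pool <- setdiff(pool, chosen)
  }
  chosen
}

# gold-label oracle over a corpus
gold_oracle <- function(corpus) function(i) corpus$label[i]
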