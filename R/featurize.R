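#' The bundled PubMed stop-word list
#'
#' Returns the standard PubMed stop-word list shipped with the package (one
#' term per line under `inst/stopwords/`). These are removed from title and
#' abstract text before bag-of-words encoding.
#'
#' @return Character vector of lowercase stopwords.
#' @export
pubmed_stopwords <- function() {
  path <- system.file("stopwords", "pubmed_stopwords.txt", package = "palscreen")
  readLines(path, warn = FALSE)
}

#' Tokenize free text
#'
#' Lowercases, splits on any run of non-alphanumeric characters, and removes
#' stopwords. Empty input yields an empty token list; punctuation never yields
#' tokens.
#'
#' @param text Character vector of free text (each element tokenized
#'   separately).
#' @param stopwords Character vector of stopwords to drop; defaults to the
#'   bundled PubMed list.
#' @return For a single string, a character vector of tokens; for longer
#'   input, a list of token vectors.
#' @export
#' @examples
#' tokenize("The EGFR gene")
tokenize <- function(text, stopwords = pubmed_stopwords()) {
  text[is.na(text)] <- ""
  toks <- strsplit(tolower(text), "[^a-z0-9]+")
  toks <- lapply(toks, function(v) v[nzchar(v) & !(v %in% stopwords)])
  if (length(toks) == 1) toks[[1]] else toks
}

# Build one sparse TF(-IDF) feature space from per-document term lists.
# `counted = TRUE` uses within-document counts as tf (text views); FALSE uses
# binary presence (keyword/concept views). Terms with document frequency
# below `min_df` are dropped. idf = ln(N/df); rows are L2-unit-normalized.
build_feature_space <- function(name, term_lists, min_df = 1) {
  n <- length(term_lists)
  df_tab <- table(unlist(lapply(term_lists, unique), use.names = FALSE))
  vocab <- sort(names(df_tab)[df_tab >= min_df])
  df <- as.integer(df_tab[vocab])
  names(df) <- vocab
  i <- integer(); j <- integer(); x <- numeric()
  if (length(vocab) > 0) {
    trip <- imap(term_lists, function(terms, doc) {
      terms <- terms[terms %in% vocab]
      if (length(terms) == 0) return(NULL)
      tf <- table(terms)
      list(i = rep.int(doc, length(tf)), j = match(names(tf), vocab), x = as.numeric(tf))
    })
    trip <- trip[!vapply(trip, is.null, logical(1))]
    i <- unlist(lapply(trip, `[[`, "i"), use.names = FALSE) %||% integer()
    j <- unlist(lapply(trip, `[[`, "j"), use.names = FALSE) %||% integer()
    x <- unlist(lapply(trip, `[[`, "x"), use.names = FALSE) %||% numeric()
  }
  X <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, max(length(vocab), 1L)))
  if (length(vocab) == 0) X <- X[, 0, drop = FALSE]
  idf <- log(n / df)
  X <- X %*% Matrix::Diagonal(x = idf)
  norms <- sqrt(Matrix::rowSums(X^2))
  X <- Matrix::Diagonal(x = ifelse(norms > 0, 1 / norms, 0)) %*% X
  structure(list(name = name, vocabulary = vocab, X = methods::as(X, "CsparseMatrix"),
                 df = df, idf = idf),
            class = "feature_space")
}

#' Build the multi-view TF-IDF representation of a corpus
#'
#' Encodes each citation as a point in up to four aligned feature spaces:
#' `title` and `abstract` (bag-of-words over tokenized text, with terms
#' appearing in fewer than `min_df` documents of the whole corpus dropped)
#' and `keywords` and `concepts` (bag-of-terms over the verbatim
#' controlled-vocabulary / concept-identifier lists, no tokenization, no
#' frequency floor). Weights are tf x ln(N/df) with tf the raw
#' within-document count (binary presence for the term views), and each
#' non-zero vector is scaled to unit Euclidean length so the linear kernel
#' is the cosine between citations.
#'
#' @param corpus A corpus tibble (see [read_corpus()]).
#' @param views Which of the four views to build.
#' @param min_df Document-count floor for text views (default 3): tokens in
#'   fewer documents are excluded from the vocabulary.
#' @param stopwords Stopword list for [tokenize()].
#' @return A `view_set` object: a list with `spaces` (named list of feature
#'   spaces, each holding `vocabulary`, a sparse citation-by-term matrix `X`,
#'   and document frequencies `df`), `k`, `n` and the citation `ids`.
#' @export
build_view_set <- function(corpus,
                           views = c("title", "abstract", "keywords", "concepts"),
                           min_df = 3, stopwords = pubmed_stopwords()) {
  validate_corpus(corpus)
  views <- match.arg(views, c("title", "abstract", "keywords", "concepts"),
                     several.ok = TRUE)
  n <- nrow(corpus)
  spaces <- list()
  for (v in views) {
    if (v %in% c("title", "abstract")) {
      toks <- tokenize(corpus[[v]], stopwords = stopwords)
      if (n == 1) toks <- list(toks)
      spaces[[v]] <- build_feature_space(v, toks, min_df = min_df)
    } else {
      terms <- lapply(corpus[[v]], function(t) unique(trimws(t[nzchar(trimws(t))])))
      spaces[[v]] <- build_feature_space(v, terms, min_df = 1)
    }
  }
  structure(list(spaces = spaces, k = length(spaces), n = n, ids = corpus$id),
            class = "view_set")
}

#' @export
print.view_set <- function(x, ...) {
  cat("<view_set> ", x$n, " citations, k = ", x$k, " views\n", sep = "")
  for (s in x$spaces) {
    cat(sprintf("  %-9s |vocab| = %d\n", s$name, length(s$vocabulary)))
  }
  invisible(x)
}

#' Extract one citation's vector in one view
#'
#' @param view_set A `view_set` from [build_view_set()].
#' @param view View name.
#' @param citation_index Integer citation index (row of the corpus).
#' @return A sparse 1 x |vocabulary| matrix; all-zero when the citation has
#'   no content in that view.
#' @export
vector_for <- function(view_set, view, citation_index) {
  sp <- view_set$spaces[[view]]
  if (is.null(sp)) abort(paste0("unknown view: \"", view, "\""))
  if (citation_index < 1 || citation_index > view_set$n) {
    abort(paste0("citation index out of range: ", citation_index))
  }
  sp$X[citation_index, , drop = FALSE]
}

# rows of a view matrix (internal)
view_matrix <- function(view_set, view) {
  sp <- view_set$spaces[[view]]
  if (is.null(sp)) abort(paste0("unknown view: \"", view, "\""))
  sp$X
}
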