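#' Read a citation corpus
#'
#' Reads a bibliographic file into the canonical corpus tibble used throughout
#' the package: one row per citation with columns `id`, `title`, `abstract`,
#' `keywords` (list of controlled-vocabulary strings), `concepts` (list of
#' pre-extracted biomedical concept identifiers) and `label` (one of
#' `"relevant"`, `"irrelevant"`, `"unknown"`).
#'
#' The canonical dialect is delimited text with header
#' `id,title,abstract,keywords,concepts,label`; multi-valued cells are
#' `";"`-separated and the `label` column is optional (missing labels become
#' `"unknown"`). RIS and MEDLINE-style flat files are read-only conveniences
#' mapped onto the same columns (RIS: `TI`/`T1` title, `AB`/`N2` abstract,
#' `KW` keywords, `C1` concepts, `ID` identifier, `LB` label; MEDLINE: `TI`,
#' `AB`, `MH`, `OT`, `PMID`, `LB` analogously). Missing fields become empty
#' strings or empty lists, never an error.
#'
#' @param path Path to the file.
#' @param format One of `"csv"`, `"tsv"`, `"ris"`, `"medline"`. Defaults to a
#'   guess from the file extension (`.tsv` -> tsv, `.ris` -> ris, `.txt`/
#'   `.medline`/`.nbib` -> medline, otherwise csv).
#' @return A corpus tibble. Row order follows file order; row `i` is document
#'   `d_i` for the whole session.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("id,title,abstract,keywords,concepts,label",
#'              "a,Asthma trial,An RCT of steroids,asthma;rct,C0004096,relevant",
#'              "b,Unrelated,Nothing here,,,irrelevant"), tf)
#' read_corpus(tf)
read_corpus <- function(path, format = NULL) {
  if (!file.exists(path)) abort(paste0("file does not exist: ", path))
  format <- format %||% guess_corpus_format(path)
  format <- match.arg(format, c("csv", "tsv", "ris", "medline"))
  corpus <- switch(format,
    csv = read_corpus_delim(path, ","),
    tsv = read_corpus_delim(path, "\t"),
    ris = read_corpus_ris(path),
    medline = read_corpus_medline(path)
  )
  validate_corpus(corpus)
  corpus
}

guess_corpus_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
    tsv = "tsv", ris = "ris", medline = "medline", nbib = "medline",
    txt = "medline", "csv")
}

read_corpus_delim <- function(path, delim) {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                           na = character(), progress = FALSE, show_col_types = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("unparseable record at row ", probs$row[1], " of ", path, ": ", probs$expected[1]))
  }
  if (!"id" %in% names(raw)) abort("corpus file must have an 'id' column")
  for (col in c("title", "abstract")) if (!col %in% names(raw)) raw[[col]] <- ""
  for (col in c("keywords", "concepts")) if (!col %in% names(raw)) raw[[col]] <- ""
  if (!"label" %in% names(raw)) raw$label <- "unknown"
  tibble(
    id       = as.character(raw$id),
    title    = raw$title %||% "",
    abstract = raw$abstract %||% "",
    keywords = split_multivalue(raw$keywords),
    concepts = split_multivalue(raw$concepts),
    label    = normalize_labels(raw$label)
  )
}

split_multivalue <- function(x) {
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE), function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

normalize_labels <- function(x) {
  x <- trimws(tolower(as.character(x)))
  x[is.na(x) | x == ""] <- "unknown"
  bad <- setdiff(unique(x), c("relevant", "irrelevant", "unknown"))
  if (length(bad) > 0) {
    abort(paste0("unknown label token: \"", bad[1], "\" (expected relevant/irrelevant/unknown)"))
  }
  x
}

# ---- tagged flat-file formats -----------------------------------------------

# Parse "TAG  - value" lines with indented continuation lines into per-record
# tag lists. `is_sep` marks end-of-record lines.
parse_tagged <- function(lines, tag_re, is_sep) {
  records <- list()
  current <- list()
  last_tag <- NULL
  flush <- function() {
    if (length(current) > 0) records[[length(records) + 1]] <<- current
    current <<- list()
    last_tag <<- NULL
  }
  for (ln in lines) {
    if (is_sep(ln)) { flush(); next }
    m <- regmatches(ln, regexec(tag_re, ln))[[1]]
    if (length(m) == 3) {
      tag <- trimws(m[2]); val <- m[3]
      current[[tag]] <- c(current[[tag]] %||% character(), val)
      last_tag <- tag
    } else if (grepl("^\\s+\\S", ln) && !is.null(last_tag)) {
      v <- current[[last_tag]]
      v[length(v)] <- paste(v[length(v)], trimws(ln))
      current[[last_tag]] <- v
    } else if (nzchar(trimws(ln))) {
      abort(paste0("unparseable record line: \"", ln, "\""))
    }
  }
  flush()
  records
}

tag1 <- function(rec, tags, default = "") {
  for (tag in tags) if (!is.null(rec[[tag]])) return(paste(rec[[tag]], collapse = " "))
  default
}

tagged_to_corpus <- function(records, id_tags, title_tags, abstract_tags,
                             keyword_tags, concept_tags, id_prefix) {
  rows <- imap(records, function(rec, i) {
    id <- tag1(rec, id_tags, default = sprintf("%s%04d", id_prefix, i))
    kw <- unlist(lapply(keyword_tags, function(tg) rec[[tg]]), use.names = FALSE) %||% character()
    cc <- unlist(lapply(concept_tags, function(tg) rec[[tg]]), use.names = FALSE) %||% character()
    tibble(
      id = trimws(id),
      title = tag1(rec, title_tags),
      abstract = tag1(rec, abstract_tags),
      keywords = list(trimws(kw)),
      concepts = list(trimws(cc)),
      label = normalize_labels(tag1(rec, "LB", default = "unknown"))
    )
  })
  bind_rows(rows)
}

read_corpus_ris <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  records <- parse_tagged(lines, "^([A-Z][A-Z0-9])\\s{2}-\\s?(.*)$",
                          is_sep = function(ln) grepl("^ER\\s{2}-", ln))
  tagged_to_corpus(records,
    id_tags = "ID", title_tags = c("TI", "T1"), abstract_tags = c("AB", "N2"),
    keyword_tags = "KW", concept_tags = "C1", id_prefix = "ris")
}

read_corpus_medline <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  records <- parse_tagged(lines, "^([A-Z][A-Z0-9]{1,3})\\s*-\\s?(.*)$",
                          is_sep = function(ln) !nzchar(trimws(ln)))
  tagged_to_corpus(records,
    id_tags = "PMID", title_tags = "TI", abstract_tags = "AB",
    keyword_tags = "MH", concept_tags = "OT", id_prefix = "med")
}

# ---- validation -------------------------------------------------------------

#' Validate a corpus tibble
#'
#' Checks the structural invariants of the canonical corpus representation:
#' required columns, unique ids, normalized labels. With `require_gold = TRUE`
#' every citation must carry a gold label (`relevant`/`irrelevant`), as
#' simulation corpora do.
#'
#' @param corpus A corpus tibble (see [read_corpus()]).
#' @param require_gold Require every label to be relevant/irrelevant.
#' @return The corpus, invisibly, for piping.
#' @export
validate_corpus <- function(corpus, require_gold = FALSE) {
  if (!is.data.frame(corpus)) abort("corpus must be a data frame")
  needed <- c("id", "title", "abstract", "keywords", "concepts", "label")
  missing_cols <- setdiff(needed, names(corpus))
  if (length(missing_cols) > 0) {
    abort(paste0("corpus is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(corpus) == 0) abort("corpus is empty")
  dup <- corpus$id[duplicated(corpus$id)]
  if (length(dup) > 0) abort(paste0("duplicate citation id: \"", dup[1], "\""))
  normalize_labels(corpus$label) # errors on unknown tokens
  if (require_gold && any(corpus$label == "unknown")) {
    abort("simulation requires gold labels: corpus contains label \"unknown\"")
  }
  invisible(corpus)
}

#' Write a corpus in the canonical CSV dialect
#'
#' Inverse of [read_corpus()] for the CSV/TSV dialect: multi-valued fields are
#' joined with `";"`. Reading the written file back reproduces the corpus.
#'
#' @param corpus A corpus tibble.
#' @param path Output path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, delim = ",") {
  validate_corpus(corpus)
  out <- tibble(
    id = corpus$id,
    title = corpus$title,
    abstract = corpus$abstract,
    keywords = map_chr(corpus$keywords, paste, collapse = ";"),
    concepts = map_chr(corpus$concepts, paste, collapse = ";"),
    label = corpus$label
  )
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Write screening decisions
#'
#' Emits the final per-citation decision file of a screening run: columns
#' `id`, `decision` (`relevant`/`irrelevant`) and `source` (`human-labeled`
#' for citations the reviewer screened during training, `model-predicted`
#' for the rest). Round-trips losslessly through [read_predictions()].
#'
#' @param corpus A corpus tibble.
#' @param decisions A data frame with columns `id`, `decision`, `source`
#'   covering every citation in `corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(corpus, decisions, path) {
  validate_corpus(corpus)
  needed <- c("id", "decision", "source")
  if (!all(needed %in% names(decisions))) {
    abort("decisions must have columns id, decision, source")
  }
  missing_ids <- setdiff(corpus$id, decisions$id)
  if (length(missing_ids) > 0) {
    abort(paste0("decisions do not cover citation id \"", missing_ids[1], "\""))
  }
  bad <- setdiff(unique(decisions$decision), c("relevant", "irrelevant"))
  if (length(bad) > 0) abort(paste0("invalid decision token: \"", bad[1], "\""))
  bad_src <- setdiff(unique(decisions$source), c("human-labeled", "model-predicted"))
  if (length(bad_src) > 0) abort(paste0("invalid source token: \"", bad_src[1], "\""))
  out <- decisions[match(corpus$id, decisions$id), needed]
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a screening-decision file written by [write_predictions()]
#'
#' @param path Path to the decision CSV.
#' @return A tibble with columns `id`, `decision`, `source`.
#' @export
read_predictions <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}
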