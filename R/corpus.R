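#' Tokenize a text string
#'
#' Default behaviour: lower-case the text, split on runs of non-alphanumeric
#' characters and drop empty fragments. Stopword removal and a minimum token
#' length are available but off by default; every choice is carried in the
#' returned configuration of fitted models so runs are reproducible.
#'
#' @param text Character scalar (UTF-8). `NA` is treated as empty.
#' @param lowercase Fold case before splitting? Default `TRUE`.
#' @param stopwords Optional character vector of tokens to drop after
#'   splitting (compared post case-folding).
#' @param min_length Minimum token length kept. Default 1 (keep everything).
#' @return Character vector of tokens in document order (possibly empty).
#' @examples
#' tokenize("GFP-tagged protein binds DNA.")
#' @export
tokenize <- function(text, lowercase = TRUE, stopwords = NULL, min_length = 1L) {
  if (length(text) != 1L) stop("tokenize() expects a single string")
  if (is.na(text) || !nzchar(text)) return(character(0))
  if (lowercase) text <- tolower(text)
  toks <- strsplit(text, "[^[:alnum:]]+")[[1L]]
  toks <- toks[nzchar(toks)]
  if (min_length > 1L) toks <- toks[nchar(toks) >= min_length]
  if (!is.null(stopwords)) toks <- toks[!(toks %in% stopwords)]
  toks
}

#' Binary term vector of an abstract sentence
#'
#' Sentences use a set-of-words representation: each distinct term maps to 1
#' regardless of how often it occurs.
#'
#' @param sentence Sentence text, or an already tokenized character vector.
#' @param ... Passed to [tokenize()] when `sentence` is a single string.
#' @return Named integer vector of 1s; `sum()` of it is the number of
#'   distinct terms.
#' @export
sentence_vector <- function(sentence, ...) {
  toks <- if (length(sentence) == 1L) tokenize(sentence, ...) else sentence
  terms <- unique(toks)
  stats::setNames(rep(1L, length(terms)), terms)
}

#' Count term vector from tokens
#' @noRd
count_vector <- function(tokens) {
  if (length(tokens) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(tokens)
  stats::setNames(as.integer(tab), names(tab))
}

#' Caption and referencing-paragraph term counts for a figure
#'
#' Figures use a bag-of-words representation: raw occurrence counts, kept
#' separately for the caption and for the pooled referencing paragraphs so
#' that figure-specific language models can weight the two sources.
#'
#' @param figure A figure record as produced by [fl_figure()].
#' @param ... Passed to [tokenize()].
#' @return List with components `caption` and `referencing`, each a named
#'   integer count vector, and `caption_total` / `referencing_total` token
#'   counts.
#' @export
figure_counts <- function(figure, ...) {
  cap <- count_vector(tokenize(figure$caption, ...))
  ref_toks <- unlist(lapply(figure$referencing_paragraphs, tokenize, ...),
                     use.names = FALSE)
  ref <- count_vector(if (is.null(ref_toks)) character(0) else ref_toks)
  list(caption = cap, referencing = ref,
       caption_total = sum(cap), referencing_total = sum(ref))
}

#' Construct a figure record
#'
#' @param caption Caption text (may be empty).
#' @param referencing_paragraphs Character vector of body paragraphs that
#'   cite the figure (may be empty).
#' @return A list with class `fl_figure`.
#' @export
fl_figure <- function(caption = "", referencing_paragraphs = character(0)) {
  stopifnot(is.character(caption), length(caption) == 1L)
  structure(list(caption = caption,
                 referencing_paragraphs = as.character(referencing_paragraphs)),
            class = "fl_figure")
}

#' Construct an annotated article
#'
#' An article is an ordered list of abstract sentences (index `j`), an
#' ordered list of figures (index `k`, tables are treated as figures), and an
#' optional gold linkage matrix `L` with `L[j, k] = 1` when sentence `j` is
#' linked with figure `k`. Order is document order and all indices are
#' 1-based.
#'
#' @param article_id Identifier string.
#' @param sentences Character vector of abstract sentences, length `n_s >= 1`.
#' @param figures List of [fl_figure()] records, length `n_f >= 1`.
#' @param linkage Optional `n_s x n_f` binary matrix.
#' @return A list with class `fl_article`.
#' @export
fl_article <- function(article_id, sentences, figures, linkage = NULL) {
  stopifnot(is.character(article_id), length(article_id) == 1L)
  sentences <- as.character(sentences)
  if (length(sentences) < 1L) stop("article ", article_id, ": needs >= 1 sentence")
  if (length(figures) < 1L) stop("article ", article_id, ": needs >= 1 figure")
  figures <- lapply(figures, function(f) {
    if (inherits(f, "fl_figure")) f else fl_figure(f$caption, f$referencing_paragraphs)
  })
  if (!is.null(linkage)) {
    linkage <- as.matrix(linkage)
    if (nrow(linkage) != length(sentences) || ncol(linkage) != length(figures))
      stop("article ", article_id, ": linkage shape ", nrow(linkage), "x",
           ncol(linkage), " does not match ", length(sentences), " sentences x ",
           length(figures), " figures")
    if (!all(linkage %in% c(0, 1)))
      stop("article ", article_id, ": linkage entries must be 0/1")
    storage.mode(linkage) <- "integer"
    dimnames(linkage) <- NULL
  }
  structure(list(article_id = article_id, sentences = sentences,
                 figures = figures, linkage = linkage),
            class = "fl_article")
}

#' @export
print.fl_article <- function(x, ...) {
  cat("<fl_article ", x$article_id, ": ", length(x$sentences), " sentences, ",
      length(x$figures), " figures, ",
      if (is.null(x$linkage)) "no linkage" else paste0(sum(x$linkage), " links"),
      ">\n", sep = "")
  invisible(x)
}

n_sentences <- function(article) length(article$sentences)
n_figures <- function(article) length(article$figures)

as_corpus <- function(articles) structure(articles, class = "fl_corpus")

#' @export
print.fl_corpus <- function(x, ...) {
  cat("<fl_corpus: ", length(x), " articles>\n", sep = "")
  invisible(x)
}

#' Read an annotated corpus from JSON
#'
#' The schema is a top-level array of objects
#' \preformatted{
#' {"article_id": str,
#'  "sentences": [str, ...],
#'  "figures": [{"caption": str, "referencing_paragraphs": [str, ...]}, ...],
#'  "linkage": [[0/1, ...], ...]}   # optional; rows = sentences
#' }
#'
#' @param path Path to a JSON file.
#' @return List of articles with class `fl_corpus`.
#' @export
read_corpus <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  arts <- lapply(raw, function(a) {
    id <- if (is.null(a$article_id)) "<missing article_id>" else a$article_id
    for (field in c("article_id", "sentences", "figures"))
      if (is.null(a[[field]]))
        stop("article ", id, ": missing required field '", field, "'")
    figures <- lapply(a$figures, function(f) {
      if (is.null(f$caption))
        stop("article ", id, ": figure missing 'caption'")
      fl_figure(f$caption,
                unlist(f$referencing_paragraphs, use.names = FALSE) %||% character(0))
    })
    linkage <- if (!is.null(a$linkage)) {
      rows <- lapply(a$linkage, function(r) unlist(r, use.names = FALSE))
      ncols <- unique(vapply(rows, length, 1L))
      if (length(ncols) != 1L)
        stop("article ", id, ": ragged linkage rows")
      do.call(rbind, rows)
    }
    fl_article(a$article_id, unlist(a$sentences, use.names = FALSE),
               figures, linkage)
  })
  as_corpus(arts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a corpus to JSON
#'
#' Inverse of [read_corpus()]: writing then reading reproduces all fields.
#'
#' @param corpus List of `fl_article` objects.
#' @param path Output path.
#' @export
write_corpus <- function(corpus, path) {
  out <- lapply(corpus, function(a) {
    rec <- list(article_id = jsonlite::unbox(a$article_id),
                sentences = as.list(a$sentences),
                figures = lapply(a$figures, function(f)
                  list(caption = jsonlite::unbox(f$caption),
                       referencing_paragraphs = as.list(f$referencing_paragraphs))))
    if (!is.null(a$linkage))
      rec$linkage <- lapply(seq_len(nrow(a$linkage)),
                            function(i) as.list(a$linkage[i, ]))
    rec
  })
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Corpus summary statistics
#'
#' Counts sentences, figures and sentence/figure instances, the fraction of
#' instances that are linked, and the degree distributions of sentences
#' (number of figures each sentence links to) and figures.
#'
#' @param corpus A corpus whose articles all carry a linkage matrix.
#' @return List with totals, `linked_fraction`, and named degree tables
#'   `sentence_degree` / `figure_degree`.
#' @export
corpus_stats <- function(corpus) {
  if (any(vapply(corpus, function(a) is.null(a$linkage), TRUE)))
    stop("corpus_stats() requires a linkage matrix on every article")
  n_s <- vapply(corpus, n_sentences, 1L)
  n_f <- vapply(corpus, n_figures, 1L)
  n_inst <- sum(n_s * n_f)
  n_linked <- sum(vapply(corpus, function(a) sum(a$linkage), 1L))
  sdeg <- unlist(lapply(corpus, function(a) rowSums(a$linkage)))
  fdeg <- unlist(lapply(corpus, function(a) colSums(a$linkage)))
  list(n_articles = length(corpus),
       n_sentences = sum(n_s), n_figures = sum(n_f),
       n_instances = n_inst, n_linked = n_linked,
       linked_fraction = if (n_inst > 0) n_linked / n_inst else 0,
       sentence_degree = table(sdeg), figure_degree = table(fdeg))
}
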