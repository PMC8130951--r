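#' Construct a target word list
#'
#' A word list is the ordered set of items participants study and are asked
#' to recall. Positions are 1-based and order is meaningful: sequence scoring
#' measures displacement relative to this order.
#'
#' @param items Character vector of target items, in presentation order.
#' @return An object of class `word_list`: a list with `items` (raw strings)
#'   and `canonical` (normalized forms, see [normalize_entry()]).
#' @examples
#' wl <- word_list(c("Metalmark", "Anglewing", "Swallowtail"))
#' wl$canonical
#' @export
word_list <- function(items) {
  items <- as.character(items)
  if (length(items) < 1L) {
    stop("word_list requires at least one item", call. = FALSE)
  }
  canonical <- vapply(items, normalize_entry, character(1), USE.NAMES = FALSE)
  if (any(is.na(canonical))) {
    stop("word_list items must not be blank", call. = FALSE)
  }
  if (anyDuplicated(canonical)) {
    stop("word_list canonical forms must be pairwise distinct", call. = FALSE)
  }
  structure(list(items = items, canonical = canonical), class = "word_list")
}

#' @export
print.word_list <- function(x, ...) {
  cat("<word_list> ", length(x$items), " items\n", sep = "")
  cat(" ", paste(utils::head(x$items, 8), collapse = ", "),
      if (length(x$items) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.word_list <- function(x) length(x$items)

#' Construct a lexicon of semantically meaningful words and morphemes
#'
#' The lexicon operationalizes the "semantically meaningful" test used to
#' separate near misses from plain spelling slips: an entry counts as
#' meaningful if it is itself a known word, a known morpheme, or can be split
#' into two known morphemes (compound decomposition). A misspelling like
#' "meselmark" decomposes into no known parts and is therefore treated as a
#' spelling slip, not a near miss.
#'
#' @param words Character vector of full meaningful words (e.g. valid
#'   compounds such as "metalmask").
#' @param morphemes Character vector of compound components (e.g. "metal",
#'   "mask").
#' @return An object of class `lexicon` with normalized `words` and
#'   `morphemes` sets.
#' @export
lexicon <- function(words = character(), morphemes = character()) {
  norm <- function(x) {
    x <- vapply(as.character(x), normalize_entry, character(1),
                USE.NAMES = FALSE)
    unique(x[!is.na(x)])
  }
  structure(list(words = norm(words), morphemes = norm(morphemes)),
            class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon> ", length(x$words), " words, ",
      length(x$morphemes), " morphemes\n", sep = "")
  invisible(x)
}

#' Test whether a token is semantically meaningful under a lexicon
#'
#' @param token Normalized token.
#' @param lex A [lexicon()].
#' @return Logical scalar.
#' @export
is_meaningful <- function(token, lex) {
  stopifnot(inherits(lex, "lexicon"))
  if (is.na(token) || !nzchar(token)) return(FALSE)
  if (token %in% lex$words || token %in% lex$morphemes) return(TRUE)
  !is.null(split_morphemes(token, lex))
}

#' Decompose a token into two lexicon morphemes
#'
#' Returns the first split (leftmost split point) of `token` into a
#' modifier + head pair with both parts in the lexicon's morpheme set, or
#' `NULL` when no such split exists.
#'
#' @inheritParams is_meaningful
#' @return Character vector of length 2, or `NULL`.
#' @export
split_morphemes <- function(token, lex) {
  if (is.na(token) || nchar(token) < 2L) return(NULL)
  n <- nchar(token)
  for (i in seq_len(n - 1L)) {
    left <- substr(token, 1L, i)
    right <- substr(token, i + 1L, n)
    if (left %in% lex$morphemes && right %in% lex$morphemes) {
      return(c(left, right))
    }
  }
  NULL
}

#' Read a word list from a plain-text file
#'
#' One item per line, UTF-8; blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @return A [word_list()].
#' @export
read_wordlist <- function(path) {
  word_list(read_token_lines(path))
}

#' Read a lexicon from plain-text files
#'
#' Each file holds one token per line with `#` comments allowed.
#'
#' @param words_path Path to the meaningful-words file.
#' @param morphemes_path Path to the morphemes file (optional).
#' @return A [lexicon()].
#' @export
read_lexicon <- function(words_path, morphemes_path = NULL) {
  words <- read_token_lines(words_path)
  morphemes <- if (!is.null(morphemes_path)) {
    read_token_lines(morphemes_path)
  } else {
    character()
  }
  lexicon(words = words, morphemes = morphemes)
}

read_token_lines <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Write a word list or lexicon component to a plain-text file
#'
#' @param tokens Character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_token_lines <- function(tokens, path) {
  writeLines(as.character(tokens), path, useBytes = TRUE)
  invisible(path)
}
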