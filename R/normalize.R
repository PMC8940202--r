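#' Normalize a clinical term into tokens
#'
#' Shared normalization contract for all name matching in the package:
#' lowercase, replace `_`, `-` and `/` by spaces, strip all other
#' punctuation, collapse whitespace, and split on spaces.  This makes
#' spellings such as `"Anti-La"` and `"anti_la"` comparable.
#'
#' @param x A character string (a column header or term name).
#' @return A character vector of tokens; `character(0)` for a string that
#'   normalizes to nothing.
#' @examples
#' normalize_term("Anti-La")               # "anti" "la"
#' normalize_term("salivary_gland-swelling")
#' @export
normalize_term <- function(x) {
  key <- normalize_key(x)
  if (!nzchar(key)) return(character(0))
  strsplit(key, " ", fixed = TRUE)[[1]]
}

#' Normalized space-joined form of a term
#'
#' @param x Character vector of term names.
#' @return Character vector of the same length with each element in
#'   normalized, space-joined form (`""` if nothing survives).
#' @export
normalize_key <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[_/-]", " ", x)
  x <- gsub("[^a-z0-9 ]", "", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Lexical similarity of two terms
#'
#' Normalized Levenshtein similarity of the normalized, space-joined forms:
#' `1 - d(a', b') / max(nchar(a'), nchar(b'))` with unit-cost edit distance
#' `d`.  Identical terms score 1; a term whose normalized form is empty
#' scores 0 against anything.
#'
#' @param a,b Character strings.
#' @return A similarity score in `[0, 1]`.
#' @examples
#' lexical_similarity("lymphadenopathy", "lymphadenopathy")  # 1
#' lexical_similarity("abc", "abd")                          # 2/3
#' @export
lexical_similarity <- function(a, b) {
  ka <- normalize_key(a)
  kb <- normalize_key(b)
  if (!nzchar(ka) || !nzchar(kb)) return(0)
  d <- utils::adist(ka, kb)[1, 1]
  1 - d / max(nchar(ka), nchar(kb))
}

# Similarity matrix between two vectors of raw names (rows = a, cols = b).
lexical_similarity_matrix <- function(a, b) {
  ka <- normalize_key(a)
  kb <- normalize_key(b)
  d <- utils::adist(ka, kb)
  denom <- outer(nchar(ka), nchar(kb), pmax)
  s <- 1 - d / pmax(denom, 1L)
  s[!nzchar(ka), ] <- 0
  s[, !nzchar(kb)] <- 0
  dimnames(s) <- list(a, b)
  s
}
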