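#' Syllable counting heuristic
#'
#' Counts maximal vowel groups (`a e i o u y`) in the letters of the word,
#' subtracts one for a silent terminal "e" (unless that "e" follows an "l",
#' as in "-le" endings like "table"), with a minimum of one syllable.
#' Deterministic and dictionary-free, so readability scores are reproducible
#' across environments.
#'
#' @param word character vector; each element must contain at least one
#'   letter after stripping punctuation.
#' @return Integer vector of syllable counts.
#' @examples
#' count_syllables(c("medication", "make", "table", "a"))
#' @export
count_syllables <- function(word) {
  w <- tolower(stringi::stri_replace_all_regex(word, "[^A-Za-z]", ""))
  if (any(!nzchar(w))) {
    abort("count_syllables() requires non-empty words after stripping punctuation",
          class = "bctmsg_argument_error")
  }
  groups <- stringi::stri_count_regex(w, "[aeiouy]+")
  silent_e <- grepl("[^aeioul]e$", w)
  pmax(groups - as.integer(silent_e), 1L)
}

split_sentences <- function(text) {
  segs <- stringi::stri_split_regex(text, "[.!?]+")[[1]]
  segs[stringi::stri_detect_regex(segs, "[A-Za-z0-9]")]
}

tokenize_words <- function(text) {
  toks <- stringi::stri_split_regex(tolower(text), "\\s+")[[1]]
  toks <- stringi::stri_replace_all_regex(toks, "^[^a-z0-9]+|[^a-z0-9]+$", "")
  toks <- stringi::stri_replace_all_regex(toks, "[^a-z0-9']", "")
  toks[nzchar(toks)]
}

#' Flesch-Kincaid grade level with ignore-word adjustment
#'
#' Tokenizes into sentences (split on runs of `.`, `!`, `?`) and words
#' (whitespace-delimited, punctuation-stripped, case-folded), then returns
#' `0.39 * (words / sentences) + 11.8 * (syllables / words) - 15.59`.
#' Tokens in `ignore_words` are removed from both the word and syllable
#' tallies (the sentence count is unchanged): domain words a target audience
#' necessarily knows (e.g. "medication" for people managing a prescription)
#' can thereby be excluded from the complexity assessment.
#'
#' @param text a single text.
#' @param ignore_words character vector of lowercase tokens to exclude.
#' @return The grade level (interpreted as a US school grade).
#' @examples
#' fk_grade("The cat sat.") # -2.62
#' @export
fk_grade <- function(text, ignore_words = character()) {
  stopifnot(is_string(text))
  sentences <- length(split_sentences(text))
  toks <- tokenize_words(text)
  toks <- toks[!(toks %in% tolower(ignore_words))]
  if (!length(toks) || sentences == 0L) {
    abort("Grade is undefined: no words remain after exclusion",
          class = "bctmsg_undefined_grade_error")
  }
  has_letters <- stringi::stri_detect_regex(toks, "[a-z]")
  syllables <- integer(length(toks))
  syllables[has_letters] <- count_syllables(toks[has_letters])
  syllables[!has_letters] <- 1L # numeric tokens count one syllable
  0.39 * (length(toks) / sentences) + 11.8 * (sum(syllables) / length(toks)) - 15.59
}
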