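#' Specification for a synthetic message bank
#'
#' Synthetic banks emulate the statistical shape of a generated message bank
#' — per-technique message counts, a character-length distribution, a target
#' readability band, and a controllable fraction of non-GSM-7 messages — so
#' every QC and diversity operation can be exercised offline at any scale.
#' Texts are grammatical filler assembled from the packaged phrase pool;
#' they carry no semantic claim.
#'
#' @param n_bcts number of techniques (labelled "1.1", "1.2", ... by major
#'   group of 9).
#' @param messages_per_bct messages per technique: a single count or a
#'   per-technique integer vector.
#' @param length_mean,length_sd,length_min,length_max target character-count
#'   distribution (truncated normal, in characters including spaces).
#' @param grade_low,grade_high target Flesch-Kincaid band used to tune word
#'   complexity.
#' @param frac_non_gsm7 fraction of messages given a non-GSM-7 character
#'   (an emoji), in `[0, 1]`.
#' @param multilabel_rate fraction of messages to code with two techniques
#'   (comparison banks only), in `[0, 1]`.
#' @param seed integer seed; one pseudo-random stream is derived per
#'   technique, so adding techniques never perturbs earlier ones.
#' @return A `synthetic_bank_spec` list.
#' @export
synthetic_bank_spec <- function(n_bcts = 46L, messages_per_bct = 25L,
                                length_mean = 119, length_sd = 28,
                                length_min = 40, length_max = 220,
                                grade_low = 5, grade_high = 9,
                                frac_non_gsm7 = 0, multilabel_rate = 0,
                                seed = 1L) {
  if (!(length_min <= length_mean && length_mean <= length_max)) {
    abort("Infeasible length spec: need length_min <= length_mean <= length_max",
          class = "bctmsg_validation_error")
  }
  for (f in c(frac_non_gsm7, multilabel_rate)) {
    if (f < 0 || f > 1) {
      abort("Fractions must lie in [0, 1]", class = "bctmsg_validation_error")
    }
  }
  if (grade_low > grade_high) {
    abort("Infeasible grade range", class = "bctmsg_validation_error")
  }
  stopifnot(n_bcts >= 1, all(messages_per_bct >= 1),
            length(messages_per_bct) %in% c(1L, n_bcts))
  structure(list(n_bcts = as.integer(n_bcts),
                 messages_per_bct = as.integer(messages_per_bct),
                 length_mean = length_mean, length_sd = length_sd,
                 length_min = length_min, length_max = length_max,
                 grade_low = grade_low, grade_high = grade_high,
                 frac_non_gsm7 = frac_non_gsm7,
                 multilabel_rate = multilabel_rate,
                 seed = as.integer(seed)),
            class = "synthetic_bank_spec")
}

# exactly k distinct evenly strided indices in 1..n (requires k <= n)
strided_indices <- function(n, k) {
  stopifnot(k <= n)
  (seq_len(k) - 1L) * (n %/% k) + 1L
}

synthetic_bct_numbers <- function(n) {
  sprintf("%d.%d", (seq_len(n) - 1L) %/% 9L + 1L, (seq_len(n) - 1L) %% 9L + 1L)
}

# One synthetic message near `target` characters. Sentences are built from
# the packaged word pools; the fraction of multi-syllable words is tuned so
# the expected Flesch-Kincaid grade falls inside the spec's band.
synth_message <- function(stream, target, grade_mid) {
  simple <- synth_simple_words()
  complex_ <- synth_complex_words()
  words_per_sentence <- 8
  # grade = 0.39*w/s + 11.8*spw - 15.59; solve spw for the band midpoint,
  # then mix 1-syllable and (mean ~3.5)-syllable words: spw = 1 + 2.5 f
  spw <- (grade_mid + 15.59 - 0.39 * words_per_sentence) / 11.8
  f <- min(1, max(0, (spw - 1) / 2.5))
  out <- character()
  nch <- 0L
  repeat {
    n_words <- words_per_sentence + floor(stream() * 5) - 2L
    ws <- vapply(seq_len(n_words), function(i) {
      if (stream() < f) stream_pick(stream, complex_) else
        stream_pick(stream, simple)
    }, character(1))
    ws[1] <- paste0(toupper(substr(ws[1], 1, 1)), substr(ws[1], 2, nchar(ws[1])))
    sentence <- paste0(paste(ws, collapse = " "), ".")
    new_nch <- nch + nchar(sentence) + (nch > 0L)
    if (nch > 0L && abs(new_nch - target) > abs(nch - target)) break
    out <- c(out, sentence)
    nch <- new_nch
    if (nch >= target) break
  }
  paste(out, collapse = " ")
}

synth_simple_words <- function() {
  unlist(strsplit(phrase_pool_section("simple-words"), "\\s+"))
}
synth_complex_words <- function() {
  unlist(strsplit(phrase_pool_section("complex-words"), "\\s+"))
}

rtrunc_norm <- function(stream, mean, sd, lo, hi) {
  repeat {
    x <- mean + sd * stream_norm(stream, 1)
    if (x >= lo && x <= hi) return(x)
  }
}

#' Generate a synthetic message bank
#'
#' Deterministic for a given seed. Realized character counts follow the
#' spec's truncated-normal distribution (the empirical mean converges to the
#' spec mean as the bank grows); the configured fraction of messages
#' (rounded up) carries a non-GSM-7 pill emoji appended to the text.
#'
#' @param spec a [synthetic_bank_spec()].
#' @return A [message_bank()].
#' @export
make_synthetic_bank <- function(spec = synthetic_bank_spec()) {
  stopifnot(inherits(spec, "synthetic_bank_spec"))
  numbers <- synthetic_bct_numbers(spec$n_bcts)
  per_bct <- rep_len(spec$messages_per_bct, spec$n_bcts)
  grade_mid <- (spec$grade_low + spec$grade_high) / 2
  rows <- vector("list", spec$n_bcts)
  for (b in seq_len(spec$n_bcts)) {
    stream <- lehmer_stream(sprintf("synth|%d|%s", spec$seed, numbers[b]))
    texts <- vapply(seq_len(per_bct[b]), function(i) {
      target <- rtrunc_norm(stream, spec$length_mean, spec$length_sd,
                            spec$length_min, spec$length_max)
      synth_message(stream, round(target), grade_mid)
    }, character(1))
    rows[[b]] <- tibble::tibble(
      bct_number = numbers[b],
      bct_label = paste("Synthetic technique", numbers[b]),
      message_index = seq_len(per_bct[b]),
      text = texts
    )
  }
  tbl <- dplyr::bind_rows(rows)
  n_non <- ceiling(spec$frac_non_gsm7 * nrow(tbl))
  if (n_non > 0) {
    # deterministic choice: stride-spaced rows get an emoji appended
    idx <- strided_indices(nrow(tbl), n_non)
    tbl$text[idx] <- paste0(tbl$text[idx], " \U0001F48A")
  }
  message_bank(tbl, provenance = list(generator = "make_synthetic_bank",
                                      seed = spec$seed,
                                      spec = unclass(spec)))
}

#' Generate a synthetic comparison bank with multi-technique codes
#'
#' Emulates an externally coded message bank in which some messages are coded
#' for more than one technique: `ceiling(multilabel_rate * n)` messages
#' receive a second code (the next technique, cyclically). The result feeds
#' [expand_multilabel()] and [match_distribution()].
#'
#' @param spec a [synthetic_bank_spec()] (its `multilabel_rate` applies).
#' @return A tibble with `message_id`, `text`, `bct_label` and a `bct_codes`
#'   list-column.
#' @export
make_comparison_bank <- function(spec = synthetic_bank_spec()) {
  bank <- make_synthetic_bank(spec)
  tbl <- tibble::as_tibble(bank)
  numbers <- synthetic_bct_numbers(spec$n_bcts)
  codes <- as.list(tbl$bct_number)
  n_multi <- ceiling(spec$multilabel_rate * nrow(tbl))
  if (n_multi > 0) {
    idx <- strided_indices(nrow(tbl), n_multi)
    for (i in idx) {
      pos <- match(tbl$bct_number[i], numbers)
      extra <- numbers[pos %% length(numbers) + 1L]
      codes[[i]] <- c(codes[[i]], extra)
    }
  }
  tibble::tibble(message_id = seq_len(nrow(tbl)), text = tbl$text,
                 bct_label = tbl$bct_label, bct_codes = codes)
}
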