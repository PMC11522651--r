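#' Validate a message bank against SMS and readability standards
#'
#' Scores every message on deliverability — character count (Unicode code
#' points after NFC normalization, spaces included), GSM-7 encodability and
#' septet cost — and on readability: the raw Flesch-Kincaid grade and the
#' grade adjusted by removing the ignore words. A message passes length when
#' its character count is at most `max_chars` *and* it is GSM-7 encodable
#' (septet count is reported alongside, since extension characters cost two
#' septets and determine true single-SMS delivery); it passes readability
#' when its adjusted grade is at most `grade_threshold`.
#'
#' @param bank a [message_bank()] (non-empty).
#' @param max_chars single-SMS character limit (default 160).
#' @param grade_threshold maximum acceptable adjusted grade (default 8.0,
#'   the common reading-level goal for general adult audiences).
#' @param ignore_words lowercase tokens excluded from the adjusted grade;
#'   default `c("medication", "medications")` — the domain word (and its
#'   plural) a medication-adherence audience necessarily knows.
#' @return A `validation_report`: list with `per_message` (tibble of
#'   per-message metrics keyed by `bct_number`, `message_index`),
#'   `aggregates` (named list) and `thresholds`.
#' @export
validate_bank <- function(bank, max_chars = 160, grade_threshold = 8.0,
                          ignore_words = c("medication", "medications")) {
  tbl <- tibble::as_tibble(bank)
  if (!nrow(tbl)) {
    abort("validate_bank() requires a non-empty bank",
          class = "bctmsg_argument_error")
  }
  text_nfc <- stringi::stri_trans_nfc(tbl$text)
  char_count <- stringi::stri_length(text_nfc)
  septets <- gsm7_septet_length(tbl$text)
  encodable <- !is.na(septets)
  grade_of <- function(t, ignore) {
    tryCatch(fk_grade(t, ignore), bctmsg_undefined_grade_error = function(e) NA_real_)
  }
  fk_raw <- vapply(tbl$text, grade_of, numeric(1), ignore = character(),
                   USE.NAMES = FALSE)
  fk_adj <- vapply(tbl$text, grade_of, numeric(1), ignore = ignore_words,
                   USE.NAMES = FALSE)
  per_message <- tibble::tibble(
    bct_number = tbl$bct_number,
    message_index = tbl$message_index,
    char_count = char_count,
    gsm7_encodable = encodable,
    septet_count = septets,
    fk_grade_raw = fk_raw,
    fk_grade_adjusted = fk_adj,
    passes_length = char_count <= max_chars & encodable,
    passes_readability = !is.na(fk_adj) & fk_adj <= grade_threshold
  )
  n_total <- nrow(per_message)
  aggregates <- list(
    n_total = n_total,
    n_pass_length = sum(per_message$passes_length),
    pct_pass_length = 100 * sum(per_message$passes_length) / n_total,
    mean_char_count = mean(char_count),
    n_pass_readability_raw = sum(!is.na(fk_raw) & fk_raw <= grade_threshold),
    n_pass_readability_adjusted = sum(per_message$passes_readability),
    pct_pass_readability_adjusted =
      100 * sum(per_message$passes_readability) / n_total,
    mean_grade_raw = mean(fk_raw, na.rm = TRUE),
    mean_grade_adjusted = mean(fk_adj, na.rm = TRUE),
    n_grade_undefined = sum(is.na(fk_adj))
  )
  structure(
    list(per_message = per_message, aggregates = aggregates,
         thresholds = list(max_chars = max_chars,
                           grade_threshold = grade_threshold,
                           ignore_words = ignore_words)),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  a <- x$aggregates
  cat("<validation_report>\n")
  cat(sprintf("  messages: %d\n", a$n_total))
  cat(sprintf("  length:   %d/%d (%.2f%%) within %d chars and GSM-7; mean %.1f chars\n",
              a$n_pass_length, a$n_total, a$pct_pass_length,
              x$thresholds$max_chars, a$mean_char_count))
  cat(sprintf("  grade:    mean %.2f raw, %.2f adjusted; %d raw / %d adjusted at or below %.1f\n",
              a$mean_grade_raw, a$mean_grade_adjusted,
              a$n_pass_readability_raw, a$n_pass_readability_adjusted,
              x$thresholds$grade_threshold))
  invisible(x)
}

#' Write a validation report to JSON (plus optional per-message CSV)
#'
#' @param report a `validation_report` from [validate_bank()].
#' @param path output JSON path.
#' @param per_message_csv optional path for a CSV of the per-message table.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path, per_message_csv = NULL) {
  jsonlite::write_json(
    list(aggregates = report$aggregates, thresholds = report$thresholds,
         per_message = report$per_message),
    path, dataframe = "rows", auto_unbox = TRUE, pretty = TRUE, digits = NA,
    na = "null"
  )
  if (!is.null(per_message_csv)) {
    readr::write_csv(report$per_message, per_message_csv, na = "")
  }
  invisible(path)
}

#' Histograms of message length and readability grade
#'
#' Companion figures to the bank-level aggregates: the character-count
#' distribution against the single-SMS limit, and the grade distribution
#' (raw or adjusted) against the reading-level goal.
#'
#' @param report a `validation_report`.
#' @param which for [plot_grade_distribution()], `"adjusted"` (default) or
#'   `"raw"`.
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(report) {
  ggplot2::ggplot(report$per_message, ggplot2::aes(x = .data$char_count)) +
    ggplot2::geom_histogram(binwidth = 5, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = report$thresholds$max_chars,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Characters (incl. spaces)", y = "Messages",
                  title = "Message length distribution") +
    ggplot2::theme_minimal()
}

#' @rdname plot_length_distribution
#' @export
plot_grade_distribution <- function(report, which = c("adjusted", "raw")) {
  which <- match.arg(which)
  col <- if (which == "adjusted") "fk_grade_adjusted" else "fk_grade_raw"
  ggplot2::ggplot(report$per_message, ggplot2::aes(x = .data[[col]])) +
    ggplot2::geom_histogram(binwidth = 0.5, fill = "seagreen", colour = "white") +
    ggplot2::geom_vline(xintercept = report$thresholds$grade_threshold,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = sprintf("Flesch-Kincaid grade (%s)", which),
                  y = "Messages",
                  title = "Readability grade distribution") +
    ggplot2::theme_minimal()
}
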