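#' Generation configuration
#'
#' @param backend_name,model_name identifier strings recorded in provenance.
#' @param temperature sampling temperature; defaults to 0 so repeated runs of
#'   a conforming backend are as deterministic as the provider allows.
#' @param messages_per_bct number of messages requested per technique
#'   (default 25).
#' @param seed integer seed consumed by the mock backend only.
#' @return A `generation_config` list.
#' @export
generation_config <- function(backend_name = "mock",
                              model_name = "gpt-3.5-turbo-0301",
                              temperature = 0,
                              messages_per_bct = 25L,
                              seed = 1L) {
  stopifnot(is.numeric(temperature), temperature >= 0,
            is.numeric(messages_per_bct), messages_per_bct >= 1)
  structure(list(backend_name = backend_name, model_name = model_name,
                 temperature = temperature,
                 messages_per_bct = as.integer(messages_per_bct),
                 seed = as.integer(seed)),
            class = "generation_config")
}

#' Chat-completion backends
#'
#' A chat backend is a list with fields `name` (identifier) and `complete`,
#' a `function(system_text, user_text, config)` returning a list with
#' `text` (the raw assistant response) and optionally `tokens` (an integer
#' total token count for the query, when the provider reports usage).
#' `chat_backend()` wraps and sanity-checks such a function. The packaged
#' [mock_chat_backend()] is a pure function of the prompts and the config
#' seed, so the whole generation pipeline runs offline and reproducibly.
#'
#' @param name backend identifier.
#' @param complete completion function as described above.
#' @return A `chat_backend` object.
#' @export
chat_backend <- function(name, complete) {
  stopifnot(is_string(name), is.function(complete))
  structure(list(name = name, complete = complete), class = "chat_backend")
}

mock_phrase_pool <- function() phrase_pool_section("sentences")

#' Deterministic mock completion
#'
#' Synthesizes `messages_per_bct` quoted message lines whose wording is a pure
#' function of the BCT label parsed from the user prompt, the line index and
#' `config$seed`. Intended as the offline stand-in for a live chat API:
#' repeated calls are byte-identical, different seeds give different texts.
#'
#' @param system_text,user_text rendered prompt texts.
#' @param config a [generation_config()].
#' @return Raw assistant text: one double-quoted message per line.
#' @export
mock_complete <- function(system_text, user_text, config = generation_config()) {
  first <- strsplit(user_text, "\n", fixed = TRUE)[[1]][1]
  label <- sub("^BCT: ", "", sub(" = .*$", "", first))
  pool <- mock_phrase_pool()
  lines <- vapply(seq_len(config$messages_per_bct), function(i) {
    stream <- lehmer_stream(sprintf("mock|%d|%s|%d", config$seed, label, i))
    opener <- stream_pick(stream, c("Small steps count:", "Quick reminder:",
                                    "You've got this:", "Today's tip:",
                                    "A friendly note:", "Keep it up:"))
    body <- stream_pick(stream, pool)
    sprintf('"%s %s (%s, idea %d.)"', opener, body, tolower(label), i)
  }, character(1))
  paste(lines, collapse = "\n")
}

#' Deterministic offline chat backend
#'
#' @return A [chat_backend()] wrapping [mock_complete()]; token usage is
#'   reported as a deterministic word-count proxy.
#' @export
mock_chat_backend <- function() {
  chat_backend("mock", function(system_text, user_text, config) {
    text <- mock_complete(system_text, user_text, config)
    tokens <- length(strsplit(paste(system_text, user_text, text), "\\s+")[[1]])
    list(text = text, tokens = tokens)
  })
}

#' Post-process a raw assistant response into discrete messages
#'
#' Splits on line breaks (collapsing blank lines), strips surrounding
#' straight/curly quotation marks, optionally strips leading list numbering
#' ("1. ", "2) ", "-", "*"), and trims whitespace.
#'
#' @param raw raw assistant text.
#' @param strip_numbering drop leading list markers (default `TRUE`).
#' @return Character vector of message texts, in response order.
#' @export
postprocess_response <- function(raw, strip_numbering = TRUE) {
  if (!is_string(raw) || !nzchar(raw)) {
    abort("Empty assistant response", class = "bctmsg_empty_response_error")
  }
  lines <- strsplit(raw, "\r?\n")[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (strip_numbering) {
    lines <- sub("^(\\d+[.)]\\s*|[-*]\\s+)", "", lines)
  }
  # surrounding quotation marks: straight " ' and curly variants
  lines <- stringi::stri_replace_all_regex(
    lines, "^[\"'“”‘’]+|[\"'“”‘’]+$", ""
  )
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    abort("Assistant response contained no messages after post-processing",
          class = "bctmsg_empty_response_error")
  }
  lines
}

new_message_bank <- function(messages, provenance = list(), token_usage = NULL) {
  messages <- tibble::as_tibble(messages)
  stopifnot(all(c("bct_number", "bct_label", "message_index", "text") %in%
                  names(messages)))
  key <- paste(messages$bct_number, messages$message_index)
  if (anyDuplicated(key)) {
    abort("Duplicate (bct_number, message_index) pairs in message bank",
          class = "bctmsg_validation_error")
  }
  structure(messages, provenance = provenance, token_usage = token_usage,
            class = c("message_bank", class(tibble::tibble())))
}

#' Assemble a message bank from a data frame
#'
#' @param messages data frame with columns `bct_number`, `bct_label`,
#'   `message_index`, `text`.
#' @param provenance named list of backend/model/config metadata.
#' @param token_usage optional tibble of per-BCT token counts.
#' @return A `message_bank` (tibble subclass).
#' @export
message_bank <- function(messages, provenance = list(), token_usage = NULL) {
  messages <- tibble::as_tibble(messages)
  messages$bct_number <- as.character(messages$bct_number)
  messages$bct_label <- as.character(messages$bct_label)
  messages$message_index <- as.integer(messages$message_index)
  messages$text <- as.character(messages$text)
  new_message_bank(messages, provenance, token_usage)
}

#' Generate a message bank over a whole BCT database
#'
#' One single-prompt, two-role chat call per technique (no conversation
#' history accumulates across techniques); the assistant response is
#' post-processed into discrete messages tagged with the technique. When a
#' backend returns a different number of messages than requested a warning is
#' logged and the actual count is recorded; a technique whose call fails
#' after retries, or yields zero usable messages, is recorded as a per-BCT
#' failure and the run continues.
#'
#' @param db a [bct_database()].
#' @param backend a [chat_backend()] (default [mock_chat_backend()]).
#' @param config a [generation_config()].
#' @param templates a [prompt_templates()] object.
#' @param max_attempts transport-level retry attempts per technique
#'   (default 3, exponential backoff).
#' @return A [message_bank()] whose `provenance` attribute records backend,
#'   model, temperature, per-BCT counts and failures, and whose
#'   `token_usage` attribute holds per-BCT token counts when reported.
#' @export
generate_bank <- function(db, backend = mock_chat_backend(),
                          config = generation_config(),
                          templates = default_prompt_templates(),
                          max_attempts = 3L) {
  pairs <- render_batch(db, templates)
  tbl <- tibble::as_tibble(db)
  rows <- list()
  usage <- list()
  counts <- list()
  failures <- character()
  for (i in seq_len(nrow(pairs))) {
    num <- pairs$bct_number[i]
    lab <- tbl$label[tbl$number == num][1]
    res <- NULL
    for (attempt in seq_len(max_attempts)) {
      res <- tryCatch(backend$complete(pairs$system[i], pairs$user[i], config),
                      error = function(e) e)
      if (!inherits(res, "error")) break
      if (attempt < max_attempts) Sys.sleep(min(2^(attempt - 1) * 0.1, 2))
    }
    if (inherits(res, "error")) {
      warn(sprintf("BCT %s: backend failed after %d attempts (%s); skipping",
                   num, max_attempts, conditionMessage(res)))
      failures <- c(failures, num)
      next
    }
    texts <- tryCatch(postprocess_response(res$text), error = function(e) character())
    if (!length(texts)) {
      warn(sprintf("BCT %s: zero usable messages; recorded as failure", num))
      failures <- c(failures, num)
      next
    }
    if (length(texts) != config$messages_per_bct) {
      warn(sprintf("BCT %s: backend returned %d messages, expected %d",
                   num, length(texts), config$messages_per_bct))
    }
    counts[[num]] <- length(texts)
    rows[[num]] <- tibble::tibble(bct_number = num, bct_label = lab,
                                  message_index = seq_along(texts),
                                  text = texts)
    if (!is.null(res$tokens)) {
      usage[[num]] <- tibble::tibble(bct_number = num,
                                     tokens = as.integer(res$tokens))
    }
  }
  messages <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(bct_number = character(), bct_label = character(),
                   message_index = integer(), text = character())
  }
  new_message_bank(
    messages,
    provenance = list(
      backend = backend$name, model = config$model_name,
      temperature = config$temperature,
      messages_per_bct = config$messages_per_bct, seed = config$seed,
      per_bct_counts = counts, failed_bcts = failures,
      n_bcts = nrow(tbl), n_messages = nrow(messages)
    ),
    token_usage = if (length(usage)) dplyr::bind_rows(usage) else NULL
  )
}

#' Read / write message banks
#'
#' CSV banks are RFC 4180 / UTF-8 with header
#' `bct_number,bct_label,message_index,text`; JSON banks are arrays of objects
#' with the same keys. [write_message_bank()] can also emit a provenance
#' sidecar JSON next to the bank.
#'
#' @param path bank file path (`.csv` or `.json`).
#' @return [read_message_bank()]: a [message_bank()].
#' @export
read_message_bank <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Message bank file not found: ", path), class = "bctmsg_io_error")
  }
  tbl <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(path, simplifyDataFrame = TRUE))
  } else {
    readr::read_csv(path, col_types = readr::cols(
      bct_number = readr::col_character(), bct_label = readr::col_character(),
      message_index = readr::col_integer(), text = readr::col_character()
    ), progress = FALSE)
  }
  missing <- setdiff(c("bct_number", "bct_label", "message_index", "text"),
                     names(tbl))
  if (length(missing)) {
    abort(paste0("Message bank is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "bctmsg_schema_error")
  }
  bad <- which(is.na(tbl$bct_number) | is.na(tbl$message_index) | is.na(tbl$text))
  if (length(bad)) {
    abort(sprintf("Malformed message bank row(s) at line(s): %s",
                  paste(bad + 1L, collapse = ", ")),
          class = "bctmsg_schema_error")
  }
  message_bank(tbl, provenance = list(source = path))
}

#' @rdname read_message_bank
#' @param bank a [message_bank()].
#' @param sidecar if `TRUE`, also write `<path>.provenance.json` with the
#'   bank's provenance metadata and per-BCT token usage.
#' @return [write_message_bank()]: `path`, invisibly.
#' @export
write_message_bank <- function(bank, path, sidecar = FALSE) {
  tbl <- tibble::as_tibble(bank)[c("bct_number", "bct_label",
                                   "message_index", "text")]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tbl, path, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE)
  } else {
    readr::write_csv(tbl, path, na = "")
  }
  if (sidecar) {
    prov <- attr(bank, "provenance") %||% list()
    usage <- attr(bank, "token_usage")
    jsonlite::write_json(
      list(provenance = prov,
           token_usage = if (is.null(usage)) NULL else usage),
      paste0(path, ".provenance.json"),
      dataframe = "rows", auto_unbox = TRUE, pretty = TRUE, null = "null"
    )
  }
  invisible(path)
}

#' @export
print.message_bank <- function(x, ...) {
  prov <- attr(x, "provenance") %||% list()
  cat(sprintf("<message_bank> %d messages, %d techniques%s\n", nrow(x),
              length(unique(x$bct_number)),
              if (!is.null(prov$backend)) paste0(" (backend: ", prov$backend, ")")
              else ""))
  NextMethod()
}
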