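#' Attributed prompt templates
#'
#' The prompt pair sent for each technique is rendered from two plain-text
#' templates by token substitution. The system template establishes the
#' conversation (setting, style rules, BCT rules, task) and references only
#' `{bct_label}`; the user template carries the technique's database fields
#' through five attribute placeholders. Lines of the user template that
#' reference an optional attribute the entry lacks are omitted ("if
#' available" semantics), so an entry with no examples, constructs or
#' strategies renders to just the definition line and the closing line.
#'
#' @name prompting
NULL

PROMPT_ATTRS <- c("bct_label", "bct_definition", "bct_examples",
                  "bct_theoretical_constructs", "bct_behavioral_strategies")
PROMPT_OPTIONAL_ATTRS <- c("bct_examples", "bct_theoretical_constructs",
                           "bct_behavioral_strategies")

placeholders_in <- function(text) {
  m <- stringi::stri_match_all_regex(text, "\\{([a-z_]+)\\}")[[1]]
  if (all(is.na(m))) character() else unique(m[, 2])
}

#' Construct a prompt template pair from template texts
#'
#' @param system_template,user_template template texts; placeholders are
#'   `{bct_label}`, `{bct_definition}`, `{bct_examples}`,
#'   `{bct_theoretical_constructs}`, `{bct_behavioral_strategies}`.
#' @return A `prompt_templates` object.
#' @export
prompt_templates <- function(system_template, user_template) {
  stopifnot(is_string(system_template), is_string(user_template))
  unknown <- setdiff(
    c(placeholders_in(system_template), placeholders_in(user_template)),
    PROMPT_ATTRS
  )
  if (length(unknown)) {
    abort(paste0("Unknown placeholder(s) in template: ",
                 paste0("{", unknown, "}", collapse = ", ")),
          class = "bctmsg_template_error")
  }
  structure(list(system_template = system_template,
                 user_template = user_template),
            class = "prompt_templates")
}

read_template_file <- function(path) {
  txt <- readChar(path, file.info(path)$size, useBytes = TRUE)
  Encoding(txt) <- "UTF-8"
  sub("\n+$", "", gsub("\r\n", "\n", txt))
}

#' Load a prompt template pair from plain-text files
#'
#' @param system_path,user_path UTF-8 text files.
#' @return A [prompt_templates()] object.
#' @export
load_prompt_templates <- function(system_path, user_path) {
  for (p in c(system_path, user_path)) {
    if (!file.exists(p)) {
      abort(paste0("Template file not found: ", p), class = "bctmsg_io_error")
    }
  }
  prompt_templates(read_template_file(system_path), read_template_file(user_path))
}

#' Packaged default attributed templates
#'
#' The templates shipped with the package: an attributed system prompt (role
#' setting, style rules, BCT rules, and the 25-message task statement) and an
#' attributed user prompt (definition line, conditional examples /
#' theoretical-constructs / behavioral-strategies sections, closing line).
#'
#' @return A [prompt_templates()] object.
#' @export
default_prompt_templates <- function() {
  load_prompt_templates(
    system.file("templates", "system_prompt.txt", package = "bctmsg", mustWork = TRUE),
    system.file("templates", "user_prompt.txt", package = "bctmsg", mustWork = TRUE)
  )
}

# One database row as a named list of present attributes ({bct_label} is the
# Label field alone; the Number is carried separately for tagging).
entry_attrs <- function(entry) {
  entry <- as.list(entry)
  attrs <- list(
    bct_label = entry$label,
    bct_definition = entry$definition,
    bct_examples = entry$examples,
    bct_theoretical_constructs = entry$theoretical_constructs,
    bct_behavioral_strategies = entry$behavioral_strategies
  )
  attrs[!vapply(attrs, function(v) is.null(v) || is.na(v), logical(1))]
}

substitute_attrs <- function(text, attrs, where) {
  for (nm in names(attrs)) {
    text <- gsub(paste0("{", nm, "}"), attrs[[nm]], text, fixed = TRUE)
  }
  left <- placeholders_in(text)
  if (length(left)) {
    abort(sprintf("Cannot render %s prompt: entry has no value for attribute(s) %s",
                  where, paste(left, collapse = ", ")),
          class = "bctmsg_render_error")
  }
  text
}

#' Render the system prompt for one BCT entry
#'
#' Every `{bct_label}` occurrence is replaced by the entry's label; no other
#' transformation is applied (attribute text is never truncated or
#' re-wrapped).
#'
#' @param entry one BCT entry: a single-row [bct_database()] slice or a named
#'   list with fields `number`, `label`, `definition`, ...
#' @param templates a [prompt_templates()] object
#'   (default [default_prompt_templates()]).
#' @return The rendered system prompt text.
#' @export
build_system_prompt <- function(entry, templates = default_prompt_templates()) {
  substitute_attrs(templates$system_template, entry_attrs(entry), "system")
}

#' Render the attributed user prompt for one BCT entry
#'
#' Template lines that reference an optional attribute absent from the entry
#' are dropped, then runs of blank lines are collapsed to one (preserving the
#' two-line-break separator before the Theoretical Constructs block when that
#' block is rendered) before substitution.
#'
#' @inheritParams build_system_prompt
#' @return The rendered user prompt text.
#' @export
build_user_prompt <- function(entry, templates = default_prompt_templates()) {
  attrs <- entry_attrs(entry)
  lines <- strsplit(templates$user_template, "\n", fixed = TRUE)[[1]]
  blank <- !nzchar(trimws(lines))
  keep <- vapply(lines, function(line) {
    used <- placeholders_in(line)
    absent_optional <- setdiff(intersect(used, PROMPT_OPTIONAL_ATTRS), names(attrs))
    length(absent_optional) == 0L
  }, logical(1), USE.NAMES = FALSE)
  # a blank separator line belongs to the section below it: keep it only if
  # the nearest following non-blank line is kept
  for (i in which(blank)) {
    after <- which(!blank & seq_along(lines) > i)
    keep[i] <- length(after) > 0L && keep[after[1L]]
  }
  lines <- lines[keep]
  blank <- !nzchar(trimws(lines))
  lines <- lines[!(blank & c(TRUE, blank[-length(blank)]))] # collapse runs
  while (length(lines) && !nzchar(trimws(lines[1L]))) lines <- lines[-1L]
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  substitute_attrs(paste(lines, collapse = "\n"), attrs, "user")
}

#' Render prompt pairs for every entry of a database
#'
#' @param db a [bct_database()].
#' @param templates a [prompt_templates()] object.
#' @return A tibble with one row per entry, in database order: `bct_number`,
#'   `system`, `user`.
#' @export
render_batch <- function(db, templates = default_prompt_templates()) {
  tbl <- tibble::as_tibble(db)
  out <- vector("list", nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    entry <- tbl[i, ]
    pair <- tryCatch(
      list(system = build_system_prompt(entry, templates),
           user = build_user_prompt(entry, templates)),
      error = function(e) {
        abort(sprintf("While rendering BCT %s: %s", entry$number,
                      conditionMessage(e)),
              class = "bctmsg_render_error", parent = e)
      }
    )
    out[[i]] <- tibble::tibble(bct_number = entry$number,
                               system = pair$system, user = pair$user)
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(bct_number = character(), system = character(),
                   user = character())
  }
}

#' Export rendered prompt pairs as JSON records
#'
#' @param pairs the tibble returned by [render_batch()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prompt_pairs <- function(pairs, path) {
  jsonlite::write_json(pairs, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
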