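#' Behavior change technique (BCT) databases
#'
#' A BCT database is the structured table that drives attributed prompt
#' construction: one row per technique, six fields. `number` and `label` and
#' `definition` are required; `examples`, `theoretical_constructs` and
#' `behavioral_strategies` are optional (absent values are stored as `NA` and
#' their prompt sections are omitted at render time).
#'
#' @details
#' The six fields follow the BCT Taxonomy v1 convention: `number` is the
#' hierarchical identifier (e.g. `"1.2"`), `label` the technique name,
#' `definition` its text definition; `examples` carries illustrative uses,
#' while `theoretical_constructs` and `behavioral_strategies` record the
#' evidence-review mappings that ground each technique in theory.
#'
#' @name bct_database
NULL

BCT_FIELDS <- c(
  "number", "label", "definition",
  "examples", "theoretical_constructs", "behavioral_strategies"
)
BCT_REQUIRED <- c("number", "label", "definition")
BCT_NUMBER_RE <- "^[0-9]+\\.[0-9]+$"

new_bct_database <- function(entries, source = NA_character_) {
  stopifnot(is.data.frame(entries))
  entries <- tibble::as_tibble(entries)[BCT_FIELDS]
  structure(entries, source = source,
            class = c("bct_database", class(tibble::tibble())))
}

#' Construct a BCT database from a data frame
#'
#' @param entries data frame with columns `number`, `label`, `definition`,
#'   `examples`, `theoretical_constructs`, `behavioral_strategies` (optional
#'   columns may be missing and are filled with `NA`).
#' @param source provenance string stored as an attribute.
#' @param validate if `TRUE` (default) invariant violations raise an error.
#' @return A `bct_database` (a tibble subclass; row order is entry order).
#' @export
bct_database <- function(entries, source = "in-memory", validate = TRUE) {
  entries <- tibble::as_tibble(entries)
  missing_req <- setdiff(BCT_REQUIRED, names(entries))
  if (length(missing_req)) {
    abort(paste0("BCT database is missing required column(s): ",
                 paste(missing_req, collapse = ", ")),
          class = "bctmsg_schema_error")
  }
  for (f in setdiff(BCT_FIELDS, names(entries))) entries[[f]] <- NA_character_
  for (f in BCT_FIELDS) {
    entries[[f]] <- as.character(entries[[f]])
    # blank cells encode absence
    entries[[f]][!is.na(entries[[f]]) & trimws(entries[[f]]) == ""] <- NA_character_
  }
  db <- new_bct_database(entries, source = source)
  if (validate) {
    issues <- validate_database(db)
    if (nrow(issues)) {
      abort(paste0("Invalid BCT database:\n",
                   paste0("  - ", issues$message, collapse = "\n")),
            class = "bctmsg_validation_error")
    }
  }
  db
}

#' Load a BCT database from CSV or JSON
#'
#' CSV is RFC 4180 / UTF-8 with header
#' `number,label,definition,examples,theoretical_constructs,behavioral_strategies`;
#' JSON is an array of objects with the same keys. Blank cells / missing keys
#' become absent optional fields. Row order is preserved.
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`; default guessed from the file extension.
#' @return A [bct_database()].
#' @export
load_bct_database <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("BCT database file not found: ", path),
          class = "bctmsg_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  entries <- if (format == "csv") {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  } else {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(raw) == 0) {
      tibble::tibble(number = character(), label = character(),
                     definition = character())
    } else {
      tibble::as_tibble(raw)
    }
  }
  bct_database(entries, source = path)
}

#' Write a BCT database to CSV or JSON
#'
#' Inverse of [load_bct_database()]: `write` then `load` reproduces an equal
#' database in either format.
#'
#' @param db a `bct_database`.
#' @param path output file path.
#' @param format `"auto"` (from extension), `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_bct_database <- function(db, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  tbl <- tibble::as_tibble(db)[BCT_FIELDS]
  if (format == "csv") {
    readr::write_csv(tbl, path, na = "")
  } else {
    jsonlite::write_json(tbl, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Check BCT database invariants
#'
#' Returns issues as data rather than raising: one row per violated invariant
#' (zero rows iff the database is clean). Checked invariants: `number` matches
#' `digits.digits`; `label` and `definition` non-empty; optional fields absent
#' or non-empty; numbers unique.
#'
#' @param db a `bct_database` (or coercible data frame).
#' @return tibble with columns `number`, `field`, `rule`, `message`.
#' @export
validate_database <- function(db) {
  tbl <- tibble::as_tibble(db)
  issues <- list()
  add <- function(number, field, rule, message) {
    issues[[length(issues) + 1L]] <<-
      tibble::tibble(number = number, field = field, rule = rule,
                     message = message)
  }
  for (i in seq_len(nrow(tbl))) {
    num <- tbl$number[i]
    if (is.na(num) || !grepl(BCT_NUMBER_RE, num)) {
      add(num %||% NA_character_, "number", "number_pattern",
          sprintf("row %d: number %s does not match the digits.digits pattern",
                  i, if (is.na(num)) "<missing>" else dQuote(num, '"')))
    }
    for (f in c("label", "definition")) {
      v <- tbl[[f]][i]
      if (is.na(v) || !nzchar(trimws(v))) {
        add(num, f, "required_nonempty",
            sprintf("row %d (%s): required field '%s' is empty", i, num, f))
      }
    }
    for (f in setdiff(BCT_FIELDS, BCT_REQUIRED)) {
      v <- tbl[[f]][i]
      if (!is.na(v) && !nzchar(trimws(v))) {
        add(num, f, "optional_absent_or_nonempty",
            sprintf("row %d (%s): optional field '%s' is an empty string", i, num, f))
      }
    }
  }
  dup <- unique(tbl$number[duplicated(tbl$number)])
  dup <- dup[!is.na(dup)]
  for (d in dup) {
    add(d, "number", "unique_numbers",
        sprintf("number \"%s\" appears %d times", d, sum(tbl$number == d)))
  }
  if (length(issues)) dplyr::bind_rows(issues) else {
    tibble::tibble(number = character(), field = character(),
                   rule = character(), message = character())
  }
}

#' Packaged 46-technique BCT database fixture
#'
#' Loads the database shipped with the package: the 46 techniques selected for
#' medication-adherence messaging. This fixture is a synthetic reconstruction
#' (see the file `bct_database_synthetic.csv`): the numbers, labels and
#' definitions follow BCT Taxonomy v1 wording, while the theoretical-construct
#' and behavioral-strategy mappings are illustrative stand-ins for the
#' evidence-review mappings, suitable for pipeline development and testing.
#'
#' @return A [bct_database()] with 46 entries.
#' @export
bct_database_fixture <- function() {
  load_bct_database(
    system.file("extdata", "bct_database_synthetic.csv", package = "bctmsg",
                mustWork = TRUE),
    format = "csv"
  )
}

#' @export
print.bct_database <- function(x, ...) {
  cat(sprintf("<bct_database> %d techniques (source: %s)\n",
              nrow(x), attr(x, "source") %||% "unknown"))
  NextMethod()
}
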