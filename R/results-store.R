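# Named append-only tables plus a key/value variable store, persisted to
# disk between tile steps and between runs. Per-tile processors are
# independent of each other; the store is the only channel through which
# they accumulate whole-slide state.

#' Create a results store
#'
#' A results store holds named append-only tables (one row per processed
#' tile or slide, in append order) and a key/value variable store for
#' scalars and ordered numeric/character vectors. The store has reference
#' semantics: processors mutate the store they are handed, and the engine
#' persists it at the end of each slide.
#'
#' On disk, each table is one RFC 4180 CSV file `<table>.csv` under `root`
#' (header = union of row keys in first-seen order; missing cells empty;
#' numbers printed with 17 significant digits so doubles round-trip
#' exactly), and variables live in one `variables.json` sidecar. Table
#' names are percent-encoded to file-name-safe form; the encoding is
#' invertible.
#'
#' @param root Folder used by [save_store()] / [load_store()]; created on
#'   first save.
#' @return An object of class `results_store`.
#' @examples
#' st <- results_store(tempfile())
#' append_row(st, "tiles", list(x = 0, y = 0, blue_area = 41))
#' get_table(st, "tiles")
#' @export
results_store <- function(root = NULL) {
  env <- new.env(parent = emptyenv())
  env$tables <- list()   # name -> list(rows = list of named lists, cols = chr)
  env$vars <- list()
  env$root <- root
  structure(list(env = env), class = "results_store")
}

#' @export
print.results_store <- function(x, ...) {
  tb <- x$env$tables
  cat("Results store")
  if (!is.null(x$env$root)) cat(" @", x$env$root)
  cat("\n")
  if (length(tb))
    for (nm in names(tb))
      cat(sprintf("  table '%s': %d rows\n", nm, length(tb[[nm]]$rows)))
  else cat("  (no tables)\n")
  if (length(x$env$vars))
    cat("  variables:", paste(names(x$env$vars), collapse = ", "), "\n")
  invisible(x)
}

#' Append one row to a named table
#'
#' The table is created on first use; several independently named tables
#' can coexist in one store. Appending never alters earlier rows.
#'
#' @param store A [results_store()].
#' @param table Table name (non-empty string).
#' @param row Named list of cells (numbers or strings); non-empty.
#' @return The store, invisibly (mutated in place).
#' @export
append_row <- function(store, table, row) {
  .check_store(store)
  if (!is.character(table) || length(table) != 1L || !nzchar(table))
    st_parameter_error("table name must be a non-empty string")
  if (!is.list(row) || !length(row) || is.null(names(row)) || any(!nzchar(names(row))))
    st_parameter_error("row must be a non-empty named list")
  tb <- store$env$tables[[table]]
  if (is.null(tb)) tb <- list(rows = list(), cols = character(0))
  tb$cols <- union(tb$cols, names(row))
  tb$rows[[length(tb$rows) + 1L]] <- row
  store$env$tables[[table]] <- tb
  invisible(store)
}

#' Materialize a named table as a data frame
#'
#' @param store A [results_store()].
#' @param table Table name.
#' @return Data frame with rows in append order and columns in first-seen
#'   order; cells absent from a row are `NA`.
#' @export
get_table <- function(store, table) {
  .check_store(store)
  tb <- store$env$tables[[table]]
  if (is.null(tb)) st_no_data("no table named '%s' in the results store", table)
  .rows_to_df(tb$rows, tb$cols)
}

#' @rdname get_table
#' @export
table_names <- function(store) {
  .check_store(store)
  names(store$env$tables)
}

.rows_to_df <- function(rows, cols) {
  out <- lapply(cols, function(cn) {
    vals <- lapply(rows, function(r) if (is.null(r[[cn]])) NA else r[[cn]])
    if (all(vapply(vals, function(v) is.numeric(v) || all(is.na(v)), TRUE)))
      vapply(vals, function(v) as.numeric(v)[1], 0)
    else
      vapply(vals, function(v) as.character(v)[1], "")
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE,
                optional = TRUE)
}

#' Store and retrieve variables between tile steps
#'
#' Variables hold scalars or ordered vectors that must survive between the
#' otherwise independent per-tile invocations (running totals, flags,
#' arrays), and across save/load.
#'
#' @param store A [results_store()].
#' @param name Variable name (non-empty string).
#' @param value Scalar or vector (numeric or character).
#' @return `set_var` returns the store invisibly; `get_var` the stored
#'   value; `has_var` a logical.
#' @export
set_var <- function(store, name, value) {
  .check_store(store)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    st_parameter_error("variable name must be a non-empty string")
  store$env$vars[[name]] <- value
  invisible(store)
}

#' @rdname set_var
#' @export
get_var <- function(store, name) {
  .check_store(store)
  if (!name %in% names(store$env$vars))
    st_missing_key("no variable named '%s' in the results store", name)
  store$env$vars[[name]]
}

#' @rdname set_var
#' @export
has_var <- function(store, name) {
  .check_store(store)
  name %in% names(store$env$vars)
}

# Invertible file-name-safe escaping for table names: every byte outside
# [A-Za-z0-9._-] (and '%' itself) becomes %XX.
sanitize_table_name <- function(name) {
  b <- as.integer(charToRaw(enc2utf8(name)))
  ok <- (b >= 0x30 & b <= 0x39) | (b >= 0x41 & b <= 0x5A) |
    (b >= 0x61 & b <= 0x7A) | b %in% c(0x2E, 0x5F, 0x2D)
  paste(ifelse(ok, vapply(b, function(x) rawToChar(as.raw(x)), ""),
               sprintf("%%%02X", b)), collapse = "")
}

unsanitize_table_name <- function(fname) {
  out <- utils::URLdecode(fname)
  Encoding(out) <- "UTF-8"
  out
}

#' Persist a results store / load one from disk
#'
#' @param store A [results_store()] with a `root` folder set (or `root`
#'   given here).
#' @param root Persistence folder.
#' @return `save_store` returns the store invisibly; `load_store` a new
#'   [results_store()] observationally equal to the one saved.
#' @export
save_store <- function(store, root = NULL) {
  .check_store(store)
  if (is.null(root)) root <- store$env$root
  if (is.null(root)) st_parameter_error("no persistence folder set for this store")
  if (!dir.exists(root) && !dir.create(root, recursive = TRUE, showWarnings = FALSE))
    st_io_error("cannot create results folder '%s'", root)
  for (nm in names(store$env$tables)) {
    tb <- store$env$tables[[nm]]
    df <- .rows_to_df(tb$rows, tb$cols)
    path <- file.path(root, paste0(sanitize_table_name(nm), ".csv"))
    .write_csv_rfc4180(df, path)
  }
  if (length(store$env$vars))
    jsonlite::write_json(store$env$vars, file.path(root, "variables.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(store)
}

#' @rdname save_store
#' @export
load_store <- function(root) {
  if (!dir.exists(root)) st_not_found("results folder not found: '%s'", root)
  store <- results_store(root)
  for (f in sort(list.files(root, pattern = "\\.csv$"))) {
    nm <- unsanitize_table_name(sub("\\.csv$", "", f))
    df <- utils::read.csv(file.path(root, f), check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "")
    rows <- lapply(seq_len(nrow(df)), function(i) {
      r <- as.list(df[i, , drop = FALSE])
      r[!vapply(r, function(v) length(v) == 1 && is.na(v), TRUE)]
    })
    store$env$tables[[nm]] <- list(rows = rows, cols = names(df))
  }
  vpath <- file.path(root, "variables.json")
  if (file.exists(vpath))
    store$env$vars <- jsonlite::read_json(vpath, simplifyVector = TRUE)
  store
}

# RFC 4180 CSV: comma separator, CRLF-agnostic, fields quoted only when
# they contain comma, quote or newline; embedded quotes doubled. Doubles
# are printed at 17 significant digits for lossless round trips.
.write_csv_rfc4180 <- function(df, path) {
  fmt_cell <- function(v) {
    if (length(v) != 1 || is.na(v)) return("")
    s <- if (is.numeric(v)) {
      if (is.finite(v) && v == floor(v) && abs(v) < 2^53) sprintf("%.0f", v)
      else sprintf("%.17g", v)
    } else as.character(v)
    if (grepl('[",\n\r]', s)) s <- paste0('"', gsub('"', '""', s), '"')
    s
  }
  header <- paste(vapply(names(df), fmt_cell, ""), collapse = ",")
  lines <- vapply(seq_len(nrow(df)), function(i)
    paste(vapply(seq_along(df), function(j) fmt_cell(df[[j]][i]), ""),
          collapse = ","), "")
  writeLines(c(header, lines), path)
}

.check_store <- function(store) {
  if (!inherits(store, "results_store"))
    st_parameter_error("expected a results_store object")
  invisible(TRUE)
}
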