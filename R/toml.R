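# Minimal TOML-subset reader/writer.
#
# No TOML parser ships with the supported R stack, so configuration files use
# a deliberately small subset of TOML: `[table]` and `[table.sub]` headers,
# `key = value` pairs with numbers, booleans, double-quoted strings and flat
# arrays of those.  Comments (#) and blank lines are ignored.  This is enough
# for parameter files, drive protocols and scene recipes; anything outside
# the subset is rejected loudly rather than guessed at.

toml_parse_value <- function(s, path, lineno) {
  s <- trimws(s)
  if (s == "") stop(path, ":", lineno, ": empty value")
  if (s == "true") return(TRUE)
  if (s == "false") return(FALSE)
  if (startsWith(s, "[")) {
    if (!endsWith(s, "]")) stop(path, ":", lineno, ": unterminated array")
    inner <- trimws(substr(s, 2, nchar(s) - 1))
    if (inner == "") return(numeric(0))
    parts <- strsplit(inner, ",")[[1]]
    vals <- lapply(parts, toml_parse_value, path = path, lineno = lineno)
    return(unlist(vals, use.names = FALSE))
  }
  if (startsWith(s, "\"")) {
    if (nchar(s) < 2 || !endsWith(s, "\""))
      stop(path, ":", lineno, ": unterminated string")
    return(substr(s, 2, nchar(s) - 1))
  }
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop(path, ":", lineno, ": cannot parse value '", s, "'")
  v
}

#' Read a TOML-subset configuration file
#'
#' Parses the flat TOML subset used by this package (tables, scalar and array
#' values).  Returns a named list; tables become nested lists.
#'
#' @param path file path.
#' @return nested named list.
#' @export
read_toml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  table <- NULL
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[i]])
    line <- trimws(line)
    if (line == "") next
    if (startsWith(line, "[")) {
      if (!endsWith(line, "]"))
        stop(path, ":", i, ": malformed table header")
      table <- strsplit(substr(line, 2, nchar(line) - 1), ".", fixed = TRUE)[[1]]
      if (length(table) > 2)
        stop(path, ":", i, ": tables nested deeper than 2 are not supported")
      next
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0) stop(path, ":", i, ": expected 'key = value'")
    key <- trimws(substr(line, 1, eq - 1))
    if (key == "") stop(path, ":", i, ": empty key")
    val <- toml_parse_value(substr(line, eq + 1, nchar(line)), path, i)
    if (is.null(table)) {
      out[[key]] <- val
    } else {
      node <- out
      for (k in table) {
        if (is.null(node[[k]])) node[[k]] <- list()
        node <- node[[k]]
      }
      node[[key]] <- val
      # write back along the (at most 2-deep) table path
      if (length(table) == 1L) out[[table]] <- node
      else {
        parent <- out[[table[1]]]
        if (is.null(parent)) parent <- list()
        parent[[table[2]]] <- node
        out[[table[1]]] <- parent
      }
    }
  }
  out
}

toml_format_value <- function(v) {
  if (is.logical(v)) return(if (v) "true" else "false")
  if (is.character(v)) return(paste0("\"", v, "\""))
  if (is.numeric(v)) {
    s <- vapply(v, function(x) format(x, digits = 17, scientific = FALSE,
                                      trim = TRUE), character(1))
    if (length(v) == 1L) return(s)
    return(paste0("[", paste(s, collapse = ", "), "]"))
  }
  stop("cannot serialize value of class ", paste(class(v), collapse = "/"))
}

#' Write a nested list as TOML
#'
#' Inverse of [read_toml()] for the supported subset: top-level scalar/array
#' entries first, then one `[table]` per top-level list entry (one level of
#' nesting).
#'
#' @param x named list.
#' @param path output path.
#' @export
write_toml <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)))
  con <- file(path, "w")
  on.exit(close(con))
  is_tab <- vapply(x, is.list, logical(1))
  for (k in names(x)[!is_tab])
    writeLines(paste0(k, " = ", toml_format_value(x[[k]])), con)
  for (k in names(x)[is_tab]) {
    writeLines(paste0("[", k, "]"), con)
    tab <- x[[k]]
    for (kk in names(tab))
      writeLines(paste0(kk, " = ", toml_format_value(tab[[kk]])), con)
    writeLines("", con)
  }
  invisible(path)
}

# Flatten one level of tables into a single named list of leaf values.
flatten_toml <- function(kv) {
  out <- list()
  for (k in names(kv)) {
    v <- kv[[k]]
    if (is.list(v)) out[names(v)] <- v else out[[k]] <- v
  }
  out
}
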