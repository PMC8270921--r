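# Flat key-value norm files.
#
# Format: one `key = value` pair per line, keys a_uXv (8) and b_uv (4),
# values decimal in [0,1]; '#' starts a comment. Preset names (L1..L8, SS)
# are accepted wherever a file path is.

#' Write a norm table to a key-value text file
#'
#' @param table a [norm_table()] (or anything [as_norm_table()] accepts).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_norm <- function(table, path) {
  table <- as_norm_table(table)
  lines <- c(
    if (!is.null(table$name)) paste0("# norm: ", table$name),
    sprintf("%s = %.17g", names(table$assessment), table$assessment),
    sprintf("%s = %.17g", names(table$behaviour), table$behaviour)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a norm table from a key-value text file or preset name
#'
#' @param path a file path, or a preset name (`"L1"`..`"L8"`, `"SS"`).
#' @return a [norm_table()].
#' @export
read_norm <- function(path) {
  if (path %in% c(names(LEADING_EIGHT), "SS")) return(leading_eight(path))
  if (!file.exists(path)) {
    stop("'", path, "' is neither a preset name nor an existing file",
         call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(parts) != 2
  if (any(bad)) stop("malformed line(s): ", paste(lines[bad], collapse = "; "),
                     call. = FALSE)
  keys <- vapply(parts, `[[`, "", 1)
  vals <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  if (anyNA(vals)) stop("non-numeric value in norm file", call. = FALSE)
  names(vals) <- keys
  missing_a <- setdiff(ALPHA_KEYS, keys)
  missing_b <- setdiff(BETA_KEYS, keys)
  if (length(missing_a) || length(missing_b)) {
    stop("norm file is missing keys: ",
         paste(c(missing_a, missing_b), collapse = ", "), call. = FALSE)
  }
  norm_table(vals[ALPHA_KEYS], vals[BETA_KEYS],
             name = sub("\\.[^.]*$", "", basename(path)))
}
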