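# Filament particle-table I/O: a plain TSV dialect and an equivalent
# STAR-style loop dialect (hand-parsed; the loop subset used by picking
# tools is a header of `_tag` lines followed by whitespace-separated rows).

#' Read a particle table
#'
#' Required columns: `filament_id`, `arc_nm`, `x_nm`, `y_nm`, `z_nm`,
#' `tilt_deg`, `psi_deg`; `class` is optional. Rows arriving unsorted in
#' arc position are re-sorted within each filament with a warning.
#'
#' @param path path to a TSV or STAR-style file.
#' @param format `"auto"` (sniffed), `"tsv"` or `"star"`.
#' @return A [particle_table].
#' @export
read_particle_table <- function(path, format = c("auto", "tsv", "star")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 20L, warn = FALSE)
    format <- if (any(grepl("^\\s*loop_", first))) "star" else "tsv"
  }
  if (format == "tsv") {
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                     check.names = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    i <- grep("^\\s*loop_\\s*$", lines)
    if (!length(i)) stop("no loop_ block in STAR file ", path, call. = FALSE)
    j <- i[1] + 1L
    tags <- character()
    while (j <= length(lines) && grepl("^\\s*_", lines[j])) {
      tags <- c(tags, sub("^\\s*_(\\S+).*$", "\\1", lines[j]))
      j <- j + 1L
    }
    rows <- lines[j:length(lines)]
    rows <- rows[nzchar(trimws(rows))]
    rows <- rows[!grepl("^\\s*(#|data_)", rows)]
    fields <- strsplit(trimws(rows), "\\s+")
    bad <- which(lengths(fields) != length(tags))
    if (length(bad))
      stop("STAR row ", bad[1], " has ", lengths(fields)[bad[1]],
           " fields, expected ", length(tags), call. = FALSE)
    df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
    names(df) <- tags
    num <- setdiff(names(df), c("filament_id", "class"))
    df[num] <- lapply(df[num], as.numeric)
  }
  miss <- setdiff(particle_cols, names(df))
  if (length(miss))
    stop("particle table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  particle_table(df)
}

#' Write a particle table
#'
#' TSV output is text-exact on round-trip (values formatted with
#' `format(..., digits = 15)`); the STAR-style dialect writes the same
#' columns as a single `loop_` block with `_column` tags.
#'
#' @param table a [particle_table].
#' @param path output path.
#' @param format `"tsv"` or `"star"`.
#' @return Invisibly, `path`.
#' @export
write_particle_table <- function(table, path, format = c("tsv", "star")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "particle_table"))
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  if (format == "tsv") {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("data_particles", "", "loop_",
                 paste0("_", names(df), sprintf(" #%d", seq_along(df)))), con)
    writeLines(do.call(paste, c(unname(df), sep = " ")), con)
  }
  invisible(path)
}
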