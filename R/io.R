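# Plain-text I/O: CSV tables with ISO-8601 timestamps and P2 (ASCII) PGM
# image frames with a CSV timestamp manifest.

#' Write a data frame as CSV with ISO-8601 timestamps
#'
#' @param df data frame; POSIXct columns are serialized as
#'   `YYYY-MM-DDTHH:MM:SSZ` (UTC).
#' @param path output file.
#' @export
write_table_csv <- function(df, path) {
  for (nm in names(df)) {
    if (inherits(df[[nm]], "POSIXct"))
      df[[nm]] <- format(df[[nm]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_table_csv()]
#'
#' @param path input file.
#' @param timestamp_cols columns to parse as POSIXct (default any column
#'   named `timestamp`, `start` or `end`).
#' @param date_cols columns to parse as Date (default `date`).
#' @return data frame.
#' @export
read_table_csv <- function(path, timestamp_cols = c("timestamp", "start", "end"),
                           date_cols = "date") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in intersect(timestamp_cols, names(df)))
    df[[nm]] <- as.POSIXct(df[[nm]], format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  for (nm in intersect(date_cols, names(df)))
    df[[nm]] <- as.Date(df[[nm]])
  df
}

#' Write an image stack as ASCII PGM frames plus a CSV manifest
#'
#' Each frame becomes `frame_0001.pgm`, ... (plain-text P2, maxval 255) and
#' `manifest.csv` records frame file names and timestamps. A plain-text
#' format is used so stacks stay human-inspectable and diff-able.
#'
#' @param stack an [image_stack()].
#' @param dir output directory (created if needed).
#' @export
write_stack_pgm <- function(stack, dir) {
  stopifnot(inherits(stack, "image_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("frame_%04d.pgm", seq_along(stack$frames))
  for (i in seq_along(stack$frames)) {
    m <- stack$frames[[i]]
    con <- file(file.path(dir, files[i]), "w")
    writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
    write(t(m), con, ncolumns = ncol(m))
    close(con)
  }
  write_table_csv(data.frame(file = files, timestamp = stack$timestamps),
                  file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Read an image stack written by [write_stack_pgm()]
#'
#' @param dir directory holding `frame_*.pgm` and `manifest.csv`.
#' @param sample_id label for the stack.
#' @return an [image_stack()].
#' @export
read_stack_pgm <- function(dir, sample_id = basename(dir)) {
  manifest <- read_table_csv(file.path(dir, "manifest.csv"))
  frames <- lapply(manifest$file, function(f) {
    lines <- readLines(file.path(dir, f))
    if (lines[1] != "P2") stop_domain("%s: only ASCII (P2) PGM is supported", f)
    dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
    vals <- as.integer(unlist(strsplit(trimws(lines[-(1:3)]), "\\s+")))
    matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
  })
  image_stack(frames, manifest$timestamp, sample_id = sample_id)
}
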