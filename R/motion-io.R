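# `.mot`/`.sto` motion tables and read-only `.trc` marker files.
# Header dialect: free-form name line(s), `key=value` lines including nRows,
# nColumns and inDegrees, then `endheader` and a tab/space separated block
# whose first column is time.

#' Read a `.mot`/`.sto` motion table
#'
#' @param path file path.
#' @return a [motion_table()]. The declared `nRows`/`nColumns` must match the
#'   data block and time must be strictly increasing; otherwise a format
#'   error is raised.
#' @export
read_motion <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- match(TRUE, trimws(lines) == "endheader")
  if (is.na(end)) stop("'", path, "': no endheader line", call. = FALSE)
  header <- lines[seq_len(end - 1)]
  kv <- regmatches(header, regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", header))
  keys <- list()
  for (m in kv) if (length(m) == 3) keys[[tolower(m[2])]] <- trimws(m[3])
  name <- if (length(header) > 0 && !grepl("=", header[1])) trimws(header[1]) else "motion"
  body <- lines[(end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  cols <- strsplit(trimws(body[1]), "[\t ]+")[[1]]
  dat <- utils::read.table(text = paste(body[-1], collapse = "\n"),
                           col.names = cols, check.names = FALSE)
  if (!is.null(keys$nrows) && as.integer(keys$nrows) != nrow(dat))
    stop("'", path, "': header declares nRows=", keys$nrows,
         " but data block has ", nrow(dat), " rows", call. = FALSE)
  if (!is.null(keys$ncolumns) && as.integer(keys$ncolumns) != ncol(dat))
    stop("'", path, "': header declares nColumns=", keys$ncolumns,
         " but data block has ", ncol(dat), " columns", call. = FALSE)
  if (cols[1] != "time")
    stop("'", path, "': first column must be 'time'", call. = FALSE)
  vals <- as.matrix(dat[, -1, drop = FALSE])
  motion_table(time = dat[[1]], values = vals,
               in_degrees = identical(tolower(keys$indegrees %||% "yes"), "yes"),
               name = name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a `.mot`/`.sto` motion table
#'
#' Values are written with 10 significant digits, so a round trip through
#' [read_motion()] reproduces the table well beyond the 6-significant-digit
#' contract.
#'
#' @param table a [motion_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motion <- function(table, path) {
  stopifnot(inherits(table, "motion_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(table$name,
               "version=1",
               paste0("nRows=", nrow(table$values)),
               paste0("nColumns=", ncol(table$values) + 1L),
               paste0("inDegrees=", if (table$in_degrees) "yes" else "no"),
               "endheader",
               paste(c("time", colnames(table$values)), collapse = "\t")), con)
  block <- cbind(table$time, table$values)
  writeLines(apply(block, 1, function(r)
    paste(sprintf("%.10g", r), collapse = "\t")), con)
  invisible(path)
}

#' Read a `.trc` marker trajectory file (read-only)
#'
#' Markers are flattened into columns named `<marker>_x/_y/_z` in the file's
#' length units.
#'
#' @param path file path.
#' @return a [motion_table()] with `in_degrees = FALSE`.
#' @export
read_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop("'", path, "': truncated trc file", call. = FALSE)
  hdr <- strsplit(lines[4], "\t")[[1]]
  markers <- hdr[-(1:2)]
  markers <- markers[nzchar(trimws(markers))]
  body <- lines[-(1:5)]
  body <- body[nzchar(trimws(body))]
  dat <- utils::read.table(text = paste(body, collapse = "\n"), sep = "\t",
                           fill = TRUE)
  nm <- length(markers)
  if (ncol(dat) < 2 + 3 * nm)
    stop("'", path, "': fewer data columns than 3 x markers", call. = FALSE)
  vals <- as.matrix(dat[, 3:(2 + 3 * nm), drop = FALSE])
  colnames(vals) <- as.vector(t(outer(markers, c("_x", "_y", "_z"), paste0)))
  motion_table(time = dat[[2]], values = vals, in_degrees = FALSE,
               name = "markers")
}
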