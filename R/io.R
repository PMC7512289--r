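# Trajectory tables and their delimited-text representation.
#
# The model consumes generic multivariate time series: one row per frame,
# one numeric column per degree of freedom, plus an assignment of columns
# to body parts.  Motion-capture container formats are out of scope; joint
# angles exported to CSV/TSV are just numeric columns here.

#' A set of observed trajectories with a column-to-part map
#'
#' @param sequences list of numeric matrices, one per trial, all with the
#'   same column count.
#' @param column_map integer vector assigning each column to a part
#'   (1-based), or a specification string such as \code{"0:0-9,1:10-19"}
#'   using 0-based part and column indices (\code{part:first-last}).
#' @param rate optional sampling rate metadata (frames per second).
#' @return object of class \code{"trajectory_set"}.
#' @export
trajectory_set <- function(sequences, column_map, rate = NULL) {
  if (!is.list(sequences) || length(sequences) < 1L) {
    stop("sequences must be a non-empty list of matrices")
  }
  sequences <- lapply(sequences, as.matrix)
  D <- ncol(sequences[[1]])
  for (s in sequences) {
    if (ncol(s) != D) stop("all sequences must share the same column count")
    if (nrow(s) < 1L) stop("sequences must have at least one row")
    if (!is.numeric(s)) stop("sequences must be numeric")
  }
  if (is.character(column_map)) column_map <- parse_column_map(column_map, D)
  column_map <- as.integer(column_map)
  if (length(column_map) != D) {
    stop("column_map must assign every observed column to a part")
  }
  parts <- sort(unique(column_map))
  if (!identical(parts, seq_along(parts))) {
    stop("column_map parts must be consecutive integers starting at 1")
  }
  structure(list(sequences = sequences, column_map = column_map, rate = rate),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("trajectory_set: %d sequence(s), %d columns, %d part(s)\n",
              length(x$sequences), length(x$column_map),
              length(unique(x$column_map))))
  cat("  lengths:", vapply(x$sequences, nrow, numeric(1)), "\n")
  invisible(x)
}

#' Parse a column-map specification string
#'
#' Parses \code{"part:first-last"} groups separated by commas, with
#' 0-based part and column indices, e.g. \code{"0:0-1,1:2-3"} maps columns
#' 1-2 to part 1 and columns 3-4 to part 2.
#'
#' @param spec specification string.
#' @param D total number of observed columns.
#' @return integer vector of 1-based part indices, one per column.
#' @export
parse_column_map <- function(spec, D) {
  map <- rep(NA_integer_, D)
  for (grp in strsplit(spec, ",", fixed = TRUE)[[1]]) {
    m <- regmatches(grp, regexec("^\\s*(\\d+)\\s*:\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", grp))[[1]]
    if (length(m) != 4) stop("malformed column map group: '", grp, "'")
    part <- as.integer(m[2]) + 1L
    cols <- (as.integer(m[3]):as.integer(m[4])) + 1L
    if (any(cols > D)) stop("column map refers to column beyond the data")
    if (any(!is.na(map[cols]))) stop("column map assigns a column twice")
    map[cols] <- part
  }
  if (anyNA(map)) stop("column map leaves some columns unassigned")
  map
}

.detect_sep <- function(line) {
  if (grepl(",", line)) "," else if (grepl("\t", line)) "\t" else ""
}

#' Read trajectory files
#'
#' Reads one or more delimited-text trajectory tables (comma, tab or
#' whitespace separated, auto-detected; optional header row) into a
#' \code{\link{trajectory_set}}.
#'
#' @param paths character vector of file paths, one per trial.
#' @param column_map part assignment: an integer vector or a
#'   specification string (see \code{\link{parse_column_map}}).
#' @return a \code{\link{trajectory_set}}; column names are preserved
#'   when a header is present.
#' @export
read_trajectories <- function(paths, column_map) {
  seqs <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("trajectory file not found: ", p)
    first <- readLines(p, n = 1L)
    sep <- .detect_sep(first)
    probe <- strsplit(first, if (sep == "") "\\s+" else sep)[[1]]
    header <- any(is.na(suppressWarnings(as.numeric(probe))))
    df <- utils::read.table(p, sep = sep, header = header,
                            stringsAsFactors = FALSE)
    for (jc in seq_along(df)) {
      if (!is.numeric(df[[jc]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(df[[jc]]))))[1]
        stop(sprintf("non-numeric cell in %s at row %d, column %d",
                     p, bad, jc))
      }
    }
    as.matrix(df)
  })
  trajectory_set(seqs, column_map)
}

#' Write trajectories to delimited-text files
#'
#' Writes each sequence to a comma-separated file at full double
#' precision, so a write/read round trip is value-exact.
#'
#' @param ts a \code{\link{trajectory_set}}.
#' @param paths one output path per sequence.
#' @export
write_trajectories <- function(ts, paths) {
  if (length(paths) != length(ts$sequences)) {
    stop("one output path per sequence is required")
  }
  for (k in seq_along(paths)) {
    utils::write.table(format(ts$sequences[[k]], digits = 17, trim = TRUE,
                              scientific = TRUE),
                       paths[k], sep = ",", row.names = FALSE,
                       col.names = !is.null(colnames(ts$sequences[[k]])),
                       quote = FALSE)
  }
  invisible(paths)
}

# Stack all sequences of a trajectory set into one matrix with a sequence
# id vector; the form consumed by model fitting.
.stack_sequences <- function(ts) {
  Y <- do.call(rbind, ts$sequences)
  seq_id <- rep(seq_along(ts$sequences),
                vapply(ts$sequences, nrow, numeric(1)))
  list(Y = Y, seq_id = seq_id)
}
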