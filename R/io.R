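## TSV interchange for every record type, with header rows, dot-decimal
## locale-independent parsing, and line-numbered errors on malformed rows.
## JSON is used for scalar results (see runPipeline).

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
}

## read a TSV, coerce `numCols` to numeric, and report the 1-based file line
## (header = line 1) of the first malformed row
.readTsv <- function(path, requiredCols, numCols) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  missing <- setdiff(requiredCols, names(df))
  if (length(missing)) {
    stop("file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in intersect(numCols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(df[[col]] %in% c("NA", "")))
    if (length(bad)) {
      stop("file '", path, "', line ", bad[1L] + 1L,
           ": malformed numeric value '", df[[col]][bad[1L]],
           "' in column '", col, "'")
    }
    df[[col]] <- v
  }
  df
}

#' Read and write microcolony trace tables
#'
#' Traces are interchanged as two TSVs: a frames table (`colony_id`,
#' `time_h`, `n_cells`, `cum_divisions`, `cum_foci`) and an event log
#' (`colony_id`, `time_h`, `kind`, `cell_id`). `readMicrocolonyTraces`
#' rebuilds one validated [MicrocolonyTrace-class] per colony;
#' `writeMicrocolonyTraces` is its inverse (round-trip stable). Malformed
#' numeric fields are reported with their file line number.
#'
#' @param traces a [MicrocolonyTrace-class] or list of them.
#' @param framesPath,eventsPath file paths for the two tables.
#' @return `readMicrocolonyTraces` returns a named list of
#'   [MicrocolonyTrace-class] objects; `writeMicrocolonyTraces` returns the
#'   paths, invisibly.
#' @examples
#' tr <- simulateMicrocolony(SimParams(), tEnd = 5, seed = 1)
#' fp <- tempfile(); ep <- tempfile()
#' writeMicrocolonyTraces(tr, fp, ep)
#' readMicrocolonyTraces(fp, ep)[[1]]
#' @export
writeMicrocolonyTraces <- function(traces, framesPath, eventsPath) {
  if (is(traces, "MicrocolonyTrace")) traces <- list(traces)
  fr <- do.call(rbind, lapply(traces, function(tr)
    cbind(colony_id = colonyId(tr), frames(tr))))
  ev <- do.call(rbind, lapply(traces, function(tr) {
    e <- events(tr)
    if (nrow(e)) cbind(colony_id = colonyId(tr), e) else NULL
  }))
  if (is.null(ev)) {
    ev <- data.frame(colony_id = character(0), time_h = numeric(0),
                     kind = character(0), cell_id = integer(0))
  }
  .writeTsv(fr, framesPath)
  .writeTsv(ev, eventsPath)
  invisible(c(framesPath, eventsPath))
}

#' @rdname writeMicrocolonyTraces
#' @export
readMicrocolonyTraces <- function(framesPath, eventsPath) {
  fr <- .readTsv(framesPath,
                 c("colony_id", "time_h", "n_cells", "cum_divisions",
                   "cum_foci"),
                 c("time_h", "n_cells", "cum_divisions", "cum_foci"))
  ev <- .readTsv(eventsPath, c("colony_id", "time_h", "kind", "cell_id"),
                 c("time_h", "cell_id"))
  ids <- unique(fr$colony_id)
  out <- lapply(ids, function(cid) {
    f <- fr[fr$colony_id == cid, -1L, drop = FALSE]
    f$n_cells <- as.integer(f$n_cells)
    f$cum_divisions <- as.integer(f$cum_divisions)
    f$cum_foci <- as.integer(f$cum_foci)
    rownames(f) <- NULL
    e <- ev[ev$colony_id == cid, -1L, drop = FALSE]
    e$cell_id <- as.integer(e$cell_id)
    rownames(e) <- NULL
    MicrocolonyTrace(colonyId = cid, frames = f, events = e)
  })
  names(out) <- ids
  out
}

#' Read and write dose-response tables
#'
#' TSV with columns `dose_Gy`, `mean_foci`, `sd_foci`, `n` (the format
#' produced by [simulateDoseResponse()] and consumed by
#' [fitDoseResponse()]).
#'
#' @param table the dose-response data.frame.
#' @param path file path.
#' @return `readDoseResponse` returns the data.frame; `writeDoseResponse`
#'   the path, invisibly.
#' @export
writeDoseResponse <- function(table, path) {
  .checkDoseTable(table)
  .writeTsv(table, path)
  invisible(path)
}

#' @rdname writeDoseResponse
#' @export
readDoseResponse <- function(path) {
  df <- .readTsv(path, c("dose_Gy", "mean_foci"),
                 c("dose_Gy", "mean_foci", "sd_foci", "n"))
  if ("n" %in% names(df)) df$n <- as.integer(df$n)
  df
}

#' Read and write focus-call tables
#'
#' TSV with columns `cell_id`, `channel`, `x_um`, `y_um`, `intensity`; one
#' file may carry both channels (the format of [simulateFocusPairs()] and
#' the input to [matchFoci()]).
#'
#' @param calls the focus-call data.frame.
#' @param path file path.
#' @return `readFocusCalls` returns the data.frame; `writeFocusCalls` the
#'   path, invisibly.
#' @export
writeFocusCalls <- function(calls, path) {
  .writeTsv(calls, path)
  invisible(path)
}

#' @rdname writeFocusCalls
#' @export
readFocusCalls <- function(path) {
  .readTsv(path, c("cell_id", "channel", "x_um", "y_um"),
           c("x_um", "y_um"))
}

#' Read and write Ct tables
#'
#' TSV with columns `sample`, `locus`, `ct` (the input to
#' [relativeCopyNumber()]).
#'
#' @param table the Ct data.frame.
#' @param path file path.
#' @return `readCtTable` returns the data.frame; `writeCtTable` the path,
#'   invisibly.
#' @export
writeCtTable <- function(table, path) {
  .writeTsv(table, path)
  invisible(path)
}

#' @rdname writeCtTable
#' @export
readCtTable <- function(path) {
  .readTsv(path, c("sample", "locus", "ct"), "ct")
}
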