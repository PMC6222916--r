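# Plain-text table IO. Input tables may be comma- or tab-delimited (sniffed
# from the header line); all output is TSV. Coordinates are 1-based grid
# indices, the plate-reader convention.

.LAYOUT_COLS <- c("plate_id", "row", "col", "strain_id", "protein_id",
                  "genotype", "role")
.READING_COLS <- c("plate_id", "row", "col", "mCherry", "sfGFP",
                   "colony_size")
.ROLES <- c("sample", "negative_control", "reference", "empty")

.sniffSep <- function(path) {
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  if (!length(header)) stop("empty file: ", path)
  if (grepl("\t", header)) "\t" else ","
}

.readTable <- function(path) {
  sep <- .sniffSep(path)
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    colClasses = "character", check.names = FALSE,
                    comment.char = "", stringsAsFactors = FALSE,
                    encoding = "UTF-8", na.strings = NULL)
}

.requireCols <- function(d, cols, path) {
  miss <- setdiff(cols, names(d))
  if (length(miss))
    stop(sprintf("%s: missing mandatory column(s): %s", path,
                 paste(miss, collapse = ", ")))
}

.asNum <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop(sprintf("%s: non-numeric value in column '%s' at data line %d: '%s'",
                 path, col, bad[1L], x[bad[1L]]))
  out
}

.checkDupes <- function(d, what) {
  key <- paste(d$plate_id, d$row, d$col)
  dup <- which(duplicated(key))
  if (length(dup))
    return(sprintf("%s: duplicate position plate=%s row=%s col=%s", what,
                   d$plate_id[dup[1L]], d$row[dup[1L]], d$col[dup[1L]]))
  TRUE
}

# Returns TRUE or a message (used both by readers and by S4 validity).
validateLayout <- function(layout) {
  miss <- setdiff(.LAYOUT_COLS, names(layout))
  if (length(miss))
    return(paste("layout missing column(s):", paste(miss, collapse = ", ")))
  chk <- .checkDupes(layout, "layout")
  if (!isTRUE(chk)) return(chk)
  if (!all(layout$role %in% .ROLES))
    return(paste("unknown role(s):",
                 paste(setdiff(unique(layout$role), .ROLES), collapse = ", ")))
  s <- layout$role == "sample"
  if (any(layout$protein_id[s] == "" | layout$genotype[s] == ""))
    return("sample positions must carry protein_id and genotype")
  if (any(layout$row < 1L | layout$row > 32L | layout$col < 1L |
          layout$col > 48L))
    return("coordinates outside the 1536 grid (row 1..32, col 1..48)")
  TRUE
}

validateReadings <- function(readings) {
  miss <- setdiff(.READING_COLS, names(readings))
  if (length(miss))
    return(paste("readings missing column(s):", paste(miss, collapse = ", ")))
  chk <- .checkDupes(readings, "readings")
  if (!isTRUE(chk)) return(chk)
  num <- c("mCherry", "sfGFP", "colony_size")
  if (any(!is.finite(as.matrix(readings[num]))))
    return("intensities and sizes must be finite")
  if (any(as.matrix(readings[num]) < 0))
    return("intensities and sizes must be >= 0")
  TRUE
}

#' Read a plate layout table
#'
#' Accepts comma- or tab-delimited UTF-8 text with a header; unknown
#' columns are preserved but ignored, row order is irrelevant. Mandatory
#' columns: plate_id, row, col, strain_id, protein_id, genotype, role.
#'
#' @param path file path
#' @return layout data.frame, sorted by (plate_id, row, col)
#' @export
readPlateLayout <- function(path) {
  d <- .readTable(path)
  .requireCols(d, .LAYOUT_COLS, path)
  d$row <- .asNum(d$row, "row", path)
  d$col <- .asNum(d$col, "col", path)
  chk <- validateLayout(d)
  if (!isTRUE(chk)) stop(path, ": ", chk)
  d <- d[order(d$plate_id, d$row, d$col), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Read a colony readings table
#'
#' Accepts comma- or tab-delimited UTF-8 text with a header. Mandatory
#' columns: plate_id, row, col, mCherry, sfGFP, colony_size.
#'
#' @param path file path
#' @return readings data.frame, sorted by (plate_id, row, col)
#' @export
readColonyReadings <- function(path) {
  d <- .readTable(path)
  .requireCols(d, .READING_COLS, path)
  for (col in c("row", "col", "mCherry", "sfGFP", "colony_size"))
    d[[col]] <- .asNum(d[[col]], col, path)
  chk <- validateReadings(d)
  if (!isTRUE(chk)) stop(path, ": ", chk)
  d <- d[order(d$plate_id, d$row, d$col), , drop = FALSE]
  rownames(d) <- NULL
  d
}

.writeTSV <- function(d, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write layout / readings / truth tables as TSV
#'
#' @param layout,readings data.frames of the corresponding shape
#' @param path output file path
#' @return the path, invisibly
#' @name write-tables
#' @export
writePlateLayout <- function(layout, path) {
  chk <- validateLayout(layout)
  if (!isTRUE(chk)) stop(chk)
  .writeTSV(layout, path)
}

#' @rdname write-tables
#' @export
writeColonyReadings <- function(readings, path) {
  chk <- validateReadings(readings)
  if (!isTRUE(chk)) stop(chk)
  .writeTSV(readings, path)
}

#' Write delta-score results as TSV
#'
#' Columns: protein_id, mutant, n_replicates, delta_mC_sfG, delta_sfG, s2,
#' t_moderated, df_total, p_value, hit_class; floats carry 6 significant
#' digits; rows are sorted by (protein_id, mutant).
#'
#' @param records delta-score record data.frame (see [scoreScreen()]);
#'   a \code{hit_class} column is added as \code{"NA"} when absent
#' @param path output file path
#' @return the path, invisibly
#' @export
writeDeltaScores <- function(records, path) {
  cols <- c("protein_id", "mutant", "n_replicates", "delta_mC_sfG",
            "delta_sfG", "s2", "t_moderated", "df_total", "p_value")
  miss <- setdiff(cols, names(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(records$hit_class)) records$hit_class <- NA_character_
  d <- records[order(records$protein_id, records$mutant),
               c(cols, "hit_class"), drop = FALSE]
  for (col in c("delta_mC_sfG", "delta_sfG", "s2", "t_moderated",
                "df_total", "p_value"))
    d[[col]] <- signif(d[[col]], 6)
  .writeTSV(format(d, digits = 6, scientific = FALSE, trim = TRUE), path)
}

#' Read back a delta-score results TSV
#'
#' @param path file path
#' @return delta-score record data.frame
#' @export
readDeltaScores <- function(path) {
  d <- .readTable(path)
  .requireCols(d, c("protein_id", "mutant", "n_replicates",
                    "delta_mC_sfG", "delta_sfG", "s2", "t_moderated",
                    "df_total", "p_value"), path)
  for (col in c("n_replicates", "delta_mC_sfG", "delta_sfG", "s2",
                "t_moderated", "df_total", "p_value"))
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  d
}

#' Read a per-cell flow-cytometry table
#'
#' Comma- or tab-delimited text with columns strain_id, genotype,
#' replicate, mCherry, sfGFP (one row per cell).
#'
#' @param path file path
#' @return per-cell data.frame
#' @export
readFlowCells <- function(path) {
  d <- .readTable(path)
  .requireCols(d, c("strain_id", "genotype", "replicate", "mCherry",
                    "sfGFP"), path)
  for (col in c("replicate", "mCherry", "sfGFP"))
    d[[col]] <- .asNum(d[[col]], col, path)
  d
}

#' Read a flat key = value configuration file
#'
#' Lines of the form \code{key = value} (or \code{key: value}); blank
#' lines and \code{#} comments ignored. Values that parse as numbers are
#' returned numeric.
#'
#' @param path file path
#' @return named list
#' @export
readScreenConfig <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln)
    key <- trimws(m[2L]); val <- trimws(m[3L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
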