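## Plain-text readers and writers for the pipeline's table dialects. All
## files are UTF-8 with headers and '.' decimal separators; writes are
## atomic (temp file + rename).

#' Write / read a plate-reader table
#'
#' CSV with columns `cell_line`, `compound`, `timepoint_h`, `dose_uM`,
#' `replicate`, `well_type`, `intensity` (the [simulate_plate()] layout).
#'
#' @param plate Plate data frame.
#' @param path File path.
#' @return `read_plate_csv()` returns the validated data frame;
#'   `write_plate_csv()` returns `path` invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  write_atomic(function(tmp) {
    utils::write.csv(plate, tmp, row.names = FALSE, quote = FALSE)
  }, path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  plate <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "compound", "timepoint_h", "dose_uM", "replicate",
            "well_type", "intensity")
  if (!all(need %in% names(plate))) {
    stop(sprintf("malformed plate CSV '%s': missing columns %s", path,
                 paste(setdiff(need, names(plate)), collapse = ", ")),
         call. = FALSE)
  }
  bad <- which(!is.finite(plate$intensity) |
                 !plate$well_type %in% c("sample", "untreated", "blank") |
                 (plate$well_type != "blank" & !is.finite(plate$dose_uM)))
  if (length(bad)) {
    stop(sprintf("malformed plate CSV '%s': invalid values at row %d",
                 path, bad[1L] + 1L),  # +1 for the header line
         call. = FALSE)
  }
  plate
}

#' Write / read an expression matrix with detection calls
#'
#' Tab-separated with a `gene_id` column followed by `<line>_value` and
#' `<line>_call` columns for each cell line.
#'
#' @param x An [expression_matrix()].
#' @param path File path.
#' @return `read_expression_tsv()` returns an `expression_matrix`;
#'   `write_expression_tsv()` returns `path` invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  lines <- colnames(x$values)
  out <- data.frame(gene_id = rownames(x$values), stringsAsFactors = FALSE)
  for (cl in lines) {
    out[[paste0(cl, "_value")]] <- x$values[, cl]
    out[[paste0(cl, "_call")]] <- x$calls[, cl]
  }
  write_atomic(function(tmp) {
    utils::write.table(out, tmp, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }, path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"gene_id" %in% names(tab)) {
    stop(sprintf("malformed expression TSV '%s': no gene_id column", path),
         call. = FALSE)
  }
  vcols <- grep("_value$", names(tab), value = TRUE)
  ccols <- grep("_call$", names(tab), value = TRUE)
  lines <- sub("_value$", "", vcols)
  if (!length(lines) || !setequal(lines, sub("_call$", "", ccols))) {
    stop(sprintf(
      "malformed expression TSV '%s': value/call columns do not pair up",
      path), call. = FALSE)
  }
  values <- as.matrix(tab[, paste0(lines, "_value"), drop = FALSE])
  calls <- as.matrix(tab[, paste0(lines, "_call"), drop = FALSE])
  dimnames(values) <- dimnames(calls) <- list(tab$gene_id, lines)
  expression_matrix(values, calls)
}

#' Read / write a gene-set file
#'
#' Plain text, one gene label per line; blank lines and `#` comments are
#' ignored.
#'
#' @param path File path.
#' @param genes Character vector of labels.
#' @return `read_gene_set()` returns a character vector.
#' @export
read_gene_set <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  genes <- lines[nzchar(lines)]
  if (!length(genes)) {
    stop(sprintf("gene-set file '%s' contains no genes", path),
         call. = FALSE)
  }
  unique(genes)
}

#' @rdname read_gene_set
#' @export
write_gene_set <- function(genes, path) {
  write_atomic(function(tmp) {
    writeLines(as.character(genes), tmp)
  }, path)
}

#' Write / read a cell-track table
#'
#' CSV with columns `track_id`, `frame`, `t_min`, `x_um`, `y_um` (the
#' [simulate_tracks()] layout).
#'
#' @param tracks Track data frame.
#' @param path File path.
#' @return `read_tracks_csv()` returns the validated data frame.
#' @export
write_tracks_csv <- function(tracks, path) {
  write_atomic(function(tmp) {
    utils::write.csv(tracks, tmp, row.names = FALSE, quote = FALSE)
  }, path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  tracks <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "t_min", "x_um", "y_um")
  if (!all(need %in% names(tracks))) {
    stop(sprintf("malformed track CSV '%s': missing columns %s", path,
                 paste(setdiff(need, names(tracks)), collapse = ", ")),
         call. = FALSE)
  }
  tracks
}

#' Read a GEO-style series-matrix text file
#'
#' Minimal adapter for the series-matrix format used to distribute processed
#' microarray matrices: `!`-prefixed metadata lines, then a tab-separated
#' table between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` with an `ID_REF` column and one column per
#' sample. Columns are labelled with `!Sample_title` entries when present
#' (falling back to the sample accessions). Series matrices carry no
#' detection calls, so all calls are set to `"P"`; supply calls separately
#' if the platform provides them.
#'
#' @param path File path (plain text, uncompressed).
#' @return An [expression_matrix()].
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    stop(sprintf("'%s' has no series-matrix table block", path),
         call. = FALSE)
  }
  tab <- utils::read.delim(text = lines[(begin + 1L):(end - 1L)],
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1L] != "ID_REF") {
    stop(sprintf("'%s': series-matrix table must start with ID_REF", path),
         call. = FALSE)
  }
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- tab$ID_REF
  title_line <- grep("^!Sample_title\\b", lines, value = TRUE)
  if (length(title_line) == 1L) {
    titles <- gsub("\"", "", strsplit(title_line, "\t")[[1L]][-1L])
    if (length(titles) == ncol(values)) colnames(values) <- titles
  }
  expression_matrix(values)
}

write_tsv_atomic <- function(tab, path) {
  write_atomic(function(tmp) {
    utils::write.table(tab, tmp, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }, path)
}

write_json_atomic <- function(x, path) {
  write_atomic(function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }, path)
}
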