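#' Read a tab-separated count table
#'
#' Reads a TSV with a header row and first-column identifiers into an
#' integer matrix. Cells must be non-negative integers; violations are
#' reported with their row/column address. Leading lines starting with `#`
#' are skipped.
#'
#' @param path File path.
#' @param orientation Layout of the file: `"samples_by_features"` (rows are
#'   samples) or `"features_by_samples"`. The returned matrix always has
#'   samples as rows.
#' @return Integer matrix, samples x features.
#' @export
read_count_table <- function(path,
                             orientation = c("samples_by_features",
                                             "features_by_samples")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate row identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(df)[-1])) {
    stop("duplicate column identifiers in ", path, call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    v <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(v) | v < 0 | abs(v - round(v)) > 1e-8)
    if (length(bad) > 0) {
      stop(sprintf("non-integer or negative count at row '%s', column '%s' in %s",
                   ids[bad[1]], colnames(m)[j], path), call. = FALSE)
    }
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  if (orientation == "features_by_samples") m <- t(m)
  m
}

#' Write a count table as TSV
#'
#' @param m Matrix with dimnames (written as stored; rows first column).
#' @param path Output path.
#' @param id_column Name of the identifier column in the header.
#' @export
write_count_table <- function(m, path, id_column = "id") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read or write the sample metadata TSV
#'
#' @param path File path.
#' @return Data.frame with `sample_id`, `mouse_id`, `sex`, `treatment`,
#'   `day`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "mouse_id", "sex", "treatment", "day")
  missing <- setdiff(need, colnames(df))
  if (length(missing) > 0) {
    stop("metadata is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  df
}

#' @rdname read_metadata
#' @param meta Metadata data.frame.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read per-sample BGC coverage intervals from a BED-like TSV
#'
#' Expects tab-separated lines `bgc_id`, `start`, `end`, `sample_id` with
#' 0-based half-open coordinates, and summarizes them per (sample, BGC) into
#' a coverage observation: `n_reads` = number of intervals, `covered_bases`
#' = length of the interval union clipped to `[0, L_BGC)`, `read_len` =
#' median interval length. Intervals extending past the BGC end are clipped
#' with a warning.
#'
#' @param path BED file path (no header).
#' @param bgcs BGC reference data.frame (`bgc_id`, `length_bp`).
#' @return Data.frame with `sample_id`, `bgc_id`, `n_reads`, `read_len`,
#'   `covered_bases`.
#' @export
read_bed_coverage <- function(path, bgcs) {
  cols <- c("bgc_id", "start", "end", "sample_id")
  empty <- data.frame(sample_id = character(0), bgc_id = character(0),
                      n_reads = integer(0), read_len = integer(0),
                      covered_bases = integer(0))
  lines <- readLines(path)
  if (length(lines) == 0 || all(!nzchar(lines) | startsWith(lines, "#"))) {
    return(empty)
  }
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (nrow(df) == 0) return(empty)
  if (ncol(df) < 4) stop("BED coverage needs 4 columns: ",
                         paste(cols, collapse = ", "), call. = FALSE)
  colnames(df)[1:4] <- cols
  if (any(df$end <= df$start)) {
    stop("BED intervals must satisfy end > start", call. = FALSE)
  }
  unknown <- setdiff(unique(df$bgc_id), bgcs$bgc_id)
  if (length(unknown) > 0) {
    stop("BED references unknown BGCs: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  L <- bgcs$length_bp[match(df$bgc_id, bgcs$bgc_id)]
  if (any(df$end > L)) {
    warning(sum(df$end > L), " interval(s) extend past the BGC end; clipped")
    df$end <- pmin(df$end, L)
  }
  df$start <- pmax(df$start, 0)
  keys <- split(seq_len(nrow(df)), paste(df$sample_id, df$bgc_id, sep = "\r"))
  out <- lapply(keys, function(idx) {
    d <- df[idx, , drop = FALSE]
    data.frame(sample_id = d$sample_id[1], bgc_id = d$bgc_id[1],
               n_reads = nrow(d),
               read_len = as.integer(round(stats::median(d$end - d$start))),
               covered_bases = as.integer(interval_union_length(d$start,
                                                                d$end)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$sample_id, out$bgc_id), , drop = FALSE]
}

#' Read or write gene sets in GMT format
#'
#' GMT: one pathway per line, tab-separated -- id, free-text description,
#' then member genes.
#'
#' @param path File path.
#' @param universe Optional gene universe; defaults to the union of all set
#'   members.
#' @return A list with `sets` (named list of gene vectors), `descriptions`,
#'   and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(ids)) stop("duplicate pathway ids in GMT", call. = FALSE)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- ids
  desc <- vapply(parts, `[`, character(1), 2)
  names(desc) <- ids
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  list(sets = sets, descriptions = desc, universe = universe)
}

#' @rdname read_gmt
#' @param sets Named list of gene vectors.
#' @param descriptions Optional named descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(id) {
    d <- if (is.null(descriptions)) "" else descriptions[[id]]
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Write an association edge list as TSV
#'
#' @param edges `"association_edges"` data.frame.
#' @param path Output path.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
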