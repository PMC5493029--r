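# OTU-table I/O: plain TSV (samples as rows or columns) and the mothur
# "shared" format.  Counts are absolute read counts; fractional cells are
# rejected because the sampling formulas are defined on integers.

new_otu_table <- function(sample_ids, otu_ids, counts, group_map = NULL,
                          label = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != length(sample_ids) ||
      ncol(counts) != length(otu_ids))
    stop("count matrix dimensions do not match id lists")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ",
         sample_ids[duplicated(sample_ids)][1])
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU id: ", otu_ids[duplicated(otu_ids)][1])
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, otu_ids)
  structure(list(sample_ids = sample_ids, otu_ids = otu_ids,
                 counts = counts, group_map = group_map, label = label),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table:", length(x$sample_ids), "samples x",
      length(x$otu_ids), "OTUs\n")
  if (!is.null(x$group_map))
    cat("  groups:", paste(names(table(x$group_map)),
                           table(x$group_map), collapse = ", "), "\n")
  invisible(x)
}

parse_count_cell <- function(x, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | v < 0 | v != floor(v)
  if (any(bad))
    stop("non-integer count in ", what, ": '", x[bad][1], "'")
  as.integer(v)
}

#' Read an OTU count table from plain TSV
#'
#' The table must be rectangular with a header of ids; the first column
#' (or row, depending on `orientation`) holds the other dimension's ids.
#' Cells must be non-negative integers (absolute read counts).
#'
#' @param path file path.
#' @param orientation `"samples_as_rows"` (default, matches mothur shared)
#'   or `"samples_as_columns"`.
#' @param group_file optional two-column TSV (sample_id, group) attaching
#'   group labels; groups must be `control`, `disease`, or `unlabeled`.
#' @return An `otu_table` object.
#' @export
read_otu_tsv <- function(path,
                         orientation = c("samples_as_rows",
                                         "samples_as_columns"),
                         group_file = NULL) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("OTU table needs a header and >= 1 row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1)
    stop("ragged table: row ", which(widths != widths[1])[1],
         " has ", widths[widths != widths[1]][1], " fields, expected ",
         widths[1])
  header <- cells[[1]]
  body <- cells[-1]
  row_ids <- vapply(body, `[[`, character(1), 1)
  col_ids <- header[-1]
  counts <- matrix(0L, length(body), length(col_ids))
  for (i in seq_along(body))
    counts[i, ] <- parse_count_cell(body[[i]][-1],
                                    paste0("row '", row_ids[i], "'"))
  if (orientation == "samples_as_rows") {
    tab <- new_otu_table(row_ids, col_ids, counts)
  } else {
    tab <- new_otu_table(col_ids, row_ids, t(counts))
  }
  if (!is.null(group_file)) tab$group_map <- read_group_file(group_file)
  tab
}

#' Write an OTU table as plain TSV
#'
#' @param table an `otu_table`.
#' @param path output path.
#' @param orientation as in [read_otu_tsv()].
#' @return Invisibly, `path`.
#' @export
write_otu_tsv <- function(table, path,
                          orientation = c("samples_as_rows",
                                          "samples_as_columns")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(table, "otu_table"))
  if (orientation == "samples_as_rows") {
    m <- table$counts
    header <- c("sample_id", table$otu_ids)
  } else {
    m <- t(table$counts)
    header <- c("otu_id", table$sample_ids)
  }
  lines <- c(paste(header, collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], m[i, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column sample-to-group mapping
#'
#' @param path TSV with columns sample_id, group (header optional; groups
#'   must be control / disease / unlabeled).
#' @return Named character vector mapping sample_id to group.
#' @export
read_group_file <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) != 2) stop("group file needs exactly two columns")
  if (tolower(df[1, 1]) %in% c("sample", "sample_id")) df <- df[-1, ]
  ok <- df[[2]] %in% c("control", "disease", "unlabeled")
  if (!all(ok))
    stop("unknown group label: '", df[[2]][!ok][1], "'")
  if (anyDuplicated(df[[1]]))
    stop("duplicate sample id in group file: ",
         df[[1]][duplicated(df[[1]])][1])
  stats::setNames(df[[2]], df[[1]])
}

#' Read a mothur "shared" OTU table
#'
#' The shared dialect: header `label Group numOtus Otu001 ...`, one row
#' per sample with the clustering label, the sample (group) name, the OTU
#' count, then the per-OTU read counts.  `numOtus` must match the actual
#' number of OTU columns.  Files holding several clustering labels must be
#' disambiguated with `label=`.
#'
#' @param path file path.
#' @param label clustering label to keep when the file has several.
#' @return An `otu_table`; the mothur label is kept in `$label`.
#' @export
read_mothur_shared <- function(path, label = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  if (length(header) < 4 ||
      tolower(header[1]) != "label" || tolower(header[2]) != "group" ||
      tolower(header[3]) != "numotus")
    stop("not a mothur shared file: header must start with ",
         "'label Group numOtus'")
  otu_ids <- header[-(1:3)]
  body <- cells[-1]
  widths <- lengths(body)
  if (any(widths != length(header)))
    stop("ragged shared file at data row ",
         which(widths != length(header))[1])
  labels <- vapply(body, `[[`, character(1), 1)
  if (is.null(label)) {
    if (length(unique(labels)) > 1)
      stop("shared file has several labels (",
           paste(unique(labels), collapse = ", "),
           "); choose one with label=")
  } else {
    body <- body[labels == label]
    if (length(body) == 0)
      stop("label '", label, "' not present in shared file")
    labels <- labels[labels == label]
  }
  sample_ids <- vapply(body, `[[`, character(1), 2)
  num_otus <- parse_count_cell(vapply(body, `[[`, character(1), 3),
                               "numOtus column")
  if (any(num_otus != length(otu_ids)))
    stop("numOtus (", num_otus[num_otus != length(otu_ids)][1],
         ") does not match the ", length(otu_ids), " OTU columns")
  counts <- matrix(0L, length(body), length(otu_ids))
  for (i in seq_along(body))
    counts[i, ] <- parse_count_cell(body[[i]][-(1:3)],
                                    paste0("sample '", sample_ids[i], "'"))
  new_otu_table(sample_ids, otu_ids, counts, label = labels[1])
}

#' Write an OTU table in mothur "shared" format
#'
#' @param table an `otu_table`.
#' @param path output path.
#' @param label clustering label column value (default the table's label,
#'   or `"0.02"`).
#' @return Invisibly, `path`.
#' @export
write_mothur_shared <- function(table, path, label = NULL) {
  stopifnot(inherits(table, "otu_table"))
  if (is.null(label)) label <- if (!is.null(table$label)) table$label
    else "0.02"
  m <- table$counts
  header <- paste(c("label", "Group", "numOtus", table$otu_ids),
                  collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(label, table$sample_ids[i], ncol(m), m[i, ]), collapse = "\t"),
    character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Turn an OTU table into per-sample community samples
#'
#' Each row becomes one [community_sample][make_sample]; zero-count OTUs
#' are dropped per sample (the SAD contains only taxa present in that
#' sample).  Group labels come from the table's `group_map` when present.
#'
#' @param table an `otu_table`.
#' @return Named list of [community_sample][make_sample] objects.
#' @export
samples_from_otu_table <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  out <- lapply(seq_along(table$sample_ids), function(i) {
    id <- table$sample_ids[i]
    grp <- if (!is.null(table$group_map) && id %in% names(table$group_map))
      table$group_map[[id]] else "unlabeled"
    make_sample(table$counts[i, ], sample_id = id, group = grp)
  })
  stats::setNames(out, table$sample_ids)
}
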