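#' Labeled numeric matrices
#'
#' Throughout the package a "labeled matrix" is a plain numeric `matrix` whose
#' `rownames` and `colnames` are unique, non-empty character labels.  Drug by
#' disease association matrices take values in \{-1, 0, 1\} (the -1 appears
#' only after side-effect marking, see [mark_side_effects()]); drug feature
#' and drug side-effect matrices are binary.
#'
#' @param values numeric matrix or something coercible to one
#' @param row_labels,col_labels character vectors of unique labels
#' @return a numeric matrix with validated dimnames
#' @export
labeled_matrix <- function(values, row_labels = rownames(values),
                           col_labels = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rownames(values) <- row_labels
  colnames(values) <- col_labels
  validate_labeled_matrix(values)
  values
}

#' Validate a labeled matrix
#'
#' Checks that dimnames are present, unique and match the grid dimensions.
#'
#' @param x numeric matrix
#' @param binary if `TRUE`, additionally require all values in \{0, 1\}
#' @param what name used in error messages
#' @return `x`, invisibly
#' @export
validate_labeled_matrix <- function(x, binary = FALSE, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  rl <- rownames(x); cl <- colnames(x)
  if (is.null(rl) || is.null(cl))
    stop(what, " must carry row and column labels", call. = FALSE)
  for (axis in list(c("row", "rl"), c("col", "cl"))) {
    labs <- if (axis[[1]] == "row") rl else cl
    dup <- labs[duplicated(labs)]
    if (length(dup))
      stop(what, ": duplicate ", axis[[1]], " label(s): ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
    if (any(!nzchar(labs)))
      stop(what, ": empty ", axis[[1]], " label", call. = FALSE)
  }
  if (anyNA(x))
    stop(what, " contains missing values", call. = FALSE)
  if (binary && !all(x %in% c(0, 1)))
    stop(what, " must be binary (0/1)", call. = FALSE)
  invisible(x)
}

#' Read a labeled matrix from disk
#'
#' Two on-disk dialects are supported.  `csv`/`tsv` is a dense grid: the first
#' cell of the header is empty (or ignored), the remaining header cells are
#' column labels, and each subsequent line is a row label followed by numeric
#' values.  `triplet` is a 3-column TSV of `(row_label, col_label, value)`
#' records plus two sidecar files `<path>.rows` and `<path>.cols` declaring
#' the full label sets (one label per line); unlisted cells are 0.
#'
#' @param path file path
#' @param format one of `"csv"`, `"tsv"`, `"triplet"`; default guessed from
#'   the file extension (`.csv`, `.tsv`/`.txt`, `.triplet`)
#' @return a labeled numeric matrix
#' @seealso [write_labeled_matrix()]
#' @export
read_labeled_matrix <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv",
                     triplet = "triplet",
                     stop("cannot guess format of ", path, call. = FALSE))
  }
  format <- match.arg(format, c("csv", "tsv", "triplet"))
  if (format == "triplet") return(read_triplet_matrix(path))
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  row_labels <- df[[1]]
  col_labels <- colnames(df)[-1]
  for (axis in list(list("row", row_labels), list("column", col_labels))) {
    dup <- axis[[2]][duplicated(axis[[2]])]
    if (length(dup))
      stop("duplicate ", axis[[1]], " label(s) in ", path, ": ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  cells <- as.matrix(df[, -1, drop = FALSE])
  m <- suppressWarnings(array(as.numeric(cells), dim(cells)))
  bad <- which(is.na(m) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric cell at row '", row_labels[bad[1, 1]], "', column '",
         col_labels[bad[1, 2]], "' in ", path, call. = FALSE)
  labeled_matrix(m, row_labels, col_labels)
}

read_triplet_matrix <- function(path) {
  rows <- readLines(paste0(path, ".rows"))
  cols <- readLines(paste0(path, ".cols"))
  rows <- rows[nzchar(rows)]; cols <- cols[nzchar(cols)]
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("row", "col", "value"),
                          colClasses = c("character", "character", "numeric"),
                          stringsAsFactors = FALSE, quote = "\"")
  m <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  i <- match(df$row, rows); j <- match(df$col, cols)
  if (anyNA(i)) stop("triplet row label not declared: ",
                     df$row[which(is.na(i))[1]], call. = FALSE)
  if (anyNA(j)) stop("triplet col label not declared: ",
                     df$col[which(is.na(j))[1]], call. = FALSE)
  m[cbind(i, j)] <- df$value
  labeled_matrix(m)
}

#' Write a labeled matrix to disk
#'
#' Inverse of [read_labeled_matrix()]; `read(write(x))` is the identity on
#' values and labels for all three formats.
#'
#' @param x labeled numeric matrix
#' @param path destination path
#' @param format `"csv"`, `"tsv"` or `"triplet"` (triplet writes only nonzero
#'   cells plus `<path>.rows` / `<path>.cols` sidecars)
#' @return `path`, invisibly
#' @export
write_labeled_matrix <- function(x, path, format = c("csv", "tsv", "triplet")) {
  validate_labeled_matrix(x)
  format <- match.arg(format)
  if (format == "triplet") {
    nz <- which(x != 0, arr.ind = TRUE)
    df <- data.frame(row = rownames(x)[nz[, 1]], col = colnames(x)[nz[, 2]],
                     value = x[nz])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    writeLines(rownames(x), paste0(path, ".rows"))
    writeLines(colnames(x), paste0(path, ".cols"))
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", colnames(x)), collapse = sep), con)
  utils::write.table(x, con, sep = sep, quote = FALSE,
                     row.names = TRUE, col.names = FALSE)
  invisible(path)
}

#' Align the three input matrices on a shared drug axis
#'
#' The association, feature and side-effect matrices all have drugs on the
#' rows but may come from different sources.  Drugs absent from any one of
#' the three are dropped everywhere, and the survivors are reordered so the
#' row label order is identical across the triple.  Column axes are left
#' untouched.
#'
#' @param assoc drug x disease association matrix
#' @param features drug x feature binary matrix
#' @param side_effects drug x side-effect binary matrix
#' @return a list with elements `assoc`, `features`, `side_effects` (aligned)
#'   and `dropped`, a named integer vector counting drugs dropped from each
#'   input
#' @export
align_inputs <- function(assoc, features, side_effects) {
  for (m in list(assoc, features, side_effects)) validate_labeled_matrix(m)
  shared <- intersect(intersect(rownames(assoc), rownames(features)),
                      rownames(side_effects))
  if (length(shared) == 0L)
    stop("no drug label occurs in all three inputs", call. = FALSE)
  dropped <- c(assoc = nrow(assoc), features = nrow(features),
               side_effects = nrow(side_effects)) - length(shared)
  list(assoc = assoc[shared, , drop = FALSE],
       features = features[shared, , drop = FALSE],
       side_effects = side_effects[shared, , drop = FALSE],
       dropped = dropped)
}
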