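#' Construct and validate a probes-by-samples expression matrix
#'
#' The unit of analysis throughout the package is the probe set (one row per
#' probe, never collapsed to genes). Values are assumed to be normalized
#' log2-scale intensities; missing or non-finite values are rejected rather
#' than imputed, because the downstream statistics (signal-to-noise weights,
#' linkage distances) assume complete matrices.
#'
#' @param values numeric matrix, rows = probes, columns = samples.
#' @param probe_ids character vector of unique probe identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `colnames(values)`.
#' @return the validated numeric matrix with `probe_ids` as row names and
#'   `sample_ids` as column names.
#' @examples
#' m <- expression_matrix(matrix(rnorm(6), 2, 3,
#'   dimnames = list(c("p1", "p2"), c("s1", "s2", "s3"))))
#' @export
expression_matrix <- function(values, probe_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression values must be a numeric matrix")
  }
  if (is.null(probe_ids) || is.null(sample_ids)) {
    stop("probe_ids and sample_ids are required (or set as dimnames)")
  }
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (length(probe_ids) != nrow(values)) {
    stop("length(probe_ids) must equal nrow(values)")
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length(sample_ids) must equal ncol(values)")
  }
  if (anyDuplicated(probe_ids)) {
    stop("duplicate probe id: ", probe_ids[duplicated(probe_ids)][1L])
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite expression value at probe '", probe_ids[bad[1L]],
         "', sample '", sample_ids[bad[2L]], "'")
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  values
}

#' Read an expression matrix from a GCT 1.2 file
#'
#' GCT 1.2 is the tab-delimited dialect with a `#1.2` version line, a
#' `<rows><TAB><cols>` dimension line, and a header
#' `Name<TAB>Description<TAB><sample ids...>`. The Description column is
#' discarded on read.
#'
#' @param path path to a GCT file.
#' @return an [expression_matrix()] (probes x samples).
#' @seealso [write_gct()]
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) stop("GCT file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L) stop("truncated GCT file: ", path)
  if (trimws(lines[1L]) != "#1.2") {
    stop("not a GCT 1.2 file (first line must be '#1.2'): ", path)
  }
  dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]))
  if (length(dims) < 2L || anyNA(dims[1:2])) {
    stop("malformed GCT dimension line: '", lines[2L], "'")
  }
  n_rows <- dims[1L]
  n_cols <- dims[2L]
  header <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  if (length(header) != n_cols + 2L) {
    stop("column count mismatch: header has ", length(header) - 2L,
         " samples, dimension line declares ", n_cols)
  }
  sample_ids <- header[-(1:2)]
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) != n_rows) {
    stop("row count mismatch: body has ", length(body),
         " rows, dimension line declares ", n_rows)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  probe_ids <- vapply(fields, `[[`, character(1L), 1L)
  values <- matrix(NA_real_, n_rows, n_cols)
  for (i in seq_len(n_rows)) {
    row <- fields[[i]]
    if (length(row) != n_cols + 2L) {
      stop("missing cell in row '", probe_ids[i], "': expected ", n_cols,
           " values, found ", length(row) - 2L)
    }
    v <- suppressWarnings(as.numeric(row[-(1:2)]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop("non-numeric cell at row '", probe_ids[i], "', column '",
           sample_ids[j], "': '", row[j + 2L], "'")
    }
    values[i, ] <- v
  }
  expression_matrix(values, probe_ids, sample_ids)
}

#' Write an expression matrix as GCT 1.2
#'
#' The Description column is filled with the probe id; values are written at
#' full decimal precision so that a write/read round trip is lossless.
#'
#' @param x an [expression_matrix()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gct <- function(x, path) {
  if (NROW(x) < 1L) stop("GCT requires at least one probe row")
  x <- expression_matrix(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(x), ncol(x), sep = "\t")), con)
  writeLines(paste(c("Name", "Description", colnames(x)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], rownames(x)[i],
            format(x[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1L))
  writeLines(body, con)
  invisible(path)
}

#' Two-class (or multi-class) sample labels
#'
#' @param labels integer class indices (1-based) or a factor/character vector;
#'   characters are mapped to indices by order of first appearance unless
#'   `class_names` is given.
#' @param class_names character vector of class names (length >= 2).
#' @param sample_ids optional sample identifiers parallel to `labels`.
#' @return an object of class `class_labels` with fields `labels` (integer),
#'   `class_names`, `sample_ids`.
#' @export
class_labels <- function(labels, class_names = NULL, sample_ids = NULL) {
  if (is.factor(labels)) {
    if (is.null(class_names)) class_names <- levels(labels)
    labels <- as.integer(labels)
  } else if (is.character(labels)) {
    if (is.null(class_names)) class_names <- unique(labels)
    idx <- match(labels, class_names)
    if (anyNA(idx)) {
      stop("unknown label symbol: '", labels[is.na(idx)][1L], "'")
    }
    labels <- idx
  } else {
    labels <- as.integer(labels)
  }
  if (is.null(class_names)) {
    stop("class_names required when labels are numeric indices")
  }
  if (length(class_names) < 2L) stop("at least two class names required")
  if (any(labels < 1L | labels > length(class_names))) {
    stop("label index outside 1..", length(class_names))
  }
  if (!is.null(sample_ids) && length(sample_ids) != length(labels)) {
    stop("sample_ids and labels must have equal length")
  }
  structure(list(labels = labels, class_names = as.character(class_names),
                 sample_ids = sample_ids),
            class = "class_labels")
}

#' @export
print.class_labels <- function(x, ...) {
  cat("<class_labels> ", length(x$labels), " samples: ",
      paste(sprintf("%s=%d", x$class_names,
                    tabulate(x$labels, length(x$class_names))),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read class labels from a CLS file
#'
#' CLS is the space-delimited three-line dialect: line 1
#' `<n_samples> <n_classes> 1`, line 2 `# <class names>`, line 3 the labels.
#' Labels may be 0-based indices into the declared class names or the class
#' name tokens themselves; tokens are mapped by order of first appearance.
#'
#' @param path path to a CLS file.
#' @return a [class_labels()] object.
#' @export
read_cls <- function(path) {
  if (!file.exists(path)) stop("CLS file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("truncated CLS file: ", path)
  split_ws <- function(s) strsplit(trimws(s), "[ \t]+")[[1L]]
  hdr <- suppressWarnings(as.integer(split_ws(lines[1L])))
  if (length(hdr) < 2L || anyNA(hdr[1:2])) {
    stop("malformed CLS header line: '", lines[1L], "'")
  }
  n_samples <- hdr[1L]
  n_classes <- hdr[2L]
  name_line <- split_ws(lines[2L])
  if (name_line[1L] != "#") stop("CLS line 2 must start with '#'")
  class_names <- name_line[-1L]
  if (length(class_names) != n_classes) {
    stop("CLS declares ", n_classes, " classes but names ",
         length(class_names))
  }
  tokens <- split_ws(lines[3L])
  if (length(tokens) != n_samples) {
    stop("CLS declares ", n_samples, " samples but gives ",
         length(tokens), " labels")
  }
  as_int <- suppressWarnings(as.integer(tokens))
  if (!anyNA(as_int)) {
    if (any(as_int < 0L | as_int >= n_classes)) {
      stop("unknown label symbol: '", tokens[which(as_int < 0L | as_int >= n_classes)[1L]], "'")
    }
    labels <- as_int + 1L
  } else {
    # name tokens: map to class_names by order of first appearance
    first_seen <- unique(tokens)
    if (length(first_seen) > n_classes) {
      stop("unknown label symbol: '", setdiff(first_seen, class_names)[1L], "'")
    }
    labels <- match(match(tokens, first_seen), seq_len(n_classes))
  }
  class_labels(labels, class_names)
}

#' Write class labels as a CLS file
#'
#' @param labels a [class_labels()] object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cls <- function(labels, path) {
  stopifnot(inherits(labels, "class_labels"))
  writeLines(c(
    paste(length(labels$labels), length(labels$class_names), "1"),
    paste(c("#", labels$class_names), collapse = " "),
    paste(labels$labels - 1L, collapse = " ")
  ), path)
  invisible(path)
}

#' Align an expression matrix with a sample annotation table
#'
#' Restricts both to their shared sample ids and puts the matrix columns in
#' the annotation row order (the canonical order, so alignment is invariant
#' to column shuffles of the matrix and idempotent). Samples present on only
#' one side are dropped with a warning.
#'
#' @param x an [expression_matrix()].
#' @param annotations a data frame with a `sample_id` column.
#' @return list with elements `expr` (reordered matrix) and `annotations`
#'   (restricted annotation table).
#' @export
align_samples <- function(x, annotations) {
  x <- expression_matrix(x)
  if (!is.data.frame(annotations) || is.null(annotations$sample_id)) {
    stop("annotations must be a data frame with a sample_id column")
  }
  if (anyDuplicated(annotations$sample_id)) stop("duplicate sample_id in annotations")
  shared <- annotations$sample_id[annotations$sample_id %in% colnames(x)]
  if (length(shared) == 0L) stop("no shared samples between matrix and annotations")
  dropped <- c(setdiff(colnames(x), shared), setdiff(annotations$sample_id, shared))
  if (length(dropped) > 0L) {
    warning("dropping ", length(dropped), " unmatched sample(s): ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  }
  ann <- annotations[match(shared, annotations$sample_id), , drop = FALSE]
  rownames(ann) <- NULL
  list(expr = x[, shared, drop = FALSE], annotations = ann)
}

# internal: coerce labels argument (class_labels / factor / character) to an
# integer vector of 1s and 2s aligned with the columns of x
.binary_labels <- function(x, labels) {
  if (!inherits(labels, "class_labels")) labels <- class_labels(labels)
  if (length(labels$labels) != ncol(x)) {
    stop("labels length (", length(labels$labels),
         ") does not match sample count (", ncol(x), ")")
  }
  if (length(labels$class_names) != 2L) {
    stop("a two-class contrast is required")
  }
  labels
}
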