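#' Read a delimited sample file
#'
#' Reads a 1- or 2-column numeric sample from a CSV, TSV or
#' whitespace-delimited text file. The delimiter is auto-detected unless
#' given; a first row whose fields are not all numeric is treated as a
#' header and skipped; blank lines are ignored. Rows with missing or
#' non-numeric fields raise an error naming the first offending row.
#'
#' @param path file path.
#' @param delimiter `NULL` for auto-detection, or an explicit single
#'   character (`","`, `"\t"`, or `""` for whitespace).
#' @param columns optional column selection (indices or names) when the file
#'   has more than the 1 or 2 columns to use.
#' @return numeric matrix with one observation per row.
#' @export
read_sample <- function(path, delimiter = NULL, columns = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no usable rows in input")

  if (is.null(delimiter)) {
    first <- lines[1]
    delimiter <- if (grepl(",", first, fixed = TRUE)) ","
                 else if (grepl("\t", first, fixed = TRUE)) "\t"
                 else ""
  }
  split1 <- function(s) {
    f <- if (delimiter == "") strsplit(trimws(s), "[[:space:]]+")[[1]]
         else strsplit(s, delimiter, fixed = TRUE)[[1]]
    trimws(f)
  }
  fields <- lapply(lines, split1)
  is_num <- function(v) !any(is.na(suppressWarnings(as.numeric(v))))
  header <- NULL
  if (!is_num(fields[[1]])) {
    header <- fields[[1]]
    fields <- fields[-1]
    if (!length(fields)) stop("no usable rows in input")
  }
  ncols <- length(fields[[1]])
  bad <- which(vapply(fields, length, 0L) != ncols)
  if (length(bad))
    stop(sprintf("row %d has %d field(s), expected %d",
                 bad[1], length(fields[[bad[1]]]), ncols))
  x <- matrix(NA_real_, length(fields), ncols)
  for (i in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[i]]))
    if (any(is.na(v)))
      stop(sprintf("non-numeric value in data row %d: '%s'",
                   i, fields[[i]][which(is.na(v))[1]]))
    x[i, ] <- v
  }
  if (!is.null(header)) colnames(x) <- header

  if (!is.null(columns)) {
    if (is.character(columns)) {
      if (is.null(header)) stop("column names given but file has no header")
      miss <- setdiff(columns, header)
      if (length(miss))
        stop(sprintf("column(s) not found: %s", paste(miss, collapse = ", ")))
      x <- x[, columns, drop = FALSE]
    } else {
      x <- x[, as.integer(columns), drop = FALSE]
    }
  }
  if (!ncol(x) %in% 1:2)
    stop(sprintf("expected 1 or 2 numeric columns, found %d; use 'columns' to select",
                 ncol(x)))
  x
}

#' Write a density field
#'
#' Long format: CSV with columns `x[,y],density`, one row per grid point,
#' row-major over the axes (first axis varying fastest). Matrix format
#' (d = 2 only): first row and column carry the axis coordinates, the body
#' the density matrix. Values are serialized at 17 significant digits so a
#' read/write round trip is bit-exact.
#'
#' @param field a [bade()] fit or a list with `grid` and `values`.
#' @param path output path.
#' @param format `"long"` or `"matrix"`.
#' @return `path`, invisibly.
#' @export
write_density <- function(field, path, format = c("long", "matrix")) {
  format <- match.arg(format)
  if (inherits(field, "bade")) {
    grid <- field$grid
    values <- field$estimate
  } else {
    grid <- field$grid
    values <- field$values
  }
  d <- length(grid)
  fmt <- function(v) sprintf("%.17g", v)
  if (format == "long") {
    pts <- as.matrix(expand.grid(grid, KEEP.OUT.ATTRS = FALSE))
    header <- if (d == 1L) "x,density" else "x,y,density"
    body <- apply(cbind(pts, as.vector(values)), 1,
                  function(r) paste(fmt(r), collapse = ","))
    writeLines(c(header, body), path)
  } else {
    if (d != 2L) stop("matrix format requires a 2-D field")
    v <- matrix(as.vector(values), length(grid[[1]]))
    lines <- c(paste(c("", fmt(grid[[2]])), collapse = ","),
               vapply(seq_along(grid[[1]]), function(i)
                 paste(c(fmt(grid[[1]][i]), fmt(v[i, ])), collapse = ","),
                 character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a density field written by [write_density()]
#'
#' @param path path to a long-format density CSV.
#' @return list with `grid` (axis vectors) and `values` (vector for d = 1,
#'   matrix for d = 2), suitable for [ise()].
#' @export
read_density <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE)
  if (!"density" %in% names(df))
    stop("not a long-format density file (no 'density' column)")
  d <- ncol(df) - 1L
  if (!d %in% 1:2) stop("expected columns x[,y],density")
  if (d == 1L) {
    list(grid = list(df$x), values = df$density)
  } else {
    ax1 <- unique(df$x)
    ax2 <- unique(df$y)
    if (nrow(df) != length(ax1) * length(ax2))
      stop("grid in file is not regular")
    list(grid = list(ax1, ax2),
         values = matrix(df$density, length(ax1)))
  }
}
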