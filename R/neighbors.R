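#' Build an incremental nearest-neighbor index
#'
#' Constructs a spatial index (a kd-tree with best-first traversal) over a
#' fixed set of 1-D or 2-D points. Streams opened on the index yield sample
#' points one at a time in nondecreasing Euclidean distance from a probe,
#' with ties broken by ascending sample index, so retrieving the (k+1)-th
#' neighbor never recomputes the first k.
#'
#' @param points numeric matrix (or vector for d = 1) of points, one per row.
#' @return an object of class `"nn_index"`.
#' @seealso [nn_stream()], [nn_next()], [nn_naive()]
#' @export
nn_index <- function(points) {
  x <- as_point_matrix(points)
  structure(list(ptr = cpp_nn_build(x), M = nrow(x), d = ncol(x)),
            class = "nn_index")
}

#' @export
print.nn_index <- function(x, ...) {
  cat(sprintf("Nearest-neighbor index: %d points, d = %d\n", x$M, x$d))
  invisible(x)
}

#' Open a neighbor stream at a probe point
#'
#' @param index an [nn_index()].
#' @param probe numeric vector of length `d`.
#' @return an object of class `"nn_stream"` from which [nn_next()] pulls
#'   successive neighbors.
#' @export
nn_stream <- function(index, probe) {
  stopifnot(inherits(index, "nn_index"))
  probe <- as.numeric(probe)
  if (length(probe) != index$d)
    stop("probe dimension does not match index")
  structure(list(ptr = cpp_nn_open(index$ptr, probe), index = index,
                 probe = probe),
            class = "nn_stream")
}

#' Pull the next neighbors from a stream
#'
#' Advances the stream cursor: each call returns the next `n` sample points
#' in nondecreasing distance from the probe (fewer once the stream is
#' exhausted; zero rows thereafter).
#'
#' @param stream an [nn_stream()].
#' @param n how many neighbors to retrieve.
#' @return data frame with columns `index` (1-based position in the original
#'   point set) and `distance`.
#' @export
nn_next <- function(stream, n = 1L) {
  stopifnot(inherits(stream, "nn_stream"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be at least 1")
  out <- cpp_nn_next(stream$ptr, n)
  data.frame(index = out$index, distance = out$distance)
}

#' Naive full-sort neighbor retrieval (oracle)
#'
#' Sorts the whole point set by distance to the probe in one pass. It obeys
#' the same contract as the incremental stream (nondecreasing distance,
#' ties by ascending index) and serves as the correctness oracle for it; for
#' many probes it is much slower than the indexed stream.
#'
#' @inheritParams nn_index
#' @param probe numeric vector of length `d`.
#' @return data frame with columns `index` and `distance`, all `M` rows.
#' @export
nn_naive <- function(points, probe) {
  x <- as_point_matrix(points)
  probe <- as.numeric(probe)
  if (length(probe) != ncol(x))
    stop("probe dimension does not match point set")
  dist <- if (ncol(x) == 1L) abs(x[, 1] - probe[1])
          else sqrt((x[, 1] - probe[1])^2 + (x[, 2] - probe[2])^2)
  ord <- order(dist, seq_len(nrow(x)))
  data.frame(index = ord, distance = dist[ord])
}

# Coerce vector/matrix/data.frame input to a finite numeric M x d matrix.
as_point_matrix <- function(points) {
  x <- if (is.data.frame(points)) as.matrix(points)
       else if (is.matrix(points)) points
       else matrix(as.numeric(points), ncol = 1)
  storage.mode(x) <- "double"
  if (nrow(x) < 1L) stop("empty point set")
  if (!ncol(x) %in% 1:2) stop("only dimensions 1 and 2 are supported")
  if (any(!is.finite(x))) stop("point coordinates must be finite")
  dimnames(x) <- NULL
  x
}
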