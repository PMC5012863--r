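#' Construct a structural connectome
#'
#' A connectome is a square, symmetric, non-negative weight matrix over named
#' brain regions, optionally carrying 3-D region coordinates (mm). The
#' diagonal is exactly zero: self-connections are not represented.
#'
#' @param weights square numeric matrix of connection weights. Row and column
#'   names, if present, supply the region identifiers.
#' @param region_ids character vector of unique region identifiers, one per
#'   row of `weights`. Defaults to the matrix dimnames.
#' @param coordinates optional numeric matrix with one row per region and
#'   three columns (x, y, z positions in mm).
#' @return An object of class `connectome`: a list with elements `weights`
#'   (with region ids as dimnames) and `coordinates` (or `NULL`).
#' @examples
#' W <- matrix(c(0, 1, 2, 1, 0, 0, 2, 0, 0), 3)
#' x <- connectome(W, region_ids = c("A", "B", "C"))
#' node_strength(x)
#' @export
connectome <- function(weights, region_ids = rownames(weights),
                       coordinates = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop_("weights must be a numeric matrix")
  }
  if (is.null(region_ids)) {
    region_ids <- sprintf("R%03d", seq_len(nrow(weights)))
  }
  dimnames(weights) <- list(region_ids, region_ids)
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    rownames(coordinates) <- region_ids
  }
  x <- structure(list(weights = weights, coordinates = coordinates),
                 class = "connectome")
  validate_connectome(x)
  x
}

#' Validate connectome invariants
#'
#' Checks that the weight matrix is square, non-negative, zero on the
#' diagonal, symmetric to within `1e-9 * max(W)`, and that region ids are
#' unique; coordinates, when present, must be N x 3.
#'
#' @param x a `connectome`.
#' @return `x`, invisibly. Raises a validation error naming the first
#'   offending entry otherwise.
#' @export
validate_connectome <- function(x) {
  stopifnot(inherits(x, "connectome"))
  W <- x$weights
  if (nrow(W) != ncol(W)) {
    stop_("connectome matrix must be square (got %d x %d)", nrow(W), ncol(W))
  }
  ids <- rownames(W)
  if (anyDuplicated(ids)) {
    stop_("duplicate region id: '%s'", ids[duplicated(ids)][1L])
  }
  if (anyNA(W) || any(!is.finite(W))) stop_("connectome weights must be finite")
  neg <- which(W < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop_("negative weight at (%s, %s): %g", ids[neg[1, 1]], ids[neg[1, 2]],
          W[neg[1, , drop = FALSE]])
  }
  if (any(diag(W) != 0)) {
    i <- which(diag(W) != 0)[1L]
    stop_("non-zero diagonal (self-connection) at region '%s'", ids[i])
  }
  tol <- 1e-9 * max(W, 1e-300)
  asym <- abs(W - t(W))
  if (any(asym > tol)) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop_("asymmetric weights at (%s, %s): %g vs %g", ids[ij[1]], ids[ij[2]],
          W[ij[1], ij[2]], W[ij[2], ij[1]])
  }
  if (!is.null(x$coordinates)) {
    if (nrow(x$coordinates) != nrow(W) || ncol(x$coordinates) != 3) {
      stop_("coordinates must be an N x 3 matrix aligned with the regions")
    }
  }
  invisible(x)
}

#' @export
print.connectome <- function(x, ...) {
  W <- x$weights
  ut <- W[upper.tri(W)]
  cat(sprintf("connectome: %d regions, %d edges (density %.3f)%s\n",
              nrow(W), sum(ut > 0), mean(ut > 0),
              if (is.null(x$coordinates)) "" else ", with coordinates"))
  invisible(x)
}

#' Region identifiers of a connectome
#' @param x a `connectome`.
#' @return character vector of region ids in matrix order.
#' @export
region_ids <- function(x) rownames(x$weights)

#' Read a connectome from a delimited text file
#'
#' Two plain-text layouts are supported. `"dense"`: a tab-delimited square
#' matrix whose first row and first column hold region ids. `"edgelist"`: a
#' three-column TSV with header `region_a`, `region_b`, `weight`, one row per
#' unordered region pair; entries are mirrored into both triangles and
#' missing pairs get weight 0. Listing the same pair twice (in either
#' orientation) is accepted when the weights agree and rejected otherwise;
#' self-pairs are rejected.
#'
#' @param path file to read.
#' @param format `"dense"` or `"edgelist"`.
#' @return a validated [connectome()].
#' @export
read_connectome <- function(path, format = c("dense", "edgelist")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_("file not found: %s", path)
  if (format == "dense") {
    d <- read.delim(path, row.names = 1, check.names = FALSE)
    W <- as.matrix(d)
    if (nrow(W) != ncol(W)) {
      stop_("dense connectome file is not square: %d rows, %d columns",
            nrow(W), ncol(W))
    }
    if (!identical(rownames(W), colnames(W))) {
      stop_("row and column region ids disagree in %s", path)
    }
    return(connectome(W))
  }
  e <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_a", "region_b", "weight")
  if (!all(need %in% names(e))) {
    stop_("edge list must have columns %s", paste(need, collapse = ", "))
  }
  ids <- unique(c(rbind(as.character(e$region_a), as.character(e$region_b))))
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  seen <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(e))) {
    a <- as.character(e$region_a[k]); b <- as.character(e$region_b[k])
    w <- e$weight[k]
    if (a == b) stop_("self-loop edge (%s, %s) is not allowed", a, b)
    key <- paste(sort(c(a, b)), collapse = "\r")
    prev <- seen[[key]]
    if (!is.null(prev) && prev != w) {
      stop_("duplicate edge (%s, %s) with conflicting weights %g and %g",
            a, b, prev, w)
    }
    seen[[key]] <- w
    W[a, b] <- w
    W[b, a] <- w
  }
  connectome(W)
}

#' Write a connectome as a dense tab-delimited matrix
#' @param x a `connectome`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(x, path) {
  validate_connectome(x)
  d <- data.frame(region = region_ids(x), x$weights, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Anatomical node strength
#'
#' The strength of region i is the sum of its connection weights,
#' `s_i = sum_j W_ji`. High-strength regions are network hubs; strength
#' drives the timescale hierarchy via [assign_frequencies()].
#'
#' @param x a `connectome`.
#' @return named numeric vector of strengths in matrix order.
#' @export
node_strength <- function(x) {
  validate_connectome(x)
  colSums(x$weights)
}

#' Normalize a connectome
#'
#' `"max"` (the default) divides all weights by the largest weight, so the
#' output has maximum 1 and the operation is idempotent. `"strength"`
#' divides by the mean node strength. Both preserve relative weights and
#' therefore the shape of the strength distribution.
#'
#' @param x a `connectome`.
#' @param mode `"max"` or `"strength"`.
#' @return a normalized `connectome` (dimensionless weights).
#' @export
normalize_connectome <- function(x, mode = c("max", "strength")) {
  mode <- match.arg(mode)
  validate_connectome(x)
  W <- x$weights
  if (max(W) <= 0) stop_("cannot normalize an all-zero connectome")
  denom <- switch(mode, max = max(W), strength = mean(node_strength(x)))
  connectome(W / denom, coordinates = x$coordinates)
}

#' Sparsify a connectome to a target edge density
#'
#' Retains the `ceiling(density * N * (N - 1) / 2)` largest-weight undirected
#' edges and zeroes the rest. Ties at the cutoff are broken by lexicographic
#' (row, column) order of the upper-triangle index, so the result is
#' deterministic and the surviving edge sets are nested across densities.
#'
#' @param x a `connectome`.
#' @param density fraction of possible undirected edges to keep, in (0, 1].
#' @return a sparsified `connectome`.
#' @export
sparsify <- function(x, density) {
  validate_connectome(x)
  if (!is_scalar_number(density) || density <= 0 || density > 1) {
    stop_("density must be a number in (0, 1], got %s", format(density))
  }
  W <- x$weights
  n <- nrow(W)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  k <- ceiling(density * n * (n - 1) / 2)
  ord <- order(-W[ut], ut[, 1], ut[, 2])
  keep <- ord[seq_len(min(k, nrow(ut)))]
  W2 <- matrix(0, n, n)
  W2[ut[keep, , drop = FALSE]] <- W[ut[keep, , drop = FALSE]]
  W2 <- W2 + t(W2)
  connectome(W2, region_ids(x), coordinates = x$coordinates)
}

#' Correct connection weights for inter-region distance
#'
#' Divides each weight by the Euclidean distance between the two region
#' centroids, a proxy for fiber distance that discounts the reconstruction
#' advantage of short-range connections. Unconnected pairs stay at 0.
#'
#' @param x a `connectome` with coordinates.
#' @return a distance-corrected `connectome`.
#' @export
distance_correct <- function(x) {
  validate_connectome(x)
  if (is.null(x$coordinates)) {
    stop_("distance correction requires region coordinates")
  }
  W <- x$weights
  D <- as.matrix(stats::dist(x$coordinates))
  bad <- which(W > 0 & D == 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    ids <- region_ids(x)
    stop_("connected regions '%s' and '%s' have zero distance",
          ids[bad[1, 1]], ids[bad[1, 2]])
  }
  W2 <- ifelse(W > 0, W / pmax(D, .Machine$double.xmin), 0)
  diag(W2) <- 0
  connectome(W2, region_ids(x), coordinates = x$coordinates)
}
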