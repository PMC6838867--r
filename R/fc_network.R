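#' Upper-triangle edge index for a k-node network
#'
#' Enumerates all undirected edges (i, j) with i < j in lexicographic order
#' ((1,2), (1,3), ..., (1,k), (2,3), ...). This ordering defines the flat
#' edge position used everywhere downstream (feature selection, feature
#' vectors, model weights) and must be identical for every session of a
#' cohort, which it is by construction since it depends only on k.
#'
#' @param k Number of regions (nodes); integer >= 2.
#' @return A data frame with integer columns `i`, `j` (1-based region
#'   positions, `i < j`) and `k(k-1)/2` rows. Row number = flat edge
#'   position.
#' @export
#' @examples
#' edge_index(3)  # (1,2), (1,3), (2,3)
#' nrow(edge_index(82))  # 3321
edge_index <- function(k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 2L)
    stop("'k' must be a single integer >= 2")
  i <- rep.int(seq_len(k - 1L), times = (k - 1L):1L)
  j <- unlist(lapply(seq_len(k - 1L), function(a) seq.int(a + 1L, k)),
              use.names = FALSE)
  data.frame(i = i, j = as.integer(j))
}

#' Number of upper-triangle edges for k nodes
#' @param k number of regions
#' @return `k * (k - 1) / 2` as an integer
#' @export
n_edges <- function(k) as.integer(k * (k - 1L) / 2L)

#' Infer the node count from an edge-vector length
#'
#' Solves E = k(k-1)/2 for k; errors if E is not a triangular number.
#' @param n_edge length of a flat edge vector
#' @return integer k
#' @export
nodes_from_edges <- function(n_edge) {
  k <- (1 + sqrt(1 + 8 * as.numeric(n_edge))) / 2
  if (abs(k - round(k)) > 1e-9)
    stop("edge vector length ", n_edge, " is not k(k-1)/2 for integer k")
  as.integer(round(k))
}

#' Construct a connectivity network object
#'
#' @param edges k x k numeric matrix of edge weights n_ij.
#' @param region_labels ordered region identifiers (defaults to matrix
#'   dimnames or 1..k).
#' @param subject_id,session_index optional back-references.
#' @param check validate symmetry/range invariants (default TRUE).
#' @return An object of class `connectivity_network`.
#' @export
connectivity_network <- function(edges, region_labels = NULL,
                                 subject_id = NA_character_,
                                 session_index = NA_integer_,
                                 check = TRUE) {
  edges <- as.matrix(edges)
  k <- nrow(edges)
  if (ncol(edges) != k) stop("'edges' must be square")
  if (is.null(region_labels)) {
    region_labels <- rownames(edges)
    if (is.null(region_labels)) region_labels <- as.character(seq_len(k))
  }
  if (length(region_labels) != k)
    stop("length of 'region_labels' must equal nrow(edges)")
  dimnames(edges) <- list(region_labels, region_labels)
  net <- structure(
    list(edges = edges, region_labels = as.character(region_labels),
         subject_id = subject_id, session_index = session_index),
    class = "connectivity_network")
  if (check) validate_network(net)
  net
}

#' Validate connectivity-network invariants
#'
#' Checks symmetry (to 1e-12), unit diagonal where defined, and that all
#' finite entries lie in [-1, 1] (skipped for transformed networks, e.g.
#' Fisher-z, which carry a `transform` attribute).
#' @param net a `connectivity_network`
#' @return `net`, invisibly; errors on violation.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "connectivity_network"))
  e <- net$edges
  if (max(abs(e - t(e)), na.rm = TRUE) > 1e-12)
    stop("network matrix is not symmetric (tolerance 1e-12)")
  transformed <- !is.null(attr(net, "transform"))
  if (!transformed) {
    d <- diag(e)
    if (any(is.finite(d) & abs(d - 1) > 1e-12))
      stop("network diagonal must be exactly 1 where defined")
    fin <- e[is.finite(e)]
    if (length(fin) && (min(fin) < -1 - 1e-12 || max(fin) > 1 + 1e-12))
      stop("correlation entries must lie in [-1, 1]")
  }
  invisible(net)
}

#' Pearson correlation connectivity network from ROI time series
#'
#' Computes the pairwise Pearson correlation n_ij between the mean time
#' courses of every region pair, the raw feature unit of the whole method.
#' The result is exactly symmetric with unit diagonal.
#'
#' @param ts T x k numeric matrix (timepoints x regions), optionally with
#'   column names as region labels, or a `roi_timeseries` object.
#' @param region_labels optional region labels overriding column names.
#' @param subject_id,session_index optional back-references.
#' @return A `connectivity_network`.
#' @details Requires T >= 3 and nonzero variance in every column; a
#'   zero-variance column makes the correlation undefined and is an error
#'   naming the region. Series with fewer timepoints than regions are
#'   allowed (each pairwise correlation is still defined) but trigger a
#'   rank-deficiency warning.
#' @export
pearson_connectivity <- function(ts, region_labels = NULL,
                                 subject_id = NA_character_,
                                 session_index = NA_integer_) {
  if (inherits(ts, "roi_timeseries")) {
    if (is.null(region_labels)) region_labels <- ts$region_labels
    if (is.na(subject_id)) subject_id <- ts$subject_id
    if (is.na(session_index)) session_index <- ts$session_index
    ts <- ts$series
  }
  ts <- as.matrix(ts)
  if (!is.numeric(ts)) stop("time series must be numeric")
  if (anyNA(ts)) stop("time series contains missing values")
  Tn <- nrow(ts); k <- ncol(ts)
  if (Tn < 3L) stop("need at least 3 timepoints, got ", Tn)
  if (is.null(region_labels)) {
    region_labels <- colnames(ts)
    if (is.null(region_labels)) region_labels <- as.character(seq_len(k))
  }
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region(s): ",
         paste(region_labels[sds == 0], collapse = ", "),
         " (correlation undefined)")
  if (Tn < k)
    warning("fewer timepoints (", Tn, ") than regions (", k,
            "): correlation matrix is rank deficient")
  r <- stats::cor(ts)
  r <- (r + t(r)) / 2          # enforce exact symmetry
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  connectivity_network(r, region_labels, subject_id, session_index)
}

#' Flatten a network's upper triangle into an edge vector
#'
#' Position p of the output holds n_ij for the p-th entry of the edge
#' index; [devectorize_edges()] restores the upper triangle exactly.
#'
#' @param net a `connectivity_network`, or a bare symmetric matrix.
#' @param index optional `edge_index(k)` data frame; validated against the
#'   network's node count.
#' @return numeric vector of length k(k-1)/2, named `i-j` by region label.
#' @export
vectorize_edges <- function(net, index = NULL) {
  e <- if (inherits(net, "connectivity_network")) net$edges else as.matrix(net)
  k <- nrow(e)
  if (is.null(index)) index <- edge_index(k)
  if (max(index$j) > k || nrow(index) != n_edges(k))
    stop("edge index does not match a ", k, "-node network")
  v <- e[cbind(index$i, index$j)]
  labs <- rownames(e)
  if (!is.null(labs)) names(v) <- paste(labs[index$i], labs[index$j], sep = "-")
  v
}

#' Rebuild a symmetric network matrix from a flat edge vector
#'
#' Inverse of [vectorize_edges()]: entries are placed back at (i, j) and
#' (j, i); the diagonal is set to `diag_value` (1, the self-correlation,
#' by default).
#'
#' @param v flat edge vector of length k(k-1)/2.
#' @param region_labels optional labels for the k nodes.
#' @param diag_value value for the (non-feature) diagonal.
#' @return a `connectivity_network`.
#' @export
devectorize_edges <- function(v, region_labels = NULL, diag_value = 1) {
  k <- nodes_from_edges(length(v))
  idx <- edge_index(k)
  m <- matrix(diag_value * 1.0, k, k)
  m[cbind(idx$i, idx$j)] <- v
  m[cbind(idx$j, idx$i)] <- v
  connectivity_network(m, region_labels, check = FALSE)
}

#' Fisher z-transform of a connectivity network
#'
#' Elementwise atanh of the off-diagonal correlations; monotone and
#' sign-preserving. Off by default in the pipeline, which uses raw
#' Pearson r as features; the transform is available for variance
#' stabilization.
#'
#' @param net a `connectivity_network` of raw correlations.
#' @return a `connectivity_network` with attribute `transform = "fisher_z"`;
#'   the diagonal (atanh(1) is infinite, and the diagonal is never a
#'   feature) is set to `NA`.
#' @export
fisher_z <- function(net) {
  stopifnot(inherits(net, "connectivity_network"))
  e <- net$edges
  off <- e[row(e) != col(e)]
  if (any(abs(off) >= 1))
    stop("|r| = 1 on an off-diagonal edge: Fisher z is infinite")
  z <- atanh(e)
  diag(z) <- NA_real_
  out <- connectivity_network(z, net$region_labels, net$subject_id,
                              net$session_index, check = FALSE)
  attr(out, "transform") <- "fisher_z"
  validate_network(out)
  out
}

#' @export
print.connectivity_network <- function(x, ...) {
  k <- length(x$region_labels)
  cat("connectivity_network: ", k, " regions, ", n_edges(k), " edges",
      if (!is.null(attr(x, "transform"))) " (Fisher-z)", "\n", sep = "")
  if (!is.na(x$subject_id))
    cat("  subject ", x$subject_id, ", session ", x$session_index, "\n",
        sep = "")
  invisible(x)
}
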