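# Weighted global graph metrics on normalized connectivity matrices.
# Clustering uses the geometric-mean (Onnela-style) triangle intensity;
# path length converts weights to lengths by reciprocal and averages
# all-pairs shortest path distances; the small-world index normalizes each
# band's CC and PL by the mean over the other bands before taking their
# ratio.

#' Min-max normalize a connectivity stack
#'
#' Rescales all off-diagonal values of all epochs in the stack jointly to
#' span exactly `[0, 1]` (the minimum maps to 0, the maximum to 1), so
#' weighted graphs are comparable across participants despite differences
#' in absolute connectivity level. The diagonal stays 0.
#'
#' @param stack epochs x channels x channels array (a `connectivity_stack`
#'   or plain array).
#' @return the rescaled stack, same shape and attributes.
#' @export
normalize_stack <- function(stack) {
  d <- dim(stack)
  if (length(d) == 2L) {
    stack <- array(stack, dim = c(1L, d))
    d <- dim(stack)
  }
  stopifnot(length(d) == 3L, d[2] == d[3])
  off <- !diag(TRUE, d[2])
  vals <- apply(stack, 1, function(m) m[off])
  lo <- min(vals); hi <- max(vals)
  if (hi - lo <= 0) {
    stop("degenerate stack: all off-diagonal values identical, cannot rescale",
         call. = FALSE)
  }
  at <- attributes(stack)
  out <- (stack - lo) / (hi - lo)
  for (e in seq_len(d[1])) {
    m <- out[e, , ]
    diag(m) <- 0
    out[e, , ] <- m
  }
  attributes(out) <- at
  out
}

#' Global weighted clustering coefficient
#'
#' Per-node clustering is the geometric-mean triangle intensity
#' `C_i = (W^(1/3))^3_ii / (k_i (k_i - 1))` with `k_i` the number of
#' nonzero neighbors; nodes with fewer than two neighbors contribute 0.
#' The global value is the mean over nodes.
#'
#' @param w symmetric channels x channels weight matrix in `[0, 1]`, zero
#'   diagonal.
#' @return global CC (dimensionless, in `[0, 1]` for weights in `[0, 1]`).
#' @examples
#' w <- matrix(0.5, 3, 3); diag(w) <- 0
#' clustering_coefficient(w)   # 0.5
#' @export
clustering_coefficient <- function(w) {
  w <- check_weight_matrix(w)
  n <- nrow(w)
  k <- rowSums(w > 0)
  w3 <- w^(1 / 3)
  t3 <- diag(w3 %*% w3 %*% w3)
  ci <- ifelse(k >= 2, t3 / (k * (k - 1)), 0)
  mean(ci)
}

#' Global characteristic path length
#'
#' Edge lengths are reciprocal weights (`1/w`, absent for `w = 0`);
#' all-pairs shortest paths are computed by Dijkstra's algorithm and
#' averaged over all ordered node pairs.
#'
#' @param w symmetric weight matrix, zero diagonal.
#' @return global PL (dimensionless, > 0).
#' @examples
#' w <- matrix(1, 3, 3); diag(w) <- 0
#' path_length(w)   # 1
#' @export
path_length <- function(w) {
  w <- check_weight_matrix(w)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  dmat <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                            algorithm = "dijkstra")
  off <- !diag(TRUE, nrow(w))
  if (any(!is.finite(dmat[off]))) {
    bad <- which(!is.finite(dmat) & off, arr.ind = TRUE)
    stop(sprintf("graph is disconnected: %d unreachable pairs (e.g. %d-%d)",
                 nrow(bad) / 2, bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  mean(dmat[off])
}

check_weight_matrix <- function(w) {
  w <- as.matrix(w)
  if (nrow(w) < 2L || nrow(w) != ncol(w)) {
    stop("weight matrix must be square with >= 2 nodes", call. = FALSE)
  }
  if (max(abs(w - t(w))) > 1e-9) {
    stop("weight matrix must be symmetric", call. = FALSE)
  }
  if (any(w < 0)) stop("weights must be >= 0", call. = FALSE)
  diag(w) <- 0
  w
}

#' Small-world index with leave-one-band-out normalization
#'
#' For each band b, CC and PL are normalized by the mean of the values of
#' the other bands (`normCC_b = CC_b / mean(CC_{b' != b})`, likewise PL),
#' and `SWI_b = normCC_b / normPL_b`. Invariant under joint rescaling of
#' all CC values, and separately of all PL values.
#'
#' @param cc_by_band,pl_by_band named numeric vectors over the same bands
#'   (>= 2 bands, all positive).
#' @return named vector of per-band SWI values.
#' @examples
#' small_world_index(c(a = 2, b = 1, c = 1), c(a = 1, b = 1, c = 1))
#' @export
small_world_index <- function(cc_by_band, pl_by_band) {
  if (length(cc_by_band) < 2L || length(cc_by_band) != length(pl_by_band)) {
    stop("need CC and PL for at least 2 bands", call. = FALSE)
  }
  if (any(cc_by_band <= 0) || any(pl_by_band <= 0)) {
    stop("CC and PL must be positive for SWI normalization", call. = FALSE)
  }
  n <- length(cc_by_band)
  swi <- vapply(seq_len(n), function(b) {
    ncc <- cc_by_band[b] / mean(cc_by_band[-b])
    npl <- pl_by_band[b] / mean(pl_by_band[-b])
    ncc / npl
  }, numeric(1))
  names(swi) <- names(cc_by_band)
  swi
}

#' Per-epoch global metrics of a normalized stack
#'
#' @param stack epochs x channels x channels array of weight matrices.
#' @return list with per-epoch `cc` and `pl` vectors.
#' @export
stack_graph_metrics <- function(stack) {
  d <- dim(stack)
  stopifnot(length(d) == 3L)
  cc <- numeric(d[1]); pl <- numeric(d[1])
  for (e in seq_len(d[1])) {
    w <- stack[e, , ]
    cc[e] <- clustering_coefficient(w)
    pl[e] <- path_length(w)
  }
  list(cc = cc, pl = pl)
}

#' Aggregate per-epoch graph values
#'
#' CC and PL are arithmetic means of per-epoch global values; the
#' small-world index is computed afterwards from the epoch-averaged CC and
#' PL (see [small_world_index()]), not averaged per epoch.
#'
#' @param metrics a list with `cc` and `pl` vectors as returned by
#'   [stack_graph_metrics()].
#' @return list with scalar `cc` and `pl`.
#' @export
aggregate_epochs <- function(metrics) {
  stopifnot(is.list(metrics), length(metrics$cc) >= 1L,
            length(metrics$cc) == length(metrics$pl))
  list(cc = mean(metrics$cc), pl = mean(metrics$pl))
}

#' Global graph outcomes for one recording
#'
#' Runs epoching, connectivity estimation, per-stack min-max normalization,
#' per-epoch graph metrics and epoch aggregation, then the cross-band SWI,
#' for every requested estimator and band.
#'
#' @param rec an [recording()].
#' @param bands named list of [band()] objects.
#' @param estimators subset of `c("wpli", "coh")`.
#' @param epoch_length,overlap,max_epochs epoching parameters (seconds,
#'   seconds, count).
#' @param segment_length,segment_overlap,window spectral parameters, see
#'   [cross_spectra()].
#' @param aggregate_matrices if `TRUE`, average the normalized matrices
#'   over epochs and compute one graph per stack instead of per-epoch
#'   graphs (sensitivity-analysis variant).
#' @return data frame with one row per estimator x band: participant,
#'   session, condition, estimator, band, CC, PL, SWI.
#' @export
graph_outcomes <- function(rec, bands = default_bands(),
                           estimators = c("wpli", "coh"),
                           epoch_length = 8, overlap = 4, max_epochs = 50,
                           segment_length = NULL, segment_overlap = 0.5,
                           window = "hann", aggregate_matrices = FALSE) {
  estimators <- match.arg(estimators, c("wpli", "coh"), several.ok = TRUE)
  ep <- epoch_signal(rec, epoch_length, overlap, max_epochs)
  stacks <- connectivity_stacks(ep, bands, estimators,
                                segment_length, segment_overlap, window)
  rows <- list()
  for (est in estimators) {
    cc <- pl <- stats::setNames(numeric(length(bands)), names(bands))
    for (b in names(bands)) {
      st <- normalize_stack(stacks[[paste(est, b, sep = ".")]])
      if (aggregate_matrices) {
        wbar <- apply(st, c(2, 3), mean)
        agg <- list(cc = clustering_coefficient(wbar),
                    pl = path_length(wbar))
      } else {
        agg <- aggregate_epochs(stack_graph_metrics(st))
      }
      cc[b] <- agg$cc; pl[b] <- agg$pl
    }
    swi <- small_world_index(cc, pl)
    rows[[est]] <- data.frame(
      participant = rec$participant_id,
      session = rec$session_id,
      condition = rec$condition,
      estimator = est,
      band = names(bands),
      CC = unname(cc), PL = unname(pl), SWI = unname(swi),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
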