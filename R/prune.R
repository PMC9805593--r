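#' Threshold CLR scores into an initial network
#'
#' @param z symmetric non-negative CLR score matrix from [clr_scores()].
#' @param lambda0 initial threshold; an edge is kept where `z > lambda0`
#'   (strict).
#' @return An object of class `network_state`: list with `adjacency`
#'   (symmetric logical, zero diagonal), `scores` (the CLR matrix, carried
#'   forward as edge weights) and `trace` (per-edge pruning record,
#'   initially empty).
#' @export
initial_network <- function(z, lambda0) {
  if (!is.matrix(z) || nrow(z) != ncol(z))
    stop("'z' must be a square matrix", call. = FALSE)
  if (length(lambda0) != 1L || !is.finite(lambda0) || lambda0 < 0)
    stop("'lambda0' must be a single value >= 0", call. = FALSE)
  adj <- z > lambda0
  diag(adj) <- FALSE
  adj <- adj & t(adj)
  structure(list(adjacency = adj, scores = z, trace = empty_trace()),
            class = "network_state")
}

empty_trace <- function() {
  data.frame(gene_a = character(), gene_b = character(), order = integer(),
             order_max = integer(), m = numeric(), threshold = numeric(),
             max_cmi2 = numeric(), decision = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.network_state <- function(x, ...) {
  cat("Network state:", nrow(x$adjacency), "genes,",
      sum(x$adjacency[upper.tri(x$adjacency)]), "edges,",
      nrow(x$trace), "trace records\n")
  invisible(x)
}

#' Common neighbours of an edge
#'
#' All genes adjacent to both endpoints, in ascending index order.
#'
#' @param state a `network_state`.
#' @param i,j endpoint indices of a present edge.
#' @return Integer vector of neighbour indices (possibly empty).
#' @export
common_neighbors <- function(state, i, j) {
  adj <- state$adjacency
  nb <- which(adj[i, ] & adj[j, ])
  setdiff(nb, c(i, j))
}

#' Dynamic CMI2 pruning threshold
#'
#' The deletion threshold at a given conditioning order scales with the
#' number of candidate conditioning subsets m = C(order_max, order): the
#' more indirect paths could explain an edge, the stricter the test.
#'
#' @param alpha base threshold (defaults to the initial threshold lambda0
#'   in the pipeline).
#' @param order conditioning-set size, `1 <= order <= order_max`.
#' @param order_max number of common neighbours of the edge.
#' @param mode `"linear_m"` (default) returns `alpha * m`; `"constant"`
#'   returns `alpha`; `"log_m"` returns `alpha * (1 + log(m))`.
#' @return The threshold, non-decreasing in m for the default mode.
#' @export
order_threshold <- function(alpha, order, order_max,
                            mode = c("linear_m", "constant", "log_m")) {
  mode <- match.arg(mode)
  if (order < 1 || order > order_max)
    stop("'order' must lie in 1..order_max", call. = FALSE)
  m <- choose(order_max, order)
  switch(mode,
         linear_m = alpha * m,
         constant = alpha,
         log_m = alpha * (1 + log(m)))
}

#' One order of the multi-order pruning loop
#'
#' Visits every edge of the current network in ascending lexicographic
#' (i, j) order. For each edge the common neighbours are found
#' (Order_Max); if fewer than `order`, the edge is skipped (retained).
#' Otherwise the maximal CMI2 over all C(Order_Max, order) conditioning
#' subsets is computed from the gene-gene sample covariance; if it falls
#' below [order_threshold()], the edge (and its mirror) is deleted. Under
#' the default asynchronous update, deletions take effect immediately, so
#' later edges see the thinned neighbourhoods; `update = "sync"` computes
#' every decision against the pass-start adjacency and applies them
#' together. Every evaluated edge is appended to the trace.
#'
#' @param state a `network_state`.
#' @param expr samples-by-genes matrix the network was inferred from.
#' @param order conditioning-set size for this pass, >= 1.
#' @param alpha base threshold for [order_threshold()].
#' @param threshold_mode passed to [order_threshold()].
#' @param cmi2_mode `"inclusive"` or `"plain"` (see [cmi2()]).
#' @param update `"async"` (default) or `"sync"`.
#' @param cov optional precomputed covariance of `expr` (internal reuse).
#' @return The updated `network_state`.
#' @export
prune_pass <- function(state, expr, order, alpha,
                       threshold_mode = c("linear_m", "constant", "log_m"),
                       cmi2_mode = c("inclusive", "plain"),
                       update = c("async", "sync"), cov = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  cmi2_mode <- match.arg(cmi2_mode)
  update <- match.arg(update)
  if (order < 1) stop("'order' must be >= 1", call. = FALSE)
  expr <- as_expression_matrix(expr)
  if (is.null(cov)) cov <- repair_cov(stats::cov(expr))
  inclusive <- cmi2_mode == "inclusive"
  genes <- colnames(expr)

  adj0 <- state$adjacency
  edges <- which(upper.tri(adj0) & adj0, arr.ind = TRUE)
  edges <- edges[base::order(edges[, 1], edges[, 2]), , drop = FALSE]
  adj <- adj0
  ref <- function() if (update == "async") adj else adj0
  rec <- vector("list", nrow(edges))
  deleted <- logical(nrow(edges))

  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    nb <- which(ref()[i, ] & ref()[j, ])
    nb <- setdiff(nb, c(i, j))
    om <- length(nb)
    if (om < order) {
      rec[[e]] <- list(gene_a = genes[i], gene_b = genes[j],
                       order = order, order_max = om, m = 0,
                       threshold = NA_real_, max_cmi2 = NA_real_,
                       decision = "skipped")
      next
    }
    m <- choose(om, order)
    if (m > 10000)
      warning(sprintf("edge %s-%s: %g conditioning subsets at order %d",
                      genes[i], genes[j], m, order), call. = FALSE)
    thr <- order_threshold(alpha, order, om, threshold_mode)
    mx <- max_cmi2_cpp(cov, i, j, as.integer(nb), as.integer(order),
                       inclusive)
    kill <- mx < thr
    if (kill && update == "async") {
      adj[i, j] <- adj[j, i] <- FALSE
    }
    deleted[e] <- kill
    rec[[e]] <- list(gene_a = genes[i], gene_b = genes[j],
                     order = order, order_max = om, m = m,
                     threshold = thr, max_cmi2 = mx,
                     decision = if (kill) "deleted" else "retained")
  }
  if (update == "sync" && any(deleted)) {
    for (e in which(deleted)) {
      adj[edges[e, 1], edges[e, 2]] <- FALSE
      adj[edges[e, 2], edges[e, 1]] <- FALSE
    }
  }
  state$adjacency <- adj
  if (length(rec))
    state$trace <- rbind(state$trace,
                         do.call(rbind.data.frame,
                                 c(rec, stringsAsFactors = FALSE)))
  state
}
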