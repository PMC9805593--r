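#' Infer a gene regulatory network from steady-state expression
#'
#' The full pipeline: (1) pairwise mutual information by the mixed
#' (shrinkage-bridged Bayes) entropy estimator on `bins` discretization
#' cells; (2) per-gene CLR standardization into likelihood scores Z_ij;
#' (3) an initial network from `Z_ij > lambda0`; (4) multi-order pruning —
#' for each conditioning order 1..`order_set`, every surviving edge is
#' tested against the maximal Gaussian CMI2 over all conditioning subsets
#' drawn from its common neighbours, and deleted when that maximum falls
#' below the dynamically scaled threshold. The final score of a surviving
#' edge is its Z_ij; pruned pairs score 0.
#'
#' `lambda0` trades density for precision: the useful range is roughly
#' 1e-6 to 1e-2, smaller for smaller gene sets (1e-6 works well up to a
#' few hundred genes). `alpha` defaults to `lambda0`, giving the single
#' tuning parameter the pipeline is usually driven by.
#'
#' @param x samples-by-genes numeric matrix; column names are the gene
#'   identifiers (see [read_expression()]).
#' @param bins discretization cells per gene (default 5).
#' @param order_set cap on the conditioning order (default 2); 0 skips
#'   pruning entirely.
#' @param lambda0 initial CLR-score threshold (default 1e-3).
#' @param alpha base CMI2 threshold; defaults to `lambda0`.
#' @param threshold_mode threshold scaling with the subset count, see
#'   [order_threshold()].
#' @param clr_combine,clr_sd CLR options, see [clr_scores()].
#' @param cmi2_mode `"inclusive"` (default) or `"plain"`, see [cmi2()].
#' @param update `"async"` (default) or `"sync"` pruning update, see
#'   [prune_pass()].
#' @param support entropy support convention, see [mixed_entropy()].
#' @return An object of class `meomi`: list with `edges` (ranked
#'   data.frame gene_a/gene_b/score/rank of surviving edges), `adjacency`,
#'   `scores` (final masked scores), `z`, `mi`, `trace`, `genes`,
#'   `n_samples`, `config` and `call`. Methods: [print.meomi()],
#'   [summary.meomi()], [coef.meomi()], [plot.meomi()].
#' @examples
#' net <- generate_topology(3, "chain", seed = 1)
#' expr <- simulate_expression(net, n_samples = 300, seed = 2)
#' fit <- meomi(expr, lambda0 = 1e-3, alpha = 0.02)
#' fit$edges
#' @export
meomi <- function(x, bins = 5, order_set = 2, lambda0 = 1e-3,
                  alpha = lambda0,
                  threshold_mode = c("linear_m", "constant", "log_m"),
                  clr_combine = c("sqrt", "sumsq"),
                  clr_sd = c("population", "sample"),
                  cmi2_mode = c("inclusive", "plain"),
                  update = c("async", "sync"),
                  support = c("declared", "occupied")) {
  threshold_mode <- match.arg(threshold_mode)
  clr_combine <- match.arg(clr_combine)
  clr_sd <- match.arg(clr_sd)
  cmi2_mode <- match.arg(cmi2_mode)
  update <- match.arg(update)
  support <- match.arg(support)
  if (order_set < 0 || order_set != round(order_set))
    stop("'order_set' must be a non-negative integer", call. = FALSE)
  x <- as_expression_matrix(x, min_genes = 3L)
  cfg <- list(bins = check_bins(bins), order_set = as.integer(order_set),
              lambda0 = lambda0, alpha = alpha,
              threshold_mode = threshold_mode, clr_combine = clr_combine,
              clr_sd = clr_sd, cmi2_mode = cmi2_mode, update = update,
              support = support)

  mi <- mi_matrix(x, bins = cfg$bins, support = support)
  z <- clr_scores(mi, combine = clr_combine, sd = clr_sd)
  state <- initial_network(z, lambda0)
  if (order_set >= 1) {
    covx <- repair_cov(stats::cov(x))
    for (ord in seq_len(cfg$order_set)) {
      if (!any(state$adjacency)) break
      state <- prune_pass(state, x, order = ord, alpha = alpha,
                          threshold_mode = threshold_mode,
                          cmi2_mode = cmi2_mode, update = update,
                          cov = covx)
    }
  }
  scores <- z
  scores[!state$adjacency] <- 0
  diag(scores) <- 0

  structure(list(edges = ranked_edges(scores, state$adjacency),
                 adjacency = state$adjacency, scores = scores,
                 z = z, mi = mi, trace = state$trace,
                 genes = colnames(x), n_samples = nrow(x),
                 config = cfg, call = match.call()),
            class = "meomi")
}

# ranked edge table from a masked symmetric score matrix; deterministic
# tie-break by identifier pair
ranked_edges <- function(scores, adjacency) {
  idx <- which(upper.tri(adjacency) & adjacency, arr.ind = TRUE)
  genes <- colnames(adjacency)
  if (is.null(genes)) genes <- paste0("G", seq_len(ncol(adjacency)))
  df <- data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                   score = scores[idx], stringsAsFactors = FALSE)
  df <- df[base::order(-df$score, df$gene_a, df$gene_b), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' @export
print.meomi <- function(x, ...) {
  cat("Mixed-entropy CLR/CMI2 network\n")
  cat(sprintf("  %d genes, %d samples; bins = %d, order_set = %d, lambda0 = %g, alpha = %g\n",
              length(x$genes), x$n_samples, x$config$bins,
              x$config$order_set, x$config$lambda0, x$config$alpha))
  initial <- sum(x$z > x$config$lambda0 & upper.tri(x$z))
  cat(sprintf("  edges: %d surviving of %d initial (%d pruned)\n",
              nrow(x$edges), initial, initial - nrow(x$edges)))
  invisible(x)
}

#' Summarize a fitted network
#'
#' @param object a `meomi` fit.
#' @param n_top number of top-ranked edges to display.
#' @param ... unused.
#' @export
summary.meomi <- function(object, n_top = 10, ...) {
  tr <- object$trace
  by_order <- if (nrow(tr)) {
    stats::aggregate(cbind(deleted = tr$decision == "deleted",
                           retained = tr$decision == "retained",
                           skipped = tr$decision == "skipped"),
                     by = list(order = tr$order), FUN = sum)
  } else {
    data.frame(order = integer(), deleted = integer(),
               retained = integer(), skipped = integer())
  }
  structure(list(fit = object, by_order = by_order,
                 top = utils::head(object$edges, n_top)),
            class = "summary.meomi")
}

#' @export
print.summary.meomi <- function(x, ...) {
  print(x$fit)
  if (nrow(x$by_order)) {
    cat("  pruning by order:\n")
    print(x$by_order, row.names = FALSE)
  }
  if (nrow(x$top)) {
    cat("  top edges:\n")
    print(x$top, row.names = FALSE)
  }
  invisible(x)
}

#' Edge scores of a fitted network
#'
#' @param object a `meomi` fit.
#' @param ... unused.
#' @return Named numeric vector of surviving edge scores
#'   (`"geneA~geneB"`), in rank order.
#' @export
coef.meomi <- function(object, ...) {
  stats::setNames(object$edges$score,
                  paste(object$edges$gene_a, object$edges$gene_b,
                        sep = "~"))
}

#' Plot a fitted network
#'
#' Draws the surviving undirected network with edge widths proportional
#' to the CLR score.
#'
#' @param x a `meomi` fit.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.meomi <- function(x, ...) {
  g <- igraph::graph_from_adjacency_matrix(
    x$adjacency * 1, mode = "undirected", diag = FALSE)
  w <- x$scores[igraph::as_edgelist(g, names = FALSE)]
  igraph::plot.igraph(
    g, edge.width = 0.5 + 2.5 * w / max(w, 1e-12), ...)
  invisible(x)
}
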