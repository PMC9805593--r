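#' Generate a ground-truth regulatory topology
#'
#' Directed acyclic topologies with edges oriented from lower to higher
#' gene index: the canonical three-gene motifs (`chain` 1->2->3 — a chain
#' of any length is accepted; `fork` 2->1, 2->3; `collider` 1->2<-3), an
#' Erdos-Renyi random DAG (`param` = edge probability) or a scale-free
#' (preferential-attachment) skeleton (`param` = edges added per gene,
#' default 1). Edge coefficients are drawn uniformly from
#' +/-\[0.5, 1.5\] — the magnitude floor keeps every true edge
#' detectable — and each gene receives unit-variance Gaussian noise.
#'
#' @param n_genes number of genes, >= 3.
#' @param model one of `"chain"`, `"fork"`, `"collider"`,
#'   `"erdos_renyi"`, `"scale_free"`.
#' @param param model parameter (edge probability / attachment count);
#'   ignored for the motifs.
#' @param seed integer seed; all randomness is drawn from it.
#' @return An object of class `synthetic_network`: list with `genes`,
#'   `edges` (data.frame from/to/weight), `coef` (genes-by-genes weight
#'   matrix, `coef[p, g]` the effect of p on g), `noise_sd`, `skeleton`
#'   (symmetric logical gold-standard adjacency), `model`, `seed`.
#' @export
generate_topology <- function(n_genes,
                              model = c("chain", "fork", "collider",
                                        "erdos_renyi", "scale_free"),
                              param = NULL, seed = NULL) {
  model <- match.arg(model)
  if (n_genes < 3) stop("'n_genes' must be >= 3", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pairs <- switch(model,
    chain = cbind(seq_len(n_genes - 1L), seq.int(2L, n_genes)),
    fork = {
      if (n_genes != 3) stop("'fork' is a 3-gene motif", call. = FALSE)
      cbind(c(2L, 2L), c(1L, 3L))
    },
    collider = {
      if (n_genes != 3) stop("'collider' is a 3-gene motif", call. = FALSE)
      cbind(c(1L, 3L), c(2L, 2L))
    },
    erdos_renyi = {
      if (is.null(param) || param <= 0 || param > 1)
        stop("'param' must be an edge probability in (0, 1]",
             call. = FALSE)
      all_ij <- which(upper.tri(diag(n_genes)), arr.ind = TRUE)
      all_ij <- all_ij[base::order(all_ij[, 1], all_ij[, 2]), ,
                       drop = FALSE]
      all_ij[stats::runif(nrow(all_ij)) < param, , drop = FALSE]
    },
    scale_free = {
      m <- if (is.null(param)) 1L else as.integer(param)
      if (m < 1) stop("'param' must be a positive attachment count",
                      call. = FALSE)
      g <- igraph::sample_pa(n_genes, power = 1, m = m, directed = TRUE)
      el <- igraph::as_edgelist(g, names = FALSE)
      cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    })
  pairs <- unique(pairs)
  genes <- sprintf("G%d", seq_len(n_genes))
  W <- matrix(0, n_genes, n_genes, dimnames = list(genes, genes))
  nE <- nrow(pairs)
  w <- if (nE) stats::runif(nE, 0.5, 1.5) *
                 sample(c(-1, 1), nE, replace = TRUE) else numeric()
  W[pairs] <- w
  skel <- (W != 0) | t(W != 0)
  structure(list(genes = genes,
                 edges = data.frame(from = genes[pairs[, 1]],
                                    to = genes[pairs[, 2]],
                                    weight = w,
                                    stringsAsFactors = FALSE),
                 coef = W, noise_sd = rep(1, n_genes),
                 skeleton = skel, model = model, seed = seed),
            class = "synthetic_network")
}

#' @export
print.synthetic_network <- function(x, ...) {
  cat("Synthetic", x$model, "network:", length(x$genes), "genes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Gold standard of a synthetic network
#'
#' The undirected skeleton of the generating topology as a
#' [gold_standard()] in complement mode.
#'
#' @param net a `synthetic_network`.
#' @return A `gold_standard` object.
#' @export
network_gold <- function(net) {
  stopifnot(inherits(net, "synthetic_network"))
  gold_standard(net$edges[, c("from", "to")], genes = net$genes)
}

#' Simulate steady-state expression from a topology
#'
#' Linear-Gaussian structural equations evaluated in topological order
#' (edges point low -> high index): x_g = sum over parents p of
#' coef\[p, g\] x_p + noise_sd\[g\] * eps, eps ~ N(0, 1).
#'
#' @param net a `synthetic_network`.
#' @param n_samples number of samples, >= 3.
#' @param seed integer seed.
#' @return Samples-by-genes numeric matrix with gene column names.
#' @export
simulate_expression <- function(net, n_samples, seed = NULL) {
  stopifnot(inherits(net, "synthetic_network"))
  if (n_samples < 3) stop("'n_samples' must be >= 3", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  G <- length(net$genes)
  x <- matrix(stats::rnorm(n_samples * G), n_samples, G) *
    rep(net$noise_sd, each = n_samples)
  for (g in seq_len(G)) {
    parents <- which(net$coef[, g] != 0)
    if (length(parents))
      x[, g] <- x[, g] + x[, parents, drop = FALSE] %*% net$coef[parents, g]
  }
  colnames(x) <- net$genes
  x
}

#' Analytic covariance of a synthetic network
#'
#' The exact population covariance of the structural equations: with
#' weight matrix W (`coef`) and noise variances D, the sample row vector
#' satisfies x = eps (I - W)^-1, so Sigma = (I - W)^-T D (I - W)^-1 —
#' the ground-truth Gaussian system for conditional-independence oracles.
#'
#' @param net a `synthetic_network`.
#' @return A [gaussian_system()] over the genes.
#' @export
analytic_covariance <- function(net) {
  stopifnot(inherits(net, "synthetic_network"))
  G <- length(net$genes)
  M <- solve(diag(G) - net$coef)          # x = eps %*% M
  Sigma <- t(M) %*% diag(net$noise_sd^2, G) %*% M
  gaussian_system(Sigma, labels = net$genes)
}
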