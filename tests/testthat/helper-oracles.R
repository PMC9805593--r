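# Independent oracles used across the suite. Everything here deliberately
# avoids the package's own closed-form code paths: densities come from the
# multivariate normal density evaluated directly, integrals from trapezoid
# grids, entropies from Monte-Carlo posterior sampling, and network pruning
# from a plain re-implementation of the traversal.

# log multivariate normal density, via Cholesky
log_dmvn <- function(x, mu, Sigma) {
  if (is.null(dim(x))) x <- matrix(x, ncol = length(mu))
  R <- chol(Sigma)
  xc <- sweep(x, 2, mu)
  q <- colSums(forwardsolve(t(R), t(xc))^2)
  -0.5 * (ncol(x) * log(2 * pi) + 2 * sum(log(diag(R))) + q)
}

trap_weights <- function(g) {
  h <- g[2] - g[1]
  w <- rep(h, length(g))
  w[c(1, length(g))] <- h / 2
  w
}

# Numerical evaluation of the symmetrized interference KL divergence:
# 0.5 * ( KL(theta || theta_{x->y}) + KL(theta || theta_{y->x}) ), each KL
# integrated on a trapezoid grid over all variables, with the interference
# conditional q(y|z) itself obtained by 1-D quadrature of
# theta(x',y,z) * theta(x') / theta(x',z) over x'. Only marginal Gaussian
# densities are used; no closed-form KL or conditional-variance algebra.
oracle_cmi2 <- function(sys, x, y, S = integer(), ngrid = NULL,
                        span = 6, ninner = NULL) {
  v <- c(x, y, S)
  d <- length(v)
  if (is.null(ngrid)) ngrid <- c(61, 45, 29)[d - 1]
  if (is.null(ninner)) ninner <- if (d >= 4) 101 else 161
  mu <- sys$mean[v]
  Sg <- sys$cov[v, v, drop = FALSE]
  sds <- sqrt(diag(Sg))
  grids <- lapply(seq_len(d), function(k)
    seq(mu[k] - span * sds[k], mu[k] + span * sds[k], length.out = ngrid))
  wts <- lapply(grids, trap_weights)

  # directed KL: theta vs interference of variable `b` given z, breaking `a`
  kl_directed <- function(a, b) {
    zidx <- seq_len(d)[-c(a, b)]
    # q(b | z) on the (b, z) subgrid by inner quadrature over a'
    xg <- seq(mu[a] - (span + 2) * sds[a], mu[a] + (span + 2) * sds[a],
              length.out = ninner)
    xw <- trap_weights(xg)
    sub <- as.matrix(expand.grid(c(list(grids[[b]]), grids[zidx]),
                                 KEEP.OUT.ATTRS = FALSE))
    nsub <- nrow(sub)
    lq <- numeric(nsub)
    la <- log_dmvn(matrix(xg, ncol = 1), mu[a], Sg[a, a, drop = FALSE])
    chunk <- max(1L, floor(4e5 / ninner))
    for (lo in seq(1L, nsub, by = chunk)) {
      hi <- min(lo + chunk - 1L, nsub)
      rows <- hi - lo + 1L
      pts <- cbind(rep(xg, rows),
                   sub[rep(seq.int(lo, hi), each = ninner), ,
                       drop = FALSE])
      l3 <- log_dmvn(pts, mu[c(a, b, zidx)],
                     Sg[c(a, b, zidx), c(a, b, zidx), drop = FALSE])
      l2 <- log_dmvn(pts[, -2, drop = FALSE], mu[c(a, zidx)],
                     Sg[c(a, zidx), c(a, zidx), drop = FALSE])
      integ <- matrix(xw * exp(l3 + la - l2), nrow = ninner)
      lq[lo:hi] <- log(colSums(integ))
    }
    # outer integral over the full grid
    full <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
    idxg <- expand.grid(lapply(seq_len(d), function(k) seq_len(ngrid)),
                        KEEP.OUT.ATTRS = FALSE)
    w_full <- Reduce(`*`, lapply(seq_len(d),
                                 function(k) wts[[k]][idxg[[k]]]))
    lth <- log_dmvn(as.matrix(full), mu, Sg)
    # conditional log theta(b | a, z) = log theta(all) - log theta(a, z)
    laz <- log_dmvn(as.matrix(full[, -b, drop = FALSE]),
                    mu[-b], Sg[-b, -b, drop = FALSE])
    # map each outer point to its (b, z) subgrid row
    key_sub <- do.call(paste, c(idxg[c(b, zidx)], sep = "\r"))
    sub_idx <- expand.grid(lapply(c(b, zidx), function(k) seq_len(ngrid)),
                           KEEP.OUT.ATTRS = FALSE)
    key_ref <- do.call(paste, c(sub_idx, sep = "\r"))
    lq_full <- lq[match(key_sub, key_ref)]
    sum(w_full * exp(lth) * (lth - laz - lq_full))
  }
  0.5 * (kl_directed(1, 2) + kl_directed(2, 1))
}

# Monte-Carlo posterior-expected plug-in entropy for Dirichlet(counts + a)
mc_bayes_entropy <- function(counts, a, ndraw = 2e5) {
  nt <- counts + a
  g <- matrix(stats::rgamma(length(nt) * ndraw, shape = nt),
              nrow = length(nt))
  p <- sweep(g, 2, colSums(g), "/")
  lp <- ifelse(p > 0, log(p), 0)
  H <- -colSums(p * lp)
  list(mean = mean(H), se = stats::sd(H) / sqrt(ndraw))
}

# plain re-implementation of one pruning pass: same visit order, subsets
# enumerated with combn, thresholds recomputed literally, CMI2 through the
# public R code path (cmi2_from_data), not the compiled kernel
brute_prune_pass <- function(adj, expr, order, alpha,
                             mode = "linear_m", cmi2_mode = "inclusive",
                             update = "async") {
  adj0 <- adj
  edges <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  edges <- edges[base::order(edges[, 1], edges[, 2]), , drop = FALSE]
  kill_later <- NULL
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    ref <- if (update == "async") adj else adj0
    nb <- setdiff(which(ref[i, ] & ref[j, ]), c(i, j))
    om <- length(nb)
    if (om < order) next
    m <- choose(om, order)
    thr <- switch(mode, linear_m = alpha * m, constant = alpha,
                  log_m = alpha * (1 + log(m)))
    subsets <- if (length(nb) == 1) matrix(nb, 1, 1)
               else utils::combn(nb, order)
    mx <- max(apply(subsets, 2, function(s)
      cmi2_from_data(expr, i, j, s, mode = cmi2_mode)$total))
    if (mx < thr) {
      if (update == "async") {
        adj[i, j] <- adj[j, i] <- FALSE
      } else {
        kill_later <- rbind(kill_later, c(i, j))
      }
    }
  }
  if (!is.null(kill_later))
    for (r in seq_len(nrow(kill_later))) {
      adj[kill_later[r, 1], kill_later[r, 2]] <- FALSE
      adj[kill_later[r, 2], kill_later[r, 1]] <- FALSE
    }
  adj
}

# concordance-count AUROC with half credit for ties
brute_auroc <- function(scores, labels) {
  sp <- scores[labels]
  sn <- scores[!labels]
  conc <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(conc)
}

# histogram recount with explicit interval tests (right-closed top cell)
brute_histogram <- function(values, bins) {
  br <- seq(min(values), max(values), length.out = bins + 1)
  vapply(seq_len(bins), function(k) {
    if (k < bins) sum(values >= br[k] & values < br[k + 1])
    else sum(values >= br[k] & values <= br[k + 1])
  }, numeric(1))
}

rand_pd_cov <- function(d) {
  A <- matrix(stats::rnorm(d * d), d)
  S <- crossprod(A) + diag(d) * 0.5
  # rescale to unit-ish variances so grids are well conditioned
  Dm <- diag(1 / sqrt(diag(S)), d)
  Dm %*% S %*% Dm
}
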