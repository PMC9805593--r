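#' Discretize a continuous series into equal-width bins
#'
#' Splits the range of `values` into `bins` equal-width cells and counts
#' occupancies. The top cell is right-closed so the maximum falls into the
#' last bin; a constant series puts all mass into the first cell, so an
#' all-flat gene has zero entropy (and zero mutual information with
#' everything) rather than raising an error.
#'
#' @param values numeric vector, finite, non-empty.
#' @param bins integer number of cells, at least 2.
#' @return An object of class `binned_counts`: a list with `counts`
#'   (integer occupancy per cell), `n` (sample count) and `K` (declared
#'   number of cells, which may exceed the number of occupied cells).
#' @examples
#' bin_series(c(0, 1, 2, 3), bins = 2)$counts  # 2 2
#' @export
bin_series <- function(values, bins) {
  if (length(values) == 0L) stop("'values' must be non-empty", call. = FALSE)
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("'values' must be finite numeric", call. = FALSE)
  bins <- check_bins(bins)
  idx <- bin_index(values, bins)
  binned_counts(tabulate(idx, nbins = bins), K = bins)
}

# cell index in 1..bins; equal width over [min, max], max mapped to top cell,
# degenerate range -> cell 1
bin_index <- function(values, bins) {
  lo <- min(values)
  hi <- max(values)
  if (hi == lo) return(rep(1L, length(values)))
  idx <- floor((values - lo) / (hi - lo) * bins) + 1L
  pmin(as.integer(idx), bins)
}

check_bins <- function(bins) {
  if (length(bins) != 1L || !is.finite(bins) || bins < 2 || bins != round(bins))
    stop("'bins' must be a single integer >= 2", call. = FALSE)
  as.integer(bins)
}

#' Construct a binned-counts object
#'
#' @param counts non-negative integer vector of cell occupancies.
#' @param K declared support size; defaults to `length(counts)`. May exceed
#'   the number of occupied cells (trailing empty cells are implicit when
#'   `K > length(counts)` is disallowed: pad `counts` instead).
#' @return A `binned_counts` object.
#' @export
binned_counts <- function(counts, K = length(counts)) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be non-negative integers", call. = FALSE)
  if (K < length(counts))
    stop("'K' cannot be smaller than length(counts)", call. = FALSE)
  counts <- c(as.numeric(counts), numeric(K - length(counts)))
  n <- sum(counts)
  if (n < 1) stop("at least one observation required", call. = FALSE)
  structure(list(counts = counts, n = n, K = as.integer(K)),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat("Binned counts: n =", x$n, ", K =", x$K, "\n")
  print(x$counts)
  invisible(x)
}

as_binned_counts <- function(b) {
  if (inherits(b, "binned_counts")) return(b)
  if (is.numeric(b)) return(binned_counts(b))
  stop("expected a 'binned_counts' object or a counts vector", call. = FALSE)
}

#' Maximum-likelihood cell probabilities
#'
#' The plug-in multinomial estimate theta_k = n_k / n.
#'
#' @param b a `binned_counts` object (or a raw counts vector).
#' @return Numeric probability vector summing to 1.
#' @export
ml_probabilities <- function(b) {
  b <- as_binned_counts(b)
  b$counts / b$n
}

#' James-Stein shrinkage intensity for multinomial probabilities
#'
#' The mean-squared-error-minimizing weight for shrinking the ML cell
#' probabilities towards a target distribution:
#' lambda = (1 - sum(theta^2)) / ((n - 1) * sum((theta - t)^2)),
#' clipped to \[0, 1\]. When the ML estimate already equals the target the
#' denominator vanishes and full shrinkage (lambda = 1) is returned — a
#' no-op; a single observation (n = 1) likewise returns 1, as the variance
#' term is undefined and the target is the only usable estimate.
#'
#' @param b a `binned_counts` object.
#' @param target shrinkage target distribution over the K cells; defaults
#'   to uniform 1/K (the maximum-entropy target).
#' @return Shrinkage intensity in \[0, 1\].
#' @examples
#' shrinkage_lambda(binned_counts(c(2, 2, 0, 0)))  # 2/3
#' @export
shrinkage_lambda <- function(b, target = NULL) {
  b <- as_binned_counts(b)
  target <- check_target(target, b$K)
  if (b$n == 1) return(1)
  theta <- b$counts / b$n
  num <- 1 - sum(theta^2)
  den <- (b$n - 1) * sum((theta - target)^2)
  if (den == 0) return(1)
  min(max(num / den, 0), 1)
}

check_target <- function(target, K) {
  if (is.null(target)) return(rep(1 / K, K))
  if (length(target) != K)
    stop("'target' must have length K = ", K, call. = FALSE)
  if (any(target < 0) || abs(sum(target) - 1) > 1e-8)
    stop("'target' must be a probability distribution", call. = FALSE)
  target
}

#' James-Stein shrinkage cell probabilities
#'
#' Convex combination lambda * t + (1 - lambda) * theta_ML with the
#' risk-minimizing lambda from [shrinkage_lambda()]. At lambda >= 1 the
#' output is exactly the target.
#'
#' @inheritParams shrinkage_lambda
#' @return A list with `theta` (the shrunken probability vector) and
#'   `shrinkage`, itself a list holding `lambda_hat`, `target`, the
#'   equivalent Dirichlet per-cell pseudocount `prior_a` and total prior
#'   mass `prior_mass_m = K * prior_a` (see [prior_from_lambda()]).
#' @examples
#' js_probabilities(binned_counts(c(2, 2, 0, 0)))$theta  # 1/3 1/3 1/6 1/6
#' @export
js_probabilities <- function(b, target = NULL) {
  b <- as_binned_counts(b)
  target <- check_target(target, b$K)
  lam <- shrinkage_lambda(b, target)
  theta <- if (lam >= 1) target else lam * target + (1 - lam) * b$counts / b$n
  a <- prior_from_lambda(lam, b$n, b$K)
  list(theta = theta,
       shrinkage = list(lambda_hat = lam, target = target,
                        prior_a = a, prior_mass_m = b$K * a))
}

#' Map shrinkage intensity to a Dirichlet pseudocount
#'
#' The bridge between the shrinkage and Bayes estimators: the per-cell
#' pseudocount `a` for which the Dirichlet posterior mean
#' (n_k + a) / (n + K a) coincides termwise with the James-Stein estimate
#' lambda/K + (1 - lambda) n_k/n under a uniform target, namely
#' a = n * lambda / (K * (1 - lambda)). Full shrinkage (lambda = 1)
#' corresponds to an infinite prior and returns `Inf`, which
#' [bayes_entropy()] resolves to the uniform-distribution entropy log(K);
#' lambda = 0 gives a = 0 (pure ML).
#'
#' @param lambda_hat shrinkage intensity in \[0, 1\].
#' @param n sample count.
#' @param K support size.
#' @return Per-cell Dirichlet parameter a >= 0 (possibly `Inf`).
#' @examples
#' prior_from_lambda(2 / 3, n = 4, K = 4)  # 2
#' @export
prior_from_lambda <- function(lambda_hat, n, K) {
  if (length(lambda_hat) != 1L || is.na(lambda_hat) ||
      lambda_hat < 0 || lambda_hat > 1)
    stop("'lambda_hat' must lie in [0, 1]", call. = FALSE)
  if (lambda_hat == 1) return(Inf)
  n * lambda_hat / (K * (1 - lambda_hat))
}

#' Dirichlet-prior Bayes entropy estimator
#'
#' Posterior-expected Shannon entropy under a symmetric Dirichlet(a) prior:
#' with posterior counts ntilde_k = n_k + a and total N = n + K a,
#' H = psi(N + 1) - sum_k (ntilde_k / N) psi(ntilde_k + 1), in nats.
#' `a = Inf` (the full-shrinkage limit) returns log(K).
#'
#' @param b a `binned_counts` object.
#' @param a per-cell Dirichlet pseudocount, >= 0.
#' @return Entropy in nats, in \[0, log(K)\].
#' @examples
#' bayes_entropy(binned_counts(c(2, 2)), a = 1)  # psi(7) - psi(4) = 37/60
#' @export
bayes_entropy <- function(b, a) {
  b <- as_binned_counts(b)
  if (length(a) != 1L || is.na(a) || a < 0)
    stop("'a' must be a single value >= 0", call. = FALSE)
  if (is.infinite(a)) return(log(b$K))
  nt <- b$counts + a
  N <- b$n + b$K * a
  if (N == 0) stop("empty posterior (no counts and a = 0)", call. = FALSE)
  # nt = 0 cells contribute 0 to the occupancy-weighted sum
  occ <- nt > 0
  H <- digamma(N + 1) - sum((nt[occ] / N) * digamma(nt[occ] + 1))
  max(H, 0)
}

#' Mixed (shrinkage-bridged Bayes) entropy estimator
#'
#' The package's working entropy estimator: estimate the James-Stein
#' shrinkage intensity against the uniform target, convert it to the
#' equivalent Dirichlet pseudocount via [prior_from_lambda()], and return
#' the posterior-expected entropy [bayes_entropy()]. Full shrinkage
#' (lambda = 1, e.g. exactly uniform counts) returns log(K).
#'
#' @param b a `binned_counts` object.
#' @param support `"declared"` (default) uses the declared K cells, so the
#'   uniform target lives on a fixed support; `"occupied"` restricts to
#'   cells with positive counts (sensitivity analysis only).
#' @param prior optional fixed per-cell pseudocount overriding the
#'   shrinkage bridge (e.g. 0, 1/2, 1, 1/K, n/K).
#' @param unit `"nats"` (natural log, default) or `"bits"`.
#' @return Entropy in the requested unit.
#' @examples
#' mixed_entropy(binned_counts(c(2, 2, 0, 0)))  # about 1.21432 nats
#' @export
mixed_entropy <- function(b, support = c("declared", "occupied"),
                          prior = NULL, unit = c("nats", "bits")) {
  b <- as_binned_counts(b)
  support <- match.arg(support)
  unit <- match.arg(unit)
  if (support == "occupied") {
    keep <- b$counts > 0
    b <- binned_counts(b$counts[keep], K = sum(keep))
  }
  a <- if (is.null(prior)) {
    prior_from_lambda(shrinkage_lambda(b), b$n, b$K)
  } else {
    prior
  }
  H <- bayes_entropy(b, a)
  if (unit == "bits") H / log(2) else H
}
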