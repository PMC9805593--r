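#' Context likelihood of relatedness (CLR) scores
#'
#' Standardizes each gene's mutual-information profile against its own
#' empirical background and combines the per-gene components per pair.
#' For gene i, mu_i and sigma_i are the mean and standard deviation of
#' \{I(X_i; X_j) : j != i\}; the i-component of pair (i, j) is
#' max(0, (I_ij - mu_i) / sigma_i) (0 when sigma_i = 0), and the pair
#' score is Z_ij = sqrt(Z_i^2 + Z_j^2).
#'
#' @param mim symmetric mutual-information matrix from [mi_matrix()],
#'   at least 3 genes (the per-gene background needs two or more values).
#' @param combine `"sqrt"` (default) combines components as
#'   sqrt(Z_i^2 + Z_j^2); `"sumsq"` keeps the plain sum of squares
#'   Z_i^2 + Z_j^2 (same ranking, different scale — relevant because the
#'   initial network threshold is applied to Z values).
#' @param sd `"population"` (default, divide by N) or `"sample"`
#'   (divide by N - 1) standard deviation for the background.
#' @return Symmetric non-negative matrix of CLR scores with zero diagonal.
#' @examples
#' m <- matrix(c(0, 4, 2, 4, 0, 2, 2, 2, 0), 3, 3)
#' clr_scores(m)[1, 2]  # sqrt(2)
#' @export
clr_scores <- function(mim, combine = c("sqrt", "sumsq"),
                       sd = c("population", "sample")) {
  combine <- match.arg(combine)
  sd <- match.arg(sd)
  if (!is.matrix(mim) || nrow(mim) != ncol(mim))
    stop("'mim' must be a square matrix", call. = FALSE)
  G <- nrow(mim)
  if (G < 3) stop("CLR needs at least 3 genes", call. = FALSE)
  if (max(abs(mim - t(mim))) > 1e-12)
    stop("'mim' must be symmetric", call. = FALSE)
  z <- matrix(0, G, G, dimnames = dimnames(mim))
  for (i in seq_len(G)) {
    v <- mim[i, -i]
    mu <- mean(v)
    s2 <- mean((v - mu)^2)
    if (sd == "sample") s2 <- s2 * length(v) / (length(v) - 1)
    sig <- sqrt(s2)
    if (sig > 0) z[i, -i] <- pmax(0, (v - mu) / sig)
  }
  zz <- z^2 + t(z)^2
  out <- if (combine == "sqrt") sqrt(zz) else zz
  diag(out) <- 0
  out
}
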