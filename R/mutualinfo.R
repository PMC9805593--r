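#' Joint discretization of two series
#'
#' Bins each series with [bin_series()]'s equal-width rule and counts the
#' flattened (row-major in the first series) 2-D table over `bins^2` cells.
#' Marginal sums of the table reproduce the two 1-D binnings.
#'
#' @param x,y numeric vectors of equal length.
#' @param bins number of cells per axis.
#' @return A `binned_counts` object with `K = bins^2`.
#' @export
joint_bin <- function(x, y, bins) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same length", call. = FALSE)
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite numeric", call. = FALSE)
  bins <- check_bins(bins)
  idx <- (bin_index(x, bins) - 1L) * bins + bin_index(y, bins)
  binned_counts(tabulate(idx, nbins = bins^2), K = bins^2)
}

#' Mutual information between two expression profiles
#'
#' I(X;Y) = H(X) + H(Y) - H(X,Y) with every entropy term computed by the
#' mixed estimator [mixed_entropy()] on its own support (the joint term
#' re-derives its own shrinkage intensity on the `bins^2` cells). Because
#' the three estimators shrink independently the difference can come out
#' slightly negative; it is clipped at 0 since downstream CLR scoring and
#' thresholding assume non-negative association.
#'
#' @inheritParams joint_bin
#' @param ... passed on to [mixed_entropy()] (`support`, `prior`).
#' @return Mutual information in nats, >= 0; symmetric in its arguments.
#' @export
mutual_information <- function(x, y, bins = 5, ...) {
  hx <- mixed_entropy(bin_series(x, bins), ...)
  hy <- mixed_entropy(bin_series(y, bins), ...)
  hxy <- mixed_entropy(joint_bin(x, y, bins), ...)
  max(0, hx + hy - hxy)
}

#' Mutual information matrix of an expression matrix
#'
#' Computes [mutual_information()] for every unordered gene pair and
#' mirrors the result into a symmetric genes-by-genes matrix. The diagonal
#' is set to 0: the CLR background distribution for gene i is formed from
#' its MI to *other* genes only.
#'
#' @param expr samples-by-genes numeric matrix with unique column names
#'   (see [read_expression()]), at least 3 samples and 2 genes.
#' @param bins number of discretization cells per gene (default 5).
#' @param ... passed on to [mixed_entropy()].
#' @return Symmetric non-negative matrix with zero diagonal, dimnames the
#'   gene identifiers, and attribute `bins`.
#' @export
mi_matrix <- function(expr, bins = 5, ...) {
  expr <- as_expression_matrix(expr)
  bins <- check_bins(bins)
  G <- ncol(expr)
  idx <- lapply(seq_len(G), function(g) bin_index(expr[, g], bins))
  hm <- vapply(idx, function(i) {
    mixed_entropy(binned_counts(tabulate(i, nbins = bins), K = bins), ...)
  }, numeric(1))
  mi <- matrix(0, G, G, dimnames = list(colnames(expr), colnames(expr)))
  for (i in seq_len(G - 1L)) {
    for (j in seq.int(i + 1L, G)) {
      joint <- binned_counts(
        tabulate((idx[[i]] - 1L) * bins + idx[[j]], nbins = bins^2),
        K = bins^2)
      v <- max(0, hm[i] + hm[j] - mixed_entropy(joint, ...))
      mi[i, j] <- v
      mi[j, i] <- v
    }
  }
  attr(mi, "bins") <- bins
  mi
}

# validate / coerce a samples x genes matrix
as_expression_matrix <- function(expr, min_samples = 3L, min_genes = 2L) {
  expr <- as.matrix(expr)
  if (!is.numeric(expr) || anyNA(expr) || !all(is.finite(expr)))
    stop("expression matrix must be finite numeric with no missing values",
         call. = FALSE)
  if (nrow(expr) < min_samples || ncol(expr) < min_genes)
    stop("need at least ", min_samples, " samples and ", min_genes,
         " genes", call. = FALSE)
  if (is.null(colnames(expr)))
    colnames(expr) <- paste0("G", seq_len(ncol(expr)))
  if (anyDuplicated(colnames(expr)))
    stop("duplicate gene identifiers: ",
         paste(unique(colnames(expr)[duplicated(colnames(expr))]),
               collapse = ", "), call. = FALSE)
  expr
}
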