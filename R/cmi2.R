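#' Construct a multivariate Gaussian system
#'
#' A mean vector and covariance matrix over a set of labelled variables;
#' the object on which the Gaussian CMI and CMI2 closed forms operate.
#' The covariance is symmetrized and checked for (near) positive
#' semidefiniteness; near-singular covariances are ridge-repaired (adding
#' `1e-8 * trace / d` to the diagonal) before any inversion, with a
#' warning of class `meomi_ridge_repair`.
#'
#' @param cov symmetric positive-semidefinite covariance matrix.
#' @param mean mean vector (defaults to zero; MI-type quantities do not
#'   depend on it).
#' @param labels variable identifiers; default from `cov` dimnames.
#' @return An object of class `gaussian_system`.
#' @export
gaussian_system <- function(cov, mean = NULL, labels = NULL) {
  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov))
    stop("'cov' must be square", call. = FALSE)
  if (max(abs(cov - t(cov))) > 1e-10)
    stop("'cov' must be symmetric (tolerance 1e-10)", call. = FALSE)
  cov <- (cov + t(cov)) / 2
  d <- nrow(cov)
  if (is.null(mean)) mean <- numeric(d)
  if (length(mean) != d) stop("'mean' has wrong length", call. = FALSE)
  if (is.null(labels)) {
    labels <- if (!is.null(colnames(cov))) colnames(cov)
              else paste0("V", seq_len(d))
  }
  cov <- repair_cov(cov)
  dimnames(cov) <- list(labels, labels)
  structure(list(mean = as.numeric(mean), cov = cov, labels = labels),
            class = "gaussian_system")
}

#' @export
print.gaussian_system <- function(x, ...) {
  cat("Gaussian system over", length(x$labels), "variables:",
      paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

# ridge-repair a covariance that fails a Cholesky / conditioning test
repair_cov <- function(M) {
  ok <- tryCatch({ chol(M); rcond(M) > 1e-10 }, error = function(e) FALSE)
  if (!ok) {
    ridge <- 1e-8 * sum(diag(M)) / nrow(M)
    M <- M + diag(ridge, nrow(M))
    warning(structure(
      class = c("meomi_ridge_repair", "warning", "condition"),
      list(message = sprintf("near-singular covariance: ridge %.3e added",
                             ridge),
           call = NULL)))
  }
  M
}

resolve_index <- function(sys, i) {
  if (is.character(i)) {
    m <- match(i, sys$labels)
    if (anyNA(m)) stop("unknown variable: ",
                       paste(i[is.na(m)], collapse = ", "), call. = FALSE)
    return(m)
  }
  as.integer(i)
}

subdet <- function(S, idx) {
  if (length(idx) == 0L) return(1)
  det(S[idx, idx, drop = FALSE])
}

#' Gaussian conditional mutual information
#'
#' Closed-form I(X;Y|S) for jointly Gaussian variables:
#' 0.5 * log( det(Sigma_xS) * det(Sigma_yS) / (det(Sigma_S) * det(Sigma_xyS)) ),
#' with det(Sigma_empty) = 1. Tiny negative values from finite-precision
#' determinants are clipped at 0.
#'
#' @param sys a [gaussian_system()].
#' @param x,y variable indices (or labels), distinct and not in `S`.
#' @param S conditioning index set (possibly empty).
#' @return Conditional mutual information in nats, >= 0.
#' @examples
#' sys <- gaussian_system(matrix(c(1, .8, .8, 1), 2))
#' gaussian_cmi(sys, 1, 2)  # -0.5 * log(1 - 0.64)
#' @export
gaussian_cmi <- function(sys, x, y, S = integer()) {
  idx <- check_cmi_args(sys, x, y, S)
  Sg <- sys$cov
  num <- subdet(Sg, c(idx$x, idx$S)) * subdet(Sg, c(idx$y, idx$S))
  den <- subdet(Sg, idx$S) * subdet(Sg, c(idx$x, idx$y, idx$S))
  if (!is.finite(num) || !is.finite(den) || num <= 0 || den <= 0)
    stop("singular covariance submatrix for variables {",
         paste(sys$labels[c(idx$x, idx$y, idx$S)], collapse = ", "), "}",
         call. = FALSE)
  max(0, 0.5 * log(num / den))
}

check_cmi_args <- function(sys, x, y, S) {
  if (!inherits(sys, "gaussian_system"))
    stop("'sys' must be a gaussian_system", call. = FALSE)
  x <- resolve_index(sys, x); y <- resolve_index(sys, y)
  S <- if (length(S)) resolve_index(sys, S) else integer()
  if (x == y) stop("'x' and 'y' must be distinct", call. = FALSE)
  if (x %in% S || y %in% S)
    stop("'x' and 'y' must not appear in the conditioning set",
         call. = FALSE)
  d <- nrow(sys$cov)
  if (any(c(x, y, S) < 1) || any(c(x, y, S) > d))
    stop("variable index out of range", call. = FALSE)
  list(x = x, y = y, S = S)
}

#' Interference (interventional) conditional of Y given Z
#'
#' The Gaussian law of Y given Z = z when the X–Z association is broken:
#' q(y | z) = integral of theta(y | x, z) theta(x) dx, integrating the
#' observational conditional of Y against the *marginal* of X. With
#' theta(y|x,z) mean a x + b'z + c and X-marginal mean mu_x, variance
#' sigma_x^2, the result is Gaussian with mean a mu_x + b'z + c and
#' variance sigma^2_(y|x,z) + a^2 sigma_x^2 — a conditional family
#' indexed by z, returned as its coefficients.
#'
#' @inheritParams gaussian_cmi
#' @param x the variable intervened upon; `y` the response.
#' @return A list of class `interference_conditional` with `intercept`,
#'   `coef` (named slope on the conditioning variables) and `var`.
#' @export
interference_conditional <- function(sys, x, y, S = integer()) {
  idx <- check_cmi_args(sys, x, y, S)
  Sg <- sys$cov
  mu <- sys$mean
  w <- c(idx$x, idx$S)
  A <- Sg[w, w, drop = FALSE]
  beta <- tryCatch(solve(A, Sg[w, idx$y]),
                   error = function(e)
                     stop("singular covariance submatrix for variables {",
                          paste(sys$labels[w], collapse = ", "), "}",
                          call. = FALSE))
  a <- beta[1L]
  b <- beta[-1L]
  s2 <- Sg[idx$y, idx$y] - sum(Sg[idx$y, w] * beta)
  # theta(y|x,z) has intercept mu_y - a mu_x - b'mu_z; the intervention
  # plugs E[x] = mu_x back in, leaving mu_y - b'mu_z
  intercept <- unname(mu[idx$y] - sum(b * mu[idx$S]))
  structure(list(intercept = intercept,
                 coef = stats::setNames(unname(b), sys$labels[idx$S]),
                 var = unname(s2 + a^2 * Sg[idx$x, idx$x]),
                 response = sys$labels[idx$y],
                 given = sys$labels[idx$S]),
            class = "interference_conditional")
}

#' @export
print.interference_conditional <- function(x, ...) {
  cat("Interference conditional of", x$response,
      if (length(x$given)) paste("given", paste(x$given, collapse = ", "))
      else "(marginal)", "\n")
  cat("  mean:", format(x$intercept, digits = 6),
      if (length(x$coef)) paste("+",
        paste(sprintf("%.6g*%s", x$coef, names(x$coef)), collapse = " + "))
      else "", "\n")
  cat("  variance:", format(x$var, digits = 6), "\n")
  invisible(x)
}

# closed-form E_z KL( theta(y|z) || q_{x->y}(y|z) ) for a Gaussian system;
# returns 0 for empty S (the interference marginal equals the marginal).
kl_interference <- function(Sg, x, y, S) {
  if (length(S) == 0L) return(0)
  Szz <- Sg[S, S, drop = FALSE]
  syy <- Sg[y, y]
  alpha <- solve(Szz, Sg[S, y])
  v1 <- syy - sum(Sg[y, S] * alpha)
  w <- c(x, S)
  beta <- solve(Sg[w, w, drop = FALSE], Sg[w, y])
  a <- beta[1L]
  b <- beta[-1L]
  s2 <- syy - sum(Sg[y, w] * beta)
  v2 <- s2 + a^2 * Sg[x, x]
  if (v1 <= 0 || v2 <= 0)
    stop("singular conditional variance in KL term", call. = FALSE)
  d <- alpha - b
  quad <- as.numeric(t(d) %*% Szz %*% d)
  max(0, 0.5 * (log(v2 / v1) + v1 / v2 + quad / v2 - 1))
}

#' Conditional mutual inclusive information (Gaussian closed form)
#'
#' CMI2(X;Y|S) = I(X;Y|S)
#'   + 0.5 * E_z KL( theta(Y|z) || q_{X->Y}(Y|z) )
#'   + 0.5 * E_z KL( theta(X|z) || q_{Y->X}(X|z) ),
#' the symmetrized KL divergence between the observed joint and the two
#' interference joints, equal to the average of the two directed causal
#' intensities. For jointly Gaussian variables every term is closed-form:
#' the conditionals are Gaussian with means linear in z, so the
#' expectation over z of each KL divergence collapses to a
#' log-variance-ratio plus a quadratic form in the regression-coefficient
#' difference. Unlike plain conditional MI, the KL corrections keep
#' direct interactions from being underestimated when X and Y share
#' strong conditioners.
#'
#' @inheritParams gaussian_cmi
#' @param mode `"inclusive"` (default) adds the interference KL terms;
#'   `"plain"` reduces to ordinary Gaussian conditional MI (both KL parts
#'   reported as 0).
#' @return An object of class `cmi2` — a list with `total`, `cmi`,
#'   `kl_xy`, `kl_yx` (all in nats, all >= 0, and
#'   `total = cmi + (kl_xy + kl_yx) / 2`).
#' @examples
#' chain <- gaussian_system(matrix(c(1, 1, 1, 1, 2, 2, 1, 2, 3), 3),
#'                          labels = c("X", "Z", "Y"))
#' cmi2(chain, "X", "Y", "Z")$total  # 0: X and Y independent given Z
#' @export
cmi2 <- function(sys, x, y, S = integer(),
                 mode = c("inclusive", "plain")) {
  mode <- match.arg(mode)
  idx <- check_cmi_args(sys, x, y, S)
  ci <- gaussian_cmi(sys, idx$x, idx$y, idx$S)
  if (mode == "plain") {
    kxy <- kyx <- 0
  } else {
    kxy <- kl_interference(sys$cov, idx$x, idx$y, idx$S)
    kyx <- kl_interference(sys$cov, idx$y, idx$x, idx$S)
  }
  structure(list(total = ci + (kxy + kyx) / 2,
                 cmi = ci, kl_xy = kxy, kl_yx = kyx,
                 x = sys$labels[idx$x], y = sys$labels[idx$y],
                 S = sys$labels[idx$S], mode = mode),
            class = "cmi2")
}

#' @export
print.cmi2 <- function(x, ...) {
  cat(sprintf("CMI2(%s; %s | {%s}) = %.6g nats\n", x$x, x$y,
              paste(x$S, collapse = ", "), x$total))
  cat(sprintf("  conditional MI: %.6g   KL %s->%s: %.6g   KL %s->%s: %.6g\n",
              x$cmi, x$x, x$y, x$kl_xy, x$y, x$x, x$kl_yx))
  invisible(x)
}

#' CMI2 from expression data
#'
#' Fits a [gaussian_system()] to the sample mean and sample covariance
#' (denominator n - 1) of the selected gene columns, then evaluates
#' [cmi2()].
#'
#' @param expr samples-by-genes numeric matrix.
#' @param i,j gene indices or names, distinct.
#' @param S conditioning gene index set; needs `length(S) + 2` to be
#'   smaller than the number of samples.
#' @inheritParams cmi2
#' @return A `cmi2` object.
#' @export
cmi2_from_data <- function(expr, i, j, S = integer(),
                           mode = c("inclusive", "plain")) {
  expr <- as_expression_matrix(expr)
  if (length(S) + 2 >= nrow(expr))
    stop("conditioning set too large for the number of samples",
         call. = FALSE)
  cols <- c(resolve_cols(expr, i), resolve_cols(expr, j),
            if (length(S)) resolve_cols(expr, S) else integer())
  sub <- expr[, cols, drop = FALSE]
  V <- stats::cov(sub)
  if (anyNA(V) || !all(is.finite(V)))
    stop("non-finite covariance", call. = FALSE)
  sys <- gaussian_system(V, mean = colMeans(sub), labels = colnames(sub))
  cmi2(sys, 1L, 2L, if (length(S)) seq.int(3L, 2L + length(S)) else integer(),
       mode = mode)
}

resolve_cols <- function(expr, i) {
  if (is.character(i)) {
    m <- match(i, colnames(expr))
    if (anyNA(m)) stop("unknown gene: ",
                       paste(i[is.na(m)], collapse = ", "), call. = FALSE)
    return(m)
  }
  as.integer(i)
}
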