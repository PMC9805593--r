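pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Construct a gold-standard edge set
#'
#' An undirected reference network: a set of positive gene pairs, an
#' optional explicit set of negative pairs (the DREAM edge-list dialect
#' lists 0-labelled rows), and the gene universe.
#'
#' @param positives two-column matrix or data.frame of gene pairs.
#' @param negatives optional two-column structure of explicit negatives.
#' @param genes gene universe; defaults to the identifiers seen in the
#'   pair lists.
#' @return An object of class `gold_standard`.
#' @export
gold_standard <- function(positives, negatives = NULL, genes = NULL) {
  as_pairs <- function(p, what) {
    if (is.null(p) || NROW(p) == 0)
      return(data.frame(a = character(), b = character()))
    p <- as.data.frame(p, stringsAsFactors = FALSE)
    a <- as.character(p[[1]]); b <- as.character(p[[2]])
    if (any(a == b)) stop("self-pair in ", what, call. = FALSE)
    data.frame(a = a, b = b, stringsAsFactors = FALSE)
  }
  pos <- as_pairs(positives, "positives")
  neg <- as_pairs(negatives, "negatives")
  pk <- unique(pair_key(pos$a, pos$b))
  nk <- unique(pair_key(neg$a, neg$b))
  if (length(intersect(pk, nk)))
    stop("pairs labelled both positive and negative", call. = FALSE)
  if (is.null(genes)) genes <- sort(unique(c(pos$a, pos$b, neg$a, neg$b)))
  structure(list(positives = pk, negatives = nk,
                 genes = as.character(genes)),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("Gold standard:", length(x$positives), "positive pairs,",
      length(x$negatives), "explicit negatives,",
      length(x$genes), "genes\n")
  invisible(x)
}

# extract surviving edge keys + gene set from a prediction
pred_edges <- function(pred) {
  if (inherits(pred, "meomi"))
    return(list(keys = pair_key(pred$edges$gene_a, pred$edges$gene_b),
                genes = pred$genes))
  if (inherits(pred, "network_state")) {
    genes <- colnames(pred$adjacency)
    idx <- which(upper.tri(pred$adjacency) & pred$adjacency,
                 arr.ind = TRUE)
    return(list(keys = pair_key(genes[idx[, 1]], genes[idx[, 2]]),
                genes = genes))
  }
  if (is.matrix(pred)) {
    genes <- colnames(pred)
    adj <- (pred != 0)
    idx <- which(upper.tri(adj) & adj, arr.ind = TRUE)
    return(list(keys = pair_key(genes[idx[, 1]], genes[idx[, 2]]),
                genes = genes))
  }
  stop("unsupported prediction object", call. = FALSE)
}

align_universe <- function(pg, gg) {
  miss_pred <- setdiff(gg, pg)
  miss_gold <- setdiff(pg, gg)
  if (length(miss_pred) || length(miss_gold))
    stop("gene universes differ; missing from prediction: {",
         paste(miss_pred, collapse = ", "), "}; missing from gold: {",
         paste(miss_gold, collapse = ", "), "}", call. = FALSE)
  invisible(TRUE)
}

#' Confusion counts against a gold standard
#'
#' Undirected comparison of a predicted edge set with the reference.
#' With `universe = "all"` (complement mode) every unordered gene pair is
#' evaluated and pairs absent from the positive list count as negatives;
#' `universe = "listed"` restricts to pairs explicitly listed in the gold
#' standard (DREAM dialect with 0-rows).
#'
#' @param pred a `meomi` fit, `network_state`, or symmetric adjacency /
#'   score matrix (non-zero = edge) with gene dimnames.
#' @param gold a [gold_standard()].
#' @param universe `"all"` or `"listed"`.
#' @return List with counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(pred, gold, universe = c("all", "listed")) {
  universe <- match.arg(universe)
  stopifnot(inherits(gold, "gold_standard"))
  pe <- pred_edges(pred)
  align_universe(pe$genes, gold$genes)
  G <- length(gold$genes)
  if (universe == "all") {
    tp <- sum(pe$keys %in% gold$positives)
    fp <- length(pe$keys) - tp
    fn <- length(gold$positives) - tp
    tn <- choose(G, 2) - tp - fp - fn
  } else {
    listed <- c(gold$positives, gold$negatives)
    keys <- pe$keys[pe$keys %in% listed]
    tp <- sum(keys %in% gold$positives)
    fp <- sum(keys %in% gold$negatives)
    fn <- length(gold$positives) - tp
    tn <- length(gold$negatives) - fp
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Scalar classification metrics from confusion counts
#'
#' TPR = tp/(tp+fn); FPR = fp/(fp+tn); PPV = tp/(tp+fp); ACC =
#' (tp+tn)/total; F1 = 2 PPV TPR/(PPV+TPR); MCC =
#' (tp tn - fp fn)/sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)). Undefined ratios
#' (zero denominators) follow the 0-convention.
#'
#' @param counts list with `tp`, `fp`, `tn`, `fn` (see [confusion()]).
#' @return List of the counts plus `tpr`, `fpr`, `ppv`, `acc`, `f1`,
#'   `mcc`.
#' @export
scalar_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (any(c(tp, fp, tn, fn) < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (tp + fn == 0 || fp + tn == 0)
    stop("need at least one positive and one negative", call. = FALSE)
  rate <- function(num, den) if (den == 0) 0 else num / den
  tpr <- rate(tp, tp + fn)
  fpr <- rate(fp, fp + tn)
  ppv <- rate(tp, tp + fp)
  acc <- (tp + tn) / (tp + fp + tn + fn)
  f1 <- if (ppv + tpr == 0) 0 else 2 * ppv * tpr / (ppv + tpr)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  c(counts, list(tpr = tpr, fpr = fpr, ppv = ppv, acc = acc,
                 f1 = f1, mcc = mcc))
}

#' Ranking metrics (AUPR, AUROC) from a score matrix
#'
#' AUROC is the tie-corrected concordance probability computed from
#' ranks; AUPR integrates the precision-recall curve stepwise through the
#' unique score thresholds in descending order, with tied scores handled
#' as a single block (step, not trapezoid, interpolation).
#'
#' @param scores symmetric finite score matrix with gene dimnames.
#' @param gold a [gold_standard()].
#' @param universe `"all"` or `"listed"` (see [confusion()]).
#' @return List with `aupr` and `auroc`.
#' @export
ranking_curves <- function(scores, gold, universe = c("all", "listed")) {
  universe <- match.arg(universe)
  stopifnot(inherits(gold, "gold_standard"))
  if (!is.matrix(scores) || !all(is.finite(scores)))
    stop("'scores' must be a finite matrix", call. = FALSE)
  genes <- colnames(scores)
  align_universe(genes, gold$genes)
  idx <- which(upper.tri(scores), arr.ind = TRUE)
  keys <- pair_key(genes[idx[, 1]], genes[idx[, 2]])
  s <- scores[upper.tri(scores)]
  y <- keys %in% gold$positives
  if (universe == "listed") {
    keep <- keys %in% c(gold$positives, gold$negatives)
    s <- s[keep]; y <- y[keep]
  }
  P <- sum(y); N <- sum(!y)
  if (P == 0 || N == 0)
    stop("need at least one positive and one negative pair", call. = FALSE)
  if (length(unique(s)) == 1L) {
    warning("all scores identical; AUROC = 0.5 by convention",
            call. = FALSE)
    return(list(aupr = P / (P + N), auroc = 0.5))
  }
  r <- rank(s)                      # midranks: tie-corrected concordance
  auroc <- (sum(r[y]) - P * (P + 1) / 2) / (P * N)
  o <- base::order(s, decreasing = TRUE)
  s <- s[o]; y <- y[o]
  block_last <- which(diff(s) != 0)
  cut <- c(block_last, length(s))   # end of each tie block
  tp <- cumsum(y)[cut]
  n_pred <- cut
  recall <- tp / P
  precision <- tp / n_pred
  list(aupr = sum(diff(c(0, recall)) * precision), auroc = auroc)
}

#' Evaluate a predicted network against a gold standard
#'
#' Combines [confusion()], [scalar_metrics()] and [ranking_curves()] into
#' one report.
#'
#' @param pred a `meomi` fit or adjacency/score matrix.
#' @param gold a [gold_standard()].
#' @param scores optional score matrix for the ranking metrics; defaults
#'   to the fit's final scores (or `pred` itself when it is a matrix).
#' @param universe `"all"` or `"listed"`.
#' @return An object of class `meomi_eval`: counts, scalar metrics,
#'   `aupr` and `auroc`.
#' @export
evaluate_network <- function(pred, gold, scores = NULL,
                             universe = c("all", "listed")) {
  universe <- match.arg(universe)
  rep_ <- scalar_metrics(confusion(pred, gold, universe))
  if (is.null(scores)) {
    scores <- if (inherits(pred, "meomi")) pred$scores
              else if (is.matrix(pred)) pred
              else NULL
  }
  if (!is.null(scores)) {
    rc <- ranking_curves(scores, gold, universe)
    rep_$aupr <- rc$aupr
    rep_$auroc <- rc$auroc
  }
  structure(rep_, class = "meomi_eval")
}

#' @export
print.meomi_eval <- function(x, ...) {
  cat("Network evaluation\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  TPR %.4f  FPR %.4f  PPV %.4f  ACC %.4f\n",
              x$tpr, x$fpr, x$ppv, x$acc))
  cat(sprintf("  F1 %.4f  MCC %.4f", x$f1, x$mcc))
  if (!is.null(x$aupr))
    cat(sprintf("  AUPR %.4f  AUROC %.4f", x$aupr, x$auroc))
  cat("\n")
  invisible(x)
}
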