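toy_gold <- function() {
  gold_standard(rbind(c("g1", "g2"), c("g2", "g3"), c("g4", "g5")),
                genes = paste0("g", 1:6))
}

adj_from <- function(pairs, genes) {
  a <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  for (p in pairs) a[p[1], p[2]] <- a[p[2], p[1]] <- 1
  a
}

test_that("confusion counts enumerate unordered pairs exhaustively", {
  genes <- paste0("g", 1:6)
  pred <- adj_from(list(c("g1", "g2"), c("g2", "g3"), c("g3", "g4"),
                        c("g5", "g6")), genes)
  cc <- confusion(pred, toy_gold())
  expect_equal(cc, list(tp = 2, fp = 2, tn = 10, fn = 1))
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, choose(6, 2))

  perfect <- adj_from(list(c("g1", "g2"), c("g2", "g3"), c("g4", "g5")),
                      genes)
  cc <- confusion(perfect, toy_gold())
  expect_equal(cc$fp, 0)
  expect_equal(cc$fn, 0)

  empty <- adj_from(list(), genes)
  cc <- confusion(empty, toy_gold())
  expect_equal(cc$tp, 0)
  expect_equal(cc$fn, 3)
})

test_that("mismatched gene universes are reported as an error", {
  pred <- adj_from(list(c("g1", "g2")), paste0("g", 1:5))
  expect_error(confusion(pred, toy_gold()), "g6")
})

test_that("explicit-negative gold standards restrict the universe", {
  gold <- gold_standard(rbind(c("a", "b")), rbind(c("a", "c")),
                        genes = c("a", "b", "c", "d"))
  pred <- adj_from(list(c("a", "b"), c("a", "c"), c("a", "d")),
                   c("a", "b", "c", "d"))
  cc <- confusion(pred, gold, universe = "listed")
  # the a-d edge is outside the listed universe and ignored
  expect_equal(cc, list(tp = 1, fp = 1, tn = 0, fn = 0))
})

test_that("scalar metrics follow the standard definitions and conventions", {
  m <- scalar_metrics(list(tp = 3, fp = 1, tn = 10, fn = 2))
  expect_equal(m$tpr, 0.6)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$acc, 0.8125)
  expect_equal(m$f1, 2 / 3, tolerance = 1e-9)
  expect_equal(m$fpr, 1 / 11, tolerance = 1e-9)
  expect_equal(m$mcc, 28 / sqrt(2640), tolerance = 1e-12)

  perfect <- scalar_metrics(list(tp = 5, fp = 0, tn = 7, fn = 0))
  expect_true(all(unlist(perfect[c("tpr", "ppv", "acc", "f1", "mcc")])
                  == 1))

  # all-negative prediction: zero factors force the 0-convention
  m0 <- scalar_metrics(list(tp = 0, fp = 0, tn = 5, fn = 5))
  expect_equal(m0$mcc, 0)
  expect_equal(m0$f1, 0)
  expect_error(scalar_metrics(list(tp = 0, fp = 0, tn = 0, fn = 0)),
               "positive")
})

test_that("AUROC equals brute-force concordance counting", {
  set.seed(70)
  genes <- paste0("g", 1:8)
  pos <- rbind(c("g1", "g2"), c("g3", "g4"), c("g5", "g6"), c("g1", "g7"))
  gold <- gold_standard(pos, genes = genes)
  pos_keys <- c(paste(pos[, 1], pos[, 2]), paste(pos[, 2], pos[, 1]))
  idx <- which(upper.tri(diag(8)), arr.ind = TRUE)
  y <- paste(genes[idx[, 1]], genes[idx[, 2]]) %in% pos_keys
  for (rep in 1:10) {
    s <- matrix(0, 8, 8, dimnames = list(genes, genes))
    v <- sample(seq(0, 1, by = 0.1), choose(8, 2), replace = TRUE) # ties
    s[upper.tri(s)] <- v
    s <- s + t(s)
    rc <- ranking_curves(s, gold)
    expect_equal(rc$auroc, brute_auroc(s[upper.tri(s)], y),
                 tolerance = 1e-10)
  }
})

test_that("perfect ranking and null scores bracket AUROC behaviour", {
  genes <- paste0("g", 1:6)
  gold <- toy_gold()
  s <- adj_from(list(c("g1", "g2"), c("g2", "g3"), c("g4", "g5")), genes)
  rc <- ranking_curves(s + 0.0, gold)
  expect_equal(rc$auroc, 1)
  expect_equal(rc$aupr, 1)

  set.seed(71)
  auc <- replicate(100, {
    v <- runif(choose(6, 2))
    s[upper.tri(s)] <- v
    s[lower.tri(s)] <- t(s)[lower.tri(s)]
    ranking_curves(s, gold)$auroc
  })
  se <- sd(auc) / sqrt(length(auc))
  expect_lt(abs(mean(auc) - 0.5), 3 * se + 0.02)

  s[] <- 0.5; diag(s) <- 0
  expect_warning(rc <- ranking_curves(s, gold), "identical")
  expect_equal(rc$auroc, 0.5)
})

test_that("ranking metrics are invariant under monotone transforms", {
  set.seed(72)
  genes <- paste0("g", 1:7)
  gold <- gold_standard(rbind(c("g1", "g2"), c("g3", "g4")),
                        genes = genes)
  s <- matrix(0, 7, 7, dimnames = list(genes, genes))
  s[upper.tri(s)] <- runif(choose(7, 2))
  s <- s + t(s)
  r1 <- ranking_curves(s, gold)
  r2 <- ranking_curves(exp(3 * s), gold)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("the combined report carries counts, rates and curve areas", {
  genes <- paste0("g", 1:6)
  pred <- adj_from(list(c("g1", "g2"), c("g2", "g3"), c("g3", "g4"),
                        c("g5", "g6")), genes)
  ev <- evaluate_network(pred, toy_gold())
  expect_s3_class(ev, "meomi_eval")
  expect_equal(ev$tp, 2)
  expect_true(!is.null(ev$aupr) && !is.null(ev$auroc))
  expect_output(print(ev), "MCC")
})
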