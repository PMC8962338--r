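# separable two-class fixture: feature 1 carries the signal, the rest noise
make_separable <- function(n = 120, p = 4, seed = 3L) {
  withr::with_seed(seed, {
    y <- rep(c(1L, -1L), length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    X[, 1] <- ifelse(y == 1, 2, -2) + rnorm(n, 0, 0.1)
    colnames(X) <- paste0("D(f", seq_len(p), ")",
                          rep(c("ma", "tg", "ei"), length.out = p))
    list(X = X, y = y)
  })
}

test_that("count-based metrics satisfy their defining identities", {
  m <- metrics_from_counts(10, 10, 20, 20)
  expect_equal(c(m$sn, m$sp, m$ac, m$mcc), c(100, 100, 100, 1))
  # degenerate denominator convention
  expect_equal(metrics_from_counts(5, 0, 5, 5)$mcc, 0)
  # weighted identity Ac = (Sn*Na + Sp*Ni)/(Na+Ni) on random confusions
  withr::with_seed(8, {
    for (i in 1:25) {
      na <- sample(5:500, 1); ni <- sample(5:500, 1)
      m <- metrics_from_counts(na, sample(0:na, 1), ni, sample(0:ni, 1))
      expect_equal(m$ac, (m$sn * na + m$sp * ni) / (na + ni),
                   tolerance = 1e-12)
      expect_gte(m$mcc, -1); expect_lte(m$mcc, 1)
    }
  })
})

test_that("entropy criteria behave at their closed-form anchors", {
  # two-bin hand example: Jeffreys = 2 * 0.6 * ln 4
  expect_equal(ptml:::jeffreys_divergence(c(0.8, 0.2), c(0.2, 0.8)),
               2 * 0.6 * log(4), tolerance = 1e-12)
  expect_equal(ptml:::mi_dse(c(0.5, 0.5), c(0.5, 0.5)), 0)
  # identical class distributions score zero through the ranking too
  withr::with_seed(4, {
    x <- rnorm(200)
    X <- cbind("D(same)ma" = c(x, x), "D(disc)tg" = c(rnorm(200, 5), rnorm(200, -5)))
    y <- rep(c(1L, -1L), each = 200)
    r <- rank_features(X, y)
    expect_equal(r$mi_dse[r$feature == "D(same)ma"], 0, tolerance = 1e-6)
    expect_equal(r$rank[r$feature == "D(disc)tg"], 1L)
    # disjoint supports dominate every other candidate
    expect_gt(r$mi_dse[r$feature == "D(disc)tg"],
              r$mi_dse[r$feature == "D(same)ma"])
  })
  # a constant feature scores 0 without error
  Xc <- cbind("D(const)ma" = rep(1, 40), "D(ok)tg" = rnorm(40))
  rc <- rank_features(Xc, rep(c(1L, -1L), 20))
  expect_equal(rc$mi_dse[rc$feature == "D(const)ma"], 0)
})

test_that("selection enforces redundancy bound and element coverage", {
  withr::with_seed(7, {
    X <- matrix(rnorm(300 * 20), 300, 20)
    colnames(X) <- paste0("D(f", 1:20, ")",
                          rep(c("ma", "tg", "ei"), length.out = 20))
    y <- rep(c(1L, -1L), 150)
    r <- rank_features(X, y)
    s <- select_features(r, X, size = 15)
    expect_length(s, 15L)
    expect_setequal(unique(ptml:::feature_suffix(s)), c("ma", "tg", "ei"))
    # an exact duplicate column is always rejected (PCC = 1)
    X2 <- cbind(X[, 1:5], X[, 1, drop = FALSE])
    colnames(X2) <- c(colnames(X)[1:5], "D(dup)ma")
    r2 <- rank_features(X2, y)
    s2 <- select_features(r2, X2, size = 6)
    expect_false(all(c(colnames(X)[1], "D(dup)ma") %in% s2))
    # all candidates from one element kind: constraint error
    X3 <- X[, ptml:::feature_suffix(colnames(X)) == "ma"]
    r3 <- rank_features(X3, y)
    expect_error(select_features(r3, X3, size = 3), "mandatory")
  })
})

test_that("classifiers are deterministic and fit separable data perfectly", {
  fx <- make_separable()
  for (algo in c("mlp", "lda")) {
    m <- train_classifier(fx$X, fx$y, algo, hidden = 6, seed = 21L)
    rep <- evaluate_model(m, fx$X, fx$y)
    expect_equal(rep$global$ac, 100, info = algo)
    expect_equal(rep$global$mcc, 1, info = algo)
  }
  m1 <- train_classifier(fx$X, fx$y, "mlp", hidden = 6, seed = 21L)
  m2 <- train_classifier(fx$X, fx$y, "mlp", hidden = 6, seed = 21L)
  expect_identical(predict(m1, fx$X), predict(m2, fx$X))
  expect_error(train_classifier(fx$X, rep(1L, nrow(fx$X)), "mlp"),
               "single class")
  expect_error(train_classifier(fx$X, fx$y, "mlp", hidden = 0), "hidden")
  expect_output(print(m1), "MLP 4-6-2")
})

test_that("evaluation produces correct local per-element metrics", {
  fx <- make_separable(n = 90)
  m <- train_classifier(fx$X, fx$y, "lda")
  # local metrics: fabricate conditions; check the arithmetic on a subset
  conds <- data.frame(ma = rep(c("A", "B"), length.out = 90),
                      tg = "T", ei = "E", stringsAsFactors = FALSE)
  rep <- evaluate_model(m, fx$X, fx$y, conds)
  loc <- rep$local$ma
  pred <- predict(m, fx$X)$label
  for (v in c("A", "B")) {
    idx <- conds$ma == v
    expect_equal(loc$sn[loc$value == v],
                 100 * sum(idx & fx$y == 1 & pred == 1) / sum(idx & fx$y == 1))
  }
  # 5 of 9 actives correct -> local Sn = 55.56
  expect_equal(round(100 * 5 / 9, 2), 55.56)
  expect_error(evaluate_model(m, fx$X[0, , drop = FALSE], integer(0)),
               "empty")
})

test_that("TSAD counts in-range features with closed intervals", {
  fx <- make_separable()
  m <- train_classifier(fx$X, fx$y, "lda")
  d <- length(m$features)
  ad <- tsad(m, fx$X)
  expect_true(all(ad$tsad == d))
  expect_true(all(ad$in_ad))
  # a case sitting exactly on the training minimum is inside
  x_min <- matrix(m$ad["min", ], 1, dimnames = list(NULL, m$features))
  expect_true(tsad(m, x_min)$in_ad)
  # one feature pushed beyond the training maximum drops TSAD by exactly 1
  x_out <- x_min
  x_out[1, 2] <- m$ad["max", 2] + 1
  expect_equal(tsad(m, x_out)$tsad, d - 1L)
  expect_false(tsad(m, x_out)$in_ad)
})

test_that("random predictions give near-zero MCC on balanced data", {
  withr::with_seed(12, {
    n <- 10000
    y <- rep(c(1L, -1L), n / 2)
    pred <- sample(c(1L, -1L), n, replace = TRUE)
    m <- metrics_from_counts(sum(y == 1), sum(y == 1 & pred == 1),
                             sum(y == -1), sum(y == -1 & pred == -1))
    expect_lt(abs(m$mcc), 0.03)  # Monte-Carlo tolerance at n = 10000
  })
})
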