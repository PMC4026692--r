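test_that("information gain matches hand-computed entropies", {
  expect_equal(information_gain(rep(1, 6), rep(c("A", "B"), 3)), 0)
  expect_warning(g <- information_gain(rnorm(6), rep("A", 6)), "single class")
  expect_equal(g, 0)

  # perfectly separating feature attains the label entropy
  y3 <- rep(c("A", "B", "C"), each = 4)
  x3 <- rep(c(0, 5, 10), each = 4)
  expect_equal(information_gain(x3, y3, bins = 3), log2(3), tolerance = 1e-12)

  # 6-sample toy: x = (1,2,3,4,5,6), y = (A,A,A,B,B,B), 2 equal-freq bins
  # -> H(y)=1, bins separate y perfectly, gain = 1 bit
  expect_equal(information_gain(1:6, rep(c("A", "B"), each = 3), bins = 2),
               1, tolerance = 1e-12)
  # interleaved labels: each bin holds 2 of one class, 1 of the other, so
  # H(y|bin) = H(1/3) and the gain is 1 - H(1/3) bits
  h13 <- -(1 / 3) * log2(1 / 3) - (2 / 3) * log2(2 / 3)
  expect_equal(information_gain(1:6, rep(c("A", "B"), 3), bins = 2),
               1 - h13, tolerance = 1e-12)
})

test_that("top-k selection finds the informative feature among noise", {
  hit <- 0L
  for (s in 1:50) {
    set.seed(s)
    y <- rep(c("A", "B"), each = 15)
    x <- matrix(rnorm(30 * 10), 30, 10,
                dimnames = list(NULL, sprintf("n%02d", 1:10)))
    x[, 4] <- ifelse(y == "A", 0, 4) + rnorm(30, 0, 0.3)
    colnames(x)[4] <- "signal"
    if (select_top_k(x, y, k = 5)[1] == "signal") hit <- hit + 1L
  }
  expect_gte(hit, 48)

  x <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_setequal(select_top_k(x, rep(c("A", "B"), 10), k = 3),
                  c("a", "b", "c"))
  expect_error(select_top_k(x, rep(c("A", "B"), 10), k = 4), "exceeds")
})

test_that("stratified splits reproduce the study's 57/21 arithmetic", {
  y <- rep(c("FTD", "AD", "NC"), times = c(30, 34, 14))
  sp <- stratified_split(y, 0.75, seed = 1)
  expect_equal(length(sp$train), 57)
  expect_equal(length(sp$test), 21)
  expect_equal(as.numeric(sp$per_class[c("FTD", "AD", "NC")]), c(22, 25, 10))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(y))

  sp2 <- stratified_split(y, 0.75, seed = 2)
  expect_false(identical(sp$train, sp2$train))
  expect_equal(sp2$per_class, sp$per_class)

  expect_error(stratified_split(y, 1.0), "train_fraction")
  expect_error(stratified_split(c("A", "B", "B"), 0.75), ">= 2 members")
})

test_that("the default model-selection grid has 84 points", {
  g <- default_grid()
  expect_equal(nrow(g), 12 * 7)
  expect_equal(sort(unique(log10(g$C))), -3:8)
  expect_equal(sort(unique(log10(g$gamma))), -3:3)
  expect_error(default_grid(integer(0)), "empty")
})

test_that("grid search is deterministic and separates separable classes", {
  d <- separable_features()
  tm1 <- grid_search_train(d$x, d$y, grid = reduced_grid(), k = 3, seed = 5)
  tm2 <- grid_search_train(d$x, d$y, grid = reduced_grid(), k = 3, seed = 5)
  expect_identical(tm1$features, tm2$features)
  expect_identical(c(tm1$C, tm1$gamma), c(tm2$C, tm2$gamma))
  expect_equal(tm1$cv_accuracy, 1.0)

  s <- predict_scores(tm1, d$x)
  expect_equal(rowSums(s), rep(1, nrow(d$x)), tolerance = 1e-9)
  expect_equal(attr(s, "predicted"), d$y)
  expect_identical(predict_scores(tm1, d$x), predict_scores(tm2, d$x))
  expect_error(predict_scores(tm1, d$x[, 1, drop = FALSE]), "missing")
})

test_that("two-class scores reduce to a complementary pair", {
  d <- separable_features()
  sel <- d$y != "C"
  tm <- grid_search_train(d$x[sel, ], d$y[sel], grid = reduced_grid(), k = 2)
  s <- predict_scores(tm, d$x[sel, ])
  expect_equal(ncol(s), 2)
  expect_equal(unname(s[, 1] + s[, 2]), rep(1, sum(sel)), tolerance = 1e-12)
})

test_that("pluggable classifiers run through the same protocol", {
  d <- separable_features()
  for (cl in c("linear_svm", "nbayes")) {
    tm <- suppressWarnings(
      grid_search_train(d$x, d$y, grid = reduced_grid(),
                        spec = classifier_spec(cl), k = 3))
    s <- predict_scores(tm, d$x)
    expect_equal(rowSums(s), rep(1, nrow(d$x)), tolerance = 1e-9)
    expect_gte(mean(attr(s, "predicted") == d$y), 0.9)
  }
})

test_that("LOOCV scores every subject exactly once", {
  d <- separable_features(n_per = 2L)   # 6 subjects
  lo <- loocv(d$x, d$y, grid = reduced_grid(), k = 2)
  expect_equal(nrow(lo$scores), 6)
  expect_length(lo$predicted, 6)
  expect_equal(lo$accuracy, 1.0)       # well-separated clusters
})

test_that("repeated hold-out is reproducible and reduces to one split", {
  d <- separable_features(n_per = 8L)
  r1 <- repeated_holdout(d$x, d$y, n_reps = 1, seed = 7,
                         grid = reduced_grid(), k = 3)
  expect_length(r1$weighted_auc, 1)
  expect_true(is.na(r1$sd_weighted_auc) || r1$sd_weighted_auc == 0 ||
              !is.nan(r1$sd_weighted_auc))
  r3a <- repeated_holdout(d$x, d$y, n_reps = 3, seed = 7,
                          grid = reduced_grid(), k = 3)
  r3b <- repeated_holdout(d$x, d$y, n_reps = 3, seed = 7,
                          grid = reduced_grid(), k = 3)
  expect_identical(r3a$weighted_auc, r3b$weighted_auc)
  expect_gte(r3a$mean_weighted_auc, 0.9)   # strong signal by construction
})

test_that("the sample-size bound follows d/(2 p_e)", {
  expect_equal(sample_size_bound(5, 0.05), 50)
  expect_equal(sample_size_bound(10, 0.05), 100)
  expect_error(sample_size_bound(5, 0), "p_e")
  expect_error(sample_size_bound(5, 1), "p_e")
  expect_error(sample_size_bound(0, 0.05), "d must")
  chk <- sample_size_bound(5, 0.05, n_available = 78)
  expect_true(chk$sufficient)
})
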