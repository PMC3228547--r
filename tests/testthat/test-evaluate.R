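test_that("metrics follow their defining formulas", {
  perfect <- compute_metrics(list(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_equal(unlist(perfect), c(precision = 1, sensitivity = 1,
                                  specificity = 1, accuracy = 1))

  m <- compute_metrics(list(TP = 3, FP = 1, TN = 2, FN = 2))
  expect_equal(m$precision, 0.75)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 2 / 3, tolerance = 1e-4)
  expect_equal(m$accuracy, 0.625)

  # zero denominators are undefined, never zero
  und <- compute_metrics(list(TP = 0, FP = 0, TN = 4, FN = 0))
  expect_true(is.na(und$precision))
  expect_true(is.na(und$sensitivity))
  expect_equal(und$specificity, 1)
})

test_that("accuracy decomposes over class-conditional rates", {
  set.seed(99)
  for (i in 1:25) {
    counts <- list(TP = sample(0:30, 1), FP = sample(0:30, 1),
                   TN = sample(0:30, 1), FN = sample(0:30, 1))
    P <- counts$TP + counts$FN
    N <- counts$TN + counts$FP
    if (P == 0 || N == 0) next
    m <- compute_metrics(counts)
    expect_equal(m$accuracy,
                 (m$sensitivity * P + m$specificity * N) / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("folds partition with sizes differing by at most one", {
  f10 <- make_folds(10, k = 5, seed = 1)
  expect_equal(unname(table(f10)), rep(2L, 5), ignore_attr = TRUE)

  f12 <- make_folds(12, k = 5, seed = 1)
  expect_equal(sort(as.integer(table(f12))), c(2L, 2L, 2L, 3L, 3L))

  expect_identical(make_folds(37, 5, seed = 4), make_folds(37, 5, seed = 4))
  expect_false(identical(make_folds(37, 5, seed = 4),
                         make_folds(37, 5, seed = 5)))
  expect_error(make_folds(3, k = 5, seed = 1), "folds")
})

test_that("threshold selection maximizes accuracy with deterministic ties", {
  # separable scores: every grid value separates; tie-break returns 0
  expect_equal(select_threshold(rep(5, 10), rep(-10, 10)), 0L)

  # identical score sets: still a unique deterministic choice in the grid
  s <- c(-3, -1, 2)
  t1 <- select_threshold(s, s)
  t2 <- select_threshold(s, s)
  expect_identical(t1, t2)
  expect_true(t1 %in% -20:0)

  # with a separating gap, the largest separating threshold is chosen
  pos <- c(-2, -1, 0, 1)
  neg <- c(-9, -8, -7, -6)
  expect_equal(select_threshold(pos, neg), -3L)
  # when no grid value separates, accuracy still drives the choice
  expect_equal(select_threshold(c(5, 5, -30), c(-10, -10, -10)), 0L)
})

test_that("sensitivity and specificity are monotone over the grid", {
  set.seed(7)
  for (i in 1:20) {
    sp <- rnorm(30, mean = sample(-5:5, 1), sd = 3)
    sn <- rnorm(30, mean = sample(-15:0, 1), sd = 3)
    grid <- -20:0
    sens <- vapply(grid, function(t) mean(sp > t), numeric(1))
    spec <- vapply(grid, function(t) mean(sn <= t), numeric(1))
    expect_true(all(diff(sens) <= 0))
    expect_true(all(diff(spec) >= 0))
    expect_true(select_threshold(sp, sn, grid) %in% grid)
  }
})

test_that("cross-validation folds stay disjoint and metrics are strong on a separable cluster", {
  spec <- dataset_spec(200, 200, motifs = list(
    motif_spec(list(`1` = list(symbol = "P", prob = 0.9),
                    `3` = list(symbol = "D", prob = 0.9),
                    `-3` = list(symbol = "E", prob = 0.9)),
               coupling = c(1, 3), weight = 1)), seed = 42)
  ds <- generate_dataset(spec)
  cl <- mddphos:::new_motif_cluster("S1", ds$positives,
                                    default_group_scheme())
  cv <- cross_validate(list(cl), ds$negatives, k = 5, seed = 42)

  expect_named(cv$per_cluster, "S1")
  pc <- cv$per_cluster$S1
  expect_equal(nrow(pc$fold_metrics), 5L)
  expect_true(pc$threshold_bits %in% -20:0)
  expect_gte(cv$macro_average$accuracy, 0.9)

  # fold partition check on the same seed path
  folds <- make_folds(200, 5, mddphos:::derive_seed(42, 1))
  expect_equal(sort(unique(folds)), 1:5)
  expect_true(max(table(folds)) - min(table(folds)) <= 1)

  # a cluster smaller than k is skipped with a warning
  tiny <- mddphos:::new_motif_cluster("S2", ds$positives[1:3, ],
                                      default_group_scheme())
  expect_warning(cv2 <- cross_validate(list(cl, tiny), ds$negatives,
                                       k = 5, seed = 42), "skipped")
  expect_equal(cv2$skipped, "S2")
})

test_that("independent test repeats are deterministic and consistent with training", {
  spec <- strong_three_motif_spec()
  ds <- generate_dataset(spec)
  root <- mdd_cluster(ds$positives, min_cluster_size = 200)
  cls <- motif_clusters(root, "S")
  bg <- background_frequencies(rbind(ds$positives, ds$negatives))
  cv <- cross_validate(cls, ds$negatives, seed = 42, background = bg)
  models <- train_final_models(cls, cv, background = bg)

  test_ds <- generate_dataset(strong_three_motif_spec(150, 400, seed = 77))
  it1 <- independent_test(models, test_ds$positives, test_ds$negatives,
                          repeats = 5, seed = 11)
  it2 <- independent_test(models, test_ds$positives, test_ds$negatives,
                          repeats = 5, seed = 11)
  expect_identical(it1$per_repeat, it2$per_repeat)
  expect_equal(nrow(it1$per_repeat), 5L)

  # matched-generator test sensitivity tracks the CV sensitivity
  expect_lt(abs(it1$mean$sensitivity - cv$macro_average$sensitivity), 0.1)

  expect_error(independent_test(models, test_ds$positives,
                                test_ds$negatives[1:10, ], repeats = 2,
                                seed = 1), "pool")
})
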