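test_that("k-fold assignment partitions rows and depends only on (n, k, seed)", {
  f1 <- kfold_indices(41, 5, seed = 42)
  f2 <- kfold_indices(41, 5, seed = 42)
  expect_identical(f1, f2)
  expect_setequal(unlist(f1), 1:41)
  expect_equal(unname(sort(lengths(f1), decreasing = TRUE)), c(9, 8, 8, 8, 8))
  expect_false(identical(unlist(kfold_indices(41, 5, seed = 1)), unlist(f1)))
})

test_that("polynomial expansion has the closed-form column count and naming", {
  tab <- tibble::as_tibble(stats::setNames(as.data.frame(matrix(rnorm(60), 5)),
                                           paste0("f", 1:12)))
  for (k in 1:12) {
    feats <- paste0("f", seq_len(k))
    ex <- polynomial_expand(tab[feats], feats)
    expect_equal(ncol(ex), 2 * k + k * (k - 1) / 2)
  }
  ex2 <- polynomial_expand(tab[c("f1", "f2")], c("f1", "f2"))
  expect_named(ex2, c("f1", "f2", "f1^2", "f2^2", "f1*f2"))
  expect_equal(ex2$`f1*f2`, tab$f1 * tab$f2)
  expect_equal(ex2$`f1^2`, tab$f1^2)
  ex1 <- polynomial_expand(tab["f1"], "f1")
  expect_named(ex1, c("f1", "f1^2"))
  # k = 8 gives the 44 predictors of the reduced model
  expect_equal(ncol(polynomial_expand(tab[paste0("f", 1:8)], paste0("f", 1:8))),
               44)
})

test_that("feature assembly joins on ID and handles bad keys", {
  he <- tibble::tibble(ID = paste0("S", 1:10), thick = rnorm(10))
  it <- tibble::tibble(ID = paste0("S", 1:10), itgb4 = rnorm(10))
  ki <- tibble::tibble(ID = paste0("S", 1:9), ki67 = rnorm(9))
  meta <- tibble::tibble(ID = paste0("S", 1:10), Age = seq(20, 65, 5))
  out <- assemble_features(he, it, ki, meta)
  expect_equal(nrow(out), 9)  # S10 absent from the Ki67 table
  expect_true(all(c("thick", "itgb4", "ki67", "Age") %in% names(out)))

  # graft-style concatenated keys join across all sources
  gid <- c("S3_Young", "S3_Old", "S4_Pre")
  g <- assemble_features(
    tibble::tibble(ID = gid, thick = 1:3),
    tibble::tibble(ID = gid, itgb4 = 4:6),
    tibble::tibble(ID = gid, ki67 = 7:9),
    tibble::tibble(ID = gid, Age = c(70, 70, 75)))
  expect_equal(nrow(g), 3)
  expect_equal(g$thick[g$ID == "S3_Young"], 1)

  dup <- tibble::tibble(ID = c("S1", "S1"), thick = 1:2)
  expect_error(assemble_features(dup, it, ki, meta), "duplicate")
  expect_warning(
    assemble_features(he, it, ki, meta[1:5, ]), "absent from metadata")
})

test_that("full model separates recoverable signal from noise targets", {
  cfg <- model_config(n_trees = 200)
  withr::with_seed(2, {
    x <- matrix(rnorm(100 * 6), 100, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
  })
  tab <- tibble::as_tibble(x)
  tab$Age <- tab$f3  # target identical to one predictor, noise-free
  m <- train_full(tab, cfg)
  expect_gte(m$cv_r2, 0.95)
  expect_equal(m$importance$feature[1], "f3")
  expect_equal(sum(m$importance$importance), 1, tolerance = 1e-9)

  # independent target: no out-of-fold skill
  tab$Age <- withr::with_seed(3, rnorm(100, 50, 15))
  m0 <- train_full(tab, cfg)
  expect_lte(m0$cv_r2, 0.1)
  expect_error(train_full(dplyr::mutate(tab, bad = "x"), cfg,
                          predictors = c("f1", "bad")), "non-numeric")
})

test_that("reduced model finds planted signal among many predictors", {
  cfg <- model_config(n_trees = 200)
  found <- vapply(1:5, function(s) {
    withr::with_seed(100 + s, {
      x <- matrix(rnorm(80 * 48), 80, 48,
                  dimnames = list(NULL, paste0("f", 1:48)))
      age <- runif(80, 20, 80)
    })
    tab <- tibble::as_tibble(x)
    # signal lives in exactly three predictors
    tab$f5 <- tab$f5 + age / 12
    tab$f17 <- tab$f17 - age / 12
    tab$f33 <- tab$f33 + age / 15
    tab$Age <- age
    full <- train_full(tab, cfg)
    red <- train_reduced(tab, full, cfg)
    expect_equal(length(red$predictors), 44)
    all(c("f5", "f17", "f33") %in% red$top_features)
  }, logical(1))
  expect_true(all(found))
})

test_that("reduced model keeps the full model's skill on planted-signal tables", {
  cfg <- model_config()
  for (s in 1:3) {
    tab <- simulate_feature_table(seed = 40 + s)
    full <- train_full(tab, cfg)
    red <- train_reduced(tab, full, cfg)
    expect_gte(red$cv_r2, full$cv_r2 - 0.1)
    # determinism under a fixed seed
    red2 <- train_reduced(tab, full, cfg)
    expect_identical(glance(red), glance(red2))
  }
})

test_that("importance ranking is stable under predictor permutation", {
  cfg <- model_config(n_trees = 300)
  tab <- simulate_feature_table(seed = 77)
  m1 <- train_full(tab, cfg)
  perm <- c("ID", "Age", rev(setdiff(names(tab), c("ID", "Age"))))
  m2 <- train_full(tab[perm], cfg)
  # the planted-signal block is recovered as the top-8 either way
  expect_setequal(m1$importance$feature[1:8], m2$importance$feature[1:8])
})

test_that("xenograft deltas are the stated differences of condition means", {
  cfg <- model_config(n_trees = 200)
  tab <- simulate_feature_table(seed = 6)
  red <- train_reduced(tab, train_full(tab, cfg), cfg)
  graft <- simulate_xenograft_table(n_donors = 3, seed = 8)
  d <- predict_and_delta(red, graft)
  # arithmetic identity against manual group means
  pred <- predict(red, graft)
  man <- tapply(pred, paste(graft$Sample, graft$Condition), mean)
  d1 <- d[d$Sample == "D01", ]
  expect_equal(d1$delta_pre_young, unname(man["D01 Pre"] - man["D01 Young"]))
  expect_equal(d1$delta_young_old, unname(man["D01 Young"] - man["D01 Old"]))

  # a donor missing one condition yields missing deltas, others intact
  g2 <- graft[!(graft$Sample == "D02" & graft$Condition == "Old"), ]
  d2 <- predict_and_delta(red, g2)
  expect_true(is.na(d2$delta_pre_old[d2$Sample == "D02"]))
  expect_false(is.na(d2$delta_pre_young[d2$Sample == "D02"]))

  # schema errors name the missing columns
  expect_error(predict(red, graft[, 1:4]), "missing feature")
})
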