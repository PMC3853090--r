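test_that("metrics follow their defining ratios with NA sentinels", {
  m <- compute_metrics(9, 2, 8, 1)
  expect_equal(m$sn, 0.9)
  expect_equal(m$sp, 0.8)
  expect_equal(m$acc, 0.85)
  expect_equal(m$pre, 9 / 11)

  und <- compute_metrics(0, 0, 5, 5)
  expect_true(is.na(und$pre))
  expect_equal(und$sp, 1)
  expect_error(compute_metrics(-1, 0, 0, 0), "non-negative")

  set.seed(17)
  for (i in 1:50) {
    x <- sample(0:30, 4, replace = TRUE)
    m <- compute_metrics(x[1], x[2], x[3], x[4])
    if (!is.na(m$sn)) expect_equal(m$sn, x[1] / (x[1] + x[4]))
    if (!is.na(m$sp)) expect_equal(m$sp, x[3] / (x[3] + x[2]))
    expect_equal(m$acc, (x[1] + x[3]) / sum(x))
    # balanced classes: accuracy is the mean of Sn and Sp
    if (x[1] + x[4] - x[2] >= 0) {
      b <- compute_metrics(x[1], x[2], x[1] + x[4] - x[2], x[4])
      if (!is.na(b$sn) && !is.na(b$sp)) {
        expect_equal(b$acc, (b$sn + b$sp) / 2)
      }
    }
  }
})

test_that("SVM training separates Gaussian blobs and enforces its schema", {
  ds <- blob_dataset(30, 30, d = 5, sep = 4, seed = 1)
  model <- train_svm(ds, seed = 1)
  pred <- predict(model, ds)
  expect_equal(as.character(pred), ds$sites$label)  # separable: 100% train acc

  wrong <- blob_dataset(10, 10, d = 7, sep = 4, seed = 2)
  expect_error(predict(model, wrong), "schema")

  model2 <- train_svm(ds, seed = 1)
  expect_equal(predict(model2, ds), pred)  # deterministic retrain

  one_class <- ds
  one_class$sites$label <- "positive"
  expect_error(train_svm(one_class), "each class")
})

test_that("cross-validation selects jackknife below 30 positives and 5-fold above", {
  small <- blob_dataset(10, 40, d = 5, sep = 3, seed = 3)
  rep_s <- cross_validate(small, repeats = 2, seed = 1)
  expect_equal(rep_s$folds, 10)
  expect_true(rep_s$jackknife)

  big <- blob_dataset(56, 112, d = 5, sep = 3, seed = 4)
  rep_b <- cross_validate(big, repeats = 2, seed = 1)
  expect_equal(rep_b$folds, 5)
  expect_false(rep_b$jackknife)

  expect_error(cross_validate(blob_dataset(10, 5, seed = 5)),
               "as many negatives")
})

test_that("cross-validation is balanced 1:1 and bit-identical under one seed", {
  ds <- blob_dataset(20, 80, d = 5, sep = 0.8, seed = 6)
  rep1 <- cross_validate(ds, repeats = 4, seed = 42)
  # every repeat tests exactly n_pos positives and n_pos negatives
  expect_equal(rep1$per_repeat$TP + rep1$per_repeat$FN, rep(20, 4))
  expect_equal(rep1$per_repeat$TN + rep1$per_repeat$FP, rep(20, 4))
  expect_equal(rep1$repeats, 4)
  expect_true(is.finite(rep1$acc_sd))

  rep2 <- cross_validate(ds, repeats = 4, seed = 42)
  expect_identical(rep1, rep2)
  rep3 <- cross_validate(ds, repeats = 4, seed = 43)
  expect_false(identical(rep1$per_repeat, rep3$per_repeat))
})

test_that("independent testing enforces disjointness and the 1:2 ratio", {
  train <- blob_dataset(25, 50, d = 5, sep = 3, seed = 7)
  model <- train_svm(train, seed = 1)
  expect_error(independent_test(model, train), "overlaps")

  test <- blob_dataset(20, 80, d = 5, sep = 3, seed = 8)
  test$sites$protein_id <- paste0("t_", test$sites$protein_id)
  rep_t <- independent_test(model, test, seed = 1)
  expect_equal(rep_t$TP + rep_t$FN, 20)
  expect_equal(rep_t$TN + rep_t$FP, 40)       # 1:2 positives:negatives
  expect_gt(rep_t$acc, 0.8)                   # well-separated blobs

  few_neg <- blob_dataset(20, 30, d = 5, sep = 3, seed = 9)
  few_neg$sites$protein_id <- paste0("u_", few_neg$sites$protein_id)
  expect_error(independent_test(model, few_neg), "too few negatives")
})

test_that("cross-classification specificity is high for orthogonal groups", {
  # group A discriminates on dims 1-3, group B on dims 4-6
  make_group <- function(dims, seed, group) {
    set.seed(seed)
    n <- 40; d <- 6
    xp <- matrix(rnorm(n * d), n, d); xp[, dims] <- xp[, dims] + 4
    xn <- matrix(rnorm(n * d), n, d)
    sites <- data.frame(protein_id = sprintf("%s%04d", group, 1:(2 * n)),
                        position = 7L, residue = "S", kinase_group = group,
                        label = rep(c("positive", "negative"), each = n))
    kinase_dataset(group, sites, rep(strrep("A", 6), 2 * n) |>
                     paste0("S", strrep("A", 6)),
                   blocks = list(spatial = rbind(xp, xn)),
                   preset = "structure_only")
  }
  dsA <- make_group(1:3, 1, "A")
  dsB <- make_group(4:6, 2, "B")
  models <- list(A = train_svm(dsA, seed = 1), B = train_svm(dsB, seed = 1))
  sp <- cross_classification_matrix(models, list(A = dsA, B = dsB))
  expect_true(all(is.na(diag(sp))))
  off <- sp[!is.na(sp)]
  expect_true(all(off >= 0 & off <= 1))
  expect_gt(sp["A", "B"], 0.8)  # B's positives look negative to A
  expect_gt(sp["B", "A"], 0.8)
  expect_error(cross_classification_matrix(models, list(A = dsA)),
               "same groups")
})

test_that("grid search maximises inner-CV accuracy with deterministic tie-breaks", {
  ds <- blob_dataset(24, 48, d = 5, sep = 4, seed = 10)
  single <- grid_search(ds, C_grid = 2, gamma_grid = 0.1, seed = 1)
  expect_equal(single$C, 2)
  expect_equal(single$gamma, 0.1)

  gs <- grid_search(ds, C_grid = c(1, 10), gamma_grid = c(0.01, 0.1),
                    seed = 1)
  expect_gte(gs$report$acc, 0.9)  # separable data reaches high accuracy
  gs_rev <- grid_search(ds, C_grid = c(10, 1), gamma_grid = c(0.1, 0.01),
                        seed = 1)
  expect_equal(gs[c("C", "gamma")], gs_rev[c("C", "gamma")])
})
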