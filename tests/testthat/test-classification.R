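test_that("positives are binned into half-open 5-minute intervals with matched negatives", {
  tab <- synth_dataset(70, effect = 1, seed = 3)
  # deterministic minutes covering the boundary cases
  pos <- tab$label == 1L
  tab$minutes_before_onset[pos][1:3] <- c(17.3, 5.0, 5.1)
  ds <- build_interval_datasets(tab)
  by_r <- setNames(ds, vapply(ds, `[[`, numeric(1), "interval"))
  in_interval <- function(r, minutes)
    any(abs(by_r[[as.character(r)]]$rows$minutes_before_onset - minutes)
        < 1e-9, na.rm = TRUE)
  expect_true(in_interval(4, 17.3))   # (15, 20]
  expect_true(in_interval(1, 5.0))    # boundary stays in interval 1
  expect_true(in_interval(2, 5.1))
  for (d in ds) {
    p <- d$rows[d$rows$label == 1L, ]
    expect_true(all(p$minutes_before_onset > (d$interval - 1) * 5 &
                      p$minutes_before_onset <= d$interval * 5))
    n <- d$rows[d$rows$label == 0L, ]
    expect_true(all(n$index_in_record %in% p$index_in_record))
  }
})

test_that("rows beyond 25 minutes are discarded with a message", {
  tab <- synth_dataset(30, effect = 1, seed = 5)
  tab$minutes_before_onset[tab$label == 1L][1] <- 29
  expect_message(build_interval_datasets(tab), "discarded")
})

test_that("nine pre-onset records contribute 45 positives to a full interval", {
  # bookkeeping: 9 records x 5 minute-slots per 5-minute interval
  rows <- expand.grid(record = sprintf("pre%02d", 1:9), minute = 1:25)
  tab <- synth_dataset(225, effect = 1, seed = 6)
  pos <- which(tab$label == 1L)
  tab$minutes_before_onset[pos] <- rows$minute
  tab$record_id[pos] <- as.character(rows$record)
  ds <- build_interval_datasets(tab)
  expect_length(ds, 5)
  for (d in ds)
    expect_equal(sum(d$rows$label == 1L), 45)
})

test_that("all three classifiers separate an easy two-feature problem", {
  tab <- synth_dataset(40, effect = c(mQRSd = 6, mHR = 6), seed = 8)
  feats <- c("mQRSd", "mHR")
  for (kind in c("dt", "nb", "svm")) {
    model <- train_classifier(classifier_spec(kind), tab, feats)
    expect_equal(predict(model, tab), tab$label,
                 info = paste("classifier", kind))
  }
})

test_that("naive Bayes approaches the closed-form Bayes rate on unit Gaussians", {
  # classes at -2 and +2 on one feature: Bayes accuracy = pnorm(2)
  set.seed(33)
  n <- 400
  train <- synth_dataset(n, effect = 0, seed = 34)
  train$mRR <- stats::rnorm(2 * n, ifelse(train$label == 1, 2, -2), 1)
  test <- synth_dataset(n, effect = 0, seed = 35)
  test$mRR <- stats::rnorm(2 * n, ifelse(test$label == 1, 2, -2), 1)
  model <- train_classifier(classifier_spec("nb"), train, "mRR")
  acc <- mean(predict(model, test) == test$label)
  expect_equal(acc, stats::pnorm(2), tolerance = 0.03)
})

test_that("naive Bayes matches e1071 on a held-out sample", {
  tab <- synth_dataset(80, effect = c(mQRSd = 1.5, SDNN = 1), seed = 12)
  test <- synth_dataset(40, effect = c(mQRSd = 1.5, SDNN = 1), seed = 13)
  feats <- c("mQRSd", "SDNN", "mHR")
  mine <- predict(train_classifier(classifier_spec("nb"), tab, feats), test)
  ref <- e1071::naiveBayes(tab[, feats], factor(tab$label))
  theirs <- as.integer(as.character(predict(ref, test[, feats])))
  expect_gt(mean(mine == theirs), 0.95)
})

test_that("a linear-kernel SVM cannot separate XOR", {
  xor_tab <- synth_dataset(2, effect = 0, seed = 14)
  xor_tab$mRR <- c(0, 0, 1, 1)
  xor_tab$mHR <- c(0, 1, 0, 1)
  xor_tab$label <- c(0L, 1L, 1L, 0L)
  model <- train_classifier(classifier_spec("svm"), xor_tab, c("mRR", "mHR"))
  expect_gt(mean(predict(model, xor_tab) != xor_tab$label), 0)
})

test_that("prediction is order-equivariant and training rows reproduce pure leaves", {
  tab <- synth_dataset(30, effect = c(mQamp = 4), seed = 16)
  model <- train_classifier(classifier_spec("dt", min_split = 2), tab,
                            feature_names())
  expect_equal(predict(model, tab), tab$label)
  perm <- sample(nrow(tab))
  expect_equal(predict(model, tab[perm, ]), tab$label[perm])
  # schema mismatch errors name the missing feature
  expect_error(predict(model, tab[, 1:3]), "missing features")
})

test_that("pooled CV confusions conserve class totals and reproduce with the seed", {
  tab <- synth_dataset(60, effect = c(mQRSd = 1), seed = 18)
  conf <- run_cv(tab, classifier_spec("dt"), feature_names(),
                 cv_config(k_folds = 5, seeds = 1:5))
  expect_true(all(conf$TP + conf$FN == 60))
  expect_true(all(conf$TN + conf$FP == 60))
  conf2 <- run_cv(tab, classifier_spec("dt"), feature_names(),
                  cv_config(k_folds = 5, seeds = 1:5))
  expect_identical(conf, conf2)
  # perfectly separable data: SE = SP = 100 for every seed
  sep <- synth_dataset(25, effect = c(mRamp = 12), seed = 19)
  conf3 <- run_cv(sep, classifier_spec("dt"), feature_names(),
                  cv_config(k_folds = 5, seeds = 1:5))
  expect_true(all(sensitivity(conf3[1, ]) == 100))
  expect_true(all(vapply(seq_len(5), function(i)
    specificity(conf3[i, ]), numeric(1)) == 100))
})

test_that("folds shrink when an interval has fewer positives than folds", {
  tab <- synth_dataset(40, effect = 2, seed = 20)
  small <- rbind(tab[tab$label == 1L, ][1:3, ], tab[tab$label == 0L, ])
  expect_message(conf <- run_cv(small, classifier_spec("dt"),
                                feature_names(),
                                cv_config(k_folds = 5, seeds = 1)),
                 "folds reduced")
  expect_equal(conf$TP + conf$FN, 3L)
})

test_that("decision-tree CV stays near the majority-class floor or better", {
  tab <- synth_dataset(100, effect = c(mQRSd = 1.2), seed = 22)
  conf <- run_cv(tab, classifier_spec("dt"), feature_names(),
                 cv_config(k_folds = 5, seeds = 1:5))
  acc <- mean((conf$TP + conf$TN) / 200)
  expect_gt(acc, 0.50 - 0.05)
  # seed-to-seed stability of SE
  se <- vapply(seq_len(5), function(i) sensitivity(conf[i, ]), numeric(1))
  expect_lte(stats::sd(se), 15)
})
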