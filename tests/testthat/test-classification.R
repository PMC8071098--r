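test_that("metrics match a hand-computed confusion matrix", {
  rep1 <- classification_metrics(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(rep1$accuracy, 0.75)
  expect_equal(rep1$precision[["A"]], 1)
  expect_equal(rep1$recall[["A"]], 0.5)
  expect_equal(rep1$precision[["B"]], 2 / 3)
  expect_equal(rep1$recall[["B"]], 1)
  expect_identical(as.integer(rep1$confusion),
                   c(1L, 0L, 1L, 2L)) # column-major: truth x predicted
  # accuracy is always trace / total
  expect_equal(rep1$accuracy, sum(diag(rep1$confusion)) / sum(rep1$confusion))
})

test_that("metrics handle perfect, degenerate and invalid inputs", {
  truth <- c("A", "B", "C", "A")
  perfect <- classification_metrics(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$precision == 1) && all(perfect$recall == 1))
  # a class never predicted gets precision 0 and a zero-division flag
  rep2 <- classification_metrics(c("A", "B"), c("A", "A"),
                                 levels = c("A", "B"))
  expect_equal(rep2$precision[["B"]], 0)
  expect_identical(rep2$zero_division, "B")
  expect_error(classification_metrics(c("A", "B"), c("A")),
               class = "eegpipe_validation_error")
  expect_error(classification_metrics("A", "Z", levels = c("A", "B")),
               class = "eegpipe_validation_error")
})

test_that("training separates the synthetic classes and validates inputs", {
  sf <- small_fixture()
  pred <- predict(sf$model, sf$feats)
  expect_identical(pred, sf$labels$label) # separable fixture: recalled exactly
  expect_identical(predict(sf$model, sf$feats[0, , drop = FALSE]),
                   character(0))
  expect_error(train_classifier(sf$feats, rep("A", nrow(sf$feats))),
               class = "eegpipe_validation_error")
  expect_error(train_classifier(sf$feats[1:5, ], sf$labels$label[1:5]),
               class = "eegpipe_validation_error")
  bad <- sf$feats
  colnames(bad)[1] <- "oops"
  expect_error(predict(sf$model, bad), class = "eegpipe_validation_error")
})

test_that("training is deterministic and invariant to row duplication", {
  sf <- small_fixture()
  probe <- sf$feats[seq(1, 40, by = 4), ]
  m1 <- train_classifier(sf$feats, sf$labels$label, seed = 5)
  m2 <- train_classifier(sf$feats, sf$labels$label, seed = 5)
  expect_identical(predict(m1, probe), predict(m2, probe))
  m3 <- train_classifier(rbind(sf$feats, sf$feats),
                         c(sf$labels$label, sf$labels$label), seed = 5)
  expect_identical(predict(m1, probe), predict(m3, probe))
})

test_that("a serialized and reloaded model predicts identically", {
  sf <- small_fixture()
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(sf$model, path)
  back <- load_classifier(path)
  expect_identical(predict(back, sf$feats), predict(sf$model, sf$feats))
  expect_identical(back$levels, sf$model$levels)
})

test_that("cross-validation is reproducible and respects preconditions", {
  sf <- small_fixture()
  cv1 <- cross_validate(sf$epochs, sf$labels$label, sf$labels$subject,
                        k = 5, seed = 9, powers = sf$powers)
  cv2 <- cross_validate(sf$epochs, sf$labels$label, sf$labels$subject,
                        k = 5, seed = 9, powers = sf$powers)
  expect_identical(cv1$mean_accuracy, cv2$mean_accuracy)
  expect_identical(cv1$mean_precision, cv2$mean_precision)
  expect_identical(cv1$mean_recall, cv2$mean_recall)
  expect_identical(cv1$fold_accuracy, cv2$fold_accuracy)
  expect_length(cv1$fold_accuracy, 5)
  expect_equal(sum(cv1$confusion), length(sf$epochs))
  # class with fewer members than folds
  expect_error(cross_validate(sf$epochs, sf$labels$label, k = 11,
                              powers = sf$powers),
               class = "eegpipe_validation_error")
})

test_that("fold accuracy equals the trace of the fold confusion matrix", {
  sf <- small_fixture()
  cv <- cross_validate(sf$epochs, sf$labels$label, sf$labels$subject,
                       k = 5, seed = 2, powers = sf$powers)
  for (f in cv$folds) {
    expect_equal(f$accuracy, sum(diag(f$confusion)) / sum(f$confusion))
    expect_identical(rowSums(f$confusion), f$support[names(rowSums(f$confusion))])
  }
})

test_that("the feature pipeline and classifier run across 16/32/64 s epochs", {
  for (len in c(16, 32, 64)) {
    spec <- synthetic_spec(epochs_per_class = 5, epoch_length_s = len,
                           subjects_per_group = 1, seed = 21)
    out <- generate_recording(spec)
    epochs <- segment_epochs(out$recording, len, labels = out$labels$label)
    powers <- band_power_matrix(epochs)
    base <- compute_baseline(epochs, out$labels$subject, powers = powers)
    feats <- features_matrix(powers, base)
    model <- train_classifier(feats, out$labels$label, seed = 1)
    expect_gte(mean(predict(model, feats) == out$labels$label), 0.95)
  }
})

test_that("subject-grouped folds hold out whole subjects", {
  sf <- small_fixture()
  cv <- cross_validate(sf$epochs, sf$labels$label, sf$labels$subject,
                       k = 3, seed = 6, group_by_subject = TRUE,
                       powers = sf$powers)
  expect_length(cv$fold_accuracy, 3)
  expect_equal(sum(cv$confusion), length(sf$epochs))
})
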