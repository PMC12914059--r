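# Shared crop set: four balanced static scenes, segmented and labeled from
# ground truth. Built once per test run.
.crop_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    crops <- list(); labs <- character(0)
    for (s in 1:4) {
      cfg <- scene_config(image_height = 560, image_width = 560, n_cells = 40,
                          class_mix = c(activated = 1/3, quiescent = 1/3,
                                        dead = 1/3),
                          seed = s, n_frames = 2)
      sc <- make_scene(cfg)
      corr <- background_correct(sc$frame)
      m <- segment_cells(corr)
      mm <- match_labels(m, sc$truth$label_mask)
      good <- mm$seg[mm$iou >= 0.5]
      crops <- c(crops, build_crops(corr, m, cell_ids = good))
      labs <- c(labs, sc$truth$cells$class[mm$truth[match(good, mm$seg)]])
    }
    cache <<- list(crops = crops, labels = labs)
    cache
  }
})

test_that("crops carry 1 or 4 channels by task with a zero exterior", {
  cfg <- scene_config(image_height = 64, image_width = 64, n_cells = 1,
                      class_mix = c("CD8-like" = 1), seed = 13, n_frames = 64)
  sc <- make_scene(cfg)
  stk <- render_stack(cfg, sc)
  corr <- background_correct(sc$frame)
  cm <- sc$truth$label_mask
  maps <- dynamic_maps(stk, cm)
  c1 <- build_crops(corr, cm, side = 64)
  expect_true(is.matrix(c1[[1]]))
  c4 <- build_crops(corr, cm, maps = maps, side = 64)
  expect_equal(dim(c4[[1]]), c(64, 64, 4))
  # exterior exactly zero in every channel
  ext <- crop_and_pad(matrix(1, 64, 64), cm, 1, side = 64) == 0
  for (ch in 1:4) expect_true(all(c4[[1]][, , ch][ext] == 0))
  # crop <-> cell id mapping is bijective
  expect_equal(names(c4), "1")
  expect_equal(attr(c4[[1]], "cell_id"), 1)
})

test_that("stratified splits and folds are seeded partitions", {
  labs <- rep(c("a", "b"), c(30, 20))
  sp <- stratified_split(labs, 0.8, seed = 4)
  expect_setequal(c(sp$train, sp$test), 1:50)
  expect_equal(length(intersect(sp$train, sp$test)), 0)
  expect_equal(sum(labs[sp$train] == "a"), 24)
  expect_equal(sum(labs[sp$train] == "b"), 16)
  expect_identical(sp, stratified_split(labs, 0.8, seed = 4))
  expect_error(stratified_split(c("a", rep("b", 10)), 0.8, 1), "absent")
  fo <- stratified_folds(labs, folds = 5, seed = 2)
  expect_equal(sort(unique(fo)), 1:5)
  for (f in 1:5) expect_equal(sum(labs[fo == f] == "a"), 6)
  expect_error(stratified_folds(c("a", "a", rep("b", 10)), folds = 5, 1),
               "fewer")
})

test_that("confusion matrices sum to the held-out counts", {
  truth <- c("a", "a", "a", "b", "b")
  pred <- c("a", "b", "a", "b", "b")
  met <- classification_metrics(truth, pred)
  expect_equal(unname(rowSums(met$confusion)), c(3, 2))
  expect_equal(met$accuracy, sum(diag(met$confusion)) / 5)
  expect_equal(met$sensitivity, 2 / 3)   # positive class = first level "a"
  expect_equal(met$specificity, 1)
})

test_that("the residual network separates the synthetic classes", {
  fx <- .crop_fixture()
  fit <- train_cnn(fx$crops, fx$labels, train_config(epochs = 20, seed = 7))
  expect_gte(fit$accuracy, 0.95)
  expect_equal(sum(fit$confusion), length(fit$split$test))
  # determinism of the split under a fixed seed
  fit2 <- train_cnn(fx$crops, fx$labels, train_config(epochs = 1, seed = 7))
  expect_identical(fit$split, fit2$split)
  pred <- predict(fit, fx$crops[fit$split$test])
  expect_equal(mean(pred == fx$labels[fit$split$test]), fit$accuracy)
})

test_that("shuffled labels bring the network back to chance", {
  fx <- .crop_fixture()
  set.seed(99)
  fit <- train_cnn(fx$crops, sample(fx$labels),
                   train_config(epochs = 20, seed = 7))
  expect_lt(abs(fit$accuracy - 1 / 3), 0.1)
})

test_that("the linear-discriminant baseline mirrors the network's interface", {
  set.seed(31)
  n <- 120
  labs <- rep(c("x", "y"), each = n / 2)
  feats <- data.frame(f1 = rnorm(n, ifelse(labs == "x", 0, 4)),
                      f2 = rnorm(n))
  mdl <- baseline_classifier(feats, labs)
  pred <- predict(mdl, feats)
  expect_gte(mean(pred == labs), 0.9)
  # adding a constant feature leaves predictions unchanged
  feats2 <- cbind(feats, const = 1)
  expect_identical(predict(baseline_classifier(feats2, labs), feats2), pred)
  # shuffled labels drop cross-validated accuracy to chance
  set.seed(5)
  cv0 <- cross_validate(feats, sample(labs), train_config(folds = 5, seed = 3))
  expect_lt(abs(cv0$accuracy - 0.5), 0.2)
  expect_error(baseline_classifier(feats, rep("x", n)), "2 classes")
  # zero within-class variance breaks lda; ridge fallback takes over
  feats3 <- data.frame(f1 = feats$f1, f2 = ifelse(labs == "x", 0, 1))
  expect_warning(mdl3 <- baseline_classifier(feats3, labs), "ridge")
  expect_gte(mean(predict(mdl3, feats3) == labs), 0.9)
})

test_that("cross-validation folds partition the data and pool metrics", {
  set.seed(77)
  n <- 100
  labs <- rep(c("p", "q"), each = n / 2)
  feats <- data.frame(a = rnorm(n, ifelse(labs == "p", 0, 3)), b = rnorm(n))
  cv <- cross_validate(feats, labs, train_config(folds = 5, seed = 3))
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_equal(length(cv$folds), n)
  expect_equal(sum(cv$confusion), n)
  expect_gte(cv$accuracy, 0.9)
  expect_equal(length(cv$fold_accuracy), 5)
  expect_error(cross_validate(feats, rep("p", n)), "2 classes")
})

test_that("composition percentages follow their definitions", {
  set.seed(12)
  labs <- rep(c("activated", "quiescent", "dead"), each = 30)
  feats <- data.frame(
    f1 = rnorm(90, c(activated = 0, quiescent = 5, dead = 10)[labs], 0.3))
  mdl <- baseline_classifier(feats, labs)
  # all-dead sample
  dead_rows <- feats[labs == "dead", , drop = FALSE]
  expect_equal(predict_composition(mdl, dead_rows)$viability_pct, 0)
  # all-activated live sample
  act_rows <- feats[labs == "activated", , drop = FALSE]
  comp <- predict_composition(mdl, act_rows)
  expect_equal(comp$viability_pct, 100)
  expect_equal(comp$activation_pct, 100)
  expect_error(predict_composition(mdl, feats[0, , drop = FALSE]), "empty")
})

test_that("agreement fits match the closed-form least-squares oracle", {
  expect_equal(agreement_fit(c(1, 2, 3), c(1, 2, 3)),
               list(slope = 1, intercept = 0, r2 = 1))
  f <- agreement_fit(2 * c(10, 20, 35, 50), c(10, 20, 35, 50))
  expect_equal(f$slope, 2); expect_equal(f$r2, 1)
  set.seed(2)
  x <- runif(30, 0, 100); y <- 1.2 * x + 3 + rnorm(30, 0, 5)
  f2 <- agreement_fit(y, x)
  # closed forms: slope = cov/var, r2 = cor^2
  expect_equal(f2$slope, cov(x, y) / var(x))
  expect_equal(f2$intercept, mean(y) - f2$slope * mean(x))
  expect_equal(f2$r2, cor(x, y)^2)
  expect_error(agreement_fit(c(1, 2, 3), c(2, 2, 2)), "zero variance")
  expect_error(agreement_fit(1:2, 1:2), "at least 3")
})

test_that("baseline and network agree on clearly separated cells", {
  fx <- .crop_fixture()
  fit <- train_cnn(fx$crops, fx$labels, train_config(epochs = 20, seed = 11))
  # features for the same cells, baseline cross-validated
  feats <- do.call(rbind, lapply(fx$crops, function(cr) static_features(cr)))
  cv <- cross_validate(feats, fx$labels, train_config(folds = 5, seed = 11))
  expect_lte(abs(cv$accuracy - fit$accuracy), 0.10)
})
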