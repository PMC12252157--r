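test_that("classifier construction is seeded and correctly shaped", {
  m1 <- build_classifier(seed = 4)
  m2 <- build_classifier(seed = 4)
  expect_identical(m1$params, m2$params)
  m3 <- build_classifier(seed = 5)
  expect_false(identical(m1$params$c1_W, m3$params$c1_W))
  # four pooling stages on 128 leave an 8x8 map feeding the dense layer
  expect_equal(nrow(m1$params$d1_W), 8 * 8 * 256)
  expect_equal(ncol(m1$params$d1_W), 256)
  expect_equal(m1$param_count, sum(vapply(m1$params, length, integer(1))))
  expect_error(build_classifier(input_size = 100), "divisible")
})

test_that("network outputs are probabilities", {
  m <- tiny_model(1)
  set.seed(2)
  imgs <- array(runif(64 * 64 * 5), dim = c(64, 64, 5))
  p <- predict_classifier(m, imgs)
  expect_length(p, 5)
  expect_true(all(p > 0 & p < 1))
})

test_that("the engine gradient matches finite differences", {
  pf <- asNamespace("printfid")
  model <- build_classifier(seed = 5, input_size = 8, depths = c(3, 4),
                            dense_units = 6, dropout = 0)
  set.seed(99)
  imgs <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  labels <- c(1, 0, 1); wts <- c(1.2, 0.8, 1.2)
  loss_fn <- function(m) {
    fwd <- pf$cnn_forward(m, imgs, train = TRUE)
    pf$weighted_bce(fwd$prob, labels, wts) + 0.5 * m$l2 * sum(m$params$d1_W^2)
  }
  fwd <- pf$cnn_forward(model, imgs, train = TRUE)
  grads <- pf$cnn_backward(model, fwd, labels, wts)
  eps <- 1e-6
  set.seed(31)
  for (nm in c("c1_W", "c2_g", "c2_beta", "d1_W", "d2_W", "d1_b")) {
    for (i in sample(length(model$params[[nm]]), 3)) {
      m2 <- model; m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
      m3 <- model; m3$params[[nm]][i] <- m3$params[[nm]][i] - eps
      num <- (loss_fn(m2) - loss_fn(m3)) / (2 * eps)
      ana <- grads[[nm]][i]
      if (abs(num) + abs(ana) < 1e-7) next
      expect_lt(abs(num - ana) / (abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("training is reproducible from its seed", {
  ds <- tiny_dataset(60, seed = 19)
  cfg <- tiny_config(5, epochs_per_stage = 2)
  m1 <- train_incremental(ds, cfg, model = tiny_model(5))
  m2 <- train_incremental(ds, cfg, model = tiny_model(5))
  expect_equal(tail(m1$history$val_loss, 1), tail(m2$history$val_loss, 1),
               tolerance = 1e-6)
  expect_identical(m1$params$d2_W, m2$params$d2_W)
})

test_that("training rejects degenerate datasets", {
  ds <- tiny_dataset(60, seed = 19)
  one_class <- list(images = ds$images, labels = rep(1L, 60))
  expect_error(train_incremental(one_class, tiny_config(1)), "both classes")
  expect_error(train_incremental(ds, training_config(initial_dataset = 500)),
               "smaller than")
})

test_that("a small separable problem is learned quickly", {
  ds <- tiny_dataset(120, seed = 23)
  m <- train_tiny(ds, seed = 23)
  val <- list(images = ds$images[, , m$val_idx, drop = FALSE],
              labels = ds$manifest$label[m$val_idx])
  met <- evaluate_classifier(m, val)
  expect_gte(met$recall, 0.9)
  expect_gte(met$auc_roc, 0.9)
})

test_that("classifier metrics match hand-computed oracles", {
  # perfect predictor
  met <- classifier_metrics(c(0.9, 0.95, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(met$recall, 1); expect_equal(met$f1, 1)
  expect_equal(met$accuracy, 1); expect_equal(met$auc_roc, 1)
  expect_equal(met$auc_pr, 1)
  # constant predictor: chance-level ranking
  expect_equal(classifier_metrics(rep(0.5, 10), rep(c(0, 1), 5))$auc_roc, 0.5)
  # 4-sample case: concordant pairs (0.9>0.8, 0.9>0.1, 0.3>0.1),
  # discordant (0.3<0.8) -> AUC = 3/4
  met4 <- classifier_metrics(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))
  expect_equal(met4$auc_roc, 0.75)
  # for binary labels with complementary scores the per-class AUCs coincide
  expect_equal(unname(met4$per_class_auc["high"]),
               unname(met4$per_class_auc["low"]))
  expect_error(classifier_metrics(c(0.2, 0.8), c(1, 1)), "single class")
})

test_that("recall sweeps from 1 to 0 across the threshold range", {
  scores <- c(0.1, 0.4, 0.6, 0.9)
  labels <- c(0, 1, 0, 1)
  expect_equal(classifier_metrics(scores, labels, threshold = 0)$recall, 1)
  expect_equal(classifier_metrics(scores, labels, threshold = 1)$recall, 0)
  r <- sapply(seq(0, 1, by = 0.25), function(th)
    classifier_metrics(scores, labels, threshold = th)$recall)
  expect_true(all(diff(r) <= 0))
})

test_that("class weighting lifts minority recall on imbalanced data", {
  ds <- tiny_dataset(120, seed = 29, quality_mixture = c(0.15, 0.85))
  expect_lt(mean(ds$manifest$label), 0.35) # High is the minority
  rec <- sapply(c(TRUE, FALSE), function(w) {
    m <- train_tiny(ds, seed = 29, class_weighting = w, augment = FALSE,
                    epochs_per_stage = 1)
    val <- list(images = ds$images[, , m$val_idx, drop = FALSE],
                labels = ds$manifest$label[m$val_idx])
    evaluate_classifier(m, val)$recall
  })
  expect_gte(rec[1], rec[2])
})

test_that("doubling the training set does not degrade mean recall", {
  recalls <- sapply(1:3, function(s) {
    sapply(c(60, 120), function(n) {
      ds <- tiny_dataset(n, seed = 100 + s)
      m <- train_tiny(ds, seed = 100 + s, epochs_per_stage = 2)
      val <- list(images = ds$images[, , m$val_idx, drop = FALSE],
                  labels = ds$manifest$label[m$val_idx])
      evaluate_classifier(m, val)$recall
    })
  })
  expect_gte(mean(recalls[2, ]), mean(recalls[1, ]) - 0.05)
})

test_that("best-print selection joins the experiment matrix and breaks ties", {
  ds <- tiny_dataset(60, seed = 31)
  m <- tiny_model(1) # untrained: probabilities near 0.5
  # threshold 0: everything predicted High; the top-SA image wins
  sel <- select_best_print(m, ds, ds$design, threshold = 0)
  expect_equal(sel$image_id, which.max(ds$manifest$sa_pct))
  expect_equal(sel$parameters$run_id, sel$run_id)
  # threshold 1: nothing predicted High
  expect_warning(sel0 <- select_best_print(m, ds, ds$design, threshold = 1.01),
                 "no image")
  expect_length(sel0$image_id, 0)
  # ties broken by the lower run id
  ds2 <- ds
  ds2$manifest$sa_pct[] <- 50
  ds2$manifest$manual_similarity_pct[] <- 50
  sel2 <- select_best_print(m, ds2, ds2$design, threshold = 0)
  expect_equal(sel2$run_id, min(ds2$manifest$run_id))
  # orphan run ids are an error
  expect_error(select_best_print(m, ds, ds$design[-1, ], threshold = 0),
               "missing from experiment matrix")
})
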