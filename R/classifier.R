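#' Build the binary print-quality CNN
#'
#' Constructs the classifier network with seeded (He-normal) initial
#' weights: four 3x3 convolution blocks with channel depths 32, 64, 128
#' and 256, each followed by batch normalization, ReLU and 2x2
#' max-pooling; a flatten; one fully connected layer of 256 ReLU units
#' with an L2 weight penalty; dropout at rate 0.5; and a single sigmoid
#' output unit (1 = "High" fidelity, 0 = "Low"). On the default 128x128
#' single-channel input, four pooling stages leave an 8x8 spatial map.
#'
#' `input_size` and `depths` are configurable so that reduced-scale
#' networks can be used for fast property checks; the defaults are the
#' classifier actually used on mesh images.
#'
#' @param seed integer seed fixing the initial weights.
#' @param input_size square input side in pixels (default 128).
#' @param depths channel depths of the conv blocks (default
#'   `c(32, 64, 128, 256)`).
#' @param dense_units fully connected layer width (default 256).
#' @param l2 L2 penalty coefficient on the dense layer (default 1e-4).
#' @param dropout dropout rate on the dense layer (default 0.5).
#' @return An object of class `print_classifier` with seeded parameters
#'   and a reported `param_count`.
#' @examples
#' m <- build_classifier(seed = 1, input_size = 32, depths = c(4, 8))
#' m$param_count
#' @export
build_classifier <- function(seed = 1, input_size = 128,
                             depths = c(32, 64, 128, 256),
                             dense_units = 256, l2 = 1e-4, dropout = 0.5) {
  if (input_size %% 2^length(depths) != 0) {
    stop_domain("input_size must be divisible by 2^%d", length(depths))
  }
  set.seed(seed)
  params <- list()
  running <- list()
  cin <- 1
  for (l in seq_along(depths)) {
    cout <- depths[l]
    fan_in <- 9 * cin
    key <- paste0("c", l)
    params[[paste0(key, "_W")]] <- matrix(rnorm(fan_in * cout, 0, sqrt(2 / fan_in)),
                                          fan_in, cout)
    params[[paste0(key, "_b")]] <- rep(0, cout)
    params[[paste0(key, "_g")]] <- rep(1, cout)
    params[[paste0(key, "_beta")]] <- rep(0, cout)
    running[[key]] <- list(mean = rep(0, cout), var = rep(1, cout))
    cin <- cout
  }
  side_out <- input_size %/% 2^length(depths)
  flat <- side_out^2 * depths[length(depths)]
  params$d1_W <- matrix(rnorm(flat * dense_units, 0, sqrt(2 / flat)),
                        flat, dense_units)
  params$d1_b <- rep(0, dense_units)
  params$d2_W <- matrix(rnorm(dense_units, 0, sqrt(1 / dense_units)),
                        dense_units, 1)
  params$d2_b <- 0
  structure(
    list(params = params, running = running, depths = depths,
         input_size = input_size, dense_units = dense_units,
         l2 = l2, dropout = dropout, seed = seed,
         param_count = sum(vapply(params, length, integer(1))),
         trained = FALSE, history = NULL, config = NULL),
    class = "print_classifier"
  )
}

#' @export
print.print_classifier <- function(x, ...) {
  cat(sprintf("<print_classifier> input %dx%dx1, conv depths %s, dense %d, %s parameters%s\n",
              x$input_size, x$input_size, paste(x$depths, collapse = "/"),
              x$dense_units, format(x$param_count, big.mark = ","),
              if (isTRUE(x$trained)) " [trained]" else " [untrained]"))
  invisible(x)
}

#' Training configuration for the incremental protocol
#'
#' @param split_fraction train fraction of the stratified split (default 0.8).
#' @param initial_dataset images in the first training stage (default 250).
#' @param batch_increment images added per stage (default 100).
#' @param epochs_per_stage maximum epochs in each stage (default 20).
#' @param early_stopping_patience epochs without validation-loss
#'   improvement before a stage halts (default 5); best weights restored.
#' @param batch_size minibatch size (default 16).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param class_weighting balance classes by inverse-frequency loss
#'   weights (default TRUE).
#' @param augment augment the minority class with symmetry-preserving
#'   flips and 90-degree rotations (default TRUE).
#' @param seed single seed for split, initialization, shuffling, dropout
#'   and augmentation.
#' @return An object of class `training_config`.
#' @export
training_config <- function(split_fraction = 0.8, initial_dataset = 250,
                            batch_increment = 100, epochs_per_stage = 20,
                            early_stopping_patience = 5, batch_size = 16,
                            learning_rate = 1e-3, class_weighting = TRUE,
                            augment = TRUE, seed = 1) {
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop_domain("split_fraction must be in (0, 1)")
  }
  check_positive(batch_increment, "batch_increment")
  check_positive(initial_dataset, "initial_dataset")
  structure(
    list(split_fraction = split_fraction, initial_dataset = initial_dataset,
         batch_increment = batch_increment, epochs_per_stage = epochs_per_stage,
         early_stopping_patience = early_stopping_patience,
         batch_size = batch_size, learning_rate = learning_rate,
         class_weighting = class_weighting, augment = augment, seed = seed),
    class = "training_config"
  )
}

augment_image <- function(m, op) {
  switch(op,
         hflip = m[, ncol(m):1],
         vflip = m[nrow(m):1, ],
         rot90 = t(m)[, nrow(m):1],
         rot180 = m[nrow(m):1, ncol(m):1],
         rot270 = t(m)[ncol(m):1, ],
         m)
}

dataset_arrays <- function(dataset) {
  if (inherits(dataset, "labeled_dataset")) {
    list(images = dataset$images, labels = dataset$manifest$label,
         manifest = dataset$manifest)
  } else if (is.list(dataset) && !is.null(dataset$images) && !is.null(dataset$labels)) {
    list(images = dataset$images, labels = dataset$labels,
         manifest = dataset$manifest)
  } else {
    stop_domain("dataset must be a labeled_dataset or list(images, labels)")
  }
}

#' Train the classifier with the incremental protocol
#'
#' Stratified 80/20 train/validation split, then training in growing
#' subsets of the training partition (250, 350, 450, ... images, capped
#' at the partition size) with the model carried across stages. Within a
#' stage, minibatch Adam on weighted binary cross-entropy; the minority
#' class is balanced by class weights and (optionally) flip/rotation
#' augmentation; early stopping watches the validation loss and restores
#' the best weights.
#'
#' @param dataset a `labeled_dataset` (from [generate_labeled_dataset()])
#'   or a `list(images = HxWxN array, labels = 0/1 vector)`.
#' @param config a [training_config()].
#' @param model optional pre-built [build_classifier()] model (e.g. a
#'   reduced-scale network); defaults to the full classifier sized to the
#'   images, seeded from `config$seed`.
#' @return The trained `print_classifier` with `history` (per stage and
#'   epoch: training loss, validation loss, validation recall) and the
#'   resolved `config` (including the validation indices).
#' @export
train_incremental <- function(dataset, config = training_config(), model = NULL) {
  da <- dataset_arrays(dataset)
  images <- da$images
  labels <- as.integer(da$labels)
  n <- length(labels)
  if (n < config$initial_dataset) {
    stop_domain("dataset (%d) smaller than initial stage size (%d)",
                n, config$initial_dataset)
  }
  if (length(unique(labels)) < 2) {
    stop_domain("both classes must be present for training")
  }
  set.seed(config$seed)
  if (is.null(model)) {
    model <- build_classifier(seed = config$seed + 1L,
                              input_size = dim(images)[1])
    set.seed(config$seed)
    invisible(runif(1)) # decouple the training stream from the init stream
  }
  # stratified split
  idx_hi <- which(labels == 1); idx_lo <- which(labels == 0)
  tr_hi <- sample(idx_hi, round(length(idx_hi) * config$split_fraction))
  tr_lo <- sample(idx_lo, round(length(idx_lo) * config$split_fraction))
  train_idx <- sample(c(tr_hi, tr_lo))
  val_idx <- setdiff(seq_len(n), train_idx)
  if (length(val_idx) == 0 || length(unique(labels[val_idx])) < 2) {
    stop_domain("validation split is degenerate; need both classes")
  }
  val_imgs <- images[, , val_idx, drop = FALSE]
  val_lab <- labels[val_idx]

  sizes <- unique(pmin(seq(config$initial_dataset, length(train_idx) +
                             config$batch_increment, by = config$batch_increment),
                       length(train_idx)))
  state <- adam_init(model$params)
  history <- NULL
  for (si in seq_along(sizes)) {
    sub <- train_idx[seq_len(sizes[si])]
    sub_lab <- labels[sub]
    if (length(unique(sub_lab)) < 2) next
    # assemble stage training tensors (with minority augmentation)
    imgs_l <- lapply(sub, function(i) images[, , i])
    labs <- sub_lab
    if (config$augment) {
      n1 <- sum(labs == 1); n0 <- sum(labs == 0)
      minority <- if (n1 < n0) 1L else 0L
      deficit <- abs(n0 - n1)
      pool <- which(labs == minority)
      ops <- c("hflip", "vflip", "rot90", "rot180", "rot270")
      if (deficit > 0 && length(pool) > 0) {
        take <- sample(pool, min(deficit, length(pool) * length(ops)),
                       replace = deficit > length(pool) * length(ops))
        op_pick <- sample(ops, length(take), replace = TRUE)
        for (j in seq_along(take)) {
          imgs_l[[length(imgs_l) + 1]] <- augment_image(imgs_l[[take[j]]], op_pick[j])
          labs <- c(labs, minority)
        }
      }
    }
    wts <- rep(1, length(labs))
    if (config$class_weighting) {
      cw <- length(labs) / (2 * c(sum(labs == 0), sum(labs == 1)))
      wts <- cw[labs + 1]
    }
    m_stage <- length(labs)
    best_loss <- Inf; best_params <- model$params; best_running <- model$running
    patience <- 0
    for (epoch in seq_len(config$epochs_per_stage)) {
      ord <- sample(m_stage)
      tr_loss <- 0; nb <- 0
      for (b0 in seq(1, m_stage, by = config$batch_size)) {
        bi <- ord[b0:min(b0 + config$batch_size - 1, m_stage)]
        if (length(bi) < 2) next
        batch <- array(unlist(imgs_l[bi]),
                       dim = c(dim(images)[1], dim(images)[2], length(bi)))
        fwd <- cnn_forward(model, batch, train = TRUE)
        model$running <- fwd$running
        loss <- weighted_bce(fwd$prob, labs[bi], wts[bi]) +
          0.5 * model$l2 * sum(model$params$d1_W^2)
        grads <- cnn_backward(model, fwd, labs[bi], wts[bi])
        upd <- adam_step(model$params, grads, state, lr = config$learning_rate)
        model$params <- upd$params
        state <- upd$state
        tr_loss <- tr_loss + loss; nb <- nb + 1
      }
      val_prob <- predict_classifier(model, val_imgs)
      val_loss <- weighted_bce(val_prob, val_lab)
      val_recall <- if (sum(val_lab == 1) > 0) {
        sum(val_prob >= 0.5 & val_lab == 1) / sum(val_lab == 1)
      } else NA_real_
      history <- rbind(history, data.frame(
        stage = si, stage_size = sizes[si], epoch = epoch,
        train_loss = tr_loss / max(nb, 1), val_loss = val_loss,
        val_recall = val_recall))
      if (val_loss < best_loss - 1e-9) {
        best_loss <- val_loss
        best_params <- model$params
        best_running <- model$running
        patience <- 0
      } else {
        patience <- patience + 1
        if (patience >= config$early_stopping_patience) break
      }
    }
    model$params <- best_params
    model$running <- best_running
  }
  model$trained <- TRUE
  model$history <- history
  model$config <- config
  model$val_idx <- val_idx
  model
}

#' Predict High-fidelity probabilities for mesh images
#'
#' @param model a `print_classifier`.
#' @param images H x W x N array (or a `labeled_dataset`).
#' @param batch_size inference batch size.
#' @return Vector of probabilities in (0, 1).
#' @export
predict_classifier <- function(model, images, batch_size = 64) {
  if (inherits(images, "labeled_dataset")) images <- images$images
  if (length(dim(images)) == 2) images <- array(images, dim = c(dim(images), 1))
  n <- dim(images)[3]
  out <- numeric(n)
  for (b0 in seq(1, n, by = batch_size)) {
    bi <- b0:min(b0 + batch_size - 1, n)
    out[bi] <- cnn_forward(model, images[, , bi, drop = FALSE],
                           train = FALSE)$prob
  }
  out
}

# PR-AUC as average precision (step-wise integration of the PR curve)
average_precision <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  rec <- tp / sum(lab)
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' Classification metrics from scores and labels
#'
#' Recall, F1 and accuracy at the 0.5 threshold; ROC-AUC (via pROC);
#' PR-AUC (average precision); and per-class one-vs-rest ROC-AUCs. For a
#' binary problem with complementary scores the two per-class ROC-AUCs
#' coincide; they are reported separately and never mixed with the
#' overall value.
#'
#' @param scores predicted probabilities for the "High" class.
#' @param labels 0/1 truth.
#' @param threshold decision threshold (default 0.5).
#' @return An object of class `classifier_metrics`.
#' @export
classifier_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop_domain("AUC undefined: test set contains a single class")
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (precision + recall > 0 && !is.na(recall)) {
    2 * precision * recall / (precision + recall)
  } else 0
  accuracy <- mean(pred == labels)
  roc_auc <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                            direction = "<", levels = c(0, 1))))
  pr_auc <- average_precision(scores, labels)
  auc_high <- roc_auc
  auc_low <- as.numeric(pROC::auc(pROC::roc(1 - labels, 1 - scores, quiet = TRUE,
                                            direction = "<", levels = c(0, 1))))
  structure(
    list(recall = recall, f1 = f1, accuracy = accuracy,
         auc_roc = roc_auc, auc_pr = pr_auc,
         per_class_auc = c(high = auc_high, low = auc_low),
         threshold = threshold),
    class = "classifier_metrics"
  )
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf("<classifier_metrics> recall %.3f, F1 %.3f, accuracy %.3f\n",
              x$recall, x$f1, x$accuracy))
  cat(sprintf("  ROC-AUC %.3f (per class High %.3f / Low %.3f), PR-AUC %.3f\n",
              x$auc_roc, x$per_class_auc["high"], x$per_class_auc["low"], x$auc_pr))
  invisible(x)
}

#' Evaluate a trained classifier on a test set
#'
#' @param model a trained `print_classifier`.
#' @param testset `labeled_dataset` or `list(images, labels)` with both
#'   classes present.
#' @param threshold decision threshold (default 0.5).
#' @return A [classifier_metrics()] object.
#' @export
evaluate_classifier <- function(model, testset, threshold = 0.5) {
  da <- dataset_arrays(testset)
  scores <- predict_classifier(model, da$images)
  classifier_metrics(scores, da$labels, threshold = threshold)
}

#' Select the best print and retrieve its process parameters
#'
#' Among images the classifier predicts "High", returns the one with the
#' highest aggregate similarity (ties broken by manual similarity, then
#' by lowest run id) and joins it to its row of the experiment matrix
#' (nozzle, pressure, velocity).
#'
#' @param model a trained `print_classifier`.
#' @param dataset `labeled_dataset` whose manifest has `run_id`, `sa_pct`
#'   and (optionally) `manual_similarity_pct`.
#' @param experiment_matrix data.frame with `run_id`, `nozzle_G`,
#'   `pressure_kPa`, `velocity_mm_s` (e.g. a [full_factorial_design()]).
#' @param threshold decision threshold for "High" (default 0.5).
#' @return List with `image_id`, `run_id`, `parameters` (one matrix row),
#'   `sa_pct` and the predicted probability; or an empty result (with a
#'   warning) if no image is predicted High.
#' @export
select_best_print <- function(model, dataset, experiment_matrix,
                              threshold = 0.5) {
  da <- dataset_arrays(dataset)
  man <- da$manifest
  if (is.null(man) || !all(c("run_id", "sa_pct") %in% names(man))) {
    stop_domain("dataset manifest must carry run_id and sa_pct")
  }
  orphans <- setdiff(man$run_id, experiment_matrix$run_id)
  if (length(orphans) > 0) {
    stop_domain("run_id(s) missing from experiment matrix: %s",
                paste(head(orphans, 5), collapse = ", "))
  }
  prob <- predict_classifier(model, da$images)
  high <- which(prob >= threshold)
  if (length(high) == 0) {
    warning("no image predicted High fidelity; returning empty result")
    return(list(image_id = integer(0), run_id = integer(0),
                parameters = experiment_matrix[0, ], sa_pct = numeric(0),
                probability = numeric(0)))
  }
  manual <- if ("manual_similarity_pct" %in% names(man)) {
    man$manual_similarity_pct
  } else rep(0, nrow(man))
  o <- high[order(-man$sa_pct[high], -manual[high], man$run_id[high])]
  best <- o[1]
  row <- experiment_matrix[match(man$run_id[best], experiment_matrix$run_id), ]
  list(image_id = best, run_id = man$run_id[best], parameters = row,
       sa_pct = man$sa_pct[best], probability = prob[best])
}
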