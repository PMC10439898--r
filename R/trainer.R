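# Unified model assembly, joint training and cross-validation.

#' Training configuration
#'
#' Defaults follow the full-scale training strategy (RAdam for the
#' segmentation path, lr 5e-4, betas 0.9/0.999, weight decay 1e-4,
#' exponential decay 0.99 per epoch; SGD for the regression/classification
#' parameters, lr 5e-4, weight decay 5e-3, momentum 0.06; batch 20;
#' 500 epochs; five folds). Desk-scale runs override `epochs`, `batch_size`
#' and the learning rates.
#'
#' @param epochs training epochs
#' @param batch_size windows per optimizer step
#' @param seg_lr,seg_beta1,seg_beta2,seg_weight_decay,seg_lr_decay
#'   RAdam settings of the segmentation path
#' @param reg_lr,reg_weight_decay,reg_momentum SGD settings of the
#'   regression path
#' @param seg_clip,reg_clip global-norm gradient clipping threshold per
#'   optimizer group (`Inf` disables clipping)
#' @param weights a [loss_weights()]
#' @param folds cross-validation folds
#' @param seed RNG seed for shuffling, augmentation and initialisation
#' @param augment apply training-time augmentation
#' @param use_clahe apply CLAHE during preprocessing
#' @param frames_per_subject optionally train on a subset of frames per
#'   subject (`NULL` = all)
#' @param eval_batch batch size at evaluation
#' @return a `lvq_train_config` list
#' @export
train_config <- function(epochs = 500L, batch_size = 20L,
                         seg_lr = 5e-4, seg_beta1 = 0.9, seg_beta2 = 0.999,
                         seg_weight_decay = 1e-4, seg_lr_decay = 0.99,
                         reg_lr = 5e-4, reg_weight_decay = 5e-3,
                         reg_momentum = 0.06,
                         seg_clip = Inf, reg_clip = Inf,
                         weights = loss_weights(), folds = 5L, seed = 0L,
                         augment = FALSE, use_clahe = TRUE,
                         frames_per_subject = NULL, eval_batch = 10L) {
  stopifnot(seg_lr >= 0, reg_lr >= 0, folds >= 2L, batch_size >= 1L)
  structure(list(epochs = epochs, batch_size = batch_size,
                 seg_lr = seg_lr, seg_beta1 = seg_beta1,
                 seg_beta2 = seg_beta2, seg_weight_decay = seg_weight_decay,
                 seg_lr_decay = seg_lr_decay, reg_lr = reg_lr,
                 reg_weight_decay = reg_weight_decay,
                 reg_momentum = reg_momentum,
                 seg_clip = seg_clip, reg_clip = reg_clip,
                 weights = weights,
                 folds = folds, seed = seed, augment = augment,
                 use_clahe = use_clahe,
                 frames_per_subject = frames_per_subject,
                 eval_batch = eval_batch),
            class = "lvq_train_config")
}

#' Build the unified two-path model
#' @param seg_cfg a [seg_config()]
#' @param reg_cfg a [reg_config()]
#' @return an `lvq_model`
#' @export
build_unified_model <- function(seg_cfg = seg_config(),
                                reg_cfg = reg_config()) {
  structure(list(seg = build_seg_path(seg_cfg),
                 reg = build_reg_path(reg_cfg, seg_cfg),
                 seg_cfg = seg_cfg, reg_cfg = reg_cfg),
            class = "lvq_model")
}

#' Forward pass of the unified model
#' @param model an `lvq_model`
#' @param x window batch tensor `(H, W, slices, 1, batch)`
#' @param training training mode
#' @return list with `seg` ([forward_seg()] output) and `reg`
#'   ([forward_reg()] output)
#' @export
forward_unified <- function(model, x, training = TRUE) {
  seg_out <- forward_seg(model$seg, x, training = training)
  reg_out <- forward_reg(model$reg, x, seg_out, training = training)
  list(seg = seg_out, reg = reg_out)
}

#' Subject-level cross-validation folds
#'
#' Partitions subject identifiers (never frames) into `k` folds whose
#' sizes differ by at most one, deterministically under `seed`.
#'
#' @param ids character or integer subject identifiers
#' @param k number of folds
#' @param seed RNG seed
#' @return list of `k` disjoint id vectors covering `ids`
#' @export
make_folds <- function(ids, k, seed = 0L) {
  if (length(ids) < k) stop("fewer subjects than folds")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  perm <- sample(ids)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  split(perm, rep_len(seq_len(k), length(perm)))
}

# Scale a parameter group's gradients so their global L2 norm does not
# exceed `clip`.
clip_gradients <- function(params, clip) {
  if (!is.finite(clip)) return(invisible(NULL))
  total <- 0
  for (p in params) if (!is.null(p$grad)) total <- total + sum(p$grad^2)
  nrm <- sqrt(total)
  if (nrm > clip) {
    sc <- clip / nrm
    for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * sc
  }
  invisible(NULL)
}

# Assemble a batch of windows into network tensors.
windows_to_batch <- function(windows, n_classes = 3L) {
  H <- dim(windows[[1]]$frames)[1]
  W <- dim(windows[[1]]$frames)[2]
  Tt <- dim(windows[[1]]$frames)[3]
  N <- length(windows)
  x <- array(0, dim = c(H, W, Tt, 1L, N))
  masks <- array(0L, dim = c(H, W, Tt, N))
  targets <- matrix(0, 11L, N)
  phase <- numeric(N)
  for (i in seq_len(N)) {
    w <- windows[[i]]
    x[, , , 1L, i] <- w$frames
    if (!is.null(w$masks)) masks[, , , i] <- w$masks
    targets[, i] <- as.numeric(w$target[1, lvq_index_names])
    phase[i] <- w$target$phase[1]
  }
  list(x = x, onehot = one_hot_masks(masks, n_classes), targets = targets,
       phase = phase)
}

# Forward + joint loss of one batch; returns the loss node and components.
batch_loss <- function(model, batch, weights, training = TRUE) {
  out <- forward_unified(model, batch$x, training = training)
  probs <- ad_softmax_c(out$seg$logits)
  l_seg <- seg_loss(probs, ad_const(batch$onehot), weights)
  p_sys <- ad_row(ad_softmax_rows(out$reg$phase_logits), 2L)
  l_reg <- reg_loss(out$reg$indices, ad_const(batch$targets), p_sys,
                    batch$phase)
  list(loss = unified_loss(l_seg, l_reg, weights),
       seg = as.numeric(ad_value(l_seg)), reg = as.numeric(ad_value(l_reg)),
       out = out)
}

#' Jointly train the unified model
#'
#' Each step runs both paths on a batch of 5-frame windows, computes the
#' unified loss and updates the segmentation parameters with RAdam and the
#' regression-path parameters (including the fusion layers) with SGD; both
#' optimizers step simultaneously. The segmentation learning rate decays
#' exponentially per epoch. Fully seeded.
#'
#' @param model an `lvq_model` (modified in place: parameter nodes are
#'   environments)
#' @param subjects list of `lvq_subject` (raw; preprocessing is applied
#'   here)
#' @param config a [train_config()]
#' @return a tibble loss history (`epoch`, `step`, `loss`, `seg`, `reg`)
#' @export
train_unified <- function(model, subjects, config = train_config()) {
  set.seed(config$seed)
  subjects <- lapply(subjects, preprocess_subject,
                     use_clahe = config$use_clahe)
  n_frames <- dim(subjects[[1]]$images)[3]
  frames <- if (is.null(config$frames_per_subject)) seq_len(n_frames) - 1L
            else round(seq(0, n_frames - 1, length.out = config$frames_per_subject))
  pool <- expand.grid(subj = seq_along(subjects), frame = frames)

  seg_params <- collect_params(model$seg)
  reg_params <- collect_params(model$reg)
  opt_seg <- opt_radam(seg_params, lr = config$seg_lr,
                       beta1 = config$seg_beta1, beta2 = config$seg_beta2,
                       weight_decay = config$seg_weight_decay)
  opt_reg <- opt_sgd(reg_params, lr = config$reg_lr,
                     momentum = config$reg_momentum,
                     weight_decay = config$reg_weight_decay)
  all_params <- c(seg_params, reg_params)

  history <- vector("list", config$epochs)
  step_id <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(nrow(pool))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    rows <- vector("list", length(batches))
    for (b in seq_along(batches)) {
      wins <- lapply(batches[[b]], function(r) {
        w <- temporal_window(subjects[[pool$subj[r]]], pool$frame[r])
        if (config$augment) w <- augment(w) else w
      })
      batch <- windows_to_batch(wins, model$seg_cfg$n_classes)
      res <- batch_loss(model, batch, config$weights, training = TRUE)
      lv <- as.numeric(ad_value(res$loss))
      if (!is.finite(lv))
        stop("non-finite loss at epoch ", epoch, " step ", b,
             " (seg = ", res$seg, ", reg = ", res$reg, ")")
      ad_zero_grad(all_params)
      ad_backward(res$loss)
      clip_gradients(seg_params, config$seg_clip)
      clip_gradients(reg_params, config$reg_clip)
      opt_seg$step()
      opt_reg$step()
      step_id <- step_id + 1L
      rows[[b]] <- tibble::tibble(epoch = epoch, step = step_id, loss = lv,
                                  seg = res$seg, reg = res$reg)
    }
    opt_seg$lr <- opt_seg$lr * config$seg_lr_decay
    history[[epoch]] <- dplyr::bind_rows(rows)
  }

  # re-estimate batch-norm running statistics under the final weights:
  # forward passes in training mode without parameter updates, with the
  # update weight set to 1/k so the stored moments become the plain average
  # of the batch statistics
  ord <- sample(nrow(pool))
  refresh <- split(ord, ceiling(seq_along(ord) / config$batch_size))
  refresh <- refresh[seq_len(min(10L, length(refresh)))]
  states <- collect_states(model[c("seg", "reg")])
  for (k in seq_along(refresh)) {
    for (st in states) st$momentum <- 1 / k
    wins <- lapply(refresh[[k]], function(r)
      temporal_window(subjects[[pool$subj[r]]], pool$frame[r]))
    batch <- windows_to_batch(wins, model$seg_cfg$n_classes)
    ad_no_grad(forward_unified(model, batch$x, training = TRUE))
  }
  for (st in states) st$momentum <- NULL
  dplyr::bind_rows(history)
}

#' Predict masks and indices for every frame of a subject
#'
#' Builds the 5-frame window of each frame, takes the centre-slice argmax
#' of the segmentation logits as the predicted mask, and reads the 11
#' indices plus the phase argmax from the regression head. Deterministic
#' at evaluation.
#'
#' @param model a trained `lvq_model`
#' @param subject an `lvq_subject` (raw)
#' @param config a [train_config()] (preprocessing and batch settings)
#' @return list: `masks` (`H x W x n_frames` predicted class array) and
#'   `indices` (tibble matching the `indices.csv` schema)
#' @export
predict_subject <- function(model, subject, config = train_config()) {
  sub <- preprocess_subject(subject, use_clahe = config$use_clahe)
  n <- dim(sub$images)[3]
  H <- dim(sub$images)[1]
  masks <- array(0L, dim = dim(sub$images))
  idx <- matrix(0, n, 11L)
  phase <- integer(n)
  center <- (dim(temporal_window(sub, 0L)$frames)[3] + 1L) %/% 2L
  for (start in seq(0L, n - 1L, by = config$eval_batch)) {
    fr <- start:min(start + config$eval_batch - 1L, n - 1L)
    wins <- lapply(fr, function(t) temporal_window(sub, t))
    batch <- windows_to_batch(wins, model$seg_cfg$n_classes)
    out <- ad_no_grad(forward_unified(model, batch$x, training = FALSE))
    logits <- ad_value(out$seg$logits)     # H W T K N
    pred_idx <- ad_value(out$reg$indices)  # 11 x N
    ph <- ad_value(out$reg$phase_logits)   # 2 x N
    for (i in seq_along(fr)) {
      sl <- logits[, , center, , i]
      masks[, , fr[i] + 1L] <- array(max.col(matrix(sl, ncol = dim(logits)[4])) - 1L,
                                     dim = c(H, H))
      idx[fr[i] + 1L, ] <- pred_idx[, i]
      phase[fr[i] + 1L] <- which.max(ph[, i]) - 1L
    }
  }
  indices <- tibble::as_tibble(stats::setNames(as.data.frame(idx),
                                               lvq_index_names))
  indices <- dplyr::mutate(indices, frame = seq_len(n) - 1L, .before = 1L)
  indices$phase <- phase
  list(masks = masks, indices = indices[, lvq_csv_columns])
}

#' Subject-level k-fold cross-validation
#'
#' Trains one freshly initialised model per fold on the complement and
#' evaluates on the held-out subjects; per-frame results are pooled across
#' folds into one report.
#'
#' @param subjects list of `lvq_subject`
#' @param seg_cfg,reg_cfg network configurations (a fresh model is built
#'   per fold)
#' @param config a [train_config()] (`config$folds` folds)
#' @return list: `report` (pooled [evaluate()] report), `fold_reports`,
#'   `folds`, `history` (per-fold loss histories)
#' @export
cross_validate <- function(subjects, seg_cfg, reg_cfg,
                           config = train_config()) {
  ids <- vapply(subjects, function(s) s$id, character(1))
  folds <- make_folds(ids, config$folds, config$seed)
  fold_reports <- vector("list", length(folds))
  histories <- vector("list", length(folds))
  pooled_pred <- list(); pooled_truth <- list()
  for (f in seq_along(folds)) {
    test_ids <- folds[[f]]
    train_subj <- subjects[!ids %in% test_ids]
    test_subj <- subjects[ids %in% test_ids]
    set.seed(config$seed + f)
    model <- build_unified_model(seg_cfg, reg_cfg)
    histories[[f]] <- train_unified(model, train_subj, config)
    preds <- lapply(test_subj, predict_subject, model = model,
                    config = config)
    fold_reports[[f]] <- evaluate(preds, test_subj)
    pooled_pred <- c(pooled_pred, preds)
    pooled_truth <- c(pooled_truth, test_subj)
  }
  list(report = evaluate(pooled_pred, pooled_truth),
       fold_reports = fold_reports, folds = folds, history = histories)
}

#' Save / load model checkpoints
#'
#' Serialises every parameter value and batch-norm running moment together
#' with both configurations; loading restores them into a freshly built
#' model.
#'
#' @param model an `lvq_model`
#' @param path file path
#' @return `save_checkpoint`: the path, invisibly. `load_checkpoint`: the
#'   restored `lvq_model`.
#' @export
save_checkpoint <- function(model, path) {
  params <- collect_params(model[c("seg", "reg")])
  states <- collect_states(model[c("seg", "reg")])
  saveRDS(list(seg_cfg = model$seg_cfg, reg_cfg = model$reg_cfg,
               values = lapply(params, function(p) p$v),
               states = lapply(states, function(s) as.list(s))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_unified_model(ck$seg_cfg, ck$reg_cfg)
  params <- collect_params(model[c("seg", "reg")])
  stopifnot(identical(sort(names(params)), sort(names(ck$values))))
  for (nm in names(params)) params[[nm]]$v <- ck$values[[nm]]
  states <- collect_states(model[c("seg", "reg")])
  for (nm in names(states)) {
    for (field in names(ck$states[[nm]]))
      assign(field, ck$states[[nm]][[field]], envir = states[[nm]])
  }
  model
}
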