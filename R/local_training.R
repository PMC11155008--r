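#' Training configuration and the published presets
#'
#' `train_config()` holds everything a single-site training run needs.
#' Three presets mirror the published hyperparameter sets:
#' `"centralized"` (batch 8, lr 0.001, Adam, 100 epochs),
#' `"federated_sim"` (batch 16, lr 0.001, plain SGD), and
#' `"federated_real"` (batch 16, lr 0.001, Adam). The loss is always
#' cross-entropy; the final model is the last epoch's (no early stopping
#' or model selection).
#'
#' @param batch_size Minibatch size; remainder batches are kept.
#' @param learning_rate Step size.
#' @param optimizer `"adam"` or `"sgd"` (plain SGD; momentum optional).
#' @param epochs Number of epochs.
#' @param momentum SGD momentum (default 0, i.e. plain SGD).
#' @param augmentation An [augmentation_config()] applied to training
#'   batches only, or `NULL` for none.
#' @param seed Seed driving per-epoch shuffling and augmentation.
#' @param preset One of `"centralized"`, `"federated_sim"`,
#'   `"federated_real"`; overrides batch size, learning rate, optimizer
#'   (and, for centralized, epochs).
#' @return A `train_config` list.
#' @examples
#' train_config(preset = "federated_sim", epochs = 2)
#' @export
train_config <- function(batch_size = 8, learning_rate = 0.001,
                         optimizer = c("adam", "sgd"), epochs = 100,
                         momentum = 0, augmentation = NULL, seed = 1,
                         preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset,
                        c("centralized", "federated_sim", "federated_real"))
    if (preset == "centralized") {
      batch_size <- 8; optimizer <- "adam"
      if (missing(epochs)) epochs <- 100
    } else if (preset == "federated_sim") {
      batch_size <- 16; optimizer <- "sgd"
    } else {
      batch_size <- 16; optimizer <- "adam"
    }
    learning_rate <- 0.001
  }
  optimizer <- match.arg(optimizer)
  stopifnot(batch_size >= 1, learning_rate >= 0, epochs >= 0, momentum >= 0)
  if (!is.null(augmentation)) {
    stopifnot(inherits(augmentation, "augmentation_config"))
  }
  structure(
    list(
      batch_size = as.integer(batch_size), learning_rate = learning_rate,
      optimizer = optimizer, epochs = as.integer(epochs),
      momentum = momentum, augmentation = augmentation,
      seed = as.integer(seed), loss = "cross_entropy"
    ),
    class = "train_config"
  )
}

#' Stratified 7:3 train/validation split
#'
#' Splits one site's patients into training and validation sets,
#' stratified by label: the total training size is `round(ratio * n)` and
#' each class contributes its share up to largest-remainder rounding, so
#' per-class train fractions are within one sample of `ratio`.
#'
#' @param ids Patient identifiers.
#' @param labels Binary labels (any two-valued vector), parallel to `ids`.
#' @param ratio Training fraction (default 0.7).
#' @param seed Integer seed; identical seeds give identical splits.
#' @return List with `train_ids` and `val_ids` (disjoint, exhaustive).
#' @examples
#' split_cohort(letters[1:10], rep(c(0, 1), 5), seed = 1)
#' @export
split_cohort <- function(ids, labels, ratio = 0.7, seed = 1) {
  stopifnot(length(ids) == length(labels), length(ids) >= 2L,
            ratio > 0, ratio < 1)
  classes <- unique(labels)
  if (length(classes) < 2L) {
    warning("only one class present; split is unstratified")
  }
  if (any(table(labels) < 2L)) {
    warning("a class has fewer than 2 members; stratification is degenerate")
  }
  n_train <- round_half_up(ratio * length(ids))
  per_class <- lapply(classes, function(cl) which(labels == cl))
  ideal <- vapply(per_class, function(ix) ratio * length(ix), 1)
  base <- floor(ideal)
  rem <- n_train - sum(base)
  if (rem > 0) {
    order_frac <- order(ideal - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    order_frac <- order(ideal - base)
    take <- order_frac[seq_len(-rem)]
    base[take] <- base[take] - 1L
  }
  train_idx <- with_seed(seed, {
    unlist(lapply(seq_along(per_class), function(i) {
      ix <- per_class[[i]]
      sample(ix, min(base[i], length(ix)))
    }))
  })
  list(train_ids = ids[sort(train_idx)],
       val_ids = ids[setdiff(seq_along(ids), train_idx)])
}

# ---- optimizers ------------------------------------------------------------

optimizer_state <- function(cfg, params) {
  st <- list(t = 0L)
  if (cfg$optimizer == "adam") {
    st$m <- lapply(params, function(a) a * 0)
    st$v <- lapply(params, function(a) a * 0)
  } else if (cfg$momentum > 0) {
    st$vel <- lapply(params, function(a) a * 0)
  }
  st
}

optimizer_step <- function(cfg, params, grads, state,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  lr <- cfg$learning_rate
  if (cfg$optimizer == "adam") {
    for (nm in names(params)) {
      state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
      state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
      mhat <- state$m[[nm]] / (1 - beta1^state$t)
      vhat <- state$v[[nm]] / (1 - beta2^state$t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  } else if (cfg$momentum > 0) {
    for (nm in names(params)) {
      state$vel[[nm]] <- cfg$momentum * state$vel[[nm]] + grads[[nm]]
      params[[nm]] <- params[[nm]] - lr * state$vel[[nm]]
    }
  } else {
    for (nm in names(params)) {
      params[[nm]] <- params[[nm]] - lr * grads[[nm]]
    }
  }
  list(params = params, state = state)
}

# evaluate mean loss and accuracy on a dataset, in inference mode
evaluate_model <- function(model, data, batch_size = 32L) {
  n <- length(data$y)
  if (n == 0L) return(list(loss = NA_real_, acc = NA_real_, probs = NULL))
  probs <- matrix(0, n, 2L)
  loss <- 0
  for (start in seq(1L, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, n)
    pb <- predict_proba(model, data$x[, , , , ix, drop = FALSE])
    probs[ix, ] <- pb
    picked <- pb[cbind(seq_along(ix), data$y[ix] + 1L)]
    loss <- loss + sum(-log(pmax(picked, 1e-12)))
  }
  pred <- as.integer(probs[, 2L] >= 0.5)
  list(loss = loss / n, acc = mean(pred == data$y), probs = probs)
}

#' Train a model on one site's data
#'
#' Runs exactly `cfg$epochs` epochs of minibatch training with per-epoch
#' reshuffling (seeded from `(cfg$seed, epoch)`), optional augmentation on
#' training batches only, and cross-entropy loss. Validation data is only
#' ever scored, never used for weight updates. Returns the final
#' (last-epoch) parameters and a per-epoch history.
#'
#' @param model A [build_model()] handle; trained in place.
#' @param train_data,val_data Lists with `x` (5D array) and `y` (0/1
#'   labels), e.g. from [load_cohort_patches()]; `val_data` may be `NULL`.
#' @param cfg A [train_config()].
#' @param epoch_offset Added to the epoch counter when deriving shuffle
#'   and augmentation seeds; lets a federated client continue the exact
#'   shuffle sequence of an uninterrupted run across rounds.
#' @return List with `params` (final parameter set) and `history` (data
#'   frame: epoch, train_loss, train_acc, val_loss, val_acc).
#' @export
train_local <- function(model, train_data, val_data = NULL, cfg,
                        epoch_offset = 0L) {
  stopifnot(inherits(model, "conv3dnet"), inherits(cfg, "train_config"))
  n <- length(train_data$y)
  if (n == 0L) stop("training set is empty", call. = FALSE)
  params <- model$params
  state <- optimizer_state(cfg, params)
  hist <- vector("list", cfg$epochs)
  aug <- cfg$augmentation
  side <- model$cfg$input_size

  for (epoch in seq_len(cfg$epochs)) {
    eseed <- derive_seed(cfg$seed, epoch_offset + epoch)
    order_ix <- with_seed(eseed, sample.int(n))
    ep_loss <- 0; ep_hits <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      ix <- order_ix[start:min(start + cfg$batch_size - 1L, n)]
      xb <- train_data$x[, , , , ix, drop = FALSE]
      if (!is.null(aug) && aug$enabled) {
        for (j in seq_along(ix)) {
          pj <- ct_patch(array(xb[, , , 1L, j], rep(side, 3L)))
          xb[, , , 1L, j] <-
            augment_patch(pj, aug, seed = derive_seed(eseed, ix[j]))$data
        }
      }
      yb <- train_data$y[ix]
      model$params <- params
      lg <- loss_and_grad(model, xb, yb)
      stepped <- optimizer_step(cfg, params, lg$grads, state)
      params <- stepped$params
      state <- stepped$state
      ep_loss <- ep_loss + lg$loss * length(ix)
      ep_hits <- ep_hits +
        sum(as.integer(lg$probs[, 2L] >= 0.5) == yb)
    }
    model$params <- params
    val <- if (!is.null(val_data)) evaluate_model(model, val_data) else
      list(loss = NA_real_, acc = NA_real_)
    hist[[epoch]] <- data.frame(
      epoch = epoch_offset + epoch,
      train_loss = ep_loss / n, train_acc = ep_hits / n,
      val_loss = val$loss, val_acc = val$acc
    )
  }
  model$params <- params
  history <- if (cfg$epochs > 0L) do.call(rbind, hist) else
    data.frame(epoch = integer(), train_loss = numeric(),
               train_acc = numeric(), val_loss = numeric(),
               val_acc = numeric())
  list(params = params, history = history)
}

# subset a patch dataset by position or id
subset_data <- function(data, ix) {
  if (is.character(ix)) ix <- match(ix, data$ids)
  list(x = data$x[, , , , ix, drop = FALSE], y = data$y[ix],
       ids = data$ids[ix], sites = data$sites[ix])
}
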