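#' Federated configuration
#'
#' Synchronous federated averaging: every round the server broadcasts the
#' global parameters, every client trains `local_epochs` epochs on its own
#' data, and the server replaces the global model with the sample-size
#' weighted average of the client parameters. The published setup is 10
#' rounds of 50 local epochs.
#'
#' @param n_rounds Number of communication rounds (default 10).
#' @param local_epochs Local epochs per client per round (default 50).
#' @param client_train_cfg A [train_config()] used by every client; its
#'   `epochs` field is ignored in favor of `local_epochs`.
#' @param aggregation Only `"fedavg"` is implemented.
#' @param seed Master seed for client seed derivation.
#' @return A `federated_config` list.
#' @export
federated_config <- function(n_rounds = 10, local_epochs = 50,
                             client_train_cfg = train_config(preset = "federated_sim"),
                             aggregation = "fedavg", seed = 1) {
  aggregation <- match.arg(aggregation, "fedavg")
  stopifnot(n_rounds >= 1, local_epochs >= 0,
            inherits(client_train_cfg, "train_config"))
  structure(
    list(
      n_rounds = as.integer(n_rounds),
      local_epochs = as.integer(local_epochs),
      client_train_cfg = client_train_cfg,
      aggregation = aggregation, seed = as.integer(seed)
    ),
    class = "federated_config"
  )
}

#' Federated averaging of client parameter sets
#'
#' Computes the sample-size weighted elementwise mean of the client
#' parameters: each array is `sum_k (n_k / sum_j n_j) * theta_k`,
#' accumulated in double precision. With equal `n_k` this is the plain
#' mean; with one client it is the identity.
#'
#' @param updates List of client updates, each a list with `parameters`
#'   (a parameter set) and `n_samples` (positive training-set size);
#'   `client_id` and `train_loss` may be carried along.
#' @return The aggregated parameter set.
#' @examples
#' u <- list(list(parameters = list(w = 0), n_samples = 1),
#'           list(parameters = list(w = 1), n_samples = 3))
#' aggregate_fedavg(u)$w  # 0.75
#' @export
aggregate_fedavg <- function(updates) {
  if (!length(updates)) stop("no client updates to aggregate", call. = FALSE)
  ns <- vapply(updates, function(u) as.double(u$n_samples), 1)
  if (any(ns <= 0)) stop("`n_samples` must be positive", call. = FALSE)
  w <- ns / sum(ns)
  ref <- updates[[1L]]$parameters
  for (u in updates[-1L]) {
    if (!identical(names(u$parameters), names(ref))) {
      stop("client parameter sets have mismatched names", call. = FALSE)
    }
  }
  out <- lapply(ref, function(a) a * 0)
  for (k in seq_along(updates)) {
    pk <- updates[[k]]$parameters
    for (nm in names(ref)) {
      if (!identical(dim(pk[[nm]]), dim(ref[[nm]])) ||
          length(pk[[nm]]) != length(ref[[nm]])) {
        stop(sprintf("shape mismatch for '%s' in client %d", nm, k),
             call. = FALSE)
      }
      out[[nm]] <- out[[nm]] + w[k] * pk[[nm]]
    }
  }
  out
}

#' Run a synchronous federated learning simulation
#'
#' In-process simulation of the broadcast -> local-train -> aggregate
#' protocol: all clients participate every round, client optimizer state
#' is reset after each broadcast, and aggregation is [aggregate_fedavg()]
#' weighted by each client's training-set size. The client/server
#' hand-off is an explicit parameter-set exchange, mirroring a networked
#' deployment without one.
#'
#' Client epoch seeds continue across rounds (round r covers epochs
#' `(r-1)*local_epochs + 1 ...`), so a single-client federation with a
#' stateless optimizer reproduces an uninterrupted centralized run batch
#' for batch.
#'
#' @param clients List of clients, each a list with `client_id`,
#'   `train_data`, optionally `val_data` (patch datasets as in
#'   [train_local()]), and optionally `seed` (overriding the derived
#'   per-client training seed).
#' @param model_cfg A [model_config()] for the shared architecture.
#' @param fed_cfg A [federated_config()].
#' @param eval_data Optional held-out dataset scored after every round;
#'   defaults to the pooled client validation sets.
#' @return List with `params` (final global parameter set), `round_log`
#'   (data frame: round, client_id, train_loss, n_samples), and
#'   `global_log` (data frame: round, val_loss, val_acc, val_auc).
#' @export
run_federated <- function(clients, model_cfg, fed_cfg, eval_data = NULL) {
  stopifnot(length(clients) >= 1L, inherits(model_cfg, "model_config"),
            inherits(fed_cfg, "federated_config"))
  for (cl in clients) {
    if (is.null(cl$train_data) || !length(cl$train_data$y)) {
      stop(sprintf("client '%s' has no training data",
                   if (is.null(cl$client_id)) "?" else cl$client_id),
           call. = FALSE)
    }
  }
  if (is.null(eval_data)) {
    vals <- Filter(function(cl) !is.null(cl$val_data) &&
                     length(cl$val_data$y) > 0, clients)
    if (length(vals)) {
      xs <- lapply(vals, function(cl) cl$val_data$x)
      n_tot <- sum(vapply(xs, function(a) dim(a)[5L], 1L))
      d <- dim(xs[[1L]])
      xall <- array(0, c(d[1:4], n_tot))
      at <- 0L
      for (a in xs) {
        nb <- dim(a)[5L]
        xall[, , , , at + seq_len(nb)] <- a
        at <- at + nb
      }
      eval_data <- list(x = xall,
                        y = unlist(lapply(vals, function(cl) cl$val_data$y)))
    }
  }

  global <- build_model(model_cfg)
  global_params <- get_parameters(global)
  round_rows <- list()
  global_rows <- list()

  for (r in seq_len(fed_cfg$n_rounds)) {
    updates <- vector("list", length(clients))
    for (k in seq_along(clients)) {
      cl <- clients[[k]]
      cid <- if (is.null(cl$client_id)) as.character(k) else cl$client_id
      cfg_k <- fed_cfg$client_train_cfg
      cfg_k$epochs <- fed_cfg$local_epochs
      cfg_k$seed <- if (!is.null(cl$seed)) as.integer(cl$seed) else
        derive_seed(fed_cfg$seed, k)
      local_model <- build_model(model_cfg)
      set_parameters(local_model, global_params)
      fit <- tryCatch(
        train_local(local_model, cl$train_data, val_data = NULL,
                    cfg = cfg_k,
                    epoch_offset = (r - 1L) * fed_cfg$local_epochs),
        error = function(e) {
          stop(sprintf("round %d: client '%s' failed: %s", r, cid,
                       conditionMessage(e)), call. = FALSE)
        }
      )
      last_loss <- if (nrow(fit$history)) {
        fit$history$train_loss[nrow(fit$history)]
      } else {
        NA_real_
      }
      updates[[k]] <- list(client_id = cid, parameters = fit$params,
                           n_samples = length(cl$train_data$y),
                           train_loss = last_loss)
      round_rows[[length(round_rows) + 1L]] <- data.frame(
        round = r, client_id = cid, train_loss = last_loss,
        n_samples = length(cl$train_data$y)
      )
    }
    global_params <- if (fed_cfg$local_epochs > 0L) {
      aggregate_fedavg(updates)
    } else {
      global_params
    }
    if (!is.null(eval_data)) {
      set_parameters(global, global_params)
      ev <- evaluate_model(global, eval_data)
      auc <- if (length(unique(eval_data$y)) == 2L) {
        roc_auc(ev$probs[, 2L], eval_data$y)
      } else {
        NA_real_
      }
      global_rows[[length(global_rows) + 1L]] <- data.frame(
        round = r, val_loss = ev$loss, val_acc = ev$acc, val_auc = auc
      )
    }
  }
  list(
    params = global_params,
    round_log = do.call(rbind, round_rows),
    global_log = if (length(global_rows)) do.call(rbind, global_rows) else NULL
  )
}
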