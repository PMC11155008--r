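#' Experiment presets mirroring the published model topologies
#'
#' Six presets: DL1/DL2 are centralized models pooling two hospitals'
#' data; FL1/FL3 are two-client federations of the same hospitals; FL2
#' and FL4 add hospital D as a third client. DL1/FL1/FL2 hold out
#' hospital C as the external test site, DL2/FL3/FL4 hold out hospital B.
#' Site identifiers are configurable so the presets apply to any cohort
#' with matching site structure.
#'
#' @param name One of `"DL1"`, `"DL2"`, `"FL1"`, `"FL2"`, `"FL3"`,
#'   `"FL4"`.
#' @param sites Character vector naming the four hospitals in the cohort
#'   (in the roles of A, B, C, D).
#' @return An `experiment_preset` list with `name`, `mode`
#'   (`"centralized"` or `"federated"`), `train_sites`, `test_site`, and
#'   `optimizer_preset`.
#' @examples
#' experiment_preset("FL1")
#' @export
experiment_preset <- function(name, sites = c("A", "B", "C", "D")) {
  name <- match.arg(name, c("DL1", "DL2", "FL1", "FL2", "FL3", "FL4"))
  stopifnot(length(sites) >= 3L)
  A <- sites[1L]; B <- sites[2L]; C <- sites[3L]
  D <- if (length(sites) >= 4L) sites[4L] else NA_character_
  def <- switch(name,
    DL1 = list(mode = "centralized", train = c(A, B), test = C,
               opt = "centralized"),
    FL1 = list(mode = "federated", train = c(A, B), test = C,
               opt = "federated_sim"),
    FL2 = list(mode = "federated", train = c(A, B, D), test = C,
               opt = "federated_real"),
    DL2 = list(mode = "centralized", train = c(A, C), test = B,
               opt = "centralized"),
    FL3 = list(mode = "federated", train = c(A, C), test = B,
               opt = "federated_sim"),
    FL4 = list(mode = "federated", train = c(A, C, D), test = B,
               opt = "federated_real")
  )
  if (anyNA(def$train)) {
    stop(sprintf("preset %s needs a fourth site", name), call. = FALSE)
  }
  if (def$test %in% def$train) {
    stop("test site overlaps training sites", call. = FALSE)
  }
  structure(
    list(name = name, mode = def$mode, train_sites = def$train,
         test_site = def$test, optimizer_preset = def$opt),
    class = "experiment_preset"
  )
}

pool_data <- function(data_list) {
  data_list <- Filter(function(d) length(d$y) > 0, data_list)
  xs <- lapply(data_list, `[[`, "x")
  d <- dim(xs[[1L]])
  n_tot <- sum(vapply(xs, function(a) dim(a)[5L], 1L))
  xall <- array(0, c(d[1:4], n_tot))
  at <- 0L
  for (a in xs) {
    nb <- dim(a)[5L]
    xall[, , , , at + seq_len(nb)] <- a
    at <- at + nb
  }
  list(x = xall,
       y = unlist(lapply(data_list, `[[`, "y")),
       ids = unlist(lapply(data_list, `[[`, "ids")),
       sites = unlist(lapply(data_list, `[[`, "sites")))
}

#' Run one experiment preset on a cohort
#'
#' Centralized mode pools the training sites' patients and makes one
#' stratified 7:3 split; federated mode gives each training site its own
#' 7:3 split and client. The test site never contributes to training or
#' model selection — disjointness of test and training patient ids is
#' asserted on every run. Metrics are reported for the (pooled) training
#' split, validation split, and test site.
#'
#' @param preset An [experiment_preset()] (or its name).
#' @param cohort A patch dataset from [load_cohort_patches()], or a
#'   manifest from [generate_cohort()] (patches are then loaded at the
#'   model's input size).
#' @param seed Master seed for splits, initialization, and training.
#' @param model_cfg A [model_config()]; defaults to the standard 64-voxel
#'   network, or use [tiny_model_config()] for desk-scale runs.
#' @param n_rounds,local_epochs Federated schedule (defaults 10 and 50).
#' @param epochs Centralized epoch count (default 100).
#' @param augmentation Optional [augmentation_config()] for training.
#' @param n_boot Bootstrap replicates for AUC intervals (0 to skip).
#' @return A `run_record`: preset, seed, `metrics` (training /
#'   validation / testing [metrics_report()]s), `test_scores`,
#'   `test_labels`, `params`, `history` or `round_log`.
#' @export
run_experiment <- function(preset, cohort, seed = 1,
                           model_cfg = model_config(),
                           n_rounds = 10, local_epochs = 50, epochs = 100,
                           augmentation = NULL, n_boot = 500) {
  if (is.character(preset)) preset <- experiment_preset(preset)
  stopifnot(inherits(preset, "experiment_preset"))
  if (is.data.frame(cohort)) {
    cohort <- load_cohort_patches(cohort, patch_size = model_cfg$input_size)
  }
  sites_present <- unique(cohort$sites)
  need <- c(preset$train_sites, preset$test_site)
  missing_site <- setdiff(need, sites_present)
  if (length(missing_site)) {
    stop(sprintf("cohort is missing site '%s'", missing_site[1L]),
         call. = FALSE)
  }

  test_data <- subset_data(cohort, which(cohort$sites == preset$test_site))
  site_data <- lapply(preset$train_sites, function(s) {
    subset_data(cohort, which(cohort$sites == s))
  })
  names(site_data) <- preset$train_sites

  # stratified 7:3 split per pooling unit
  split_one <- function(d, s) {
    sp <- split_cohort(d$ids, d$y, ratio = 0.7, seed = s)
    list(train = subset_data(d, sp$train_ids),
         val = subset_data(d, sp$val_ids))
  }

  model_cfg$init_seed <- derive_seed(seed, 11L)
  if (preset$mode == "centralized") {
    pooled <- pool_data(site_data)
    sp <- split_one(pooled, derive_seed(seed, 1L))
    train_data <- sp$train; val_data <- sp$val
    cfg <- train_config(preset = preset$optimizer_preset, epochs = epochs,
                        augmentation = augmentation,
                        seed = derive_seed(seed, 2L))
    model <- build_model(model_cfg)
    fit <- train_local(model, train_data, val_data, cfg)
    params <- fit$params
    log <- list(history = fit$history)
  } else {
    splits <- lapply(seq_along(site_data), function(i) {
      split_one(site_data[[i]], derive_seed(seed, 100L + i))
    })
    clients <- lapply(seq_along(splits), function(i) {
      list(client_id = preset$train_sites[i],
           train_data = splits[[i]]$train, val_data = splits[[i]]$val)
    })
    fed_cfg <- federated_config(
      n_rounds = n_rounds, local_epochs = local_epochs,
      client_train_cfg = train_config(preset = preset$optimizer_preset,
                                      augmentation = augmentation),
      seed = derive_seed(seed, 2L)
    )
    fed <- run_federated(clients, model_cfg, fed_cfg)
    params <- fed$params
    train_data <- pool_data(lapply(splits, `[[`, "train"))
    val_data <- pool_data(lapply(splits, `[[`, "val"))
    log <- list(round_log = fed$round_log, global_log = fed$global_log)
  }

  if (length(intersect(train_data$ids, test_data$ids))) {
    stop("data leakage: test patients appear in the training split",
         call. = FALSE)
  }

  model <- build_model(model_cfg)
  set_parameters(model, params)
  score_set <- function(d) {
    ev <- evaluate_model(model, d)
    list(scores = ev$probs[, 2L], labels = d$y)
  }
  report <- function(sc) {
    metrics_report(sc$scores, sc$labels, n_boot = n_boot,
                   seed = derive_seed(seed, 3L))
  }
  sc_train <- score_set(train_data)
  sc_val <- score_set(val_data)
  sc_test <- score_set(test_data)
  structure(
    c(list(
      preset = preset$name, mode = preset$mode, seed = seed,
      test_site = preset$test_site,
      metrics = list(training = report(sc_train),
                     validation = report(sc_val),
                     testing = report(sc_test)),
      test_scores = sc_test$scores, test_labels = sc_test$labels,
      params = params
    ), log),
    class = "run_record"
  )
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record> %s (%s), test site %s, seed %d\n",
              x$preset, x$mode, x$test_site, x$seed))
  for (nm in names(x$metrics)) {
    cat(sprintf("  %-10s", nm)); print(x$metrics[[nm]])
  }
  invisible(x)
}

#' Compare experiment runs on a shared test set
#'
#' Builds the side-by-side Training/Validation/Testing x
#' Acc/AUC/Spe/Recall table for a set of runs, and the pairwise test-AUC
#' difference of every run against the first, with a bootstrap interval
#' (joint resampling of the shared test patients).
#'
#' @param records List of `run_record`s sharing a test site.
#' @param n_boot Bootstrap replicates for the AUC-difference intervals.
#' @param seed Seed for the bootstrap.
#' @return List with `table` (one row per run) and `auc_diff` (one row
#'   per non-reference run: difference, lower, upper).
#' @export
compare_runs <- function(records, n_boot = 1000, seed = 1) {
  stopifnot(length(records) >= 2L)
  test_sites <- vapply(records, `[[`, "", "test_site")
  if (length(unique(test_sites)) != 1L) {
    stop("runs use different test sites and are not comparable",
         call. = FALSE)
  }
  grab <- function(rec) {
    row <- list(model = rec$preset)
    for (ph in c("training", "validation", "testing")) {
      m <- rec$metrics[[ph]]
      short <- c(training = "train", validation = "val", testing = "test")[ph]
      row[[paste0(short, "_acc")]] <- m$accuracy
      row[[paste0(short, "_auc")]] <- m$auc
      row[[paste0(short, "_spe")]] <- m$specificity
      row[[paste0(short, "_recall")]] <- m$recall
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, lapply(records, grab))

  ref <- records[[1L]]
  y <- ref$test_labels
  diffs <- lapply(records[-1L], function(rec) {
    if (!identical(rec$test_labels, y)) {
      stop("test labels differ between runs; not the same test cohort",
           call. = FALSE)
    }
    d0 <- roc_auc(rec$test_scores, y) - roc_auc(ref$test_scores, y)
    pos <- which(y == 1L); neg <- which(y == 0L)
    bs <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        ix <- c(sample(pos, length(pos), TRUE), sample(neg, length(neg), TRUE))
        roc_auc(rec$test_scores[ix], y[ix]) -
          roc_auc(ref$test_scores[ix], y[ix])
      }, 1)
    })
    q <- stats::quantile(bs, c(0.025, 0.975), names = FALSE)
    data.frame(model = rec$preset, reference = ref$preset,
               auc_diff = d0, lower = q[1L], upper = q[2L])
  })
  list(table = tab, auc_diff = do.call(rbind, diffs))
}

#' Write a run's artifacts to disk
#'
#' Emits metrics JSON, training history / round log CSV, test ROC curve
#' CSV, confusion matrix CSV, and the model checkpoint (parameter archive
#' plus model configuration JSON).
#'
#' @param record A `run_record` from [run_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_record <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  metr <- lapply(record$metrics, function(m) {
    list(accuracy = m$accuracy, auc = m$auc,
         auc_ci = as.numeric(m$auc_ci), specificity = m$specificity,
         recall = m$recall, n = m$n)
  })
  jsonlite::write_json(
    list(preset = record$preset, seed = record$seed,
         test_site = record$test_site, metrics = metr),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA
  )
  if (!is.null(record$history)) {
    utils::write.csv(record$history, file.path(dir, "history.csv"),
                     row.names = FALSE)
  }
  if (!is.null(record$round_log)) {
    utils::write.csv(record$round_log, file.path(dir, "round_log.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(roc_curve(record$test_scores, record$test_labels),
                   file.path(dir, "roc_test.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(record$metrics$testing$confusion),
                   file.path(dir, "confusion_test.csv"), row.names = FALSE)
  save_parameters(record$params, file.path(dir, "checkpoint.bin"))
  invisible(dir)
}
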