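# small four-site cohort shared by the experiment tests
mini_cohort <- function(seed = 3) {
  ph <- phantom_spec(volume_shape = c(24, 24, 24),
                     tumor_axes_mean_responsive = c(3, 3, 3),
                     tumor_axes_mean_nonresponsive = c(6, 6, 6),
                     tumor_axes_sd = 0.6, tumor_intensity_contrast = 100,
                     texture_sd = 3)
  sites <- list(
    site_spec("A", 10, noise_sd = 4),
    site_spec("B", 8, noise_sd = 5, intensity_offset = 10),
    site_spec("C", 8, noise_sd = 5, intensity_offset = -10),
    site_spec("D", 8, noise_sd = 8, intensity_offset = 20)
  )
  man <- generate_cohort(sites, ph, seed = seed, write = FALSE)
  load_cohort_patches(man, patch_size = 16)
}

test_that("the six presets encode the published topologies", {
  expect_equal(experiment_preset("DL1")$train_sites, c("A", "B"))
  expect_equal(experiment_preset("DL1")$test_site, "C")
  expect_equal(experiment_preset("DL1")$mode, "centralized")
  expect_equal(experiment_preset("FL1")$mode, "federated")
  expect_equal(experiment_preset("FL2")$train_sites, c("A", "B", "D"))
  expect_equal(experiment_preset("DL2")$test_site, "B")
  expect_equal(experiment_preset("FL3")$train_sites, c("A", "C"))
  expect_equal(experiment_preset("FL4")$train_sites, c("A", "C", "D"))
  for (nm in c("DL1", "DL2", "FL1", "FL2", "FL3", "FL4")) {
    p <- experiment_preset(nm)
    expect_false(p$test_site %in% p$train_sites)
  }
  expect_equal(experiment_preset("FL1")$optimizer_preset, "federated_sim")
  expect_equal(experiment_preset("FL2")$optimizer_preset, "federated_real")
  expect_error(experiment_preset("FL2", sites = c("A", "B", "C")),
               "fourth site")
})

test_that("centralized and federated experiments run end to end", {
  cohort <- mini_cohort()
  mcfg <- tiny_model_config()
  dl <- run_experiment("DL1", cohort, seed = 2, model_cfg = mcfg,
                       epochs = 2, n_boot = 50)
  expect_s3_class(dl, "run_record")
  expect_named(dl$metrics, c("training", "validation", "testing"))
  expect_equal(dl$metrics$testing$n, 8)
  expect_equal(nrow(dl$history), 2L)

  fl <- run_experiment("FL1", cohort, seed = 2, model_cfg = mcfg,
                       n_rounds = 1, local_epochs = 1, n_boot = 50)
  expect_equal(nrow(fl$round_log), 2L)  # 2 clients x 1 round
  expect_true(all(fl$test_scores >= 0 & fl$test_scores <= 1))

  missing_site <- list(
    x = cohort$x[, , , , cohort$sites == "A", drop = FALSE],
    y = cohort$y[cohort$sites == "A"],
    ids = cohort$ids[cohort$sites == "A"],
    sites = cohort$sites[cohort$sites == "A"]
  )
  expect_error(run_experiment("DL1", missing_site, seed = 1,
                              model_cfg = mcfg, epochs = 1),
               "missing site")
})

test_that("experiments are deterministic and leakage-free", {
  cohort <- mini_cohort()
  mcfg <- tiny_model_config()
  r1 <- run_experiment("FL1", cohort, seed = 7, model_cfg = mcfg,
                       n_rounds = 1, local_epochs = 1, n_boot = 0)
  r2 <- run_experiment("FL1", cohort, seed = 7, model_cfg = mcfg,
                       n_rounds = 1, local_epochs = 1, n_boot = 0)
  expect_identical(r1$test_scores, r2$test_scores)
  expect_identical(r1$params, r2$params)
  # the test site never appears in training: all test ids are site C
  test_ids <- cohort$ids[cohort$sites == "C"]
  expect_true(all(grepl("^C_", test_ids)))
})

test_that("compare_runs builds the side-by-side table and AUC differences", {
  cohort <- mini_cohort()
  mcfg <- tiny_model_config()
  dl <- run_experiment("DL1", cohort, seed = 4, model_cfg = mcfg,
                       epochs = 1, n_boot = 0)
  fl <- run_experiment("FL1", cohort, seed = 4, model_cfg = mcfg,
                       n_rounds = 1, local_epochs = 1, n_boot = 0)
  cmp <- compare_runs(list(dl, fl), n_boot = 100, seed = 1)
  expect_equal(nrow(cmp$table), 2L)
  expect_true(all(c("train_acc", "train_auc", "train_spe", "train_recall",
                    "val_acc", "val_auc", "val_spe", "val_recall",
                    "test_acc", "test_auc", "test_spe", "test_recall")
                  %in% names(cmp$table)))
  expect_equal(cmp$auc_diff$auc_diff,
               fl$metrics$testing$auc - dl$metrics$testing$auc,
               tolerance = 1e-12)

  self <- compare_runs(list(dl, dl), n_boot = 50, seed = 1)
  expect_equal(self$auc_diff$auc_diff, 0)
  expect_equal(self$auc_diff$lower, 0)
  expect_equal(self$auc_diff$upper, 0)

  dl_b <- run_experiment("DL2", cohort, seed = 4, model_cfg = mcfg,
                         epochs = 1, n_boot = 0)
  expect_error(compare_runs(list(dl, dl_b)), "different test sites")
})

test_that("run artifacts are written for downstream inspection", {
  dir <- withr::local_tempdir()
  cohort <- mini_cohort()
  dl <- run_experiment("DL1", cohort, seed = 5,
                       model_cfg = tiny_model_config(), epochs = 1,
                       n_boot = 20)
  write_run_record(dl, dir)
  expect_true(file.exists(file.path(dir, "metrics.json")))
  expect_true(file.exists(file.path(dir, "history.csv")))
  expect_true(file.exists(file.path(dir, "roc_test.csv")))
  expect_true(file.exists(file.path(dir, "confusion_test.csv")))
  expect_true(file.exists(file.path(dir, "checkpoint.bin")))
  meta <- jsonlite::read_json(file.path(dir, "metrics.json"))
  expect_equal(meta$preset, "DL1")
  ck <- load_parameters(file.path(dir, "checkpoint.bin"))
  expect_equal(names(ck), names(dl$params))
})
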