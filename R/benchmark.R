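#' Desk-scale three-site phantom cohort
#'
#' The reduced benchmark conditions used throughout the package's
#' end-to-end checks: three hospital sites of unequal size (60/30/30 by
#' default) with site-level distribution shift (intensity offsets 0 /
#' +15 / -15, noise SD 5 / 8 / 10, native spacings 1 / 1.25 / 0.8 mm),
#' ~45% responsive prevalence, and a strong morphological class effect
#' (mean semi-axes 3.5 mm responsive vs 6.5 mm nonresponsive, SD 0.8), so
#' tumors fit a 16-voxel patch after 1 mm resampling.
#'
#' @param seed Master seed.
#' @param n_per_site Integer length-3 site sizes.
#' @param label_effect_size Morphology/label coupling in [0, 1].
#' @return A cohort manifest (in memory, see [generate_cohort()]).
#' @export
desk_cohort <- function(seed, n_per_site = c(60, 30, 30),
                        label_effect_size = 1) {
  phantom <- phantom_spec(
    volume_shape = c(32, 32, 32),
    tumor_axes_mean_responsive = c(3.5, 3.5, 3.5),
    tumor_axes_mean_nonresponsive = c(6.5, 6.5, 6.5),
    tumor_axes_sd = 0.8, tumor_intensity_contrast = 100,
    texture_sd = 5, label_effect_size = label_effect_size
  )
  sites <- list(
    site_spec("S1", n_per_site[1L], intensity_offset = 0, noise_sd = 5,
              voxel_spacing = c(1, 1, 1)),
    site_spec("S2", n_per_site[2L], intensity_offset = 15, noise_sd = 8,
              voxel_spacing = c(1.25, 1.25, 1.25)),
    site_spec("S3", n_per_site[3L], intensity_offset = -15, noise_sd = 10,
              voxel_spacing = c(0.8, 0.8, 0.8))
  )
  generate_cohort(sites, phantom, seed = seed, write = FALSE)
}

#' Centralized-vs-federated parity benchmark at desk scale
#'
#' For each seed: generates a [desk_cohort()], makes one stratified 7:3
#' split per site, trains (a) a centralized model on the pooled training
#' splits and (b) a three-client federation, both with the reduced
#' 16-voxel network and matched optimization budgets (centralized
#' `n_rounds * local_epochs` epochs vs `n_rounds` rounds of
#' `local_epochs`), and scores both on the same held-out set (the pooled
#' validation splits, never used for weight updates).
#'
#' @param seeds Integer vector of seeds (one cohort + run per seed).
#' @param n_rounds,local_epochs Federated schedule (defaults 5 and 2).
#' @param label_effect_size Passed to [desk_cohort()].
#' @return Data frame with one row per seed: `seed`, `auc_centralized`,
#'   `auc_federated`, `first_round_val_loss`, `final_round_val_loss`.
#' @export
parity_benchmark <- function(seeds, n_rounds = 5, local_epochs = 2,
                             label_effect_size = 1) {
  rows <- lapply(seeds, function(seed) {
    manifest <- desk_cohort(seed, label_effect_size = label_effect_size)
    cohort <- load_cohort_patches(manifest, patch_size = 16)
    site_ids <- c("S1", "S2", "S3")
    splits <- lapply(seq_along(site_ids), function(i) {
      d <- subset_data(cohort, which(cohort$sites == site_ids[i]))
      sp <- split_cohort(d$ids, d$y, ratio = 0.7,
                         seed = derive_seed(seed, 200L + i))
      list(train = subset_data(d, sp$train_ids),
           val = subset_data(d, sp$val_ids))
    })
    heldout <- pool_data(lapply(splits, `[[`, "val"))
    pooled_train <- pool_data(lapply(splits, `[[`, "train"))
    mcfg <- tiny_model_config(init_seed = derive_seed(seed, 11L))

    central <- build_model(mcfg)
    train_local(central, pooled_train, NULL,
                train_config(preset = "centralized",
                             epochs = n_rounds * local_epochs,
                             seed = derive_seed(seed, 2L)))
    auc_c <- roc_auc(evaluate_model(central, heldout)$probs[, 2L],
                     heldout$y)

    clients <- lapply(seq_along(splits), function(i) {
      list(client_id = site_ids[i], train_data = splits[[i]]$train,
           val_data = splits[[i]]$val)
    })
    fed <- run_federated(
      clients, mcfg,
      federated_config(n_rounds = n_rounds, local_epochs = local_epochs,
                       client_train_cfg = train_config(preset = "federated_real"),
                       seed = derive_seed(seed, 2L)),
      eval_data = heldout
    )
    fmodel <- build_model(mcfg)
    set_parameters(fmodel, fed$params)
    auc_f <- roc_auc(evaluate_model(fmodel, heldout)$probs[, 2L],
                     heldout$y)
    data.frame(
      seed = seed, auc_centralized = auc_c, auc_federated = auc_f,
      first_round_val_loss = fed$global_log$val_loss[1L],
      final_round_val_loss = fed$global_log$val_loss[nrow(fed$global_log)]
    )
  })
  do.call(rbind, rows)
}
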