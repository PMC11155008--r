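#' Site specification for the phantom cohort generator
#'
#' Describes one hospital site: its size, class prevalence, and a
#' controllable site-level distribution shift (additive intensity offset,
#' acquisition noise, native voxel spacing). Shifted sites emulate the
#' non-IID behavior of real multicenter imaging data, where one hospital's
#' scanner and protocol differ from the others'.
#'
#' @param site_id Short string identifier, e.g. `"A"`.
#' @param n_patients Number of patients (>= 2).
#' @param responsive_fraction Fraction of responsive patients in [0, 1].
#'   Default 0.45, matching the ~45% responsive prevalence of the
#'   multicenter cohort the generator emulates (110 of 245).
#' @param intensity_offset Additive site intensity shift (CT-like units).
#' @param noise_sd Standard deviation of site acquisition noise (>= 0).
#' @param voxel_spacing Native voxel spacing in mm, each in [0.5, 5.0].
#' @return A `site_spec` list.
#' @examples
#' site_spec("A", 102)
#' @export
site_spec <- function(site_id, n_patients,
                      responsive_fraction = 0.45,
                      intensity_offset = 0,
                      noise_sd = 10,
                      voxel_spacing = c(1, 1, 1)) {
  if (!is.character(site_id) || length(site_id) != 1L || !nzchar(site_id)) {
    stop("`site_id` must be a non-empty string", call. = FALSE)
  }
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 2L) {
    stop("`n_patients` must be an integer >= 2", call. = FALSE)
  }
  stop_if_not_scalar_prob(responsive_fraction, "responsive_fraction")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) != 3L ||
      any(voxel_spacing < 0.5) || any(voxel_spacing > 5.0)) {
    stop("`voxel_spacing` components must lie in [0.5, 5.0] mm", call. = FALSE)
  }
  structure(
    list(
      site_id = site_id, n_patients = n_patients,
      responsive_fraction = responsive_fraction,
      intensity_offset = intensity_offset, noise_sd = noise_sd,
      voxel_spacing = voxel_spacing
    ),
    class = "site_spec"
  )
}

#' Phantom specification: tumor geometry and its coupling to the label
#'
#' The phantom is a homogeneous background containing a single ellipsoidal
#' "tumor" of elevated intensity. Tumor semi-axes (mm) are drawn per
#' patient from a class-conditional normal distribution, which is how the
#' response label becomes predictable from morphology: `label_effect_size`
#' in [0, 1] interpolates the two class means between their common average
#' (0: identical distributions, nothing to learn) and the fully separated
#' values given here (1: maximal separation). `label_noise` is the
#' probability that a patient's morphology is drawn from the wrong class.
#'
#' Defaults target the standard 64 mm patch: semi-axes stay well under
#' 32 mm so every tumor fits the patch after 1 mm isotropic resampling.
#'
#' @param volume_shape Integer length-3, phantom extent in voxels.
#' @param tumor_axes_mean_responsive,tumor_axes_mean_nonresponsive
#'   Length-3 mean ellipsoid semi-axes (mm) per class; responsive tumors
#'   are smaller by default.
#' @param tumor_axes_sd Between-patient SD of each semi-axis (mm).
#' @param tumor_intensity_contrast Added intensity inside the tumor.
#' @param texture_sd SD of voxelwise Gaussian texture (>= 0).
#' @param background Background intensity before site offset.
#' @param label_effect_size Morphology/label coupling in [0, 1]; see above.
#' @param label_noise Class-swap probability in [0, 0.5].
#' @return A `phantom_spec` list.
#' @examples
#' phantom_spec()
#' @export
phantom_spec <- function(volume_shape = c(96, 96, 96),
                         tumor_axes_mean_responsive = c(10, 10, 10),
                         tumor_axes_mean_nonresponsive = c(18, 18, 18),
                         tumor_axes_sd = 2,
                         tumor_intensity_contrast = 100,
                         texture_sd = 5,
                         background = 0,
                         label_effect_size = 1,
                         label_noise = 0) {
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 4L)) {
    stop("`volume_shape` must be 3 integers >= 4", call. = FALSE)
  }
  for (ax in list(tumor_axes_mean_responsive, tumor_axes_mean_nonresponsive)) {
    if (length(ax) != 3L || any(ax <= 1)) {
      stop("tumor semi-axes must be 3 values > 1 mm", call. = FALSE)
    }
    if (any(ax > 32)) {
      stop("tumor semi-axes must be <= 32 mm so the tumor fits a 64 mm patch",
           call. = FALSE)
    }
  }
  if (tumor_axes_sd <= 0) stop("`tumor_axes_sd` must be > 0", call. = FALSE)
  if (texture_sd < 0) stop("`texture_sd` must be >= 0", call. = FALSE)
  if (label_effect_size < 0) {
    stop("`label_effect_size` must be >= 0", call. = FALSE)
  }
  if (label_noise < 0 || label_noise > 0.5) {
    stop("`label_noise` must lie in [0, 0.5]", call. = FALSE)
  }
  structure(
    list(
      volume_shape = volume_shape,
      tumor_axes_mean_responsive = as.numeric(tumor_axes_mean_responsive),
      tumor_axes_mean_nonresponsive = as.numeric(tumor_axes_mean_nonresponsive),
      tumor_axes_sd = tumor_axes_sd,
      tumor_intensity_contrast = tumor_intensity_contrast,
      texture_sd = texture_sd,
      background = background,
      label_effect_size = label_effect_size,
      label_noise = label_noise
    ),
    class = "phantom_spec"
  )
}

# Class-conditional semi-axis means after applying the effect size.
effective_axes_mean <- function(phantom, label) {
  mid <- (phantom$tumor_axes_mean_responsive +
            phantom$tumor_axes_mean_nonresponsive) / 2
  target <- if (identical(label, "responsive")) {
    phantom$tumor_axes_mean_responsive
  } else {
    phantom$tumor_axes_mean_nonresponsive
  }
  mid + phantom$label_effect_size * (target - mid)
}

#' Generate one phantom patient: image volume plus tumor mask
#'
#' Builds a centered ellipsoidal tumor on a homogeneous background at the
#' site's native voxel spacing. The image is
#' background + site intensity offset + contrast inside the tumor +
#' voxelwise Gaussian texture + site acquisition noise. Bit-identical
#' output for identical (specs, label, seed).
#'
#' @param phantom A [phantom_spec()].
#' @param site A [site_spec()].
#' @param label `"responsive"` or `"nonresponsive"`.
#' @param seed Integer seed for this patient.
#' @return List with elements `image` ([image_volume()]), `mask`
#'   ([binary_mask()]), and `axes` (the drawn semi-axes, mm).
#' @examples
#' p <- make_phantom(phantom_spec(volume_shape = c(48, 48, 48)),
#'                   site_spec("A", 10), "responsive", seed = 1)
#' sum(p$mask$data) > 0
#' @export
make_phantom <- function(phantom, site, label, seed) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(site, "site_spec"))
  label <- match.arg(label, c("responsive", "nonresponsive"))
  shp <- phantom$volume_shape
  sp <- site$voxel_spacing

  axes_mean <- effective_axes_mean(phantom, label)
  with_seed(seed, {
    axes <- pmax(1.5, stats::rnorm(3, axes_mean, phantom$tumor_axes_sd))
    # physical half-extent available around the volume center, per axis
    half_extent <- shp * sp / 2
    bad <- which(axes >= half_extent - sp)
    if (length(bad)) {
      stop(sprintf(
        "tumor semi-axis %.1f mm exceeds volume half-extent on axis %d (%s)",
        axes[bad[1L]], bad[1L], c("x", "y", "z")[bad[1L]]
      ), call. = FALSE)
    }
    center_mm <- (shp - 1) / 2 * sp
    xs <- ((seq_len(shp[1L]) - 1) * sp[1L] - center_mm[1L]) / axes[1L]
    ys <- ((seq_len(shp[2L]) - 1) * sp[2L] - center_mm[2L]) / axes[2L]
    zs <- ((seq_len(shp[3L]) - 1) * sp[3L] - center_mm[3L]) / axes[3L]
    inside <- outer(outer(xs^2, ys^2, "+"), zs^2, "+") <= 1
    mask <- array(as.numeric(inside), dim = shp)

    img <- array(phantom$background + site$intensity_offset, dim = shp) +
      mask * phantom$tumor_intensity_contrast
    if (phantom$texture_sd > 0) {
      img <- img + array(stats::rnorm(prod(shp), 0, phantom$texture_sd), shp)
    }
    if (site$noise_sd > 0) {
      img <- img + array(stats::rnorm(prod(shp), 0, site$noise_sd), shp)
    }
    list(
      image = image_volume(img, spacing = sp),
      mask = binary_mask(mask, spacing = sp),
      axes = axes
    )
  })
}

#' Generate a multi-site phantom cohort
#'
#' Draws per-patient labels, demographics and phantom images for each
#' site, writes NIfTI image/mask pairs under `out_dir`, and returns the
#' cohort manifest. Labels are assigned in `"exact"` mode by default
#' (round(n * responsive_fraction) responsive patients per site, then
#' shuffled) or per-patient `"bernoulli"` draws. Per-patient seeds follow
#' a fixed counter scheme from the master seed, so extending a cohort
#' never changes already-generated patients.
#'
#' @param sites List of [site_spec()] (>= 1).
#' @param phantom A [phantom_spec()].
#' @param seed Master integer seed.
#' @param out_dir Output directory for the NIfTI files and
#'   `manifest.csv`; created if missing. With `write = FALSE` no files are
#'   written and `image_path`/`mask_path` are `NA`.
#' @param label_mode `"exact"` or `"bernoulli"`.
#' @param write Write NIfTI/CSV output (default TRUE).
#' @return A data frame (the manifest) with columns `patient_id`,
#'   `site_id`, `label`, `age`, `sex`, `image_path`, `mask_path`, plus a
#'   hidden list column is avoided: drawn tumor axes are in attribute
#'   `"axes"` (n x 3 matrix), and in-memory volumes in attribute
#'   `"volumes"` when `write = FALSE`.
#' @examples
#' m <- generate_cohort(list(site_spec("A", 4), site_spec("B", 3)),
#'                      phantom_spec(volume_shape = c(32, 32, 32),
#'                                   tumor_axes_mean_responsive = c(4, 4, 4),
#'                                   tumor_axes_mean_nonresponsive = c(7, 7, 7),
#'                                   tumor_axes_sd = 1),
#'                      seed = 1, write = FALSE)
#' table(m$site_id)
#' @export
generate_cohort <- function(sites, phantom, seed, out_dir = NULL,
                            label_mode = c("exact", "bernoulli"),
                            write = TRUE) {
  if (inherits(sites, "site_spec")) sites <- list(sites)
  if (!length(sites)) stop("need at least one site", call. = FALSE)
  label_mode <- match.arg(label_mode)
  if (write) {
    if (is.null(out_dir)) stop("`out_dir` is required when write = TRUE",
                               call. = FALSE)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) {
      stop(sprintf("cannot create output directory '%s'", out_dir),
           call. = FALSE)
    }
  }

  rows <- list()
  volumes <- list()
  axes_all <- list()
  counter <- 0L
  for (site in sites) {
    n <- site$n_patients
    labels <- with_seed(derive_seed(seed, counter), {
      if (label_mode == "exact") {
        n_resp <- round_half_up(n * site$responsive_fraction)
        sample(rep(c("responsive", "nonresponsive"), c(n_resp, n - n_resp)))
      } else {
        ifelse(stats::runif(n) < site$responsive_fraction,
               "responsive", "nonresponsive")
      }
    })
    counter <- counter + 1L
    for (i in seq_len(n)) {
      pid <- sprintf("%s_%03d", site$site_id, i)
      pseed <- derive_seed(seed, counter)
      counter <- counter + 1L
      # demographics and label noise come from a seed distinct from the image
      demo <- with_seed(derive_seed(pseed, 1L), {
        list(
          age = round(stats::rnorm(1, 65, 9)),
          sex = if (stats::runif(1) < 0.7) "M" else "F",
          swap = stats::runif(1) < phantom$label_noise
        )
      })
      draw_label <- labels[i]
      if (demo$swap) {
        draw_label <- setdiff(c("responsive", "nonresponsive"), draw_label)
      }
      ph <- make_phantom(phantom, site, draw_label, seed = pseed)
      img_path <- mask_path <- NA_character_
      if (write) {
        img_path <- file.path(out_dir, paste0(pid, "_image.nii.gz"))
        mask_path <- file.path(out_dir, paste0(pid, "_mask.nii.gz"))
        write_volume(ph$image, img_path)
        write_volume(ph$mask, mask_path)
      } else {
        volumes[[pid]] <- ph
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, site_id = site$site_id, label = labels[i],
        age = demo$age, sex = demo$sex,
        image_path = img_path, mask_path = mask_path,
        stringsAsFactors = FALSE
      )
      axes_all[[pid]] <- ph$axes
    }
  }
  manifest <- do.call(rbind, rows)
  attr(manifest, "axes") <- do.call(rbind, axes_all)
  if (!write) attr(manifest, "volumes") <- volumes
  if (write) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  manifest
}
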