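# --- separable cubic B-spline resampling -----------------------------------
#
# Interpolation is exact at the input voxel centers: per axis we evaluate
# the cubic B-spline basis at the output coordinates (matrix S) and apply
# the inverse of the same basis evaluated at the input nodes (matrix B,
# tridiagonal 1/6, 2/3, 1/6 with mirrored boundary), i.e. out = S B^{-1} v.
# Resampling to the input grid is then the identity up to solver roundoff.

cubic_bspline <- function(t) {
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at < 1
  w[i1] <- 2 / 3 - at[i1]^2 + at[i1]^3 / 2
  i2 <- at >= 1 & at < 2
  w[i2] <- (2 - at[i2])^3 / 6
  w
}

# reflect 1-based index j into 1..n (mirror boundary, period 2n - 2)
mirror_index <- function(j, n) {
  if (n == 1L) return(rep(1L, length(j)))
  m <- (j - 1L) %% (2L * n - 2L)
  m <- ifelse(m >= n, 2L * n - 2L - m, m)
  m + 1L
}

# basis matrix: rows = output coords t (1-based input-index units)
bspline_basis_matrix <- function(t, n) {
  S <- matrix(0, length(t), n)
  j0 <- floor(t)
  for (off in -1:2) {
    j <- j0 + off
    w <- cubic_bspline(t - j)
    jm <- mirror_index(as.integer(j), n)
    S[cbind(seq_along(t), jm)] <- S[cbind(seq_along(t), jm)] + w
  }
  S
}

bspline_axis_operator <- function(t, n) {
  S <- bspline_basis_matrix(t, n)
  B <- bspline_basis_matrix(seq_len(n), n)
  S %*% solve(B)
}

# mode-n product: apply matrix A along one axis of a 3D array
apply_axis <- function(A, arr, axis) {
  d <- dim(arr)
  if (axis == 1L) {
    array(A %*% matrix(arr, d[1L]), c(nrow(A), d[2L], d[3L]))
  } else if (axis == 2L) {
    aperm(apply_axis(A, aperm(arr, c(2L, 1L, 3L)), 1L), c(2L, 1L, 3L))
  } else {
    array(matrix(arr, d[1L] * d[2L]) %*% t(A), c(d[1L], d[2L], nrow(A)))
  }
}

#' Resample a volume to a target (isotropic) spacing
#'
#' Images are interpolated with cubic B-splines (with the exact
#' interpolation prefilter, applied separably per axis); masks use
#' nearest-neighbor so they stay binary. The output grid has
#' `round(shape * spacing / target)` voxels per axis, with voxel centers
#' at multiples of the target spacing from the first input voxel center.
#'
#' @param vol An [image_volume()] or [binary_mask()].
#' @param target_spacing Length-3 positive spacing in mm; default 1 mm
#'   isotropic.
#' @param mode `"bspline"` or `"nearest"`. Defaults to `"nearest"` for
#'   [binary_mask()] input and `"bspline"` otherwise.
#' @return A resampled object of the same class as `vol`.
#' @examples
#' v <- image_volume(array(7, c(8, 8, 8)), spacing = c(2, 2, 2))
#' dim(resample_isotropic(v)$data)  # 16 16 16
#' @export
resample_isotropic <- function(vol, target_spacing = c(1, 1, 1),
                               mode = NULL) {
  stopifnot(inherits(vol, "image_volume"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3L)
  if (any(target_spacing <= 0)) {
    stop("`target_spacing` must be positive", call. = FALSE)
  }
  if (is.null(mode)) {
    mode <- if (inherits(vol, "binary_mask")) "nearest" else "bspline"
  }
  mode <- match.arg(mode, c("bspline", "nearest"))

  d <- dim(vol$data)
  out_shape <- as.integer(round_half_up(d * vol$spacing / target_spacing))
  if (any(out_shape < 1L)) {
    stop(sprintf("degenerate axis: output shape %s",
                 paste(out_shape, collapse = "x")), call. = FALSE)
  }
  out <- vol$data
  for (ax in 1:3) {
    # output voxel k center at (k-1)*target in input-index units + 1
    t <- (seq_len(out_shape[ax]) - 1) * target_spacing[ax] / vol$spacing[ax] + 1
    if (mode == "nearest") {
      j <- pmin(pmax(as.integer(round_half_up(t)), 1L), d[ax])
      out <- switch(ax,
        out[j, , , drop = FALSE],
        out[, j, , drop = FALSE],
        out[, , j, drop = FALSE]
      )
    } else {
      out <- apply_axis(bspline_axis_operator(t, d[ax]), out, ax)
    }
  }
  if (inherits(vol, "binary_mask")) {
    binary_mask(out, spacing = target_spacing, origin = vol$origin)
  } else {
    image_volume(out, spacing = target_spacing, origin = vol$origin)
  }
}

#' Centroid of a tumor mask, in voxel coordinates
#'
#' Returns the mean coordinate of the nonzero voxels, rounded half-up per
#' axis (1-based indices, (x, y, z) order).
#'
#' @param mask A [binary_mask()] with at least one nonzero voxel.
#' @return Integer length-3 voxel coordinate.
#' @examples
#' m <- array(0, c(8, 8, 8)); m[5, 6, 7] <- 1
#' tumor_center(binary_mask(m))
#' @export
tumor_center <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  idx <- which(mask$data != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty: no tumor voxels", call. = FALSE)
  as.integer(round_half_up(colMeans(idx)))
}

#' A normalized tumor-centered patch
#'
#' @param data Cubic numeric array (side `size`).
#' @param patient_id,label Optional provenance carried through training.
#' @return A `ct_patch` list.
#' @export
ct_patch <- function(data, patient_id = NA_character_, label = NA_character_) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            length(unique(dim(data))) == 1L)
  structure(list(data = data, patient_id = patient_id, label = label),
            class = "ct_patch")
}

#' Extract a tumor-centered cubic patch
#'
#' Cuts a `size`^3 region whose center voxel (index `floor(size/2) + 1`
#' within the patch) sits at `center` in the source volume; regions
#' falling outside the volume are filled with `pad_value` (default 0, the
#' normalized minimum, mimicking air). Intensity normalization to [0, 1]
#' is applied first: `"window"` clips to `window` (default [-1000, 400],
#' a CT soft-tissue window in HU) and rescales; `"range"` uses the
#' volume's own min-max unless an explicit `window` is given; `"none"`
#' leaves intensities untouched.
#'
#' @param vol An [image_volume()], assumed already resampled to isotropic
#'   spacing (1 mm for the standard 64 mm patch).
#' @param center Integer length-3 voxel coordinate (e.g. [tumor_center()]).
#' @param size Patch side length in voxels (default 64).
#' @param normalize `"window"`, `"range"`, or `"none"`.
#' @param window Length-2 intensity window for normalization.
#' @param pad_value Fill value for out-of-volume voxels (normalized scale).
#' @param patient_id,label Provenance stored on the patch.
#' @return A [ct_patch()].
#' @export
extract_patch <- function(vol, center, size = 64,
                          normalize = c("window", "range", "none"),
                          window = c(-1000, 400), pad_value = 0,
                          patient_id = NA_character_, label = NA_character_) {
  stopifnot(inherits(vol, "image_volume"))
  normalize <- match.arg(normalize)
  size <- as.integer(size)
  if (size < 1L) stop("`size` must be >= 1", call. = FALSE)
  center <- as.integer(center)
  d <- dim(vol$data)

  x <- vol$data
  if (normalize == "window") {
    x <- pmin(pmax(x, window[1L]), window[2L])
    x <- (x - window[1L]) / (window[2L] - window[1L])
  } else if (normalize == "range") {
    w <- if (missing(window)) range(x) else window
    if (w[2L] <= w[1L]) w[2L] <- w[1L] + 1
    x <- pmin(pmax(x, w[1L]), w[2L])
    x <- (x - w[1L]) / (w[2L] - w[1L])
  }

  half <- size %/% 2L
  lo <- center - half          # first source index per axis (may be < 1)
  hi <- lo + size - 1L
  if (any(hi < 1L) || any(lo > d)) {
    stop("patch does not intersect the volume", call. = FALSE)
  }
  out <- array(pad_value, rep(size, 3L))
  src_lo <- pmax(lo, 1L); src_hi <- pmin(hi, d)
  dst_lo <- src_lo - lo + 1L; dst_hi <- src_hi - lo + 1L
  out[dst_lo[1L]:dst_hi[1L], dst_lo[2L]:dst_hi[2L], dst_lo[3L]:dst_hi[3L]] <-
    x[src_lo[1L]:src_hi[1L], src_lo[2L]:src_hi[2L], src_lo[3L]:src_hi[3L]]
  ct_patch(out, patient_id = patient_id, label = label)
}

#' Augmentation configuration
#'
#' Mirrors the training-time augmentation list: random horizontal
#' (left-right, x-axis) flip, random rotation about the z axis within
#' +/- 15 degrees, random cropping (pad then re-crop at a random offset),
#' and brightness/contrast jitter with factor 0.2. Saturation and hue are
#' recorded for fidelity but are inert on single-channel CT data.
#'
#' @param flip_prob Probability of a horizontal flip.
#' @param rotation_range_deg Length-2 rotation range in degrees.
#' @param crop_pad_voxels Padding (per side) before the random re-crop.
#' @param brightness,contrast Jitter half-widths: factors are drawn
#'   uniformly from [1 - x, 1 + x].
#' @param saturation,hue Recorded but inert for single-channel volumes.
#' @param enabled Master switch; `FALSE` makes [augment_patch()] the
#'   identity.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(flip_prob = 0.5,
                                rotation_range_deg = c(-15, 15),
                                crop_pad_voxels = 4,
                                brightness = 0.2, contrast = 0.2,
                                saturation = 0.2, hue = 0.2,
                                enabled = TRUE) {
  stop_if_not_scalar_prob(flip_prob, "flip_prob")
  stopifnot(length(rotation_range_deg) == 2L,
            rotation_range_deg[1L] <= rotation_range_deg[2L],
            crop_pad_voxels >= 0, brightness >= 0, contrast >= 0)
  structure(
    list(
      flip_prob = flip_prob,
      rotation_range_deg = as.numeric(rotation_range_deg),
      crop_pad_voxels = as.integer(crop_pad_voxels),
      brightness = brightness, contrast = contrast,
      saturation = saturation, hue = hue, enabled = isTRUE(enabled)
    ),
    class = "augmentation_config"
  )
}

# rotate all axial (x-y) slices about the z axis by `deg`, bilinear, pad fill
rotate_z <- function(arr, deg, pad_value = 0) {
  if (deg == 0) return(arr)
  n <- dim(arr)[1L]
  th <- deg * pi / 180
  c0 <- (n + 1) / 2
  g <- expand.grid(i = seq_len(n), j = seq_len(n))
  u <- g$i - c0; v <- g$j - c0
  xs <- cos(th) * u + sin(th) * v + c0
  ys <- -sin(th) * u + cos(th) * v + c0
  x0 <- floor(xs); y0 <- floor(ys)
  wx <- xs - x0; wy <- ys - y0
  A <- matrix(arr, n * n, dim(arr)[3L])
  gather <- function(xi, yi) {
    ok <- xi >= 1 & xi <= n & yi >= 1 & yi <= n
    idx <- ifelse(ok, xi + (yi - 1) * n, 1L)
    m <- A[idx, , drop = FALSE]
    m[!ok, ] <- pad_value
    m
  }
  out <- (1 - wx) * (1 - wy) * gather(x0, y0) +
    wx * (1 - wy) * gather(x0 + 1, y0) +
    (1 - wx) * wy * gather(x0, y0 + 1) +
    wx * wy * gather(x0 + 1, y0 + 1)
  array(out, dim(arr))
}

#' Apply training-time augmentation to a patch
#'
#' Applies, in order: horizontal flip (probability `flip_prob`), rotation
#' about the z axis by a uniform draw from `rotation_range_deg` (bilinear,
#' pad fill), pad-and-random-crop back to the original size, then
#' brightness and contrast jitter; the result is clipped to [0, 1]. Fully
#' deterministic given `seed`; the label and shape never change.
#'
#' @param patch A [ct_patch()].
#' @param cfg An [augmentation_config()].
#' @param seed Integer seed.
#' @param pad_value Fill value for rotation and crop padding.
#' @return The augmented [ct_patch()].
#' @export
augment_patch <- function(patch, cfg, seed, pad_value = 0) {
  stopifnot(inherits(patch, "ct_patch"), inherits(cfg, "augmentation_config"))
  if (!cfg$enabled) return(patch)
  n <- dim(patch$data)[1L]
  data <- with_seed(seed, {
    x <- patch$data
    if (stats::runif(1) < cfg$flip_prob) {
      x <- x[n:1, , , drop = FALSE]
    }
    deg <- stats::runif(1, cfg$rotation_range_deg[1L],
                        cfg$rotation_range_deg[2L])
    x <- rotate_z(x, deg, pad_value)
    if (cfg$crop_pad_voxels > 0L) {
      p <- cfg$crop_pad_voxels
      big <- array(pad_value, dim(x) + 2L * p)
      big[p + seq_len(n), p + seq_len(n), p + seq_len(n)] <- x
      off <- sample.int(2L * p + 1L, 3L, replace = TRUE) - 1L
      x <- big[off[1L] + seq_len(n), off[2L] + seq_len(n),
               off[3L] + seq_len(n)]
    }
    if (cfg$brightness > 0) {
      x <- x * stats::runif(1, 1 - cfg$brightness, 1 + cfg$brightness)
    }
    if (cfg$contrast > 0) {
      f <- stats::runif(1, 1 - cfg$contrast, 1 + cfg$contrast)
      x <- mean(x) + (x - mean(x)) * f
    }
    pmin(pmax(x, 0), 1)
  })
  ct_patch(data, patient_id = patch$patient_id, label = patch$label)
}

#' Load and preprocess a whole cohort into model-ready patches
#'
#' For each manifest row: read (or take in-memory) image and mask,
#' resample both to 1 mm isotropic spacing, locate the tumor centroid, and
#' extract a normalized patch of the requested size. Phantom cohorts are
#' normalized with a fixed window spanning the cohort's intensity range.
#'
#' @param manifest A cohort manifest from [generate_cohort()] (or a data
#'   frame with the same columns).
#' @param patch_size Patch side length in voxels (64 for the standard
#'   setup; 16 for the reduced desk-scale presets).
#' @param normalize,window Passed to [extract_patch()]. `window = NULL`
#'   computes a shared window from the cohort's global intensity range.
#' @return A list with `x` (array `size^3 x 1 x n`, i.e. dim
#'   `c(size, size, size, 1, n)`), `y` (integer 0/1; 1 = responsive),
#'   `ids`, `sites`.
#' @export
load_cohort_patches <- function(manifest, patch_size = 64,
                                normalize = "window", window = NULL) {
  volumes <- attr(manifest, "volumes")
  get_pair <- function(row) {
    if (!is.null(volumes)) {
      volumes[[row$patient_id]][c("image", "mask")]
    } else {
      list(image = read_volume(row$image_path),
           mask = read_mask(row$mask_path))
    }
  }
  if (is.null(window)) {
    rng <- c(Inf, -Inf)
    for (i in seq_len(nrow(manifest))) {
      v <- get_pair(manifest[i, ])$image
      rng <- c(min(rng[1L], min(v$data)), max(rng[2L], max(v$data)))
    }
    window <- rng
  }
  n <- nrow(manifest)
  x <- array(0, c(patch_size, patch_size, patch_size, 1L, n))
  y <- integer(n)
  for (i in seq_len(n)) {
    row <- manifest[i, ]
    pair <- get_pair(row)
    img <- resample_isotropic(pair$image, c(1, 1, 1), mode = "bspline")
    msk <- resample_isotropic(pair$mask, c(1, 1, 1), mode = "nearest")
    ctr <- tumor_center(msk)
    p <- extract_patch(img, ctr, size = patch_size,
                       normalize = normalize, window = window,
                       patient_id = row$patient_id, label = row$label)
    x[, , , 1L, i] <- p$data
    y[i] <- as.integer(row$label == "responsive")
  }
  list(x = x, y = y, ids = manifest$patient_id, sites = manifest$site_id,
       window = window)
}
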