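# Shared fixtures: everything is generated in code at test time.

# micro network: 8^3 input, one pooled voxel left after three pools
micro_cfg <- function(init_seed = 7) {
  model_config(input_size = 8, conv_channels = c(2, 3, 4), hidden = 8,
               init_seed = init_seed)
}

# small noise-free phantom settings for geometry tests
quiet_phantom <- function(shape = c(48, 48, 48), axes = c(10, 10, 10)) {
  phantom_spec(volume_shape = shape,
               tumor_axes_mean_responsive = axes,
               tumor_axes_mean_nonresponsive = axes,
               tumor_axes_sd = 1e-6, tumor_intensity_contrast = 100,
               texture_sd = 0)
}

quiet_site <- function(n = 4, spacing = c(1, 1, 1), offset = 0) {
  site_spec("T", n, intensity_offset = offset, noise_sd = 0,
            voxel_spacing = spacing)
}

# random labelled micro dataset for training tests
micro_data <- function(n, side = 8, seed = 1, separable = FALSE) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- array(runif(side^3 * n, 0, 0.2), c(side, side, side, 1, n))
  if (separable) {
    for (i in which(y == 1L)) {
      x[3:6, 3:6, 3:6, 1, i] <- x[3:6, 3:6, 3:6, 1, i] + 0.7
    }
  }
  list(x = x, y = y, ids = sprintf("p%02d", seq_len(n)),
       sites = rep("T", n))
}

random_params_like <- function(cfg, seed) {
  model <- build_model(cfg)
  p <- get_parameters(model)
  set.seed(seed)
  lapply(p, function(a) {
    if (is.null(dim(a))) rnorm(length(a)) else array(rnorm(length(a)), dim(a))
  })
}
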