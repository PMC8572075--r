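# Shared fixtures: phantom populations, projection datasets and a
# once-per-run trained network (training is the expensive fixture, so it is
# cached across test files).

# a clean (noise-free, pathology-free) default phantom configuration
quiet_config <- function(...) {
  phantom_config(noise_sd = 0, pathology_fraction = 0, ...)
}

# population variability used across tests: body habitus and lung geometry
# drawn from plausible adult ranges (draws come from the caller's RNG state)
random_phantom_config <- function(noise_sd = 20, pathology_fraction = 0.1) {
  phantom_config(
    body_ap_cm = runif(1, 20, 26), body_lat_cm = runif(1, 28, 34),
    apex_taper_mm = runif(1, 20, 40),
    costophrenic_slant_mm = runif(1, 15, 35),
    lung_top_frac = runif(1, 0.12, 0.22),
    lung_len_frac = runif(1, 0.55, 0.68),
    noise_sd = noise_sd, pathology_fraction = pathology_fraction)
}

# n (projection, mask) training pairs from the phantom population
make_projection_dataset <- function(n, size = 64, seed = 1, view = "AP",
                                    scout = FALSE, geom = scout_geometry(
                                      table_height_offset_mm = 80)) {
  withr::with_seed(seed, {
    configs <- replicate(n, random_phantom_config(), simplify = FALSE)
  })
  ds <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(configs[[i]], seed = seed * 10000 + i)
    p <- project_volume(ph$volume, view)
    m <- project_mask(ph$mask, view)
    if (scout) {
      sc <- apply_magnification(p, m, geom)
      p <- sc$projection; m <- sc$mask
    }
    nr <- normalize_resize(p, m, size)
    ds[[i]] <- list(image = nr$projection, mask = nr$mask, range = ph$range)
  }
  ds
}

# training is the expensive fixture: run once per test session
.sr_cache <- new.env(parent = emptyenv())

get_training_fixture <- function() {
  if (is.null(.sr_cache$fit)) {
    ds <- make_projection_dataset(200, size = 64, seed = 11)
    model <- build_model(seg_model_config())
    .sr_cache$fit <- c(train(model, ds), list(dataset = ds))
  }
  .sr_cache$fit
}

# independent brute-force oracle for mask_to_range: explicit row scan
brute_force_range <- function(m, margin = 1) {
  occupied <- integer(0)
  for (r in seq_len(nrow(m$pixels)))
    if (any(m$pixels[r, ])) occupied <- c(occupied, r)
  r1 <- max(1, occupied[1] - margin)
  r2 <- min(nrow(m$pixels), occupied[length(occupied)] + margin)
  c(m$row_to_z[1] + (r1 - 1) * m$row_to_z[2],
    m$row_to_z[1] + (r2 - 1) * m$row_to_z[2])
}
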