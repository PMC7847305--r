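# Shared fixtures and oracles for the test suite. Scene simulations are
# memoised so several test files can reuse the same rendered volumes.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Canonical side-view scene: 20 boutons on 2 straight dendrons, classes
# planted with wide margins from the 0.95 um side threshold.
side_scene_params <- function(seed = 11, n_boutons = 20) {
  scene_params(
    n_dendrons = 2, dendron_radius = 1, dendron_length = 60,
    n_boutons = n_boutons, bouton_diameter_mean = 2.2,
    bouton_diameter_sd = 0.1,
    gap_distribution = data.frame(gap = c(-1.5, 0.3, 2.5),
                                  fraction = c(0.3, 0.4, 0.3)),
    cochannel_fraction = 1, voxel_xy = 0.25, voxel_z = 0.4,
    psf_sigma_xy = 0.1, psf_sigma_z = 0.25, noise_snr = 10,
    expansion_factor = 4, seed = seed)
}

# Face-view scene: deeply embedded boutons viewed down the optical axis,
# margins wide against the 1.75 um face threshold.
face_scene_params <- function(seed = 21, n_boutons = 8) {
  scene_params(
    n_dendrons = 1, dendron_radius = 1.6, dendron_length = 60,
    n_boutons = n_boutons, bouton_diameter_mean = 3.4,
    bouton_diameter_sd = 0.1,
    gap_distribution = data.frame(gap = c(-2.8, 0.3),
                                  fraction = c(0.5, 0.5),
                                  orientation = c("face", "face")),
    cochannel_fraction = 1, voxel_xy = 0.25, voxel_z = 0.4,
    psf_sigma_xy = 0.1, psf_sigma_z = 0.25, noise_snr = 10,
    expansion_factor = 4, seed = seed)
}

get_side_sim <- function() memo("side_sim",
                                simulate_exm_scene(side_scene_params()))
get_side_result <- function() memo("side_result", {
  classify_contacts(get_side_sim()$scene, morph_thresholds())
})
get_face_sim <- function() memo("face_sim",
                                simulate_exm_scene(face_scene_params()))
get_face_result <- function() memo("face_result", {
  classify_contacts(get_face_sim()$scene, morph_thresholds())
})

# Match each detected apposition to the nearest planted bouton.
match_truth <- function(app, truth) {
  vapply(seq_len(nrow(app)), function(i) {
    which.min((truth$x - app$bx[i])^2 + (truth$y - app$by[i])^2 +
                (truth$z - app$bz[i])^2)
  }, 0L)
}

# Brute-force overlap oracle: resample both channels onto a 1 nm grid by
# linear interpolation and measure the longest contiguous joint
# super-level run directly.
oracle_overlap <- function(profile, channel_a, channel_b, level = 0.5,
                           pitch = 1e-3) {
  p <- profile$positions
  grid <- seq(min(p), max(p), by = pitch)
  ga <- approx(p, profile$values[[channel_a]], grid)$y
  gb <- approx(p, profile$values[[channel_b]], grid)$y
  ok <- pmin(ga, gb) >= level
  if (!any(ok)) return(0)
  r <- rle(ok)
  max(r$lengths[r$values]) * pitch
}

# Noise-free closed-form ROI trace: percentage signal pct(t) on top of f0.
make_trace <- function(pct, times = seq(0, 499, by = 1),
                       puff_window = c(60, 150), f0 = 1000,
                       baseline_frames = 15, roi_id = 1L) {
  roi_trace(times, f0 * (1 + pct / 100), puff_window = puff_window,
            baseline_frames = baseline_frames, roi_id = roi_id)
}
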