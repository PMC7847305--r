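# Contact-classification pipeline: image utilities, segmentation, bouton
# detection, profiles, overlap measurement, classification and census.

test_that("otsu_threshold returns a single global threshold for a volume", {
  # regression: per-plane thresholding collapses to the noise level on
  # signal-free planes
  a <- array(rnorm(20 * 20 * 10, 2, 0.5), c(20, 20, 10))
  a[8:12, 8:12, 5] <- 100
  th <- pulsegen:::otsu_threshold(a)
  expect_length(th, 1)
  expect_gt(th, 10)
})

test_that("gaussian blur conserves total intensity away from borders", {
  a <- array(0, c(21, 21, 11))
  a[11, 11, 6] <- 1
  b <- pulsegen:::gaussian_blur3d(a, c(1.5, 1.5, 1))
  expect_equal(sum(b), 1, tolerance = 1e-6)
  expect_equal(which.max(b), which.max(a))
})

test_that("trilinear interpolation is exact for a linear field", {
  nx <- 12; ny <- 10; nz <- 8
  xs <- (seq_len(nx) - 1) * 0.2
  ys <- (seq_len(ny) - 1) * 0.2
  zs <- (seq_len(nz) - 1) * 0.5
  a <- outer(outer(2 * xs, 3 * ys, "+"), 5 * zs, "+")
  pts <- cbind(c(0.31, 1.7), c(0.55, 1.1), c(0.62, 2.9))
  v <- pulsegen:::interp_trilinear(a, pts, 0.2, 0.5)
  expect_equal(v, 2 * pts[, 1] + 3 * pts[, 2] + 5 * pts[, 3],
               tolerance = 1e-10)
  # outside the volume -> NA
  expect_true(is.na(pulsegen:::interp_trilinear(a, cbind(50, 0, 0),
                                                0.2, 0.5)))
})

test_that("3D labelling separates disconnected components", {
  m <- array(FALSE, c(12, 12, 6))
  m[2:4, 2:4, 2:3] <- TRUE
  m[8:10, 8:10, 4:5] <- TRUE
  lab <- pulsegen:::label_components3d(m)
  expect_equal(max(lab), 2)
  expect_equal(sum(lab > 0), sum(m))
  expect_equal(length(unique(lab[m])), 2)
})

test_that("dendron segmentation recovers tube count, length and radius", {
  dend <- as.data.frame(segment_dendrons(get_side_sim()$scene))
  expect_equal(nrow(dend), 2)
  expect_equal(dend$length_pre, c(15, 15), tolerance = 0.03)
  expect_equal(dend$mean_radius, c(1, 1), tolerance = 0.15)
})

test_that("blank volumes yield no segments and no boutons", {
  blank <- exm_scene(array(1, c(8, 8, 4)), array(1, c(8, 8, 4)),
                     array(1, c(8, 8, 4)), voxel_xy = 0.2, voxel_z = 0.5)
  expect_length(segment_dendrons(blank), 0)
  expect_equal(nrow(detect_boutons(blank)), 0)
})

test_that("the minimum length rule drops short segments", {
  segs <- segment_dendrons(get_side_sim()$scene, min_length_pre = 20)
  expect_length(segs, 0)
})

test_that("bouton detection finds the planted count and applies the size rule", {
  sim <- get_side_sim()
  b <- detect_boutons(sim$scene)
  expect_equal(nrow(b), 20)
  # centroids land within half a bouton radius of the planted centres
  d <- vapply(seq_len(nrow(b)), function(i) {
    min(sqrt((sim$truth$x - b$x[i])^2 + (sim$truth$y - b$y[i])^2 +
               (sim$truth$z - b$z[i])^2))
  }, 0)
  expect_lt(max(d), 0.6)
  # an absurd minimum diameter excludes everything
  none <- detect_boutons(sim$scene,
                         morph_thresholds(min_bouton_diameter = 5))
  expect_equal(nrow(none), 0)
})

test_that("dual-label flags and require_cochannel follow the planted labels", {
  sim <- get_side_sim()  # cochannel_fraction 1
  b <- detect_boutons(sim$scene)
  expect_true(all(b$has_kisspeptin))
  expect_true(all(b$has_synaptophysin))
  expect_equal(nrow(detect_boutons(sim$scene, require_cochannel = TRUE)),
               nrow(b))
})

test_that("face-view appositions are recognized by the orientation cone", {
  res <- get_face_result()
  expect_gte(mean(res$appositions$orientation == "face"), 7 / 8)
})

test_that("overlap_length measures a rectangle intersection exactly", {
  pos <- seq(0, 10, by = 0.01)
  a <- as.numeric(pos >= 2 & pos <= 6)
  b <- as.numeric(pos >= 4 & pos <= 9)
  prof <- intensity_profile(pos, list(gfp = a, kisspeptin = b))
  expect_equal(overlap_length(prof, "gfp", "kisspeptin"), 2,
               tolerance = 0.02)
})

test_that("overlap_length is zero for disjoint supports", {
  pos <- seq(0, 10, by = 0.01)
  a <- as.numeric(pos <= 3)
  b <- as.numeric(pos >= 7)
  prof <- intensity_profile(pos, list(gfp = a, kisspeptin = b))
  expect_equal(overlap_length(prof, "gfp", "kisspeptin"), 0)
})

test_that("overlap_length matches the Gaussian closed form and is symmetric", {
  pos <- seq(0, 10, by = 0.05)
  g <- exp(-(pos - 5)^2 / (2 * 0.8^2))
  prof <- intensity_profile(pos, list(gfp = g, kisspeptin = g))
  fwhm <- 2 * 0.8 * sqrt(2 * log(2))
  expect_equal(overlap_length(prof, "gfp", "kisspeptin"), fwhm,
               tolerance = 0.05)
  expect_equal(overlap_length(prof, "gfp", "kisspeptin"),
               overlap_length(prof, "kisspeptin", "gfp"))
})

test_that("overlap_length is non-increasing in the measurement level", {
  pos <- seq(0, 10, by = 0.05)
  a <- exp(-(pos - 4.5)^2 / (2 * 1.1^2))
  b <- exp(-(pos - 5.5)^2 / (2 * 0.9^2))
  prof <- intensity_profile(pos, list(gfp = a, kisspeptin = b))
  levels <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  ov <- vapply(levels, function(l)
    overlap_length(prof, "gfp", "kisspeptin", level = l), 0)
  expect_true(all(diff(ov) <= 1e-9))
})

test_that("overlap crossings are interpolated, not quantized to the pitch", {
  pos <- seq(0, 4, by = 0.5)       # coarse sampling
  tri <- pmax(0, 1 - abs(pos - 2)) # triangle, half-max span exactly 1
  prof <- intensity_profile(pos, list(gfp = tri, kisspeptin = tri))
  expect_equal(overlap_length(prof, "gfp", "kisspeptin"), 1,
               tolerance = 1e-9)
})

test_that("classification respects the strict side and face thresholds", {
  cand <- data.frame(orientation = "side", gap = 0,
                     has_synaptophysin = TRUE, confocal_close = NA)
  th <- morph_thresholds()
  expect_equal(classify_apposition(cand, 0.95, th)$class,
               "close_nonsynaptic")
  expect_equal(classify_apposition(cand, 0.951, th)$class, "synapse")
  cand$orientation <- "face"
  expect_equal(classify_apposition(cand, 1.75, th)$class,
               "close_nonsynaptic")
  expect_equal(classify_apposition(cand, 1.76, th)$class, "synapse")
  # non-synaptic contacts split on the gap rule
  cand$orientation <- "side"
  cand$gap <- 1.2
  expect_equal(classify_apposition(cand, 0.2, th)$class, "separate")
})

test_that("confocal scenes never yield synapse calls", {
  p <- scene_params(
    n_dendrons = 1, dendron_radius = 1, dendron_length = 25,
    n_boutons = 6, bouton_diameter_mean = 2.0, bouton_diameter_sd = 0.1,
    gap_distribution = data.frame(gap = c(0, 2.5), fraction = c(0.5, 0.5)),
    cochannel_fraction = 1, voxel_xy = 0.25, voxel_z = 0.5,
    psf_sigma_xy = 0.25, psf_sigma_z = 0.6, noise_snr = 10,
    modality = "confocal", seed = 31)
  sim <- simulate_exm_scene(p)
  res <- classify_contacts(sim$scene, morph_thresholds())
  expect_false(any(res$appositions$class == "synapse"))
  # touching boutons are close by the no-dark-pixel rule, distant ones not
  m <- match_truth(res$appositions, sim$truth)
  touching <- sim$truth$gap[m] <= 0
  expect_true(all(res$appositions$class[touching] == "close_nonsynaptic"))
  expect_true(all(res$appositions$class[!touching] == "separate"))
})

test_that("census arithmetic matches hand-computed densities", {
  app <- data.frame(
    class = c(rep("synapse", 4), rep("close_nonsynaptic", 4),
              rep("separate", 2)),
    gap = c(rep(0, 4), rep(0.5, 4), 2, 3),
    dendron_id = c(1, 1, 2, 2, 1, 1, 2, 2, 1, 2),
    has_kisspeptin = c(TRUE, TRUE, TRUE, FALSE, rep(TRUE, 6)))
  dend <- data.frame(dendron_id = 1:2, length_pre = c(120, 80),
                     length_post = c(120, 80) * 4, mean_radius = 1)
  cs <- contact_census(app, dend, fiber_ids = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5))
  expect_equal(cs$appositions_per_100um, 100 * 8 / 200)
  expect_equal(cs$synapses_per_10um, 10 * 4 / 200)
  expect_equal(cs$pct_synaptophysin_synapses_with_kisspeptin, 75)
  # fibers 1 and 2 each touch one dendron twice; 3 and 4 touch one each
  expect_equal(cs$dendrons_per_fiber, 1)
  expect_equal(cs$mean_bouton_dendron_distance, mean(c(0.5, 0.5, 0.5, 0.5, 2, 3)))
  expect_error(contact_census(app, data.frame(length_pre = 0)), "zero")
})

test_that("census densities recover the generator settings on a scene", {
  res <- get_side_result()
  cs <- contact_census(res$appositions, res$dendrons, expansion_factor = 4)
  # planted: 6 synapses + 8 close over 2 x 15 um of pre-expansion dendron
  expect_equal(cs$appositions_per_100um, 100 * 14 / 30, tolerance = 0.1)
  expect_equal(cs$synapses_per_10um, 10 * 6 / 30, tolerance = 0.1)
})

test_that("classification is invariant to detector gain", {
  sim <- get_face_sim()
  base <- get_face_result()
  sc <- sim$scene
  scaled <- exm_scene(sc$channels$gfp * 2.5, sc$channels$kisspeptin * 2.5,
                      sc$channels$synaptophysin * 2.5,
                      voxel_xy = sc$voxel_xy, voxel_z = sc$voxel_z,
                      expansion_factor = sc$expansion_factor,
                      modality = sc$modality)
  res2 <- classify_contacts(scaled, morph_thresholds())
  expect_equal(res2$appositions$class, base$appositions$class)
  expect_equal(res2$appositions$overlap, base$appositions$overlap,
               tolerance = 1e-8)
})
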