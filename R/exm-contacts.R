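# Contact classification in expansion-microscopy stacks: dendron
# segmentation, bouton detection, apposition pairing, intensity-profile
# extraction, overlap-length scoring, synapse classification, and census
# statistics.

#' Morphological thresholds for contact classification
#'
#' All length thresholds are in micrometres of the imaged (post-expansion)
#' frame. A contact counts as a synapse when the two-channel fluorescence
#' overlap exceeds `theta_side` (0.95 um, i.e. 0.23 um pre-expansion) in a
#' side-on view or `theta_face` (1.75 um / 0.42 um pre-expansion) in the
#' z-stack face view; both comparisons are strict, matching the published
#' ">" rule. Overlap is read off normalized intensity profiles at
#' `profile_level` (half-maximum by default; the measurement level is a
#' package convention, see the methods vignette).
#'
#' @param theta_side Side-view synapse overlap threshold (um).
#' @param theta_face Face-view synapse overlap threshold (um).
#' @param min_bouton_diameter Minimum bouton equivalent diameter (um).
#' @param profile_level Fraction of the normalized in-scan peak at which
#'   overlap is measured (in (0, 1)).
#' @param face_box Side length (um) of the square box used for face-view
#'   z-profiles (2 x 2 um).
#' @param face_cone_deg Half-angle (degrees) of the cone around the z axis
#'   within which a bouton-dendron axis counts as a face view.
#' @param contact_max_gap Maximum surface-to-surface gap (um) for a
#'   non-synaptic contact to count as "close" rather than "separate".
#' @param confocal_max_gap Maximum gap, in voxels, for the confocal
#'   close-apposition rule (no dark pixels between elements).
#' @return A list of class `morph_thresholds`.
#' @export
morph_thresholds <- function(theta_side = 0.95,
                             theta_face = 1.75,
                             min_bouton_diameter = 0.4,
                             profile_level = 0.5,
                             face_box = 2,
                             face_cone_deg = 45,
                             contact_max_gap = 1,
                             confocal_max_gap = 1) {
  stopifnot(theta_side > 0, theta_face > 0, min_bouton_diameter > 0,
            profile_level > 0, profile_level < 1, face_box > 0,
            face_cone_deg > 0, contact_max_gap > 0, confocal_max_gap >= 0)
  structure(list(theta_side = theta_side, theta_face = theta_face,
                 min_bouton_diameter = min_bouton_diameter,
                 profile_level = profile_level, face_box = face_box,
                 face_cone_deg = face_cone_deg,
                 contact_max_gap = contact_max_gap,
                 confocal_max_gap = confocal_max_gap),
            class = "morph_thresholds")
}

# physical coordinates of voxel centres along each axis
scene_axes <- function(scene) {
  d <- dim(scene$channels$gfp)
  list(x = (seq_len(d[1]) - 1) * scene$voxel_xy,
       y = (seq_len(d[2]) - 1) * scene$voxel_xy,
       z = (seq_len(d[3]) - 1) * scene$voxel_z)
}

#' Segment GFP-filled dendrons from a scene
#'
#' Thresholds the GFP channel (Otsu unless an absolute threshold is given),
#' labels 6-connected 3D components, and reduces each tube-like component to
#' an ordered centre-line by binning voxel positions along the component's
#' principal axis. Lengths are reported both in the imaged frame
#' (`length_post`) and divided by the expansion factor (`length_pre`).
#' Components whose pre-expansion length falls below `min_length_pre` are
#' discarded, as are specks smaller than `min_voxels`.
#'
#' @param scene An [exm_scene()].
#' @param min_length_pre Minimum segment length (um, pre-expansion frame).
#' @param threshold Absolute GFP intensity threshold; `NULL` for Otsu.
#' @param min_voxels Minimum component size in voxels.
#' @return An object of class `dendron_segments`: a list of segments, each
#'   with `dendron_id`, `skeleton` (n x 3 matrix, um), `mean_radius`,
#'   `length_post` and `length_pre`. `as.data.frame()` gives one row per
#'   segment.
#' @export
segment_dendrons <- function(scene, min_length_pre = 15, threshold = NULL,
                             min_voxels = 50) {
  stopifnot(inherits(scene, "exm_scene"))
  gfp <- scene$channels$gfp
  if (all(gfp == gfp[1])) {
    return(structure(list(), class = "dendron_segments"))
  }
  thr <- if (is.null(threshold)) otsu_threshold(gfp) else threshold
  lab <- label_components3d(gfp > thr)
  n_comp <- max(lab)
  if (n_comp == 0) return(structure(list(), class = "dendron_segments"))
  ax <- scene_axes(scene)
  vox_vol <- scene$voxel_xy^2 * scene$voxel_z
  fg <- which(lab > 0L)
  comp_idx <- split(fg, lab[fg])
  segs <- list()
  for (idx in comp_idx) {
    if (length(idx) < min_voxels) next
    co <- arrayInd(idx, dim(gfp))
    pts <- cbind(ax$x[co[, 1]], ax$y[co[, 2]], ax$z[co[, 3]])
    ctr <- colMeans(pts)
    pc <- prcomp(pts, center = TRUE, scale. = FALSE)
    t_proj <- pts %*% pc$rotation[, 1] - sum(ctr * pc$rotation[, 1])
    # centre-line: centroid of voxels per ~1 um slab along the main axis
    bw <- max(1, 2 * scene$voxel_xy)
    bins <- floor((t_proj - min(t_proj)) / bw)
    sk <- do.call(rbind, lapply(split(seq_along(bins), bins), function(ii) {
      colMeans(pts[ii, , drop = FALSE])
    }))
    t_bin <- vapply(split(t_proj, bins), mean, 0)
    ord <- order(t_bin)
    sk <- sk[ord, , drop = FALSE]
    t_bin <- t_bin[ord]
    # bin centroids sit half a slab inside the component ends; extend the
    # centre-line to the extreme projections so tube length is unbiased
    u <- as.numeric(pc$rotation[, 1])
    sk <- rbind(sk[1, ] + u * (min(t_proj) - t_bin[1]),
                sk,
                sk[nrow(sk), ] + u * (max(t_proj) - t_bin[length(t_bin)]))
    len <- sum(sqrt(rowSums(diff(sk)^2)))
    if (len / scene$expansion_factor < min_length_pre) next
    radius <- sqrt(length(idx) * vox_vol / (pi * max(len, 1e-6)))
    segs[[length(segs) + 1L]] <- list(
      dendron_id = length(segs) + 1L,
      skeleton = sk,
      mean_radius = radius,
      length_post = len,
      length_pre = len / scene$expansion_factor)
  }
  structure(segs, class = "dendron_segments")
}

#' @export
as.data.frame.dendron_segments <- function(x, ...) {
  if (length(x) == 0) {
    return(data.frame(dendron_id = integer(0), length_post = numeric(0),
                      length_pre = numeric(0), mean_radius = numeric(0)))
  }
  data.frame(
    dendron_id = vapply(x, `[[`, 0L, "dendron_id"),
    length_post = vapply(x, `[[`, 0, "length_post"),
    length_pre = vapply(x, `[[`, 0, "length_pre"),
    mean_radius = vapply(x, `[[`, 0, "mean_radius"))
}

#' @export
print.dendron_segments <- function(x, ...) {
  cat(sprintf("<dendron_segments> %d segment(s)\n", length(x)))
  if (length(x)) print(as.data.frame(x))
  invisible(x)
}

#' Detect boutons in a scene
#'
#' Thresholds the requested channel (Otsu), labels 3D connected components,
#' and measures each component's half-maximum equivalent diameter (the
#' diameter of a sphere with the same volume as the voxels above half of the
#' component's background-subtracted peak). Components at or below
#' `min_bouton_diameter` are dropped, following the "diameter > 0.4 um"
#' inclusion rule. Channel membership flags (`has_kisspeptin`,
#' `has_synaptophysin`) are set when the mean in-mask intensity of the other
#' channel reaches that channel's own Otsu level.
#'
#' @param scene An [exm_scene()].
#' @param thresholds A [morph_thresholds()].
#' @param require_cochannel If `TRUE`, keep only dual-labelled
#'   (kisspeptin AND synaptophysin) boutons.
#' @param channel Channel to segment boutons from.
#' @param min_voxels Minimum component size in voxels; removes
#'   few-voxel noise fluctuations riding on blob tails.
#' @return Data frame with one row per bouton: `bouton_id`, centroid
#'   `x`, `y`, `z` (um), `equivalent_diameter`, `has_kisspeptin`,
#'   `has_synaptophysin`, and `peak_<channel>` intensities.
#' @export
detect_boutons <- function(scene, thresholds = morph_thresholds(),
                           require_cochannel = FALSE,
                           channel = "kisspeptin", min_voxels = 5) {
  stopifnot(inherits(scene, "exm_scene"), channel %in% names(scene$channels))
  img <- scene$channels[[channel]]
  empty <- data.frame(bouton_id = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), equivalent_diameter = numeric(0),
                      has_kisspeptin = logical(0),
                      has_synaptophysin = logical(0),
                      peak_gfp = numeric(0), peak_kisspeptin = numeric(0),
                      peak_synaptophysin = numeric(0))
  if (all(img == img[1])) return(empty)
  thr <- otsu_threshold(img)
  lab <- label_components3d(img > thr)
  n_comp <- max(lab)
  if (n_comp == 0) return(empty)
  ax <- scene_axes(scene)
  vox_vol <- scene$voxel_xy^2 * scene$voxel_z
  bg <- median(img)
  ch_levels <- lapply(scene$channels, function(a) {
    if (all(a == a[1])) Inf else otsu_threshold(a)
  })
  fg <- which(lab > 0L)
  comp_idx <- split(fg, lab[fg])
  comp_idx <- comp_idx[lengths(comp_idx) >= min_voxels]
  if (length(comp_idx) == 0) return(empty)
  rows <- lapply(comp_idx, function(idx) {
    vals <- img[idx]
    peak <- max(vals)
    half <- bg + 0.5 * (peak - bg)
    v_half <- sum(vals >= half) * vox_vol
    dia <- 2 * (3 * v_half / (4 * pi))^(1 / 3)
    co <- arrayInd(idx, dim(img))
    w <- pmax(vals - bg, 0)
    ctr <- c(sum(ax$x[co[, 1]] * w), sum(ax$y[co[, 2]] * w),
             sum(ax$z[co[, 3]] * w)) / sum(w)
    means <- vapply(scene$channels, function(a) mean(a[idx]), 0)
    peaks <- vapply(scene$channels, function(a) max(a[idx]), 0)
    data.frame(x = ctr[1], y = ctr[2], z = ctr[3],
               equivalent_diameter = dia,
               has_kisspeptin = means[["kisspeptin"]] >=
                 ch_levels[["kisspeptin"]],
               has_synaptophysin = means[["synaptophysin"]] >=
                 ch_levels[["synaptophysin"]],
               peak_gfp = peaks[["gfp"]],
               peak_kisspeptin = peaks[["kisspeptin"]],
               peak_synaptophysin = peaks[["synaptophysin"]])
  })
  out <- do.call(rbind, rows)
  out <- out[out$equivalent_diameter > thresholds$min_bouton_diameter, ,
             drop = FALSE]
  if (channel == "kisspeptin") out$has_kisspeptin <- rep(TRUE, nrow(out))
  if (channel == "synaptophysin")
    out$has_synaptophysin <- rep(TRUE, nrow(out))
  if (require_cochannel) {
    out <- out[out$has_kisspeptin & out$has_synaptophysin, , drop = FALSE]
  }
  if (nrow(out)) out <- cbind(bouton_id = seq_len(nrow(out)), out)
  else out <- empty
  rownames(out) <- NULL
  out
}

#' Pair boutons with their nearest dendron
#'
#' For every bouton, finds the nearest dendron centre-line point, the
#' surface-to-surface gap (clipped at 0 for touching or overlapping
#' contacts), and the viewing orientation: `"face"` when the bouton-dendron
#' axis lies within `face_cone_deg` of the optical (z) axis, `"side"`
#' otherwise. In confocal scenes the candidate close-apposition flag applies
#' the dark-pixel rule: a contact is close only if no sample between the two
#' surfaces falls below both channels' intensity thresholds.
#'
#' @param boutons Data frame from [detect_boutons()].
#' @param dendrons A `dendron_segments` object from [segment_dendrons()].
#' @param scene The [exm_scene()] the inputs came from.
#' @param thresholds A [morph_thresholds()].
#' @return Data frame of candidate appositions: `bouton_id`, `dendron_id`,
#'   `gap` (um, >= 0), `orientation`, nearest axis point (`ax_x`, `ax_y`,
#'   `ax_z`), bouton flags, and for confocal scenes `confocal_close`.
#' @export
pair_appositions <- function(boutons, dendrons, scene,
                             thresholds = morph_thresholds()) {
  stopifnot(inherits(scene, "exm_scene"))
  if (nrow(boutons) == 0 || length(dendrons) == 0) {
    stop("pair_appositions needs at least one bouton and one dendron")
  }
  skel_all <- do.call(rbind, lapply(dendrons, function(s) {
    cbind(s$skeleton, s$dendron_id, s$mean_radius)
  }))
  gfp_thr <- otsu_threshold(scene$channels$gfp)
  kiss_thr <- otsu_threshold(scene$channels$kisspeptin)
  rows <- lapply(seq_len(nrow(boutons)), function(i) {
    b <- boutons[i, ]
    ctr <- c(b$x, b$y, b$z)
    d2 <- (skel_all[, 1] - ctr[1])^2 + (skel_all[, 2] - ctr[2])^2 +
      (skel_all[, 3] - ctr[3])^2
    j <- which.min(d2)
    axpt <- skel_all[j, 1:3]
    r_d <- skel_all[j, 5]
    r_b <- b$equivalent_diameter / 2
    cdist <- sqrt(d2[j])
    gap <- max(0, cdist - r_d - r_b)
    v <- ctr - axpt
    ang <- acos(min(1, abs(v[3]) / max(sqrt(sum(v^2)), 1e-9))) * 180 / pi
    orientation <- if (ang <= thresholds$face_cone_deg) "face" else "side"
    confocal_close <- NA
    if (scene$modality == "confocal") {
      confocal_close <- gap <= thresholds$confocal_max_gap * scene$voxel_xy
      if (gap > 0 && !confocal_close) {
        # sample the segment strictly between the two labelled surfaces
        u <- v / max(cdist, 1e-9)
        t_from <- r_d
        t_to <- cdist - r_b
        if (t_to > t_from) {
          tt <- seq(t_from, t_to, by = scene$voxel_xy)
          pts <- cbind(axpt[1] + tt * u[1], axpt[2] + tt * u[2],
                       axpt[3] + tt * u[3])
          g <- interp_trilinear(scene$channels$gfp, pts,
                                scene$voxel_xy, scene$voxel_z)
          k <- interp_trilinear(scene$channels$kisspeptin, pts,
                                scene$voxel_xy, scene$voxel_z)
          dark <- (g < gfp_thr & k < kiss_thr)
          confocal_close <- !any(dark, na.rm = TRUE)
        }
      }
    }
    data.frame(bouton_id = b$bouton_id, dendron_id = skel_all[j, 4],
               gap = gap, orientation = orientation,
               ax_x = axpt[1], ax_y = axpt[2], ax_z = axpt[3],
               bouton_radius = r_b, dendron_radius = r_d,
               has_kisspeptin = b$has_kisspeptin,
               has_synaptophysin = b$has_synaptophysin,
               confocal_close = confocal_close)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Construct an intensity profile
#'
#' @param positions Strictly increasing positions (um).
#' @param values Named list of per-channel intensity vectors; each is
#'   normalized to its own in-scan peak (values clipped to `[0, 1]`).
#' @param truncated Flag set when a scan left the imaged volume.
#' @return Object of class `intensity_profile`.
#' @export
intensity_profile <- function(positions, values, truncated = FALSE) {
  stopifnot(is.numeric(positions), length(positions) > 1,
            all(diff(positions) > 0), is.list(values),
            !is.null(names(values)))
  values <- lapply(values, function(v) {
    stopifnot(length(v) == length(positions))
    m <- max(v, na.rm = TRUE)
    if (!is.finite(m) || m <= 0) return(rep(0, length(v)))
    pmin(pmax(v / m, 0), 1)
  })
  structure(list(positions = positions, values = values,
                 truncated = truncated),
            class = "intensity_profile")
}

#' Extract the two-channel intensity profile across an apposition
#'
#' Side-view contacts are scanned along the line from the bouton centre
#' through the nearest dendron axis point, sampled at the xy voxel pitch and
#' averaged over three parallel lines one voxel apart (the usual wide line
#' scan). Face-view contacts are profiled through the z-stack as the per-z
#' mean intensity inside a `face_box` x `face_box` um box centred on the
#' bouton. Each channel is normalized to its in-scan peak.
#'
#' @param scene An [exm_scene()].
#' @param apposition One row of the data frame from [pair_appositions()].
#' @param thresholds A [morph_thresholds()].
#' @param channels Character vector of channels to sample.
#' @return An [intensity_profile()]; the `truncated` flag is set (with a
#'   warning) when part of the scan left the volume.
#' @export
extract_profile <- function(scene, apposition,
                            thresholds = morph_thresholds(),
                            channels = c("gfp", "kisspeptin",
                                         "synaptophysin")) {
  stopifnot(inherits(scene, "exm_scene"),
            apposition$orientation %in% c("side", "face"))
  ax <- scene_axes(scene)
  if (apposition$orientation == "side") {
    ctr <- c(apposition$ax_x, apposition$ax_y, apposition$ax_z)
    if (is.null(apposition$bx)) {
      stop("apposition must carry bouton centre columns bx, by, bz")
    }
    bc <- c(apposition$bx, apposition$by, apposition$bz)
    v <- bc - ctr
    nv <- sqrt(sum(v^2))
    u <- if (nv > 1e-9) v / nv else c(0, 1, 0)
    pad <- 1.5
    t0 <- -(apposition$dendron_radius + pad)   # beyond the far dendron wall
    t1 <- nv + apposition$bouton_radius + pad  # beyond the bouton
    tt <- seq(t0, t1, by = scene$voxel_xy)
    # transverse averaging: three parallel lines, one xy voxel apart
    perp <- c(-u[2], u[1], 0)
    np <- sqrt(sum(perp^2))
    perp <- if (np > 1e-9) perp / np else c(1, 0, 0)
    offs <- c(-scene$voxel_xy, 0, scene$voxel_xy)
    vals <- lapply(channels, function(ch) {
      acc <- matrix(NA_real_, length(tt), length(offs))
      for (k in seq_along(offs)) {
        pts <- cbind(ctr[1] + tt * u[1] + offs[k] * perp[1],
                     ctr[2] + tt * u[2] + offs[k] * perp[2],
                     ctr[3] + tt * u[3] + offs[k] * perp[3])
        acc[, k] <- interp_trilinear(scene$channels[[ch]], pts,
                                     scene$voxel_xy, scene$voxel_z)
      }
      rowMeans(acc, na.rm = TRUE)
    })
    names(vals) <- channels
    keep <- Reduce(`&`, lapply(vals, function(v) !is.nan(v) & !is.na(v)))
    truncated <- !all(keep)
    if (truncated) warning("profile scan exited the volume; truncated")
    intensity_profile(tt[keep] - tt[keep][1],
                      lapply(vals, `[`, keep), truncated = truncated)
  } else {
    half <- thresholds$face_box / 2
    if (is.null(apposition$bx)) {
      stop("apposition must carry bouton centre columns bx, by, bz")
    }
    ix <- which(ax$x >= apposition$bx - half & ax$x <= apposition$bx + half)
    iy <- which(ax$y >= apposition$by - half & ax$y <= apposition$by + half)
    truncated <- length(ix) == 0 || length(iy) == 0
    if (truncated) {
      warning("face box exited the volume; truncated")
      ix <- if (length(ix)) ix else seq_along(ax$x)
      iy <- if (length(iy)) iy else seq_along(ax$y)
    }
    vals <- lapply(channels, function(ch) {
      apply(scene$channels[[ch]][ix, iy, , drop = FALSE], 3, mean)
    })
    names(vals) <- channels
    intensity_profile(ax$z, vals, truncated = truncated)
  }
}

#' Overlap length of two channels in a profile
#'
#' Length of the longest contiguous span over which both normalized channels
#' sit at or above `level`. Crossing positions are located by linear
#' interpolation between samples, so the result is not quantized to the
#' sampling pitch. Returns 0 when the supports are disjoint. The measure is
#' symmetric in its two channels and non-increasing in `level`.
#'
#' @param profile An [intensity_profile()].
#' @param channel_a,channel_b Channel names present in the profile.
#' @param level Threshold fraction of the normalized peak (default
#'   half-maximum).
#' @return Overlap length in um.
#' @export
overlap_length <- function(profile, channel_a, channel_b, level = 0.5) {
  stopifnot(inherits(profile, "intensity_profile"),
            channel_a %in% names(profile$values),
            channel_b %in% names(profile$values),
            level > 0, level < 1)
  p <- profile$positions
  g <- pmin(profile$values[[channel_a]], profile$values[[channel_b]]) - level
  n <- length(g)
  if (all(g < 0)) return(0)
  best <- 0
  i <- 1L
  while (i <= n) {
    if (g[i] >= 0) {
      j <- i
      while (j < n && g[j + 1L] >= 0) j <- j + 1L
      left <- p[i]
      if (i > 1L) {
        # linear interpolation of the upward crossing
        left <- p[i - 1L] + (p[i] - p[i - 1L]) * (-g[i - 1L]) /
          (g[i] - g[i - 1L])
      }
      right <- p[j]
      if (j < n) {
        right <- p[j] + (p[j + 1L] - p[j]) * g[j] / (g[j] - g[j + 1L])
      }
      best <- max(best, right - left)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  best
}

#' Classify one candidate apposition
#'
#' A contact is a synapse when its measured overlap strictly exceeds the
#' threshold for its orientation (0.95 um side-on, 1.75 um face view);
#' otherwise it is a close non-synaptic contact when the surface gap is at
#' most `contact_max_gap`, else separate. In confocal scenes no synapse call
#' is made (the resolution cannot support one); contacts are close when the
#' dark-pixel rule held in [pair_appositions()], else separate.
#'
#' @param candidate One row from [pair_appositions()].
#' @param overlap Measured overlap length (um) from [overlap_length()].
#' @param thresholds A [morph_thresholds()].
#' @param modality Scene modality the candidate came from.
#' @return The candidate row with `overlap` and `class` columns added.
#' @export
classify_apposition <- function(candidate, overlap,
                                thresholds = morph_thresholds(),
                                modality = "ExM") {
  if (modality == "confocal") {
    cls <- if (isTRUE(candidate$confocal_close)) "close_nonsynaptic"
           else "separate"
  } else {
    theta <- if (candidate$orientation == "face") thresholds$theta_face
             else thresholds$theta_side
    cls <- if (overlap > theta) "synapse"
           else if (candidate$gap <= thresholds$contact_max_gap)
             "close_nonsynaptic"
           else "separate"
  }
  candidate$overlap <- overlap
  candidate$class <- cls
  candidate
}

#' Run the full contact-classification pipeline on a scene
#'
#' Segments dendrons, detects boutons, pairs each bouton with its nearest
#' dendron, extracts the orientation-appropriate intensity profile, measures
#' the overlap between GFP and the bouton's synaptic channel (synaptophysin
#' when present, otherwise kisspeptin -- but only synaptophysin-positive
#' boutons are eligible to be synapses), and classifies every contact.
#'
#' @param scene An [exm_scene()].
#' @param thresholds A [morph_thresholds()].
#' @param min_length_pre Minimum dendron length passed to
#'   [segment_dendrons()].
#' @return List with `appositions` (classified data frame), `boutons`, and
#'   `dendrons`.
#' @export
classify_contacts <- function(scene, thresholds = morph_thresholds(),
                              min_length_pre = 15) {
  dendrons <- segment_dendrons(scene, min_length_pre = min_length_pre)
  boutons <- detect_boutons(scene, thresholds)
  if (nrow(boutons) == 0 || length(dendrons) == 0) {
    return(list(appositions = data.frame(), boutons = boutons,
                dendrons = dendrons))
  }
  cands <- pair_appositions(boutons, dendrons, scene, thresholds)
  cands$bx <- boutons$x[match(cands$bouton_id, boutons$bouton_id)]
  cands$by <- boutons$y[match(cands$bouton_id, boutons$bouton_id)]
  cands$bz <- boutons$z[match(cands$bouton_id, boutons$bouton_id)]
  rows <- lapply(seq_len(nrow(cands)), function(i) {
    cand <- cands[i, ]
    if (scene$modality == "confocal") {
      return(classify_apposition(cand, NA_real_, thresholds,
                                 modality = "confocal"))
    }
    ch <- if (isTRUE(cand$has_synaptophysin)) "synaptophysin"
          else "kisspeptin"
    prof <- suppressWarnings(
      extract_profile(scene, cand, thresholds, channels = c("gfp", ch)))
    ov <- overlap_length(prof, "gfp", ch, level = thresholds$profile_level)
    out <- classify_apposition(cand, ov, thresholds)
    if (out$class == "synapse" && !isTRUE(cand$has_synaptophysin)) {
      out$class <- if (out$gap <= thresholds$contact_max_gap)
        "close_nonsynaptic" else "separate"
    }
    out
  })
  app <- do.call(rbind, rows)
  rownames(app) <- NULL
  list(appositions = app, boutons = boutons, dendrons = dendrons)
}

#' Census statistics over classified appositions
#'
#' Computes the contact-density and co-expression summaries used to
#' characterize the innervation: close appositions per 100 um of
#' pre-expansion dendron length, synapses per 10 um, the percentage of
#' synaptophysin synapses containing kisspeptin, the percentage of
#' kisspeptin appositions co-expressing NKB (when an `has_nkb` column is
#' present), the mean number of distinct dendrons contacted per fiber (when
#' fiber identities are supplied), and the mean bouton-dendron gap over
#' non-synaptic contacts.
#'
#' @param appositions Classified apposition data frame (needs `class`,
#'   `gap`, `dendron_id`; optionally `has_kisspeptin`, `has_nkb`).
#' @param dendrons A `dendron_segments` object or a data frame with a
#'   `length_pre` column.
#' @param expansion_factor Used only if `dendrons` carries post-expansion
#'   lengths but no `length_pre`.
#' @param fiber_ids Optional vector of fiber identities, one per apposition
#'   row.
#' @return A list of class `contact_stats`.
#' @export
contact_census <- function(appositions, dendrons, expansion_factor = 1,
                           fiber_ids = NULL) {
  dd <- if (inherits(dendrons, "dendron_segments")) as.data.frame(dendrons)
        else as.data.frame(dendrons)
  if (is.null(dd$length_pre)) {
    if (is.null(dd$length_post)) stop("dendrons must carry segment lengths")
    dd$length_pre <- dd$length_post / expansion_factor
  }
  total_pre <- sum(dd$length_pre)
  if (total_pre <= 0) stop("total dendron length is zero; densities undefined")
  cls <- appositions$class
  n_close <- sum(cls %in% c("synapse", "close_nonsynaptic"))
  n_syn <- sum(cls == "synapse")
  pct_syn_kiss <- if (n_syn > 0 && !is.null(appositions$has_kisspeptin)) {
    100 * mean(appositions$has_kisspeptin[cls == "synapse"])
  } else NA_real_
  pct_kiss_nkb <- if (!is.null(appositions$has_nkb) && n_close > 0) {
    100 * mean(appositions$has_nkb[cls %in%
                                     c("synapse", "close_nonsynaptic")])
  } else NA_real_
  dpf <- NA_real_
  if (!is.null(fiber_ids)) {
    stopifnot(length(fiber_ids) == nrow(appositions))
    keep <- cls %in% c("synapse", "close_nonsynaptic")
    if (any(keep)) {
      dpf <- mean(tapply(appositions$dendron_id[keep], fiber_ids[keep],
                         function(d) length(unique(d))))
    }
  }
  nonsyn <- cls != "synapse"
  structure(list(
    n_appositions = nrow(appositions),
    n_close = n_close,
    n_synapses = n_syn,
    total_length_pre = total_pre,
    appositions_per_100um = 100 * n_close / total_pre,
    synapses_per_10um = 10 * n_syn / total_pre,
    pct_synaptophysin_synapses_with_kisspeptin = pct_syn_kiss,
    pct_kisspeptin_appositions_with_nkb = pct_kiss_nkb,
    dendrons_per_fiber = dpf,
    mean_bouton_dendron_distance =
      if (any(nonsyn)) mean(appositions$gap[nonsyn]) else NA_real_
  ), class = "contact_stats")
}

#' @export
print.contact_stats <- function(x, ...) {
  cat("<contact_stats>\n")
  cat(sprintf("  close appositions / 100 um (pre-expansion): %.2f\n",
              x$appositions_per_100um))
  cat(sprintf("  synapses / 10 um (pre-expansion): %.2f\n",
              x$synapses_per_10um))
  cat(sprintf("  synapses: %d of %d contacts over %.1f um\n",
              x$n_synapses, x$n_appositions, x$total_length_pre))
  if (!is.na(x$pct_synaptophysin_synapses_with_kisspeptin))
    cat(sprintf("  %% synaptophysin synapses with kisspeptin: %.1f\n",
                x$pct_synaptophysin_synapses_with_kisspeptin))
  if (!is.na(x$dendrons_per_fiber))
    cat(sprintf("  dendrons per fiber: %.2f\n", x$dendrons_per_fiber))
  if (!is.na(x$mean_bouton_dendron_distance))
    cat(sprintf("  mean non-synaptic bouton-dendron gap: %.2f um\n",
                x$mean_bouton_dendron_distance))
  invisible(x)
}
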