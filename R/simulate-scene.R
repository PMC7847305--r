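# Ground-truthed simulator for three-channel expansion-microscopy scenes:
# GFP-filled dendron tubes, kisspeptin boutons, and synaptophysin boutons
# co-centred on a configurable fraction of the kisspeptin boutons.

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Parameters for a simulated expansion-microscopy scene
#'
#' Bundles the geometry, optics and noise settings used by
#' [simulate_exm_scene()]. All lengths are micrometres in the imaged
#' (post-expansion) frame. Defaults follow the imaging geometry the contact
#' pipeline targets: 0.1 um xy pixels (1024 px over ~102.5 um), 0.6 um focus
#' steps, and an expansion factor of 4.17 (60 um of tissue imaged as 250 um).
#'
#' @param n_dendrons Number of dendron tubes, laid parallel to the x axis.
#' @param dendron_radius Tube radius (um).
#' @param dendron_length Tube length (um).
#' @param curvature_amp Amplitude (um) of a gentle sinusoidal bend of each
#'   tube axis in the xy plane; 0 gives straight tubes.
#' @param n_boutons Total number of kisspeptin boutons planted.
#' @param bouton_diameter_mean,bouton_diameter_sd Bouton full-width half-max
#'   diameter distribution (um); boutons have isotropic Gaussian intensity
#'   profiles whose half-maximum surface defines their nominal diameter.
#' @param gap_distribution Data frame with columns `gap` (um, signed
#'   surface-to-surface distance between bouton and dendron; negative plants
#'   an overlap), `fraction` (summing to 1), and optionally `orientation`
#'   (`"side"` or `"face"`, default side). Counts per row are assigned by
#'   largest-remainder rounding so planted class counts are exact.
#' @param cochannel_fraction Fraction of kisspeptin boutons that also carry a
#'   co-centred synaptophysin bouton.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF sigmas (um).
#' @param noise_snr Peak signal-to-noise ratio: the peak clean intensity is
#'   rendered as `noise_snr^2` expected photon counts before Poisson noise.
#' @param read_noise_sd Additive Gaussian read noise (counts).
#' @param background Background level as a fraction of peak intensity.
#' @param voxel_xy,voxel_z Voxel pitch (um, post-expansion frame).
#' @param expansion_factor Physical expansion factor (1 for confocal).
#' @param modality `"ExM"` or `"confocal"`.
#' @param thresholds [morph_thresholds()] used to derive each bouton's
#'   intended class in the ground truth (by construction the intended overlap
#'   of a planted bouton is `max(0, -gap)`, capped by the bouton and dendron
#'   extents along the scan line).
#' @param margin_xy,margin_z Empty margins (um) around the planted geometry.
#' @param seed Integer seed; fixes the output bit-for-bit.
#'
#' @return A list of class `scene_params`.
#' @seealso [simulate_exm_scene()]
#' @export
scene_params <- function(n_dendrons = 2,
                         dendron_radius = 1.0,
                         dendron_length = 60,
                         curvature_amp = 0,
                         n_boutons = 20,
                         bouton_diameter_mean = 2.0,
                         bouton_diameter_sd = 0.15,
                         gap_distribution = data.frame(
                           gap = c(-1.5, 0.3, 2.5),
                           fraction = c(0.3, 0.4, 0.3)
                         ),
                         cochannel_fraction = 0.7,
                         psf_sigma_xy = 0.1,
                         psf_sigma_z = 0.25,
                         noise_snr = 10,
                         read_noise_sd = 1,
                         background = 0.02,
                         voxel_xy = 0.1,
                         voxel_z = 0.6,
                         expansion_factor = 4.17,
                         modality = c("ExM", "confocal"),
                         thresholds = morph_thresholds(),
                         margin_xy = 4,
                         margin_z = 6,
                         seed = 1L) {
  modality <- match.arg(modality)
  if (modality == "confocal") expansion_factor <- 1
  p <- list(
    n_dendrons = n_dendrons, dendron_radius = dendron_radius,
    dendron_length = dendron_length, curvature_amp = curvature_amp,
    n_boutons = n_boutons,
    bouton_diameter_mean = bouton_diameter_mean,
    bouton_diameter_sd = bouton_diameter_sd,
    gap_distribution = gap_distribution,
    cochannel_fraction = cochannel_fraction,
    psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
    noise_snr = noise_snr, read_noise_sd = read_noise_sd,
    background = background,
    voxel_xy = voxel_xy, voxel_z = voxel_z,
    expansion_factor = expansion_factor, modality = modality,
    thresholds = thresholds,
    margin_xy = margin_xy, margin_z = margin_z,
    seed = as.integer(seed)
  )
  validate_scene_params(p)
  class(p) <- "scene_params"
  p
}

validate_scene_params <- function(p) {
  lens <- c(p$dendron_radius, p$dendron_length, p$bouton_diameter_mean,
            p$voxel_xy, p$voxel_z)
  if (any(lens <= 0)) stop("all lengths must be > 0")
  if (p$cochannel_fraction < 0 || p$cochannel_fraction > 1)
    stop("cochannel_fraction must lie in [0, 1]")
  gd <- p$gap_distribution
  if (!is.data.frame(gd) || !all(c("gap", "fraction") %in% names(gd)))
    stop("gap_distribution needs columns 'gap' and 'fraction'")
  if (any(gd$fraction < 0) || abs(sum(gd$fraction) - 1) > 1e-8)
    stop("gap_distribution fractions must be non-negative and sum to 1")
  if (!is.null(gd$orientation) &&
      !all(gd$orientation %in% c("side", "face")))
    stop("gap_distribution orientation must be 'side' or 'face'")
  if (max(p$voxel_xy, p$voxel_z) > p$bouton_diameter_mean)
    stop("undersampled scene: voxel size exceeds the mean bouton diameter")
  if (p$expansion_factor < 1) stop("expansion_factor must be >= 1")
  invisible(p)
}

#' Construct a three-channel image scene
#'
#' Container for a multichannel 3D fluorescence volume with its voxel and
#' expansion metadata. Channels are `[x, y, z]` arrays of identical shape.
#'
#' @param gfp,kisspeptin,synaptophysin 3D intensity arrays.
#' @param voxel_xy,voxel_z Voxel pitch in um (imaged, i.e. post-expansion
#'   frame).
#' @param expansion_factor Physical expansion factor (confocal scenes use 1).
#' @param modality `"ExM"` or `"confocal"`.
#' @return An object of class `exm_scene`.
#' @export
exm_scene <- function(gfp, kisspeptin, synaptophysin,
                      voxel_xy, voxel_z, expansion_factor = 1,
                      modality = c("ExM", "confocal")) {
  modality <- match.arg(modality)
  dims <- list(dim(gfp), dim(kisspeptin), dim(synaptophysin))
  if (length(unique(lapply(dims, as.integer))) != 1L ||
      any(vapply(dims, length, 1L) != 3L))
    stop("all channels must be 3D arrays of identical shape")
  if (voxel_xy <= 0 || voxel_z <= 0) stop("voxel sizes must be > 0")
  if (expansion_factor < 1) stop("expansion_factor must be >= 1")
  if (modality == "confocal" && expansion_factor != 1)
    stop("confocal scenes must have expansion_factor 1")
  structure(
    list(channels = list(gfp = gfp, kisspeptin = kisspeptin,
                         synaptophysin = synaptophysin),
         voxel_xy = voxel_xy, voxel_z = voxel_z,
         expansion_factor = expansion_factor, modality = modality),
    class = "exm_scene")
}

#' @export
print.exm_scene <- function(x, ...) {
  d <- dim(x$channels$gfp)
  cat(sprintf(
    "<exm_scene> %s, %d x %d x %d voxels (%.2f x %.2f x %.2f um), expansion %.2fx\n",
    x$modality, d[1], d[2], d[3],
    d[1] * x$voxel_xy, d[2] * x$voxel_xy, d[3] * x$voxel_z,
    x$expansion_factor))
  invisible(x)
}

# Largest-remainder apportionment of n among fractions (exact total).
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Intended bouton class by construction: the overlap a noise-free profile
# measurement would read off is -gap (clipped to the bouton/dendron extents).
intended_class <- function(gap, orientation, r_bouton, r_dendron, th) {
  ov <- pmax(0, pmin(-gap, 2 * r_bouton, 2 * r_dendron))
  theta <- ifelse(orientation == "face", th$theta_face, th$theta_side)
  ifelse(ov > theta, "synapse",
         ifelse(gap <= th$contact_max_gap, "close_nonsynaptic", "separate"))
}

#' Simulate a ground-truthed expansion-microscopy scene
#'
#' Renders dendron tubes (GFP channel) and Gaussian-profiled boutons
#' (kisspeptin channel, with synaptophysin co-centred on a configurable
#' fraction), blurs with an anisotropic Gaussian PSF, and applies Poisson
#' photon noise plus Gaussian read noise scaled to the requested peak SNR.
#' Every planted bouton is recorded in the returned ground truth with its
#' signed gap, orientation and intended contact class, so downstream
#' detection and classification can be scored exactly.
#'
#' @param params A [scene_params()] object.
#' @return A list with elements `scene` (an [exm_scene()]) and `truth`
#'   (data frame: `bouton_id`, `fiber_id`, `dendron_id`, `x`, `y`, `z`,
#'   `diameter`, `has_synaptophysin`, `orientation`, `gap`,
#'   `intended_overlap`, `intended_class`) plus `dendrons` (data frame of
#'   planted tube axes and lengths).
#' @export
simulate_exm_scene <- function(params) {
  validate_scene_params(params)
  p <- params
  with_seed(p$seed, {
    # ---- layout ---------------------------------------------------------
    reach <- p$dendron_radius + p$bouton_diameter_mean +
      max(0, max(p$gap_distribution$gap)) + 2
    spacing <- max(2 * reach + 1, 8)
    ext_x <- p$dendron_length + 2 * p$margin_xy
    ext_y <- 2 * (p$margin_xy + reach) +
      max(0, (p$n_dendrons - 1)) * spacing
    ext_z <- 2 * (p$margin_z + p$dendron_radius)
    nx <- max(4L, ceiling(ext_x / p$voxel_xy))
    ny <- max(4L, ceiling(ext_y / p$voxel_xy))
    nz <- max(4L, ceiling(ext_z / p$voxel_z))
    xs <- (seq_len(nx) - 1) * p$voxel_xy
    ys <- (seq_len(ny) - 1) * p$voxel_xy
    zs <- (seq_len(nz) - 1) * p$voxel_z
    z0 <- ext_z / 2
    y_axes <- p$margin_xy + reach + (seq_len(p$n_dendrons) - 1) * spacing
    x_start <- p$margin_xy

    X <- array(rep(xs, times = ny * nz), c(nx, ny, nz))
    Y <- array(rep(rep(ys, each = nx), times = nz), c(nx, ny, nz))
    Z <- array(rep(zs, each = nx * ny), c(nx, ny, nz))

    gfp <- array(0, c(nx, ny, nz))
    dend <- data.frame(dendron_id = integer(0), y0 = numeric(0),
                       z0 = numeric(0), x_start = numeric(0),
                       length_post = numeric(0), length_pre = numeric(0),
                       radius = numeric(0))
    axis_y <- function(x, y0) {
      y0 + p$curvature_amp * sin(2 * pi * (x - x_start) / p$dendron_length)
    }
    for (i in seq_len(p$n_dendrons)) {
      yc <- axis_y(X, y_axes[i])
      r2 <- (Y - yc)^2 + (Z - z0)^2
      inside <- r2 <= p$dendron_radius^2 &
        X >= x_start & X <= x_start + p$dendron_length
      gfp[inside] <- 1
      # arc length of the gently bent axis
      xx <- seq(0, p$dendron_length, length.out = 512)
      dy <- p$curvature_amp * 2 * pi / p$dendron_length *
        cos(2 * pi * xx / p$dendron_length)
      arc <- sum(sqrt(1 + dy[-1]^2) * diff(xx))
      dend <- rbind(dend, data.frame(
        dendron_id = i, y0 = y_axes[i], z0 = z0, x_start = x_start,
        length_post = arc, length_pre = arc / p$expansion_factor,
        radius = p$dendron_radius))
    }

    # ---- boutons --------------------------------------------------------
    kiss <- array(0, c(nx, ny, nz))
    syn <- array(0, c(nx, ny, nz))
    truth <- data.frame()
    if (p$n_boutons > 0) {
      gd <- p$gap_distribution
      if (is.null(gd$orientation)) gd$orientation <- "side"
      counts <- apportion(p$n_boutons, gd$fraction)
      gaps <- rep(gd$gap, counts)
      orients <- rep(gd$orientation, counts)
      shuffle <- sample.int(p$n_boutons)
      gaps <- gaps[shuffle]
      orients <- orients[shuffle]
      dend_of <- rep(seq_len(p$n_dendrons), length.out = p$n_boutons)
      n_coch <- apportion(p$n_boutons,
                          c(p$cochannel_fraction, 1 - p$cochannel_fraction))[1]
      coch <- sample(rep(c(TRUE, FALSE),
                         c(n_coch, p$n_boutons - n_coch)))
      diam <- pmax(0.5 * p$bouton_diameter_mean,
                   rnorm(p$n_boutons, p$bouton_diameter_mean,
                         p$bouton_diameter_sd))
      # evenly spaced slots along each dendron, with small jitter
      per_d <- table(factor(dend_of, levels = seq_len(p$n_dendrons)))
      xpos <- numeric(p$n_boutons)
      for (i in seq_len(p$n_dendrons)) {
        idx <- which(dend_of == i)
        k <- length(idx)
        if (k == 0) next
        slots <- x_start + (seq_len(k) - 0.5) * p$dendron_length / k
        xpos[idx] <- slots + runif(k, -0.2, 0.2)
      }
      side_sign <- sample(c(-1, 1), p$n_boutons, replace = TRUE)
      tilt <- runif(p$n_boutons, -10, 10) * pi / 180
      cx <- cy <- cz <- numeric(p$n_boutons)
      for (b in seq_len(p$n_boutons)) {
        r_b <- diam[b] / 2
        c_dist <- max(0.05, p$dendron_radius + r_b + gaps[b])
        ax <- c(xpos[b], axis_y(xpos[b], y_axes[dend_of[b]]), z0)
        dir <- if (orients[b] == "side") {
          c(0, side_sign[b] * cos(tilt[b]), sin(tilt[b]))
        } else {
          c(0, sin(tilt[b]), side_sign[b] * cos(tilt[b]))
        }
        ctr <- ax + dir * c_dist
        cx[b] <- ctr[1]; cy[b] <- ctr[2]; cz[b] <- ctr[3]
        # render into a local box (4 sigma support)
        sig <- diam[b] / (2 * sqrt(2 * log(2)))
        half <- 4 * sig
        ix <- which(xs >= ctr[1] - half & xs <= ctr[1] + half)
        iy <- which(ys >= ctr[2] - half & ys <= ctr[2] + half)
        iz <- which(zs >= ctr[3] - half & zs <= ctr[3] + half)
        if (!length(ix) || !length(iy) || !length(iz)) next
        bx <- outer(outer((xs[ix] - ctr[1])^2, (ys[iy] - ctr[2])^2, "+"),
                    (zs[iz] - ctr[3])^2, "+")
        blob <- exp(-bx / (2 * sig^2))
        kiss[ix, iy, iz] <- pmax(kiss[ix, iy, iz], blob)
        if (coch[b]) syn[ix, iy, iz] <- pmax(syn[ix, iy, iz], blob)
      }
      ov <- pmax(0, pmin(-gaps, diam, 2 * p$dendron_radius))
      cls <- intended_class(gaps, orients, diam / 2, p$dendron_radius,
                            p$thresholds)
      # a synapse requires a synaptophysin-positive terminal; overlapping
      # kisspeptin-only boutons count as close contacts
      demote <- cls == "synapse" & !coch
      cls[demote] <- ifelse(gaps[demote] <= p$thresholds$contact_max_gap,
                            "close_nonsynaptic", "separate")
      truth <- data.frame(
        bouton_id = seq_len(p$n_boutons),
        fiber_id = seq_len(p$n_boutons),
        dendron_id = dend_of,
        x = cx, y = cy, z = cz,
        diameter = diam,
        has_synaptophysin = coch,
        orientation = orients,
        gap = gaps,
        intended_overlap = ov,
        intended_class = cls,
        stringsAsFactors = FALSE)
    }

    # ---- optics + noise -------------------------------------------------
    sig_vox <- c(p$psf_sigma_xy / p$voxel_xy, p$psf_sigma_xy / p$voxel_xy,
                 p$psf_sigma_z / p$voxel_z)
    render <- function(clean) {
      blurred <- gaussian_blur3d(clean, sig_vox)
      lam <- (p$background + (1 - p$background) * blurred) * p$noise_snr^2
      counts <- array(rpois(length(lam), lam), dim(lam))
      counts + array(rnorm(length(lam), 0, p$read_noise_sd), dim(lam))
    }
    scene <- exm_scene(render(gfp), render(kiss), render(syn),
                       voxel_xy = p$voxel_xy, voxel_z = p$voxel_z,
                       expansion_factor = p$expansion_factor,
                       modality = p$modality)
    list(scene = scene, truth = truth, dendrons = dend)
  })
}
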