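#' Specify a synthetic CT-angiography phantom
#'
#' A phantom emulates the structure of a contrast-enhanced lower-extremity
#' CTA at desk scale: square transverse slices containing one continuous
#' bright vessel (contrast-filled lumen surrounded by a darker wall),
#' hyperintense calcified arcs embedded in the wall, and bone-like disk
#' confounders whose intensity overlaps the calcification range. All
#' geometry is analytic, so the true vessel mask and the true calcium
#' volume are known exactly, independent of rendering.
#'
#' Intensities are specified directly on the 0--255 8-bit scale that
#' calcium scoring operates on. A voxel belongs to a region iff its centre
#' lies inside the analytic region (no anti-aliasing), which makes the
#' closed-form truth exact. Gaussian noise, when requested, is added after
#' rendering and truncated to \[0, 255\]; it never changes the truth.
#'
#' @param image_size pixels per side of the square slices (default 128).
#' @param n_slices number of transverse slices (default 40).
#' @param voxel_spacing `(dx, dy, dz)` in mm; default 1 mm isotropic.
#' @param vessel_path `n_slices x 2` matrix of per-slice `(row, col)`
#'   centreline coordinates; default is a smooth sinusoidal drift about the
#'   image centre.
#' @param vessel_radius_profile per-slice outer vessel radius in pixels
#'   (lumen + wall); default tapers mildly toward the last slice.
#' @param wall_thickness radial thickness of the vessel wall in pixels.
#' @param lumen_intensity 8-bit intensity of contrast-enhanced blood; must
#'   stay below the 145 scoring threshold so lumen never scores as calcium.
#' @param wall_intensity 8-bit intensity of non-calcified wall (< 145).
#' @param background_intensity 8-bit soft-tissue background level.
#' @param calcifications list of calcified wall arcs, each a list with
#'   `slice_range` (inclusive `c(first, last)`), `angular_arc`
#'   (`c(theta0, theta1)` radians, counter-clockwise from the +col axis),
#'   `radial_thickness` (pixels, at most `wall_thickness`), and
#'   `intensity` (strictly greater than 145).
#' @param bones list of disk confounders, each `list(center = c(row, col),
#'   radius, intensity)`, rendered on every slice; must not intersect the
#'   vessel on any slice.
#' @param artifact one of `"none"`, `"no_contrast"`, `"metal_streak"`,
#'   `"stent"`; applied by [generate_phantom()] after rendering.
#' @param noise_sigma additive Gaussian noise standard deviation (8-bit
#'   units).
#' @param start_slice index standing in for the anatomical start of the
#'   scoring range (the slice just below the left renal artery in the
#'   clinical protocol).
#' @param seed integer seed controlling the noise; generation is
#'   deterministic for a fixed spec.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [random_phantom_spec()]
#' @export
phantom_spec <- function(image_size = 128L,
                         n_slices = 40L,
                         voxel_spacing = c(1, 1, 1),
                         vessel_path = NULL,
                         vessel_radius_profile = NULL,
                         wall_thickness = NULL,
                         lumen_intensity = 130L,
                         wall_intensity = 95L,
                         background_intensity = 35L,
                         calcifications = list(),
                         bones = list(),
                         artifact = c("none", "no_contrast", "metal_streak", "stent"),
                         noise_sigma = 0,
                         start_slice = 1L,
                         seed = 1L) {
  artifact <- match.arg(artifact)
  image_size <- as.integer(image_size); n_slices <- as.integer(n_slices)
  stopifnot(image_size >= 16L, n_slices >= 1L)
  if (is.null(vessel_path)) {
    s <- seq_len(n_slices)
    amp <- image_size / 10
    vessel_path <- cbind(
      image_size / 2 + amp * sin(2 * pi * s / n_slices),
      image_size / 2 + amp * cos(2 * pi * s / (1.7 * n_slices)))
  }
  vessel_path <- matrix(as.numeric(vessel_path), ncol = 2L)
  if (nrow(vessel_path) != n_slices)
    stop("vessel_path must have one (row, col) centre per slice", call. = FALSE)
  if (is.null(vessel_radius_profile)) {
    base_r <- image_size / 12
    vessel_radius_profile <-
      base_r * (1 - 0.25 * (seq_len(n_slices) - 1) / max(1L, n_slices - 1L))
  }
  vessel_radius_profile <- rep_len(as.numeric(vessel_radius_profile), n_slices)
  if (is.null(wall_thickness)) wall_thickness <- max(2, image_size / 40)
  spec <- structure(
    list(image_size = image_size, n_slices = n_slices,
         voxel_spacing = as.numeric(voxel_spacing),
         vessel_path = vessel_path,
         vessel_radius_profile = vessel_radius_profile,
         wall_thickness = as.numeric(wall_thickness),
         lumen_intensity = as.integer(lumen_intensity),
         wall_intensity = as.integer(wall_intensity),
         background_intensity = as.integer(background_intensity),
         calcifications = calcifications, bones = bones,
         artifact = artifact, noise_sigma = as.numeric(noise_sigma),
         start_slice = as.integer(start_slice), seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  n <- spec$image_size
  r <- spec$vessel_radius_profile
  if (any(r <= 0)) stop("vessel radius must be positive on every slice", call. = FALSE)
  lo_row <- spec$vessel_path[, 1L] - r; hi_row <- spec$vessel_path[, 1L] + r
  lo_col <- spec$vessel_path[, 2L] - r; hi_col <- spec$vessel_path[, 2L] + r
  if (any(lo_row < 1) || any(hi_row > n) || any(lo_col < 1) || any(hi_col > n))
    stop("geometry error: vessel path exits the image frame", call. = FALSE)
  if (spec$lumen_intensity >= 145L)
    stop("lumen intensity must stay below the 145 scoring threshold", call. = FALSE)
  if (spec$wall_intensity >= 145L)
    stop("wall intensity must stay below the 145 scoring threshold", call. = FALSE)
  for (ca in spec$calcifications) {
    sr <- ca$slice_range
    if (sr[1L] < 1L || sr[2L] > spec$n_slices || sr[1L] > sr[2L])
      stop("geometry error: calcification slice_range outside the volume", call. = FALSE)
    if (ca$radial_thickness > spec$wall_thickness + 1e-9)
      stop("geometry error: calcification arc thicker than the vessel wall", call. = FALSE)
    if (ca$intensity <= 145)
      stop("calcification intensity must be strictly above 145", call. = FALSE)
  }
  for (b in spec$bones) {
    d <- sqrt((spec$vessel_path[, 1L] - b$center[1L])^2 +
              (spec$vessel_path[, 2L] - b$center[2L])^2)
    if (any(d <= r + b$radius))
      stop("geometry error: bone disk intersects the vessel", call. = FALSE)
  }
  invisible(spec)
}

#' Draw a randomized phantom specification
#'
#' Samples a phantom with a randomly phased sinusoidal centreline, one to
#' `max_calcifications` calcified wall arcs of random extent, arc angle and
#' intensity, and a bone confounder whose intensity lies inside the
#' calcification range. Geometry is sampled so that the validity
#' constraints of [phantom_spec()] hold by construction.
#'
#' @param seed integer; the single source of randomness.
#' @param image_size,n_slices,noise_sigma passed to [phantom_spec()].
#' @param max_calcifications upper bound on the number of calcified arcs.
#' @param artifact artifact kind forwarded to the spec.
#' @return A `phantom_spec`.
#' @export
random_phantom_spec <- function(seed, image_size = 128L, n_slices = 40L,
                                noise_sigma = 0, max_calcifications = 4L,
                                artifact = "none") {
  image_size <- as.integer(image_size); n_slices <- as.integer(n_slices)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  s <- seq_len(n_slices)
  amp <- runif(2, image_size / 16, image_size / 10)
  phase <- runif(2, 0, 2 * pi)
  path <- cbind(
    image_size / 2 + amp[1] * sin(2 * pi * s / n_slices + phase[1]),
    image_size / 2 + amp[2] * cos(2 * pi * s / (1.5 * n_slices) + phase[2]))
  base_r <- runif(1, image_size / 14, image_size / 10)
  radius <- base_r * (1 - runif(1, 0.1, 0.3) * (s - 1) / max(1L, n_slices - 1L))
  wall <- max(2, image_size / 40)
  n_calc <- sample.int(max_calcifications, 1L)
  calcs <- lapply(seq_len(n_calc), function(i) {
    len <- sample(3:max(4L, n_slices %/% 3L), 1L)
    first <- sample.int(max(1L, n_slices - len + 1L), 1L)
    th0 <- runif(1, 0, 2 * pi)
    list(slice_range = c(first, min(n_slices, first + len - 1L)),
         angular_arc = c(th0, th0 + runif(1, pi / 4, pi)),
         radial_thickness = runif(1, wall * 0.6, wall),
         intensity = round(runif(1, 195, 230)))
  })
  # bone in a corner quadrant, provably clear of the path envelope
  bone_r <- runif(1, image_size / 14, image_size / 10)
  corner <- sample(1:4, 1L)
  off <- image_size * 0.2
  centre <- switch(corner,
    c(off, off), c(off, image_size - off),
    c(image_size - off, off), c(image_size - off, image_size - off))
  bones <- list(list(center = centre, radius = bone_r,
                     intensity = round(runif(1, 175, 220))))
  phantom_spec(image_size = image_size, n_slices = n_slices,
               vessel_path = path, vessel_radius_profile = radius,
               wall_thickness = wall, calcifications = calcs, bones = bones,
               artifact = artifact, noise_sigma = noise_sigma,
               start_slice = sample.int(max(1L, n_slices %/% 8L), 1L),
               seed = seed)
}

# save/restore the global RNG stream so generators are pure functions of seed
.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Render a phantom volume and its analytic ground truth
#'
#' Rasterizes the spec (voxel centre in analytic region), renders intensity
#' (background, bones, vessel wall, lumen, calcified arcs, in that order),
#' applies the requested artifact, then adds truncated Gaussian noise. The
#' returned truth carries the vessel mask, the calcium mask (a subset of
#' the vessel mask by construction), the exact calcified voxel count and
#' its volume `count * dx*dy*dz`, and the scoring start slice. Noise and
#' artifacts corrupt only the image, never the truth.
#'
#' @param spec a [phantom_spec()].
#' @return `list(volume = ct_volume, truth = phantom_truth)` where
#'   `phantom_truth` has fields `vessel_mask`, `calcium_mask`,
#'   `true_calcium_voxels`, `true_calcium_volume`, `start_slice`.
#' @examples
#' ph <- generate_phantom(random_phantom_spec(seed = 7, image_size = 32,
#'                                            n_slices = 6))
#' ph$truth$true_calcium_volume
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  n <- spec$image_size; ns <- spec$n_slices
  ii <- matrix(seq_len(n), n, n)        # row coordinate of each voxel centre
  jj <- matrix(seq_len(n), n, n, byrow = TRUE)
  img <- array(spec$background_intensity, c(n, n, ns))
  vessel <- array(0L, c(n, n, ns))
  calcium <- array(0L, c(n, n, ns))
  for (b in spec$bones) {
    inb <- (ii - b$center[1L])^2 + (jj - b$center[2L])^2 <= b$radius^2
    for (s in seq_len(ns)) { sl <- img[, , s]; sl[inb] <- b$intensity; img[, , s] <- sl }
  }
  for (s in seq_len(ns)) {
    c0 <- spec$vessel_path[s, ]
    r <- spec$vessel_radius_profile[s]
    d2 <- (ii - c0[1L])^2 + (jj - c0[2L])^2
    in_vessel <- d2 <= r^2
    r_lumen <- max(0, r - spec$wall_thickness)
    in_lumen <- d2 <= r_lumen^2
    sl <- img[, , s]
    sl[in_vessel] <- spec$wall_intensity
    sl[in_lumen] <- spec$lumen_intensity
    vessel[, , s][in_vessel] <- 1L
    theta <- atan2(ii - c0[1L], jj - c0[2L])  # (-pi, pi]
    for (ca in spec$calcifications) {
      if (s < ca$slice_range[1L] || s > ca$slice_range[2L]) next
      r_in <- r - ca$radial_thickness
      in_ring <- d2 <= r^2 & d2 > r_in^2
      in_arc <- angle_in_arc(theta, ca$angular_arc[1L], ca$angular_arc[2L])
      hit <- in_ring & in_arc
      sl[hit] <- ca$intensity
      calcium[, , s][hit] <- 1L
    }
    img[, , s] <- sl
  }
  truth <- structure(
    list(vessel_mask = binary_mask(vessel, spec$voxel_spacing),
         calcium_mask = binary_mask(calcium, spec$voxel_spacing),
         true_calcium_voxels = sum(calcium),
         true_calcium_volume = sum(calcium) * voxel_volume_mm3(spec$voxel_spacing),
         start_slice = spec$start_slice),
    class = "phantom_truth")
  vol <- ct_volume(img, spacing = spec$voxel_spacing, intensity_scale = "8bit",
                   patient_id = sprintf("phantom-%d", spec$seed))
  if (spec$artifact != "none")
    vol <- apply_artifact(vol, truth, spec$artifact, seed = spec$seed)
  if (spec$noise_sigma > 0) {
    old <- .Random.seed_store(); on.exit(.Random.seed_restore(old))
    set.seed(spec$seed)
    noisy <- vol$voxels + rnorm(length(vol$voxels), 0, spec$noise_sigma)
    vol$voxels <- array(as.integer(pmin(255, pmax(0, round(noisy)))), dim(vol$voxels))
  }
  list(volume = vol, truth = truth)
}

angle_in_arc <- function(theta, a0, a1) {
  # membership of theta in the CCW arc [a0, a1], all reduced mod 2*pi
  width <- (a1 - a0) %% (2 * pi)
  if (width == 0 && a1 != a0) return(theta == theta)  # full circle
  rel <- (theta - a0) %% (2 * pi)
  rel <= width
}

#' Corrupt a phantom image with an acquisition artifact
#'
#' Phenomenological versions of the failure modes seen in clinical scans:
#' `no_contrast` pulls the lumen intensity toward background (an
#' unenhanced scan; calcified arcs stay bright), `metal_streak` overlays
#' saturated radial streaks emanating from the brightest extra-vascular
#' structure (a spinal screw), and `stent` paints a hyperintense annulus on
#' the vessel wall over the middle third of the volume. Truth masks are
#' never modified: artifacts corrupt the image, not the anatomy.
#'
#' @param volume a [ct_volume()] rendered from `truth`'s phantom.
#' @param truth the matching `phantom_truth`.
#' @param artifact `"none"`, `"no_contrast"`, `"metal_streak"` or `"stent"`.
#' @param seed seed for the streak geometry.
#' @return The corrupted [ct_volume()]; identity when `artifact = "none"`.
#' @export
apply_artifact <- function(volume, truth, artifact, seed = 1L) {
  stopifnot(inherits(volume, "ct_volume"))
  artifact <- match.arg(artifact, c("none", "no_contrast", "metal_streak", "stent"))
  if (artifact == "none") return(volume)
  vox <- volume$voxels
  vmask <- truth$vessel_mask$voxels
  cmask <- truth$calcium_mask$voxels
  d <- dim(vox)
  if (artifact == "no_contrast") {
    bg <- stats::median(vox[vmask == 0L])
    sel <- vmask == 1L & cmask == 0L
    vox[sel] <- round(bg + 0.25 * (vox[sel] - bg))
  } else if (artifact == "metal_streak") {
    outside <- which(vmask == 0L, arr.ind = FALSE)
    ctr_idx <- outside[which.max(vox[outside])]
    ai <- arrayInd(ctr_idx, d)
    old <- .Random.seed_store(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    angles <- runif(14, 0, 2 * pi)
    ii <- matrix(seq_len(d[1]), d[1], d[2])
    jj <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
    theta <- atan2(ii - ai[1], jj - ai[2])
    streak <- Reduce(`|`, lapply(angles, function(a) {
      da <- abs(((theta - a + pi) %% (2 * pi)) - pi)
      da < 0.03
    }))
    slices <- seq(max(1L, ai[3] - 4L), min(d[3], ai[3] + 4L))
    for (s in slices) { sl <- vox[, , s]; sl[streak] <- 255L; vox[, , s] <- sl }
  } else if (artifact == "stent") {
    ring <- vmask - erode_mask_slices(vmask)
    slices <- seq(floor(d[3] / 3) + 1L, floor(2 * d[3] / 3))
    for (s in slices) { sl <- vox[, , s]; sl[ring[, , s] == 1L] <- 250L; vox[, , s] <- sl }
  }
  volume$voxels <- array(as.integer(pmin(255L, pmax(0L, vox))), d)
  volume
}

# 4-neighbour erosion applied slice-wise; used to find the wall ring
erode_mask_slices <- function(m) {
  d <- dim(m)
  out <- m
  shift <- function(x, dr, dc) {
    y <- matrix(0L, nrow(x), ncol(x))
    rs <- seq_len(nrow(x)) + dr; cs <- seq_len(ncol(x)) + dc
    ok_r <- rs >= 1 & rs <= nrow(x); ok_c <- cs >= 1 & cs <= ncol(x)
    y[ok_r, ok_c] <- x[rs[ok_r], cs[ok_c]]
    y
  }
  for (s in seq_len(d[3])) {
    sl <- m[, , s]
    out[, , s] <- sl * shift(sl, 1, 0) * shift(sl, -1, 0) *
      shift(sl, 0, 1) * shift(sl, 0, -1)
  }
  out
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d calcified voxels (%.1f mm^3), start slice %d\n",
              x$true_calcium_voxels, x$true_calcium_volume, x$start_slice))
  invisible(x)
}
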