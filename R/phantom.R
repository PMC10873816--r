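#' Specification of a synthetic growing-plant phantom
#'
#' Parameters of the 4D ground-truth generator: a plant body with tubular
#' roots inside a cylindrical container (emulating a specimen in its Falcon
#' tube inside the scanner holder). Between timepoints the roots elongate at
#' the tip, their long axis tilts (bending), and a bright surface bead
#' carried on each root advances around the root midline at the roll rate —
#' the ground truth for twisting/resupination. The whole specimen is rigidly
#' repositioned between scan sessions (rotation about the vertical axis plus
#' translation, drawn from the stated ranges using the seed), and Gaussian
#' noise is added last. All lengths are voxels, angles degrees, rates per
#' timepoint.
#'
#' @param grid Grid extents in voxels (default `c(64, 64, 64)` so full test
#'   suites run in minutes).
#' @param container_radius,container_height,container_wall Radius/height of
#'   the container shell and its intensity.
#' @param wall_thickness Shell thickness in voxels.
#' @param n_roots Number of roots.
#' @param root_radius Tube radius in voxels.
#' @param root_length Initial root length in voxels.
#' @param helix_pitch Voxels per turn of the slight helical wobble of each
#'   root centerline (breaks rotational symmetry; real aerial roots are not
#'   straight).
#' @param roll_rate Degrees of axial roll per timepoint (default 45: a
#'   weekly cadence that resupinates in four intervals).
#' @param bend_rate Degrees of in-plane tilt change per timepoint.
#' @param growth_rate Voxels of tip extension per timepoint.
#' @param tissue,background Intensities of root/body tissue and medium.
#' @param marker_intensity,marker_radius,marker_offset Bead intensity,
#'   radius, and distance of the bead center from the root axis.
#' @param noise_sigma Additive Gaussian noise s.d. as a fraction of the
#'   dynamic range (default 0.02).
#' @param reposition_max_rot,reposition_max_shift Ranges (+/-) of the
#'   per-session rigid repositioning: z-rotation in degrees, per-axis
#'   translation in voxels.
#' @param seed Integer seed; generation is bit-exactly deterministic given
#'   the seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(64, 64, 64),
                         container_radius = 24, container_height = 56,
                         container_wall = 0.7, wall_thickness = 2,
                         n_roots = 2, root_radius = 4, root_length = 20,
                         helix_pitch = 40,
                         roll_rate = 45, bend_rate = 1, growth_rate = 1.2,
                         tissue = 0.5, background = 0.05,
                         marker_intensity = 1, marker_radius = 2, marker_offset = 6,
                         noise_sigma = 0.02,
                         reposition_max_rot = 15, reposition_max_shift = 5,
                         seed = 1L) {
  spec <- list(
    grid = as.integer(grid), container_radius = container_radius,
    container_height = container_height, container_wall = container_wall,
    wall_thickness = wall_thickness, n_roots = as.integer(n_roots),
    root_radius = root_radius, root_length = root_length,
    helix_pitch = helix_pitch, roll_rate = roll_rate, bend_rate = bend_rate,
    growth_rate = growth_rate, tissue = tissue, background = background,
    marker_intensity = marker_intensity, marker_radius = marker_radius,
    marker_offset = marker_offset, noise_sigma = noise_sigma,
    reposition_max_rot = reposition_max_rot,
    reposition_max_shift = reposition_max_shift, seed = as.integer(seed)
  )
  stopifnot(all(spec$grid >= 8), spec$n_roots >= 1, spec$root_radius >= 1,
            spec$noise_sigma >= 0, all(is.finite(unlist(spec))))
  structure(spec, class = "phantom_spec")
}

#' Generate a phantom scan sequence with ground truth
#'
#' Renders `n_timepoints` volumes of the phantom described by `spec`
#' (deterministic given `spec$seed`): roots are soft-edged tubes (distance-
#' to-centerline field with a 1-voxel edge, so sub-voxel motion is visible
#' to registration), marker beads advance by the roll rate, the whole
#' specimen is rigidly repositioned per session, and Gaussian noise is added
#' last. Acquisition days run weekly from day 70.
#'
#' @param spec A [phantom_spec()].
#' @param n_timepoints Number of scan sessions (`>= 1`).
#' @return A list with elements `sequence` (a [scan_sequence()]), and
#'   `truth`: `transforms` (per-timepoint [rigid_transform()] realigning
#'   each scan to the first session's frame), `angles` (per-root
#'   [angle_series()] with cumulative roll), and `events` (per-root event
#'   tibbles from [detect_events()]).
#' @export
generate_sequence <- function(spec, n_timepoints) {
  stopifnot(inherits(spec, "phantom_spec"), n_timepoints >= 1)
  check_phantom_feasible(spec, n_timepoints)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  days <- 70 + 7 * (seq_len(n_timepoints) - 1)

  # per-session rigid repositioning (identity for the first session)
  moves <- vector("list", n_timepoints)
  moves[[1]] <- rigid_transform()
  for (t in seq_len(n_timepoints)[-1]) {
    moves[[t]] <- rigid_transform(
      rotation = c(runif(1, -spec$reposition_max_rot, spec$reposition_max_rot), 0, 0),
      translation = runif(3, -spec$reposition_max_shift, spec$reposition_max_shift)
    )
  }

  scans <- vector("list", n_timepoints)
  for (t in seq_len(n_timepoints)) {
    vol <- render_phantom_volume(spec, t - 1, moves[[t]])
    if (spec$noise_sigma > 0) {
      vol <- vol + rnorm(length(vol), 0, spec$noise_sigma * spec$marker_intensity)
      # clip to the detector range (slice files store [0, 1])
      vol <- pmin(pmax(vol, 0), 1)
      dim(vol) <- spec$grid
    }
    scans[[t]] <- volume_scan(vol, voxel_size = 0.05, day = days[t],
                              scan_label = sprintf("day %d", days[t]),
                              bit_depth = 32L)
  }

  angles <- lapply(seq_len(spec$n_roots), function(k) {
    geo <- lapply(seq_len(n_timepoints) - 1, function(t) phantom_root_geometry(spec, t, k))
    angle_series(
      days = days,
      orientation_deg = vapply(geo, function(g) g$bend, numeric(1)),
      roll_deg = vapply(geo, function(g) g$roll, numeric(1)),
      unwrapped = TRUE, organ = sprintf("root_%d", k)
    )
  })
  events <- lapply(angles, function(a) if (length(days) >= 2) detect_events(a) else NULL)

  list(
    sequence = scan_sequence(scans),
    truth = list(
      transforms = lapply(moves, invert_transform),
      angles = angles,
      events = events
    )
  )
}

check_phantom_feasible <- function(spec, n_timepoints) {
  max_bend <- (5 + abs(spec$bend_rate) * (n_timepoints - 1)) * pi / 180
  max_len <- spec$root_length + spec$growth_rate * (n_timepoints - 1)
  base_r <- spec$container_radius / 3
  sinb <- sin(min(max_bend, pi / 2))
  tip_reach <- base_r + max_len * sinb + spec$root_radius + 2
  marker_reach <- base_r + 0.6 * spec$root_length * sinb +
    spec$marker_offset + spec$marker_radius + 2
  inner <- spec$container_radius - spec$wall_thickness / 2 - 1
  if (max(tip_reach, marker_reach) > inner) {
    stop("spec infeasible: roots (radial reach ", round(max(tip_reach, marker_reach), 1),
         " voxels) do not fit the container (inner radius ", round(inner, 1), ")")
  }
  if (spec$container_radius * 2 + spec$wall_thickness > min(spec$grid[1:2])) {
    stop("spec infeasible: container does not fit the grid")
  }
  invisible(TRUE)
}

# analytic per-root state at timepoint t (0-based), reference frame
phantom_root_geometry <- function(spec, t, k) {
  alpha <- 2 * pi * (k - 1) / spec$n_roots + 0.5
  base <- c((spec$grid[1] - 1) / 2 + spec$container_radius / 3 * cos(alpha),
            (spec$grid[2] - 1) / 2 + spec$container_radius / 3 * sin(alpha),
            6)
  bend <- spec$bend_rate * t + 5          # degrees from vertical, in-plane
  b <- bend * pi / 180
  dir <- c(sin(b) * cos(alpha), sin(b) * sin(alpha), cos(b))
  len <- spec$root_length + spec$growth_rate * t
  roll <- spec$roll_rate * t              # cumulative ground-truth roll
  list(base = base, dir = dir, len = len, bend = bend, roll = roll, alpha = alpha)
}

render_phantom_volume <- function(spec, t, move) {
  d <- spec$grid
  n <- prod(d)
  # evaluate the moved scene at grid points x by sampling the reference-frame
  # scene at inv(move)(x)
  inv <- invert_transform(move)
  A <- euler_to_matrix(inv$rotation)
  c0 <- (d - 1) / 2
  px <- rep.int(0:(d[1] - 1), d[2] * d[3]) - c0[1]
  py <- rep.int(rep(0:(d[2] - 1), each = d[1]), d[3]) - c0[2]
  pz <- rep(0:(d[3] - 1), each = d[1] * d[2]) - c0[3]
  qx <- A[1, 1] * px + A[1, 2] * py + A[1, 3] * pz + c0[1] + inv$translation[1]
  qy <- A[2, 1] * px + A[2, 2] * py + A[2, 3] * pz + c0[2] + inv$translation[2]
  qz <- A[3, 1] * px + A[3, 2] * py + A[3, 3] * pz + c0[3] + inv$translation[3]

  soft <- function(x) pmin(pmax(x, 0), 1)  # 1-voxel soft edge
  vol <- rep(spec$background, n)

  # container shell + base disc
  r_xy <- sqrt((qx - c0[1])^2 + (qy - c0[2])^2)
  shell <- soft(spec$wall_thickness / 2 + 0.5 - abs(r_xy - spec$container_radius)) *
    soft(spec$container_height - qz) * soft(qz + 0.5)
  base_disc <- soft(spec$container_radius - r_xy) * soft(2 - qz) * soft(qz + 0.5)
  vol <- pmax(vol, spec$container_wall * pmax(shell, base_disc))

  # plant body: squat ellipsoid at the container center
  body <- 1 - sqrt(((qx - c0[1]) / 10)^2 + ((qy - c0[2]) / 10)^2 + ((qz - 8) / 6)^2)
  vol <- pmax(vol, spec$tissue * soft(body * 6))

  # leaves: flattened ellipsoids fanning out at unequal azimuths and sizes,
  # giving the specimen the azimuthal asymmetry registration relies on.
  # They sit low, below the marked root sections, so the ground-truth
  # marker neighbourhood stays free of other organs.
  leaves <- list(
    list(az = 0.9, len = 13, z = 10, th = 2.2),
    list(az = 2.6, len = 10, z = 9, th = 2.0),
    list(az = 4.6, len = 15, z = 11, th = 2.5)
  )
  for (lf in leaves) {
    ux <- cos(lf$az); uy <- sin(lf$az)
    lx <- qx - c0[1] - ux * (lf$len / 2 + 4)
    ly <- qy - c0[2] - uy * (lf$len / 2 + 4)
    du <- lx * ux + ly * uy          # along the leaf
    dv <- -lx * uy + ly * ux         # across the leaf
    dw <- qz - lf$z
    leaf <- 1 - sqrt((du / (lf$len / 2))^2 + (dv / lf$th)^2 + (dw / 2.5)^2)
    vol <- pmax(vol, spec$tissue * soft(leaf * 5))
  }

  for (k in seq_len(spec$n_roots)) {
    g <- phantom_root_geometry(spec, t, k)
    u <- c(-sin(g$alpha), cos(g$alpha), 0)           # normal to bend plane
    v <- vcross(g$dir, u)                            # completes the frame
    # helical wobble of the centerline, sampled as a polyline; the wobble
    # fades out smoothly around the marked arc position, so the section
    # carrying the bead is locally straight and the bead's rotation frame
    # (hence the ground-truth roll) is unambiguous by construction
    ns <- 12L
    s <- seq(0, g$len, length.out = ns + 1)
    ph <- 2 * pi * s / spec$helix_pitch
    sm0 <- 0.6 * spec$root_length
    wob <- 1.5 * (1 - exp(-(s - sm0)^2 / (2 * 6^2)))
    pts <- cbind(
      g$base[1] + s * g$dir[1] + wob * (cos(ph) * u[1] + sin(ph) * v[1]),
      g$base[2] + s * g$dir[2] + wob * (cos(ph) * u[2] + sin(ph) * v[2]),
      g$base[3] + s * g$dir[3] + wob * (cos(ph) * u[3] + sin(ph) * v[3])
    )
    dist2 <- rep(Inf, n)
    for (i in seq_len(ns)) {
      dist2 <- pmin(dist2, segment_dist2(qx, qy, qz, pts[i, ], pts[i + 1, ]))
    }
    vol <- pmax(vol, spec$tissue * soft(spec$root_radius + 0.5 - sqrt(dist2)))

    # marker bead on the tube surface at the (locally straight) marked arc
    # position; its azimuth about the tube axis advances at the roll rate
    axis_pt <- g$base + sm0 * g$dir
    a <- g$roll * pi / 180
    mc <- axis_pt + spec$marker_offset * (cos(a) * u + sin(a) * v)
    md2 <- (qx - mc[1])^2 + (qy - mc[2])^2 + (qz - mc[3])^2
    vol <- pmax(vol, spec$marker_intensity * soft(spec$marker_radius + 0.5 - sqrt(md2)))
  }
  array(vol, d)
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

segment_dist2 <- function(qx, qy, qz, p0, p1) {
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]; vz <- p1[3] - p0[3]
  L2 <- vx^2 + vy^2 + vz^2
  wx <- qx - p0[1]; wy <- qy - p0[2]; wz <- qz - p0[3]
  tt <- pmin(pmax((wx * vx + wy * vy + wz * vz) / L2, 0), 1)
  (wx - tt * vx)^2 + (wy - tt * vy)^2 + (wz - tt * vz)^2
}

#' Apply known rigid perturbations to a sequence
#'
#' Resamples each volume under its transform, producing a sequence with
#' known misalignment — the closed-loop harness for registration tests.
#'
#' @param seq A [scan_sequence()].
#' @param transforms List of [rigid_transform()], one per scan.
#' @return The perturbed [scan_sequence()].
#' @export
perturb_rigid <- function(seq, transforms) {
  stopifnot(inherits(seq, "scan_sequence"))
  if (length(transforms) != length(seq$scans)) {
    stop("transform count (", length(transforms), ") does not match scan count (",
         length(seq$scans), ")")
  }
  scan_sequence(Map(apply_transform, seq$scans, transforms))
}

#' Extract the marker-bead roll series from aligned volumes
#'
#' Given a registered (aligned) sequence containing a single marked root,
#' measures the bead's roll azimuth about the local root axis in each
#' timepoint. The bead is the intensity-weighted centroid of voxels above
#' `marker_threshold`. The local axis is a 3D line fitted through per-slice
#' mean-shift centers around the bead's height: in each slice the centroid
#' of tissue voxels inside a small window is re-centered iteratively, so
#' the window locks onto the tube cross-section and sheds fragments of
#' other organs that graze the slab; voxels near the bead (its soft edge)
#' are excluded so the bead cannot drag the axis toward itself. The
#' azimuth is then measured in the plane perpendicular to the fitted axis
#' (basis: the lab x direction projected off the axis, completed by the
#' right-handed cross product), which removes the ellipse distortion a
#' plain in-plane measurement suffers when the root is tilted.
#'
#' @param seq An aligned [scan_sequence()].
#' @param marker_threshold Absolute intensity above which voxels seed the
#'   bead search; must exceed every other structure's intensity.
#' @param bead_ramp Intensity floor of the bead's soft edge used for the
#'   sub-voxel refinement of its centroid (just above root tissue).
#' @param tissue_range Intensity interval of root tissue used for the axis
#'   estimate.
#' @param slab_half_depth Axis centers are fitted over slices within this
#'   many voxels of the bead's height.
#' @param window_radius Radius in voxels of the mean-shift window; about
#'   1.5 tube radii works well.
#' @param bead_exclusion Radius in voxels around the bead centroid whose
#'   voxels are ignored in the axis estimate.
#' @return An [angle_series()] with the wrapped roll channel.
#' @export
track_marker_roll <- function(seq, marker_threshold = 0.75, bead_ramp = 0.55,
                              tissue_range = c(0.25, 0.8),
                              slab_half_depth = 4, window_radius = 6,
                              bead_exclusion = 3.5) {
  stopifnot(inherits(seq, "scan_sequence"))
  days <- vapply(seq$scans, function(s) as.numeric(s$day), numeric(1))
  roll <- vapply(seq$scans, function(s) {
    vol <- s$intensities
    d <- dim(vol)
    idx <- which(vol > marker_threshold)
    if (length(idx) == 0) {
      stop("no marker voxels above threshold ", marker_threshold)
    }
    w <- vol[idx] - marker_threshold
    ijk <- arrayInd(idx, d) - 1
    m <- colSums(ijk * w) / sum(w)
    # sub-voxel refinement over the bead's full soft edge: the few voxels
    # above the seed threshold carry too little gradation for a stable
    # centroid, so re-weight everything down the ramp near the seed,
    # re-centering the window on the refined position
    ramp <- which(vol > bead_ramp)
    rj <- arrayInd(ramp, d) - 1
    rv <- vol[ramp]
    for (it in 1:4) {
      near <- rowSums(sweep(rj, 2, m)^2) <= 3.2^2
      if (!any(near)) break
      rw <- rv[near] - bead_ramp
      nxt <- colSums(rj[near, , drop = FALSE] * rw) / sum(rw)
      if (max(abs(nxt - m)) < 1e-3) {
        m <- nxt
        break
      }
      m <- nxt
    }
    tiss <- which(vol > tissue_range[1] & vol < tissue_range[2])
    tijk <- arrayInd(tiss, d) - 1
    # soft-edge weights carry the sub-voxel information; the tube core is
    # flat, so cap the weight there
    tw <- pmin(vol[tiss], 0.5) - tissue_range[1]
    near_bead <- (tijk[, 1] - m[1])^2 + (tijk[, 2] - m[2])^2 +
      (tijk[, 3] - m[3])^2 <= bead_exclusion^2
    tijk <- tijk[!near_bead, , drop = FALSE]
    tw <- tw[!near_bead]

    # per-slice mean-shift centers of the tube cross-section, walking
    # outward from the bead's slice with each slice initialized at its
    # neighbor's center (continuity keeps the window on the tube)
    z0 <- round(m[3])
    zs <- (z0 - slab_half_depth):(z0 + slab_half_depth)
    zs <- zs[zs >= 0 & zs < d[3]]
    mean_shift <- function(sl, sw, init) {
      center <- init
      for (it in 1:20) {
        keep <- (sl[, 1] - center[1])^2 + (sl[, 2] - center[2])^2 <= window_radius^2
        if (sum(keep) < 3) {
          return(NULL)
        }
        nxt <- colSums(sl[keep, 1:2, drop = FALSE] * sw[keep]) / sum(sw[keep])
        if (max(abs(nxt - center)) < 1e-3) {
          return(nxt)
        }
        center <- nxt
      }
      center
    }
    centers <- matrix(NA_real_, length(zs), 3)
    ord <- order(abs(zs - z0))
    for (k in ord) {
      sel <- tijk[, 3] == zs[k]
      sl <- tijk[sel, , drop = FALSE]
      if (nrow(sl) < 5) next
      neighbor <- which(!is.na(centers[, 3]) & abs(zs - zs[k]) <= 2)
      init <- if (length(neighbor)) {
        colMeans(centers[neighbor, 1:2, drop = FALSE])
      } else {
        m[1:2]
      }
      center <- mean_shift(sl, tw[sel], init)
      if (!is.null(center)) centers[k, ] <- c(center, zs[k])
    }
    centers <- centers[stats::complete.cases(centers), , drop = FALSE]
    if (nrow(centers) < 3) {
      stop("no tissue voxels found for the axis estimate")
    }
    # the centerline is locally curved (roots are not straight), so fit
    # per-coordinate quadratics in z and evaluate position and tangent at
    # the bead's height
    fit_axis <- function(centers) {
      dz <- centers[, 3] - m[3]
      X <- if (nrow(centers) >= 5) cbind(1, dz, dz^2) else cbind(1, dz)
      cx <- qr.solve(X, centers[, 1])
      cy <- qr.solve(X, centers[, 2])
      res <- sqrt((X %*% cx - centers[, 1])^2 + (X %*% cy - centers[, 2])^2)
      list(cx = cx, cy = cy, res = as.vector(res))
    }
    fit <- fit_axis(centers)
    good <- fit$res <= pmax(0.8, 2.5 * stats::median(fit$res))
    if (sum(good) >= 4 && any(!good)) {
      fit <- fit_axis(centers[good, , drop = FALSE])  # contaminated slices out
    }
    axis_xy <- c(fit$cx[1], fit$cy[1])   # position at the bead's height
    slope <- c(fit$cx[2], fit$cy[2])     # tangent d(x,y)/dz there
    dirv <- c(slope, 1)
    dirv <- dirv / sqrt(sum(dirv^2))
    axis_pt <- c(axis_xy, m[3])
    r <- (m - axis_pt) - sum((m - axis_pt) * dirv) * dirv
    e1 <- c(1, 0, 0) - dirv[1] * dirv
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- vcross(dirv, e1)
    if (sqrt(sum(r^2)) < .Machine$double.eps) {
      stop("marker on midline: roll azimuth undefined")
    }
    atan2(sum(r * e2), sum(r * e1)) * 180 / pi
  }, numeric(1))
  angle_series(days = days, roll_deg = roll, unwrapped = FALSE, organ = "root_1")
}
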