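#' Bin a volume by block averaging
#'
#' Replaces non-overlapping `factor^3` voxel blocks by their mean. Output
#' extents are `floor(input / factor)` per axis; trailing remainder voxels
#' are dropped (and logged); the physical voxel size is multiplied by the
#' factor. Binning reduces data size and noise and speeds up processing;
#' the pipeline's default factor is 8.
#'
#' @param scan A [volume_scan()].
#' @param factor Positive integer binning factor (default 8).
#' @param log Optional run-log path.
#' @return The binned [volume_scan()].
#' @export
#' @examples
#' v <- volume_scan(array(runif(16^3), c(16, 16, 16)))
#' dim(bin_volume(v, 8))  # 2 2 2
bin_volume <- function(scan, factor = 8, log = NULL) {
  stopifnot(inherits(scan, "volume_scan"))
  factor <- as.integer(factor)
  if (factor < 1) {
    stop("bin factor must be a positive integer")
  }
  d <- dim(scan$intensities)
  if (any(factor > d)) {
    stop("bin factor too large: ", factor, " exceeds grid extents ",
         paste(d, collapse = "x"))
  }
  if (factor == 1L) {
    return(scan)
  }
  if (any(d %% factor != 0)) {
    run_log(log, "bin_volume: dropped remainder voxels ",
            paste(d %% factor, collapse = "x"), " (extents ",
            paste(d, collapse = "x"), ", factor ", factor, ")")
  }
  scan$intensities <- bin_array(scan$intensities, factor)
  scan$voxel_size <- scan$voxel_size * factor
  scan
}

bin_array <- function(vol, factor) {
  d <- dim(vol)
  out_d <- d %/% factor
  vol <- vol[seq_len(out_d[1] * factor), seq_len(out_d[2] * factor),
             seq_len(out_d[3] * factor), drop = FALSE]
  dim(vol) <- c(factor, out_d[1], factor, out_d[2], factor, out_d[3])
  vol <- aperm(vol, c(1, 3, 5, 2, 4, 6))
  dim(vol) <- c(factor^3, prod(out_d))
  array(colMeans(vol), out_d)
}

# Integer-shift estimate via FFT cross-correlation of zero-mean volumes,
# with per-axis quadratic sub-voxel refinement of the correlation peak.
# `fixed_fft` may carry fft(fixed - mean(fixed)) precomputed.
xcorr_shift <- function(fixed, moving, fixed_fft = NULL) {
  d <- dim(fixed)
  f <- fixed - mean(fixed)
  m <- moving - mean(moving)
  if (is.null(fixed_fft)) fixed_fft <- fft(f)
  cc <- Re(fft(fixed_fft * Conj(fft(m)), inverse = TRUE)) / length(f)
  peak <- which.max(cc)
  idx <- arrayInd(peak, d) - 1L
  shift <- ifelse(idx > d / 2, idx - d, idx)
  wrap <- function(i, n) ((i %% n) + n) %% n + 1L
  sub <- numeric(3)
  for (ax in 1:3) {
    at <- function(off) {
      ijk <- idx
      ijk[ax] <- ijk[ax] + off
      cc[matrix(wrap(ijk, d), 1)]
    }
    c0 <- at(0L); cm <- at(-1L); cp <- at(1L)
    den <- cm - 2 * c0 + cp
    sub[ax] <- if (abs(den) > .Machine$double.eps) {
      max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
    } else 0
  }
  norm <- sqrt(sum(f^2) * sum(m^2))
  list(shift = shift + sub, corr = if (norm > 0) cc[peak] / norm else 0)
}

# 3x3x3 box prefilter (edge-replicated): averages out reconstruction noise
# before the registration metric is evaluated; applied to both volumes, so
# the comparison stays symmetric.
box_smooth <- function(v) {
  d <- dim(v)
  v <- (v[c(1, 1:(d[1] - 1)), , ] + v + v[c(2:d[1], d[1]), , ]) / 3
  v <- (v[, c(1, 1:(d[2] - 1)), ] + v + v[, c(2:d[2], d[2]), ]) / 3
  (v[, , c(1, 1:(d[3] - 1))] + v + v[, , c(2:d[3], d[3])]) / 3
}

#' Rigidly register one volume to another
#'
#' Finds the [rigid_transform()] maximizing normalized cross-correlation
#' between `fixed` and the transformed `moving`, at full resolution
#' throughout. One global spectral (FFT) cross-correlation at the
#' initialization provides a translation baseline; the rotation about the
#' vertical (z) axis is then searched by warm-started profile scans (each
#' angle candidate receives a short translation polish seeded from its
#' neighbor): a coarse 5-degree scan over the full range and a 0.5-degree
#' scan on box-smoothed copies of both volumes settle the basin, and a
#' 0.25-degree scan plus a joint Nelder-Mead pass on the raw volumes
#' deliver sub-degree, sub-voxel precision. The metric is normalized
#' cross-correlation over the inscribed cylinder intersected with the
#' in-bounds footprint of the candidate, evaluated by trilinear sampling
#' at a fixed thinned subset of that support whose points carry a
#' deterministic low-discrepancy jitter off the voxel lattice
#' (milliseconds per candidate; the jitter averages away the one-voxel
#' interpolation ripple that otherwise splits the metric's peak). Repositioning of an upright specimen between scan sessions
#' is dominated by rotation about the vertical axis, so the global search
#' covers z; the out-of-plane (y, x) angles are refined locally around
#' the initialization.
#'
#' @param fixed,moving [volume_scan()] objects on identical grids
#'   (harmonize first).
#' @param init Search seed, a [rigid_transform()]; chaining the previous
#'   timepoint's result stabilizes sequence registration.
#' @param rot_range Half-width in degrees of the coarse z-rotation grid
#'   around `init` (default 25).
#' @param refine_all If `TRUE`, also refine the y and x Euler angles at full
#'   resolution (automatic when `init` carries nonzero y/x rotation).
#' @param prefilter Run the global search on 3x3x3 box-smoothed copies of
#'   both volumes (default), which keeps interpolation blur from biasing
#'   the candidate comparison; the final local refinement and the reported
#'   score always use the unfiltered volumes.
#' @param log Optional run-log path.
#' @return A [rigid_transform()] with its `score` set to the exact
#'   normalized cross-correlation at the optimum.
#' @export
register_pair <- function(fixed, moving, init = rigid_transform(),
                          rot_range = 25, refine_all = FALSE,
                          prefilter = TRUE, log = NULL) {
  stopifnot(inherits(fixed, "volume_scan"), inherits(moving, "volume_scan"))
  if (!all(dim(fixed$intensities) == dim(moving$intensities))) {
    stop("harmonize first: fixed and moving grids differ (",
         paste(dim(fixed$intensities), collapse = "x"), " vs ",
         paste(dim(moving$intensities), collapse = "x"), ")")
  }
  if (all(fixed$intensities == 0) || all(moving$intensities == 0)) {
    stop("empty volume: registration metric undefined")
  }
  refine_all <- refine_all || any(init$rotation[2:3] != 0)
  rot <- init$rotation

  # restrict the metric to the inscribed cylinder: its support is invariant
  # under rotation about z, so rotated candidates are not penalized by the
  # zero-filled corners that resampling introduces
  cyl_mask <- function(d) {
    r <- min(d[1], d[2]) / 2 - 0.5
    cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2
    m2 <- outer(0:(d[1] - 1), 0:(d[2] - 1),
                function(x, y) (x - cx)^2 + (y - cy)^2 <= r^2)
    array(rep(m2, d[3]), d)
  }

  # Metric: normalized cross-correlation restricted to the inscribed
  # cylinder intersected with the in-bounds footprint of the resampled
  # candidate (zero-filled samples of content that left the grid would
  # otherwise bias the metric, and interpolation smoothing affects every
  # resampled candidate alike).
  mask1 <- cyl_mask(dim(fixed$intensities))
  mask1_idx <- which(mask1 == 1)
  # Global search runs on box-smoothed volumes: trilinear resampling blurs
  # each candidate by an amount that depends on its rotation and the
  # fractional part of its translation, and on sharp data that
  # inconsistency can outvote the true alignment (an unrotated candidate
  # with a near-integer shift is evaluated nearly blur-free). Smoothing
  # both volumes makes the interpolation blur negligible relative to the
  # data's intrinsic scale, so candidates compete on alignment alone. The
  # final local refinement then runs on the raw volumes for precision.
  m1_raw <- moving$intensities
  f_raw <- fixed$intensities
  m1 <- if (prefilter) box_smooth(moving$intensities) else m1_raw
  f_smooth <- if (prefilter) box_smooth(fixed$intensities) else f_raw
  f1_raw <- f_raw * mask1
  f1 <- f_smooth * mask1
  f1_fft <- fft(f1 - mean(f1))
  masked_ncc <- function(aligned) {
    idx <- which(attr(aligned, "valid") & mask1 == 1)
    cor(f1_raw[idx], aligned[idx])
  }
  ncc_at <- function(rotation, tr) {
    masked_ncc(resample_rigid(m1_raw, rotation, tr, with_valid = TRUE))
  }
  ctr <- (dim(m1) - 1) / 2
  # Sample points carry a fixed low-discrepancy jitter off the voxel
  # lattice, and the fixed volume is interpolated at them once. On-lattice
  # sampling makes every point share one fractional phase, which imprints
  # a one-voxel scallop on the metric and splits its peak into near-equal
  # modes; jittered sampling averages the phases out. The jitter is
  # deterministic (no RNG), so results are bit-reproducible.
  make_ncc_sub <- function(thin, vol_f, vol_m) {
    idx <- mask1_idx[seq(1, length(mask1_idx), by = thin)]
    ijk <- arrayInd(idx, dim(vol_m)) - 1
    n <- nrow(ijk)
    jit <- cbind(
      (seq_len(n) * 0.7548776662466927) %% 1,
      (seq_len(n) * 0.5698402909980532) %% 1,
      (seq_len(n) * 0.4301597090019468) %% 1
    ) - 0.5
    pts <- ijk + jit
    fs <- trilinear_points(vol_f, pts[, 1], pts[, 2], pts[, 3])
    keep <- fs$valid
    pts <- pts[keep, , drop = FALSE]
    fv <- fs$values[keep]
    function(rotation, tr) {
      A <- t(euler_to_matrix(rotation))
      px <- pts[, 1] - ctr[1] - tr[1]
      py <- pts[, 2] - ctr[2] - tr[2]
      pz <- pts[, 3] - ctr[3] - tr[3]
      s <- trilinear_points(
        vol_m,
        A[1, 1] * px + A[1, 2] * py + A[1, 3] * pz + ctr[1],
        A[2, 1] * px + A[2, 2] * py + A[2, 3] * pz + ctr[2],
        A[3, 1] * px + A[3, 2] * py + A[3, 3] * pz + ctr[3]
      )
      if (sum(s$valid) < 100) return(-1)
      cor(fv[s$valid], s$values[s$valid])
    }
  }
  ncc_sub <- make_ncc_sub(10L, f_smooth, m1)

  # Translation baseline: one global spectral cross-correlation at the
  # initialization rotation. Rotating the volume changes the optimal
  # translation only smoothly, so the profile scans below re-polish the
  # translation per rotation candidate from this warm start.
  rotated <- resample_rigid(m1, rot, c(0, 0, 0)) * mask1
  shift <- xcorr_shift(f1, rotated, fixed_fft = f1_fft)$shift

  # All further search runs on subsampled NCC evaluations (milliseconds
  # each): a per-axis integer scan escapes the one-voxel scallops that
  # trilinear interpolation imprints on the metric, profile scans over
  # the z rotation give each angle candidate its own short translation
  # polish warm-started from its neighbor (rotation about the grid
  # center and in-plane translation form a shallow ridge that
  # coordinate-wise refinement cannot climb), and a Nelder-Mead pass
  # fine-tunes rotation and translation jointly. The chain runs first on
  # the smoothed volumes (coarse 5-degree grid over the full range, then
  # a half-degree scan) to settle the basin, then on the raw volumes for
  # full precision.
  quad_polish <- function(metric, rotation, shift, ref, h = 0.35, passes = 2,
                          axes = 1:3) {
    for (pass in seq_len(passes)) {
      for (ax in axes) {
        tp <- shift; tp[ax] <- shift[ax] + h; cp <- metric(rotation, tp)
        tm <- shift; tm[ax] <- shift[ax] - h; cm <- metric(rotation, tm)
        den <- cm - 2 * ref + cp
        cand <- shift
        if (den < 0) {
          cand[ax] <- shift[ax] + max(-2 * h, min(2 * h, 0.5 * h * (cm - cp) / den))
        } else {
          cand[ax] <- shift[ax] + ifelse(cp >= cm, h, -h)
        }
        cc <- metric(rotation, cand)
        if (cc > ref) {
          shift <- cand; ref <- cc
        } else if (cp > ref) {
          shift <- tp; ref <- cp
        } else if (cm > ref) {
          shift <- tm; ref <- cm
        }
      }
    }
    list(shift = shift, ref = ref)
  }

  profile_scan <- function(metric, rot, shift, offsets, passes = 1) {
    best <- list(rz = rot[1], shift = shift, ref = metric(rot, shift))
    warm <- shift
    for (drz in offsets) {
      cand_rot <- c(rot[1] + drz, rot[2], rot[3])
      st <- quad_polish(metric, cand_rot, warm, metric(cand_rot, warm),
                        passes = passes, axes = 1:2)
      st <- quad_polish(metric, cand_rot, st$shift, st$ref, passes = 1, axes = 3)
      warm <- st$shift
      if (st$ref > best$ref) {
        best <- list(rz = rot[1] + drz, shift = st$shift, ref = st$ref)
      }
    }
    best
  }

  int_scan <- function(metric, rot, shift, steps) {
    ref <- metric(rot, shift)
    for (ax in 1:3) {
      for (dlt in steps) {
        cand <- shift; cand[ax] <- shift[ax] + dlt
        cc <- metric(rot, cand)
        if (cc > ref) { shift <- cand; ref <- cc }
      }
    }
    shift
  }

  run_nm <- function(metric, rot, shift, ref, maxit) {
    par0 <- c(rot[1], shift, if (refine_all) rot[2:3])
    obj <- function(p) {
      rotation <- c(p[1], if (refine_all) p[5:6] else rot[2:3])
      -metric(rotation, p[2:4])
    }
    nm <- optim(par0, obj, method = "Nelder-Mead",
                control = list(maxit = maxit, reltol = 1e-9))
    if (-nm$value > ref) {
      rot[1] <- nm$par[1]
      shift <- nm$par[2:4]
      if (refine_all) rot[2:3] <- nm$par[5:6]
    }
    list(rot = rot, shift = shift)
  }

  # basin stage (smoothed volumes); the coarse scan runs in both
  # directions, since the warm start is path dependent across 5-degree
  # jumps
  shift <- int_scan(ncc_sub, rot, shift, c(-2, -1, 1, 2))
  st_a <- profile_scan(ncc_sub, rot, shift,
                       seq(-rot_range, rot_range, by = 5), passes = 2)
  st_b <- profile_scan(ncc_sub, rot, shift,
                       seq(rot_range, -rot_range, by = -5), passes = 2)
  st <- if (st_a$ref >= st_b$ref) st_a else st_b
  rot[1] <- st$rz; shift <- st$shift
  st <- profile_scan(ncc_sub, rot, shift, seq(-3, 3, by = 0.5))
  rot[1] <- st$rz; shift <- st$shift

  # precision stage (raw volumes)
  ncc_raw <- make_ncc_sub(6L, f_raw, m1_raw)
  shift <- int_scan(ncc_raw, rot, shift, c(-1, -0.5, 0.5, 1))
  st <- profile_scan(ncc_raw, rot, shift, seq(-2, 2, by = 0.25), passes = 2)
  rot[1] <- st$rz; shift <- st$shift
  st2 <- run_nm(ncc_raw, rot, shift, st$ref, maxit = 150)
  rot <- st2$rot; shift <- st2$shift

  best <- ncc_at(rot, shift)
  result <- rigid_transform(rotation = rot, translation = shift, score = best)
  run_log(log, "register_pair: rot (z,y,x) ",
          paste(signif(rot, 5), collapse = ", "), " deg, shift ",
          paste(signif(shift, 5), collapse = ", "), " vox, score ",
          signif(result$score, 6))
  result
}

#' Register every timepoint to the first scan's frame
#'
#' The first timepoint defines the reference frame (all-to-first rather than
#' pairwise chaining of resampled volumes, which accumulates drift); each
#' subsequent timepoint is registered directly to the reference, with the
#' search seeded at the previous timepoint's transform — growth between
#' adjacent scan sessions is small, so chaining the initialization
#' stabilizes the search while resampling never chains.
#'
#' @param seq A harmonized [scan_sequence()].
#' @param ... Passed to [register_pair()].
#' @param log Optional run-log path.
#' @return List of [rigid_transform()], one per scan; the first is identity
#'   with score 1.
#' @export
register_sequence <- function(seq, ..., log = NULL) {
  stopifnot(inherits(seq, "scan_sequence"))
  if (!seq$uniform_grid) {
    stop("harmonize first: scan grids are not uniform")
  }
  n <- length(seq$scans)
  out <- vector("list", n)
  out[[1]] <- rigid_transform(score = 1)
  if (n == 1) {
    return(out)
  }
  prev <- rigid_transform()
  for (i in 2:n) {
    out[[i]] <- register_pair(seq$scans[[1]], seq$scans[[i]], init = prev, ..., log = log)
    prev <- out[[i]]
    run_log(log, "register_sequence: timepoint ", i - 1, " score ",
            signif(out[[i]]$score, 6))
  }
  out
}

#' Tidy a list of rigid transforms
#'
#' @param transforms List of [rigid_transform()] as returned by
#'   [register_sequence()].
#' @return A tibble with one row per timepoint: Euler angles (degrees),
#'   translations (voxels) and the alignment score.
#' @export
transforms_tibble <- function(transforms) {
  tibble::tibble(
    timepoint = seq_along(transforms) - 1L,
    rot_z_deg = vapply(transforms, function(t) t$rotation[1], numeric(1)),
    rot_y_deg = vapply(transforms, function(t) t$rotation[2], numeric(1)),
    rot_x_deg = vapply(transforms, function(t) t$rotation[3], numeric(1)),
    shift_x_vox = vapply(transforms, function(t) t$translation[1], numeric(1)),
    shift_y_vox = vapply(transforms, function(t) t$translation[2], numeric(1)),
    shift_z_vox = vapply(transforms, function(t) t$translation[3], numeric(1)),
    score = vapply(transforms, function(t) t$score, numeric(1))
  )
}
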