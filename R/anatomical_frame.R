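## Rigid-body poses and the cranium-bound anatomical coordinate system (ACS).
## The ACS origin sits at the caudal tip of the chewing pad (midsagittal),
## approximating the esophagus entrance; x points anteriorly (parallel to the
## pharyngeal-process plate), y dorsally, z to the animal's right.

#' Least-squares rigid pose from labelled point correspondences
#'
#' Kabsch/Procrustes fit of a proper rotation and translation mapping
#' `reference_points` onto `observed_points`. Correspondences are matched by
#' row name when both matrices are labelled; rows with missing coordinates on
#' either side are dropped. Reflections are rejected.
#'
#' @param reference_points n-by-3 matrix (bone-model coordinates, mm).
#' @param observed_points n-by-3 matrix (world coordinates, mm).
#' @param frame optional integer frame index carried on the result (and in
#'   error messages).
#' @return a list of class `rigid_pose`: `rotation` (3x3, det +1),
#'   `translation` (length 3), `rmsd` (mm), `frame`. The pose maps reference
#'   to observed: `obs ~ R %*% ref + t`.
#' @export
fit_rigid_pose <- function(reference_points, observed_points, frame = NA_integer_) {
  ref <- as.matrix(reference_points)
  obs <- as.matrix(observed_points)
  if (!is.null(rownames(ref)) && !is.null(rownames(obs))) {
    common <- intersect(rownames(ref), rownames(obs))
    ref <- ref[common, , drop = FALSE]
    obs <- obs[common, , drop = FALSE]
  }
  if (nrow(ref) != nrow(obs)) stop("correspondence count mismatch")
  ok <- stats::complete.cases(ref) & stats::complete.cases(obs)
  ref <- ref[ok, , drop = FALSE]
  obs <- obs[ok, , drop = FALSE]
  if (nrow(ref) < 3) {
    stop(sprintf("degenerate frame %s: %d usable correspondences (need >= 3)",
                 as.character(frame), nrow(ref)))
  }
  cr <- colMeans(ref)
  co <- colMeans(obs)
  refc <- sweep(ref, 2, cr)
  obsc <- sweep(obs, 2, co)
  sv_ref <- svd(refc)$d
  if (sv_ref[2] <= 1e-9 * max(sv_ref[1], 1)) {
    stop(sprintf("degenerate frame %s: collinear marker configuration",
                 as.character(frame)))
  }
  H <- t(refc) %*% obsc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- co - as.vector(R %*% cr)
  fitted <- sweep(ref %*% t(R), 2, tr, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - obs)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd, frame = frame),
            class = "rigid_pose")
}

#' Per-frame rigid poses of a marker set
#'
#' Fits [fit_rigid_pose()] at every frame of a trajectory set for the named
#' markers. Frames with fewer than three visible markers (or a collinear
#' configuration) are marked pose-missing rather than extrapolated.
#'
#' @param ts a [trajectory_set()] in world frame.
#' @param marker_names tracks used for the fit (e.g. the four neurocranium
#'   markers).
#' @param reference n-by-3 matrix of the same markers in bone-model
#'   coordinates, rownames matching `marker_names`.
#' @return a list of class `pose_series`: `frames`, `rotation` (3x3xN array),
#'   `translation` (N-by-3), `rmsd`, `valid` (logical).
#' @export
fit_pose_series <- function(ts, marker_names, reference) {
  stopifnot(inherits(ts, "trajectory_set"))
  if (!all(marker_names %in% names(ts$points))) {
    stop("unknown marker track(s): ",
         paste(setdiff(marker_names, names(ts$points)), collapse = ", "))
  }
  reference <- as.matrix(reference)
  if (nrow(reference) != length(marker_names)) {
    stop("reference must have one row per marker")
  }
  rownames(reference) <- marker_names    # rows are positional
  nfr <- n_frames(ts)
  rot <- array(NA_real_, c(3, 3, nfr))
  trans <- matrix(NA_real_, nfr, 3)
  rmsd <- rep(NA_real_, nfr)
  valid <- logical(nfr)
  for (f in seq_len(nfr)) {
    obs <- t(vapply(marker_names, function(nm) ts$points[[nm]][f, ], numeric(3)))
    rownames(obs) <- marker_names
    pose <- tryCatch(
      fit_rigid_pose(reference, obs, frame = ts$frame_index[f]),
      error = function(e) NULL)
    if (!is.null(pose)) {
      rot[, , f] <- pose$rotation
      trans[f, ] <- pose$translation
      rmsd[f] <- pose$rmsd
      valid[f] <- TRUE
    }
  }
  structure(list(frames = ts$frame_index, rotation = rot, translation = trans,
                 rmsd = rmsd, valid = valid), class = "pose_series")
}

#' Anatomical landmarks defining the ACS in bone-model space
#'
#' @param origin 3-vector: caudal tip of the chewing pad, midsagittal
#'   (approximates the esophagus entrance).
#' @param x_axis_pair 2-by-3 matrix: two points on a line parallel to the
#'   pharyngeal-process plate; the direction from row 1 to row 2 points
#'   anteriorly.
#' @param y_hint 3-vector: a point dorsal to `origin` on the midsagittal
#'   plane, fixing the dorsal direction.
#' @return a list of class `anatomical_landmarks`.
#' @export
anatomical_landmarks <- function(origin, x_axis_pair, y_hint) {
  origin <- as.numeric(origin)
  x_axis_pair <- as.matrix(x_axis_pair)
  y_hint <- as.numeric(y_hint)
  stopifnot(length(origin) == 3, all(dim(x_axis_pair) == c(2, 3)),
            length(y_hint) == 3)
  dx <- x_axis_pair[2, ] - x_axis_pair[1, ]
  if (sqrt(sum(dx^2)) < 1e-12) stop("x_axis_pair points coincide")
  dy <- y_hint - origin
  cr <- cross3(dx, dy)
  if (sqrt(sum(cr^2)) < 1e-9 * sqrt(sum(dx^2)) * sqrt(sum(dy^2))) {
    stop("y_hint is collinear with the x axis")
  }
  structure(list(origin = origin, x_axis_pair = x_axis_pair, y_hint = y_hint),
            class = "anatomical_landmarks")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' ACS basis in bone-model coordinates
#'
#' Orthonormalises the landmark directions: unit x along the `x_axis_pair`
#' line (anterior positive), unit y the component of the dorsal hint
#' orthogonal to x (Gram-Schmidt), unit z = x cross y (right positive).
#'
#' @param landmarks an [anatomical_landmarks()].
#' @return 3x3 matrix with columns (x, y, z); right-handed, det +1.
#' @export
acs_basis <- function(landmarks) {
  stopifnot(inherits(landmarks, "anatomical_landmarks"))
  x <- landmarks$x_axis_pair[2, ] - landmarks$x_axis_pair[1, ]
  x <- x / sqrt(sum(x^2))
  yd <- landmarks$y_hint - landmarks$origin
  y <- yd - sum(yd * x) * x
  y <- y / sqrt(sum(y^2))
  z <- cross3(x, y)
  cbind(x = x, y = y, z = z)
}

#' Build the per-frame anatomical coordinate system
#'
#' Composes the neurocranium rigid poses with the fixed landmark-defined ACS
#' so that the ACS is cranium-fixed: its world origin and axes move rigidly
#' with the skull.
#'
#' @param neuro_poses a `pose_series` from [fit_pose_series()] (bone-model to
#'   world).
#' @param landmarks an [anatomical_landmarks()] in bone-model coordinates.
#' @return a list of class `frame_series`: `frames`, `axes` (3x3xN, columns
#'   x/y/z in world coordinates), `origin` (N-by-3, mm, world), `valid`.
#' @export
build_acs <- function(neuro_poses, landmarks) {
  stopifnot(inherits(neuro_poses, "pose_series"))
  A <- acs_basis(landmarks)
  nfr <- length(neuro_poses$frames)
  axes <- array(NA_real_, c(3, 3, nfr))
  origin <- matrix(NA_real_, nfr, 3)
  for (f in seq_len(nfr)) {
    if (!neuro_poses$valid[f]) next
    R <- neuro_poses$rotation[, , f]
    axes[, , f] <- R %*% A
    origin[f, ] <- as.vector(R %*% landmarks$origin) + neuro_poses$translation[f, ]
  }
  structure(list(frames = neuro_poses$frames, axes = axes, origin = origin,
                 valid = neuro_poses$valid), class = "frame_series")
}

#' Re-express trajectories in the anatomical frame
#'
#' Every point is re-expressed in the per-frame ACS: a point coincident with
#' the origin landmark maps to (0,0,0). Frames whose ACS pose is missing
#' become missing samples.
#'
#' @param ts a [trajectory_set()] in world frame.
#' @param acs a `frame_series` from [build_acs()] with matching frames.
#' @return a `trajectory_set` with `coordinate_frame = "anatomical"`.
#' @export
to_anatomical <- function(ts, acs) {
  stopifnot(inherits(ts, "trajectory_set"), inherits(acs, "frame_series"))
  if (ts$coordinate_frame != "world") stop("trajectory set is not in world frame")
  if (!identical(as.integer(ts$frame_index), as.integer(acs$frames))) {
    stop("frame range mismatch between trajectory set and ACS")
  }
  nfr <- n_frames(ts)
  pts <- lapply(ts$points, function(p) {
    out <- matrix(NA_real_, nfr, 3)
    for (f in seq_len(nfr)) {
      if (!acs$valid[f] || is.na(p[f, 1])) next
      out[f, ] <- as.vector(t(acs$axes[, , f]) %*% (p[f, ] - acs$origin[f, ]))
    }
    out
  })
  trajectory_set(pts, frame_rate = ts$frame_rate, track_kind = ts$track_kind,
                 frame_index = ts$frame_index, coordinate_frame = "anatomical")
}

#' Map anatomical-frame trajectories back to the world frame
#'
#' Inverse of [to_anatomical()].
#'
#' @param ts a `trajectory_set` with `coordinate_frame = "anatomical"`.
#' @param acs the `frame_series` used for the forward transform.
#' @return a world-frame `trajectory_set`.
#' @export
to_world <- function(ts, acs) {
  stopifnot(inherits(ts, "trajectory_set"), inherits(acs, "frame_series"))
  if (ts$coordinate_frame != "anatomical") {
    stop("trajectory set is not in anatomical frame")
  }
  if (!identical(as.integer(ts$frame_index), as.integer(acs$frames))) {
    stop("frame range mismatch between trajectory set and ACS")
  }
  nfr <- n_frames(ts)
  pts <- lapply(ts$points, function(p) {
    out <- matrix(NA_real_, nfr, 3)
    for (f in seq_len(nfr)) {
      if (!acs$valid[f] || is.na(p[f, 1])) next
      out[f, ] <- as.vector(acs$axes[, , f] %*% p[f, ]) + acs$origin[f, ]
    }
    out
  })
  trajectory_set(pts, frame_rate = ts$frame_rate, track_kind = ts$track_kind,
                 frame_index = ts$frame_index, coordinate_frame = "world")
}

#' World-to-anatomical conversion in one call
#'
#' Convenience wrapper: fits the neurocranium pose at every frame, builds the
#' cranium-fixed ACS and re-expresses all tracks in it.
#'
#' @param ts world-frame [trajectory_set()].
#' @param marker_names neurocranium marker track names.
#' @param reference bone-model coordinates of those markers.
#' @param landmarks an [anatomical_landmarks()].
#' @param marker_cutoff low-pass cutoff (Hz) applied to the marker
#'   trajectories before pose fitting (default 25). Skull motion is far
#'   slower than the frame rate, and unsmoothed +/-0.1 mm marker noise turns
#'   into milliradian pose jitter that contaminates every re-expressed
#'   trajectory as common-mode noise. `Inf` disables.
#' @return a list: `anatomical` (the converted `trajectory_set`), `acs`
#'   (`frame_series`), `poses` (`pose_series`).
#' @export
anatomical_transform <- function(ts, marker_names, reference, landmarks,
                                 marker_cutoff = 25) {
  if (!all(marker_names %in% names(ts$points))) {
    stop("unknown marker track(s): ",
         paste(setdiff(marker_names, names(ts$points)), collapse = ", "))
  }
  ts_fit <- ts
  if (is.finite(marker_cutoff)) {
    for (nm in marker_names) {
      ts_fit$points[[nm]] <- smooth_positions(ts_fit$points[[nm]],
                                              ts$frame_rate, marker_cutoff)
    }
  }
  poses <- fit_pose_series(ts_fit, marker_names, reference)
  acs <- build_acs(poses, landmarks)
  list(anatomical = to_anatomical(ts, acs), acs = acs, poses = poses)
}
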