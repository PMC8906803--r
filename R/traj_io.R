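TRACK_KINDS <- c("bone_marker", "locator", "water_tracer", "food_tracer")

#' Construct a trajectory set
#'
#' A `trajectory_set` holds named per-frame 3D point series (bone markers,
#' anatomical locators, water tracers, food tracers) sampled at a common frame
#' rate. Positions are stored in millimetres; a missing sample is an explicit
#' `NA` row, never a zero (zero is a legal coordinate: the esophagus-entrance
#' origin of the anatomical frame).
#'
#' @param points named list of numeric n-by-3 matrices (mm), one per track;
#'   all tracks must span the same frames. `NA` marks missing samples.
#' @param frame_rate frames per second (default 750, the X-ray video rate).
#' @param track_kind named character vector mapping each track to one of
#'   `"bone_marker"`, `"locator"`, `"water_tracer"`, `"food_tracer"`. Missing
#'   entries are guessed from the track name (see [guess_track_kind()]).
#' @param frame_index integer frame numbers (default `1:n`).
#' @param coordinate_frame `"world"` or `"anatomical"`.
#' @return an object of class `trajectory_set`.
#' @export
trajectory_set <- function(points, frame_rate = 750, track_kind = NULL,
                           frame_index = NULL, coordinate_frame = "world") {
  stopifnot(is.list(points))
  if (length(points) > 0 && is.null(names(points))) {
    stop("tracks must be named")
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0) {
    stop("frame_rate must be a single positive number")
  }
  coordinate_frame <- match.arg(coordinate_frame, c("world", "anatomical"))
  points <- lapply(points, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 3) stop("each track must be an n-by-3 matrix")
    storage.mode(p) <- "double"
    colnames(p) <- c("x", "y", "z")
    # a sample with any missing axis is wholly missing
    p[!stats::complete.cases(p), ] <- NA_real_
    p
  })
  nf <- unique(vapply(points, nrow, integer(1)))
  if (length(nf) > 1) stop("all tracks must share the same frame range")
  if (length(nf) == 0) nf <- 0L
  if (is.null(frame_index)) frame_index <- seq_len(nf)
  if (length(frame_index) != nf) stop("frame_index length must equal frame count")
  bad <- vapply(points, function(p) any(is.infinite(p)), logical(1))
  if (any(bad)) {
    stop("non-finite positions in track(s): ", paste(names(points)[bad], collapse = ", "))
  }
  kinds <- stats::setNames(rep(NA_character_, length(points)), names(points))
  if (!is.null(track_kind)) kinds[names(track_kind)] <- unname(track_kind)
  miss <- is.na(kinds)
  kinds[miss] <- guess_track_kind(names(kinds)[miss])
  if (!all(kinds %in% TRACK_KINDS)) {
    stop("track_kind values must be one of: ", paste(TRACK_KINDS, collapse = ", "))
  }
  structure(
    list(frame_rate = frame_rate, frame_index = as.integer(frame_index),
         points = points, track_kind = kinds,
         coordinate_frame = coordinate_frame, units = "mm"),
    class = "trajectory_set")
}

#' Guess a track's kind from its name
#'
#' Heuristic used when no explicit kind map is supplied: names containing
#' "water" are water tracers, "food" food tracers, jaw/hyoid/operculum names
#' are locators, anything else is a bone marker.
#'
#' @param name character vector of track names.
#' @return character vector of kinds.
#' @export
guess_track_kind <- function(name) {
  kind <- rep("bone_marker", length(name))
  kind[grepl("water", name, ignore.case = TRUE)] <- "water_tracer"
  kind[grepl("food", name, ignore.case = TRUE)] <- "food_tracer"
  kind[grepl("jaw|hyoid|operc|loc", name, ignore.case = TRUE)] <- "locator"
  kind
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d tracks x %d frames @ %g fps [%s frame]\n",
              length(x$points), length(x$frame_index), x$frame_rate,
              x$coordinate_frame))
  if (length(x$points)) {
    tab <- table(x$track_kind)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of frames in a trajectory set
#' @param ts a `trajectory_set`.
#' @return integer frame count.
#' @export
n_frames <- function(ts) length(ts$frame_index)

#' Time axis of a trajectory set
#' @param ts a `trajectory_set`.
#' @return numeric vector of times in seconds (first frame at 0).
#' @export
time_axis <- function(ts) {
  (ts$frame_index - ts$frame_index[1]) / ts$frame_rate
}

#' Select tracks of a given kind
#' @param ts a `trajectory_set`.
#' @param kind one of the track kinds.
#' @return named list of position matrices.
#' @export
tracks_of_kind <- function(ts, kind) {
  kind <- match.arg(kind, TRACK_KINDS)
  ts$points[names(ts$track_kind)[ts$track_kind == kind]]
}

## ---------------------------------------------------------------------------
## unit converters: one canonical store (mm, s); velocities printed in cm/s

#' Unit converters
#'
#' Positions are stored in mm and time in seconds; velocities are reported in
#' cm/s to match the conventions of the suction-feeding literature. These
#' helpers centralise the conversions.
#' @param x numeric vector.
#' @return numeric vector in the target unit.
#' @export
mm_per_s_to_cm_per_s <- function(x) x / 10

#' @rdname mm_per_s_to_cm_per_s
#' @export
cm_per_s_to_mm_per_s <- function(x) x * 10

#' @rdname mm_per_s_to_cm_per_s
#' @export
mm_to_m <- function(x) x / 1000

#' @rdname mm_per_s_to_cm_per_s
#' @export
m_to_mm <- function(x) x * 1000

## ---------------------------------------------------------------------------
## reading / writing

#' Read 3D point trajectories
#'
#' Reads a per-frame 3D trajectory table in the `xmalab_3d` dialect: one row
#' per frame, per-track column triplets named `<track>_X`, `<track>_Y`,
#' `<track>_Z`, blank cells marking missing samples. An optional leading
#' comment block (lines starting with `#`) may carry `frame_rate`,
#' `coordinate_frame` and a `kind:` map; files written by
#' [write_trajectories()] round-trip all metadata through it. The `generic`
#' dialect is identical but keeps unrecognised track names as bone markers
#' instead of guessing.
#'
#' @param path CSV file path.
#' @param dialect `"xmalab_3d"` (default) or `"generic"`.
#' @param frame_rate fallback frame rate if the file carries none.
#' @return a [trajectory_set()].
#' @export
read_trajectories <- function(path, dialect = c("xmalab_3d", "generic"),
                              frame_rate = 750) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    stop("empty input file: ", path)
  }
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0) stop("empty input file (no header row): ", path)

  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([a-z_]+)\\s*:\\s*(.*)$", ml))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  if (!is.null(meta$frame_rate)) frame_rate <- as.numeric(meta$frame_rate)
  coordinate_frame <- if (!is.null(meta$coordinate_frame)) {
    meta$coordinate_frame
  } else "world"

  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  ncol_expected <- length(header)
  has_frame_col <- tolower(header[1]) %in% c("frame", "frame_index")
  coord_cols <- if (has_frame_col) header[-1] else header
  if (length(coord_cols) %% 3 != 0) {
    stop("malformed header: coordinate columns not in X/Y/Z triplets")
  }
  suffix <- sub("^.*_", "", coord_cols)
  base <- sub("_[XYZxyz]$", "", coord_cols)
  ok_triplet <- function(i) {
    idx <- (3 * (i - 1) + 1):(3 * i)
    length(unique(base[idx])) == 1 &&
      identical(toupper(suffix[idx]), c("X", "Y", "Z"))
  }
  n_tracks <- length(coord_cols) / 3
  for (i in seq_len(n_tracks)) {
    if (!ok_triplet(i)) {
      stop("malformed header near column '", coord_cols[3 * (i - 1) + 1],
           "': expected <track>_X,<track>_Y,<track>_Z triplets")
    }
  }
  track_names <- base[3 * seq_len(n_tracks) - 2]
  if (anyDuplicated(track_names)) {
    stop("malformed header: duplicated track '",
         track_names[duplicated(track_names)][1], "'")
  }

  data_lines <- body[-1]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  nfr <- length(data_lines)
  vals <- matrix(NA_real_, nrow = nfr, ncol = ncol_expected)
  for (r in seq_len(nfr)) {
    cells <- strsplit(data_lines[r], ",", fixed = TRUE)[[1]]
    # a trailing blank cell is dropped by strsplit; pad
    if (length(cells) < ncol_expected &&
        grepl(",$", data_lines[r])) {
      cells <- c(cells, rep("", ncol_expected - length(cells)))
    }
    if (length(cells) != ncol_expected) {
      stop(sprintf("inconsistent row length at data row %d: %d cells, expected %d",
                   r, length(cells), ncol_expected))
    }
    cells <- trimws(cells)
    cells[cells == ""] <- NA
    suppressWarnings(vals[r, ] <- as.numeric(cells))
  }
  frame_index <- if (has_frame_col) as.integer(vals[, 1]) else seq_len(nfr)
  coords <- if (has_frame_col) vals[, -1, drop = FALSE] else vals

  points <- stats::setNames(vector("list", n_tracks), track_names)
  for (i in seq_len(n_tracks)) {
    points[[i]] <- coords[, (3 * (i - 1) + 1):(3 * i), drop = FALSE]
  }

  track_kind <- NULL
  if (!is.null(meta$kind)) {
    pairs <- strsplit(strsplit(meta$kind, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    track_kind <- stats::setNames(
      vapply(pairs, `[`, character(1), 2) |> trimws(),
      vapply(pairs, `[`, character(1), 1) |> trimws())
  } else if (dialect == "generic") {
    track_kind <- stats::setNames(rep("bone_marker", n_tracks), track_names)
  }
  trajectory_set(points, frame_rate = frame_rate, track_kind = track_kind,
                 frame_index = frame_index, coordinate_frame = coordinate_frame)
}

#' Write 3D point trajectories
#'
#' Writes the `xmalab_3d` CSV dialect with a metadata comment block so that
#' [read_trajectories()] round-trips positions, names, kinds, frame rate and
#' coordinate frame losslessly.
#'
#' @param ts a [trajectory_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ts, path) {
  stopifnot(inherits(ts, "trajectory_set"))
  con <- tryCatch(file(path, "w"), condition = function(e) {
    stop("cannot open for writing: ", path)
  })
  on.exit(close(con))
  writeLines(c(
    sprintf("# frame_rate: %.17g", ts$frame_rate),
    sprintf("# coordinate_frame: %s", ts$coordinate_frame),
    sprintf("# kind: %s",
            paste(sprintf("%s=%s", names(ts$track_kind), ts$track_kind),
                  collapse = ";"))), con)
  header <- c("Frame", unlist(lapply(names(ts$points), function(nm) {
    paste0(nm, c("_X", "_Y", "_Z"))
  })))
  writeLines(paste(header, collapse = ","), con)
  nfr <- n_frames(ts)
  if (nfr > 0) {
    coords <- do.call(cbind, c(list(ts$frame_index),
                               unname(ts$points[names(ts$points)])))
    txt <- apply(coords, 1, function(row) {
      cells <- sprintf("%.17g", row)
      cells[is.na(row)] <- ""
      cells[1] <- sprintf("%d", as.integer(row[1]))
      paste(cells, collapse = ",")
    })
    writeLines(txt, con)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## gap filling

#' Fill short tracking gaps by linear interpolation
#'
#' Interior runs of missing samples of length `<= max_gap` are replaced by
#' per-axis linear interpolation between the flanking observed samples; longer
#' runs and leading/trailing gaps are left missing. Observed samples are never
#' modified. An audit log of filled spans is attached as attribute
#' `"fill_log"` (data frame: track, start_frame, end_frame, length).
#'
#' @param ts a [trajectory_set()].
#' @param max_gap maximum gap length, in frames, that may be filled.
#' @return a new `trajectory_set` with gaps filled.
#' @export
fill_gaps <- function(ts, max_gap) {
  stopifnot(inherits(ts, "trajectory_set"), max_gap >= 0)
  log <- list()
  pts <- ts$points
  for (nm in names(pts)) {
    p <- pts[[nm]]
    miss <- is.na(p[, 1])
    if (!any(miss) || all(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      if (k == 1 || k == length(r$values)) next   # leading/trailing gap
      len <- r$lengths[k]
      if (len > max_gap) next
      i0 <- starts[k] - 1          # last observed before the gap
      i1 <- ends[k] + 1            # first observed after the gap
      w <- seq_len(len) / (len + 1)
      for (ax in 1:3) {
        p[starts[k]:ends[k], ax] <- p[i0, ax] + w * (p[i1, ax] - p[i0, ax])
      }
      log[[length(log) + 1]] <- data.frame(
        track = nm, start_frame = ts$frame_index[starts[k]],
        end_frame = ts$frame_index[ends[k]], length = len)
    }
    pts[[nm]] <- p
  }
  out <- trajectory_set(pts, frame_rate = ts$frame_rate,
                        track_kind = ts$track_kind,
                        frame_index = ts$frame_index,
                        coordinate_frame = ts$coordinate_frame)
  attr(out, "fill_log") <- if (length(log)) {
    do.call(rbind, log)
  } else {
    data.frame(track = character(), start_frame = integer(),
               end_frame = integer(), length = integer())
  }
  out
}

#' Fluid properties
#'
#' Density, dynamic viscosity and gravitational acceleration of the working
#' fluid. Defaults are water at 20 degrees C (viscosity 1.002 mPa s) with
#' g = 9.81 m/s^2.
#'
#' @param density kg/m^3.
#' @param dynamic_viscosity Pa s.
#' @param gravity m/s^2.
#' @return a list of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1000, dynamic_viscosity = 1.002e-3,
                             gravity = 9.81) {
  stopifnot(density > 0, dynamic_viscosity > 0, gravity > 0)
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity,
                 gravity = gravity), class = "fluid_properties")
}

#' Tracer specification
#'
#' Diameter and density of a spherical flow tracer. The default diameter,
#' 1.4 mm, is that of the brass-cored expanded-polystyrene tracers (rod plus
#' foam sphere).
#'
#' @param diameter m.
#' @param density kg/m^3.
#' @return a list of class `tracer_spec`.
#' @export
tracer_spec <- function(diameter = 1.4e-3, density = 1000) {
  stopifnot(diameter > 0, density > 0)
  structure(list(diameter = diameter, density = density), class = "tracer_spec")
}
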