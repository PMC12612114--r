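# Z-stack detection counting pipeline: parse per-slice detection text files,
# convert to physical coordinates, deduplicate with the 3 um exclusion
# sphere, assign species by majority vote, drop static false positives, and
# smooth the per-species count series.
#
# Detections travel as data frames with columns
#   t_index, z_index, class_id (0 = PA rod, 1 = SA coccus),
#   cx, cy, w, h (normalized to the frame), conf
# and deduplicated cells ("cell points") as data frames with columns
#   species, x_um, y_um, z_um, t_min, n_detections, pa_vote_fraction,
#   mean_confidence.

SPECIES_LEVELS <- c("PA", "SA")

#' Z-stack acquisition metadata
#'
#' Geometry and timing of the imaging run: slice count and spacing, the
#' pixel scale, frame size and the time-lapse interval. Defaults describe the
#' platform's typical acquisition (40 slices every 0.5 um spanning 20 um,
#' 640 x 480 pixels at 8 bits, one stack every 5 min).
#'
#' @param n_slices number of Z slices per stack.
#' @param dz_um slice spacing (um).
#' @param z0_um height of slice index 0 (um).
#' @param microns_per_pixel pixel scale; the camera/objective combination is
#'   not standardized, default 0.17 um/px.
#' @param frame_w_px,frame_h_px frame size in pixels.
#' @param frame_interval_min minutes between consecutive stacks.
#' @param stack_duration_s seconds to acquire one full stack.
#' @return an object of class `zstack_meta`.
#' @export
zstack_meta <- function(n_slices = 40L, dz_um = 0.5, z0_um = 0,
                        microns_per_pixel = 0.17,
                        frame_w_px = 640L, frame_h_px = 480L,
                        frame_interval_min = 5, stack_duration_s = 6) {
  stopifnot_scalar_num(n_slices, "n_slices", positive = TRUE)
  stopifnot_scalar_num(dz_um, "dz_um", positive = TRUE)
  stopifnot_scalar_num(microns_per_pixel, "microns_per_pixel",
                       positive = TRUE)
  stopifnot_scalar_num(frame_interval_min, "frame_interval_min",
                       positive = TRUE)
  structure(list(n_slices = as.integer(n_slices), dz_um = dz_um,
                 z0_um = z0_um, microns_per_pixel = microns_per_pixel,
                 frame_w_px = as.integer(frame_w_px),
                 frame_h_px = as.integer(frame_h_px),
                 frame_interval_min = frame_interval_min,
                 stack_duration_s = stack_duration_s),
            class = "zstack_meta")
}

#' Parse a per-slice detection text file
#'
#' One line per detection: `class cx cy w h conf`, whitespace-separated, with
#' the box center/size normalized to the frame. Class 0 is the rod-shaped
#' species (PA), class 1 the cocci (SA).
#'
#' @param lines character vector of lines, or a length-1 path to a file.
#' @param t_index,z_index indices attached to every parsed detection.
#' @return data frame of detections (possibly zero rows).
#' @export
parse_detection_file <- function(lines, t_index = 0L, z_index = 0L) {
  if (length(lines) == 1L && !grepl("[\n ]", lines) && file.exists(lines))
    lines <- readLines(lines, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(t_index = integer(), z_index = integer(),
                      class_id = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric(), conf = numeric())
  if (length(lines) == 0) return(empty)
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != 6L)
      stop(sprintf("line %d: expected 6 fields, got %d", i, length(f)),
           call. = FALSE)
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v)))
      stop(sprintf("line %d: non-numeric field", i), call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, as.numeric))
  colnames(m) <- c("class_id", "cx", "cy", "w", "h", "conf")
  check_range <- function(col, lo, hi, lo_open = FALSE) {
    x <- m[, col]
    bad <- if (lo_open) x <= lo | x > hi else x < lo | x > hi
    if (any(bad))
      stop(sprintf("line %d: field '%s' out of range [%g, %g]",
                   which(bad)[1], col, lo, hi), call. = FALSE)
  }
  if (any(!m[, "class_id"] %in% c(0, 1)))
    stop(sprintf("line %d: field 'class_id' must be 0 or 1",
                 which(!m[, "class_id"] %in% c(0, 1))[1]), call. = FALSE)
  check_range("cx", 0, 1); check_range("cy", 0, 1)
  check_range("w", 0, 1, lo_open = TRUE)
  check_range("h", 0, 1, lo_open = TRUE)
  check_range("conf", 0, 1)
  data.frame(t_index = as.integer(t_index), z_index = as.integer(z_index),
             class_id = as.integer(m[, "class_id"]),
             cx = m[, "cx"], cy = m[, "cy"], w = m[, "w"], h = m[, "h"],
             conf = m[, "conf"])
}

#' Read a directory tree of detection files
#'
#' Files are named `d{droplet:02d}_t{t:04d}_z{z:02d}.txt`; indices are taken
#' from the filename.
#'
#' @param dir directory containing detection files.
#' @param droplet_id droplet to read (default: all).
#' @return data frame of detections with an extra `droplet_id` column.
#' @export
read_detection_dir <- function(dir, droplet_id = NULL) {
  files <- list.files(dir, pattern = "^d\\d+_t\\d+_z\\d+\\.txt$",
                      full.names = TRUE)
  if (length(files) == 0)
    stop("no detection files found in ", dir, call. = FALSE)
  meta <- regmatches(basename(files),
                     regexec("^d(\\d+)_t(\\d+)_z(\\d+)\\.txt$",
                             basename(files)))
  d <- as.integer(vapply(meta, `[`, "", 2))
  t <- as.integer(vapply(meta, `[`, "", 3))
  z <- as.integer(vapply(meta, `[`, "", 4))
  if (!is.null(droplet_id)) {
    keep <- d == droplet_id
    files <- files[keep]; d <- d[keep]; t <- t[keep]; z <- z[keep]
  }
  out <- mapply(function(f, dd, tt, zz) {
    det <- parse_detection_file(f, t_index = tt, z_index = zz)
    if (nrow(det)) det$droplet_id <- dd
    det
  }, files, d, t, z, SIMPLIFY = FALSE)
  out <- out[vapply(out, nrow, 0L) > 0]
  if (length(out) == 0)
    return(cbind(parse_detection_file(character()),
                 data.frame(droplet_id = integer())))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Filter detections by confidence
#'
#' Keeps detections whose confidence is strictly above the threshold
#' (detections "above" 40% are valid by default).
#'
#' @param dets detection data frame.
#' @param threshold confidence threshold in [0, 1].
#' @return filtered detection data frame.
#' @export
filter_confidence <- function(dets, threshold = 0.40) {
  stopifnot_scalar_num(threshold, "threshold", nonneg = TRUE)
  if (threshold > 1) stop("threshold must be in [0, 1]", call. = FALSE)
  dets[dets$conf > threshold, , drop = FALSE]
}

#' Convert normalized detections to physical coordinates
#'
#' Pixel origin is the top-left corner, x rightward, y downward, z increasing
#' with slice index from the stack bottom:
#' `x = cx * frame_w * um/px`, `y = cy * frame_h * um/px`,
#' `z = z0 + z_index * dz`.
#'
#' @param dets detection data frame.
#' @param meta a [zstack_meta()].
#' @return `dets` with added columns `x_um`, `y_um`, `z_um`.
#' @export
to_physical <- function(dets, meta = zstack_meta()) {
  dets$x_um <- dets$cx * meta$frame_w_px * meta$microns_per_pixel
  dets$y_um <- dets$cy * meta$frame_h_px * meta$microns_per_pixel
  dets$z_um <- meta$z0_um + dets$z_index * meta$dz_um
  dets
}

#' Majority-vote species assignment for one cluster
#'
#' A cluster is labelled PA when more than 50% of its member detections are
#' PA, SA when fewer; an exact 50/50 tie goes to the class with the higher
#' mean confidence among its own votes.
#'
#' @param class_ids integer vector of member classes (0 = PA, 1 = SA).
#' @param confs matching confidences (used only to break ties).
#' @return `"PA"` or `"SA"`.
#' @export
vote_class <- function(class_ids, confs = rep(1, length(class_ids))) {
  if (length(class_ids) == 0) stop("empty cluster", call. = FALSE)
  frac_pa <- mean(class_ids == 0)
  if (frac_pa > 0.5) return("PA")
  if (frac_pa < 0.5) return("SA")
  mean_pa <- mean(confs[class_ids == 0])
  mean_sa <- mean(confs[class_ids == 1])
  if (mean_pa >= mean_sa) "PA" else "SA"
}

#' Deduplicate one timepoint's Z-stack detections into cells
#'
#' Detections of the same physical cell recur in consecutive slices: two
#' detections in different slices within a sphere of half the exclusion
#' diameter are the same cell. Working in z order (ties by raster order: y,
#' then x), each detection joins the existing cluster holding its nearest
#' already-clustered detection when that detection lies within half the
#' exclusion diameter (3-D Euclidean), otherwise it seeds a new cluster —
#' greedy single linkage, which keeps a cell's whole slice chain together.
#' Each cluster becomes one cell at the member centroid, with species
#' assigned by [vote_class()].
#'
#' @param dets detections of a single timepoint (confidence-filtered).
#' @param meta a [zstack_meta()].
#' @param exclusion_diameter_um diameter of the exclusion sphere (default
#'   3 um, set by the bacterial movement speed between slices).
#' @param t_min elapsed time to stamp on the output cells.
#' @return data frame of cell points.
#' @export
merge_zstack <- function(dets, meta = zstack_meta(),
                         exclusion_diameter_um = 3.0, t_min = NA_real_) {
  empty <- data.frame(species = character(), x_um = numeric(),
                      y_um = numeric(), z_um = numeric(), t_min = numeric(),
                      n_detections = integer(),
                      pa_vote_fraction = numeric(),
                      mean_confidence = numeric())
  if (nrow(dets) == 0) return(empty)
  if (length(unique(dets$t_index)) > 1)
    stop("merge_zstack expects detections from a single timepoint",
         call. = FALSE)
  if (!all(c("x_um", "y_um", "z_um") %in% names(dets)))
    dets <- to_physical(dets, meta)
  ord <- order(dets$z_um, dets$y_um, dets$x_um)
  dets <- dets[ord, , drop = FALSE]
  r <- exclusion_diameter_um / 2
  n <- nrow(dets)
  member_of <- integer(n)
  ncl <- 0L
  P <- cbind(dets$x_um, dets$y_um, dets$z_um)
  for (i in seq_len(n)) {
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      d2 <- (P[prev, 1] - P[i, 1])^2 + (P[prev, 2] - P[i, 2])^2 +
            (P[prev, 3] - P[i, 3])^2
      j <- which.min(d2)
      if (d2[j] <= r^2) {
        member_of[i] <- member_of[j]
        next
      }
    }
    ncl <- ncl + 1L
    member_of[i] <- ncl
  }
  out <- lapply(seq_len(ncl), function(j) {
    idx <- which(member_of == j)
    data.frame(
      species = vote_class(dets$class_id[idx], dets$conf[idx]),
      x_um = mean(dets$x_um[idx]), y_um = mean(dets$y_um[idx]),
      z_um = mean(dets$z_um[idx]), t_min = t_min,
      n_detections = length(idx),
      pa_vote_fraction = mean(dets$class_id[idx] == 0),
      mean_confidence = mean(dets$conf[idx]))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

# Test oracle: single-linkage connected components at a distance cutoff,
# via breadth-first search over the full pairwise distance matrix.
single_linkage_components <- function(points, cutoff) {
  n <- nrow(points)
  if (n == 0) return(integer())
  d <- as.matrix(stats::dist(points))
  adj <- d <= cutoff
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Remove static detections across a time series
#'
#' Real cells drift and swim; detections that sit at the same physical spot
#' over many consecutive timepoints are trap imperfections or debris and are
#' removed. Cell points from all timepoints are clustered by position
#' (single linkage at `displacement_tol_um`); any cluster present in
#' `min_persistence` or more consecutive timepoints has those points removed.
#'
#' @param cells cell-point data frame spanning several timepoints (`t_min`).
#' @param displacement_tol_um maximum per-frame displacement still considered
#'   static (default 0.5 um, sub-diffraction over the frame interval).
#' @param min_persistence consecutive timepoints required to flag a track as
#'   static (default 5, i.e. 25 min at 5-min framing).
#' @return `cells` with static tracks removed.
#' @export
remove_static <- function(cells, displacement_tol_um = 0.5,
                          min_persistence = 5L) {
  if (nrow(cells) == 0) return(cells)
  comp <- single_linkage_components(
    cbind(cells$x_um, cells$y_um, cells$z_um), displacement_tol_um)
  times <- sort(unique(cells$t_min))
  t_rank <- match(cells$t_min, times)
  drop <- logical(nrow(cells))
  for (cl in unique(comp)) {
    idx <- which(comp == cl)
    ranks <- sort(unique(t_rank[idx]))
    if (length(ranks) < min_persistence) next
    runs <- split(ranks, cumsum(c(1, diff(ranks) != 1)))
    for (run in runs) {
      if (length(run) >= min_persistence)
        drop[idx[t_rank[idx] %in% run]] <- TRUE
    }
  }
  cells[!drop, , drop = FALSE]
}

#' Elapsed minutes from file timestamps
#'
#' Parses acquisition timestamps and returns minutes elapsed since the first
#' image. Out-of-order stamps are sorted with a warning.
#'
#' @param stamps character timestamps (`"HH:MM:SS"` or
#'   `"YYYY-mm-dd HH:MM:SS"`) or POSIXct.
#' @return numeric vector of elapsed minutes starting at 0.
#' @export
assign_times <- function(stamps) {
  if (length(stamps) == 0) stop("no timestamps", call. = FALSE)
  if (!inherits(stamps, "POSIXct")) {
    parsed <- as.POSIXct(stamps, tz = "UTC",
                         tryFormats = c("%Y-%m-%d %H:%M:%S",
                                        "%Y-%m-%dT%H:%M:%S"),
                         optional = TRUE)
    if (any(is.na(parsed))) {
      parsed <- as.POSIXct(paste("1970-01-01", stamps), tz = "UTC",
                           format = "%Y-%m-%d %H:%M:%S", optional = TRUE)
    }
    if (any(is.na(parsed)))
      stop("unparseable timestamp: ", stamps[which(is.na(parsed))[1]],
           call. = FALSE)
    stamps <- parsed
  }
  if (is.unsorted(stamps)) {
    warning("timestamps out of order; sorting")
    stamps <- sort(stamps)
  }
  as.numeric(difftime(stamps, stamps[1], units = "mins"))
}

#' Moving-average smoothing of a count series
#'
#' Centered moving mean and sample standard deviation over `window`
#' consecutive timepoints (default 8), applied per species. For even windows
#' the window at index i covers i-floor((w-1)/2) .. i+ceiling((w-1)/2);
#' windows are truncated to the series bounds at the edges.
#'
#' @param series a count-series data frame with columns `time_min`,
#'   `species`, `raw_count` (one row per timepoint per species).
#' @param window window length in timepoints.
#' @return `series` with added `smoothed_count` and `smoothed_sd` columns.
#' @export
moving_average_counts <- function(series, window = 8L) {
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  before <- floor((window - 1) / 2)
  after <- window - 1 - before
  out <- lapply(split(series, series$species), function(s) {
    s <- s[order(s$time_min), , drop = FALSE]
    n <- nrow(s)
    if (window > n)
      stop("window longer than series", call. = FALSE)
    sm <- numeric(n); sd_ <- numeric(n)
    for (i in seq_len(n)) {
      idx <- max(1, i - before):min(n, i + after)
      sm[i] <- mean(s$raw_count[idx])
      sd_[i] <- if (length(idx) > 1) stats::sd(s$raw_count[idx]) else 0
    }
    s$smoothed_count <- sm
    s$smoothed_sd <- sd_
    s
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$time_min, res$species), , drop = FALSE]
}

#' Run the full counting pipeline on a detection stream
#'
#' Confidence filter, per-timepoint exclusion-sphere deduplication, static
#' removal across time, then per-species counting and moving-average
#' smoothing.
#'
#' @param dets detection data frame spanning all timepoints of one droplet.
#' @param meta a [zstack_meta()].
#' @param conf_threshold confidence threshold.
#' @param exclusion_diameter_um deduplication sphere diameter (um).
#' @param window smoothing window (timepoints).
#' @param static_tol_um,static_persistence static-removal parameters
#'   (see [remove_static()]); `static_persistence = Inf` disables removal.
#' @param droplet_id id stamped on the output.
#' @return list with `cells` (deduplicated cell points) and `counts`
#'   (per-timepoint per-species raw and smoothed counts).
#' @export
count_droplet <- function(dets, meta = zstack_meta(), conf_threshold = 0.40,
                          exclusion_diameter_um = 3.0, window = 8L,
                          static_tol_um = 0.5, static_persistence = 5L,
                          droplet_id = 1L) {
  dets <- filter_confidence(dets, conf_threshold)
  dets <- to_physical(dets, meta)
  t_indices <- sort(unique(dets$t_index))
  cells <- do.call(rbind, c(lapply(t_indices, function(ti) {
    merge_zstack(dets[dets$t_index == ti, , drop = FALSE], meta,
                 exclusion_diameter_um,
                 t_min = ti * meta$frame_interval_min)
  }), make.row.names = FALSE))
  if (is.finite(static_persistence))
    cells <- remove_static(cells, static_tol_um, static_persistence)
  times <- t_indices * meta$frame_interval_min
  grid <- expand.grid(time_min = times, species = SPECIES_LEVELS,
                      stringsAsFactors = FALSE)
  grid$raw_count <- mapply(function(tm, sp) {
    sum(cells$t_min == tm & cells$species == sp)
  }, grid$time_min, grid$species)
  counts <- moving_average_counts(grid, window = min(window, length(times)))
  counts$droplet_id <- droplet_id
  list(cells = cells, counts = counts)
}
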