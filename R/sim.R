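# Stochastic agent-based simulator of mono-/bi-species bacterial populations
# and a lytic phage confined in an anchored ellipsoidal droplet. Cells carry
# position, species, morphology and infection stage; free phage is an integer
# pool with exact adsorption/release bookkeeping. The simulator is the
# synthetic-data backbone: it emits ground-truth count trajectories, noisy
# per-slice detection streams in the pipeline's text dialect, and bulk
# one-step growth curves.
#
# Coordinates are droplet-centered micrometres: the ellipsoid is
# (x/a)^2 + (y/a)^2 + (z/c)^2 <= 1 with a = diameter/2, c = height/2.

#' Per-species simulation parameters
#'
#' @param species_id `"PA"` or `"SA"`.
#' @param doubling_time_min target population doubling time (min). Defaults
#'   are the average droplet monoculture doubling times observed on the
#'   platform (PA 33.96 min, SA 69.49 min).
#' @param doubling_cv coefficient of variation of interdivision times
#'   (default 0.2, matching the droplet-to-droplet spread).
#' @param speed_um_per_s swimming/drift speed. The rod species is a
#'   flagellum-deficient mutant, so speeds are well below the ~15 um/s
#'   countability ceiling.
#' @param phage_susceptible can this species be infected by the phage?
#' @param aggregation_prob probability a daughter stays attached to its
#'   parent (cocci chains/clusters).
#' @return an object of class `species_params`.
#' @export
species_params <- function(species_id = c("PA", "SA"),
                           doubling_time_min = NULL, doubling_cv = 0.2,
                           speed_um_per_s = NULL, phage_susceptible = NULL,
                           aggregation_prob = NULL) {
  species_id <- match.arg(species_id)
  defaults <- if (species_id == "PA") {
    list(td = 33.96, speed = 0.5, sus = TRUE, agg = 0)
  } else {
    list(td = 69.49, speed = 0.2, sus = FALSE, agg = 0.7)
  }
  if (is.null(doubling_time_min)) doubling_time_min <- defaults$td
  if (is.null(speed_um_per_s)) speed_um_per_s <- defaults$speed
  if (is.null(phage_susceptible)) phage_susceptible <- defaults$sus
  if (is.null(aggregation_prob)) aggregation_prob <- defaults$agg
  stopifnot_scalar_num(doubling_time_min, "doubling_time_min",
                       positive = TRUE)
  stopifnot_scalar_num(doubling_cv, "doubling_cv", nonneg = TRUE)
  stopifnot_scalar_num(speed_um_per_s, "speed_um_per_s", nonneg = TRUE)
  structure(list(species_id = species_id,
                 doubling_time_min = doubling_time_min,
                 doubling_cv = doubling_cv,
                 speed_um_per_s = speed_um_per_s,
                 phage_susceptible = isTRUE(phage_susceptible),
                 aggregation_prob = aggregation_prob),
            class = "species_params")
}

#' Phage life-cycle parameters
#'
#' @param burst_size mean phages released per lysed cell (default 45, the
#'   characterized value for the platform's lytic phage).
#' @param latent_min latent period / time to first burst (default 37 min).
#' @param latent_sd_min per-cell Gaussian jitter of the burst time.
#' @param adsorption_rate per-phage per-cell infection rate inside one
#'   droplet (1/min). The default 0.005 is a heuristic calibration: it makes
#'   a low-MOI (~0.6) population peak near 50 min before declining.
#' @param fixed_burst if `TRUE`, every burst releases exactly `burst_size`
#'   phages instead of a Poisson draw (for exact bookkeeping tests).
#' @return an object of class `phage_params`.
#' @export
phage_params <- function(burst_size = 45, latent_min = 37,
                         latent_sd_min = 3, adsorption_rate = 0.005,
                         fixed_burst = FALSE) {
  stopifnot_scalar_num(burst_size, "burst_size", positive = TRUE)
  if (burst_size < 1) stop("burst_size must be >= 1", call. = FALSE)
  stopifnot_scalar_num(latent_min, "latent_min", positive = TRUE)
  stopifnot_scalar_num(latent_sd_min, "latent_sd_min", nonneg = TRUE)
  stopifnot_scalar_num(adsorption_rate, "adsorption_rate", nonneg = TRUE)
  structure(list(burst_size = burst_size, latent_min = latent_min,
                 latent_sd_min = latent_sd_min,
                 adsorption_rate = adsorption_rate,
                 fixed_burst = isTRUE(fixed_burst)),
            class = "phage_params")
}

#' Detection noise model
#'
#' Emulates the platform's documented counting error sources: missed
#' detections that worsen toward the water-oil/trap boundary, class flips,
#' fixed-position false detections (trap imperfections, debris), and
#' per-class confidence distributions.
#'
#' @param depth_of_field_um axial range within which a cell registers in a
#'   slice (default 3 um).
#' @param miss_prob_center,miss_prob_boundary per-slice miss probabilities at
#'   the droplet center and boundary (boundary >= center).
#' @param boundary_margin_um radial band counted as "near boundary".
#' @param misclass_prob probability a detection carries the wrong class.
#' @param n_static_debris number of fixed-position false-detection sources.
#' @param conf_shape1,conf_shape2 Beta parameters for detection confidences.
#' @param spheroplast_miss_prob extra miss probability for spheroplast
#'   (lysing, rounded) cells, which the rod detector tends not to see.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(depth_of_field_um = 3, miss_prob_center = 0.05,
                        miss_prob_boundary = 0.3, boundary_margin_um = 5,
                        misclass_prob = 0.03, n_static_debris = 0L,
                        conf_shape1 = 8, conf_shape2 = 2,
                        spheroplast_miss_prob = 0.7) {
  if (miss_prob_boundary < miss_prob_center)
    stop("boundary miss probability must be >= center miss probability",
         call. = FALSE)
  structure(list(depth_of_field_um = depth_of_field_um,
                 miss_prob_center = miss_prob_center,
                 miss_prob_boundary = miss_prob_boundary,
                 boundary_margin_um = boundary_margin_um,
                 misclass_prob = misclass_prob,
                 n_static_debris = as.integer(n_static_debris),
                 conf_shape1 = conf_shape1, conf_shape2 = conf_shape2,
                 spheroplast_miss_prob = spheroplast_miss_prob),
            class = "noise_model")
}

# Interdivision-time mean correction. With Gamma(shape k) interdivision
# times of mean m, the Euler-Lotka relation for binary fission,
# 2 * (1 + r m / k)^(-k) = 1, gives population rate r. Inverting for a
# target population doubling time Td (r = ln2/Td):
#   m = Td * k * (2^(1/k) - 1) / ln(2),
# which tends to Td as the CV tends to 0.
interdivision_mean <- function(td_min, cv) {
  if (cv <= 0) return(td_min)
  k <- 1 / cv^2
  td_min * k * (2^(1 / k) - 1) / log(2)
}

draw_interdivision <- function(n, sp) {
  m <- interdivision_mean(sp$doubling_time_min, sp$doubling_cv)
  if (sp$doubling_cv <= 0) return(rep(m, n))
  k <- 1 / sp$doubling_cv^2
  stats::rgamma(n, shape = k, scale = m / k)
}

new_cell_df <- function(n = 0L) {
  data.frame(id = integer(n), species = character(n),
             x = numeric(n), y = numeric(n), z = numeric(n),
             morphology = character(n), stage = character(n),
             next_division_min = numeric(n), burst_time_min = numeric(n),
             burst_draw = numeric(n), attached_to = integer(n),
             parent = integer(n))
}

#' Load a droplet with cells and phage
#'
#' Per-species initial counts are Poisson draws at the encapsulation mean
#' computed from the mixed inoculum concentrations (pipetted volumes dilute
#' one another) and the droplet volume; positions are uniform in the
#' ellipsoid; the initial free-phage count is a Poisson draw at the diluted
#' titer times the droplet volume. Alternatively pass explicit per-species
#' means via `lambda` (named vector) and a phage mean via `lambda_phage`.
#'
#' @param mix an [inoculum_mix()], or `NULL` when using `lambda`.
#' @param geometry a [droplet_geometry()].
#' @param species_params named list of [species_params()] keyed by species.
#' @param phage a [phage_params()].
#' @param lambda named numeric vector of per-species Poisson means
#'   (overrides `mix`).
#' @param lambda_phage Poisson mean of the initial free-phage count.
#' @param seed optional integer seed.
#' @return an object of class `sim_state`.
#' @export
load_droplet <- function(mix = NULL, geometry = droplet_geometry(),
                         species_params = default_species_params(),
                         phage = phage_params(), lambda = NULL,
                         lambda_phage = NULL, seed = NULL) {
  vol_pl <- ellipsoid_volume_pl(geometry)
  if (is.null(lambda)) {
    if (is.null(mix)) stop("need 'mix' or 'lambda'", call. = FALSE)
    total_ul <- sum(vapply(mix$species, function(s) s$volume_ul, 0)) +
      mix$phage_volume_ul
    lambda <- vapply(mix$species, function(s) {
      conc <- s$cfu_per_ml * s$volume_ul / total_ul
      expected_cells_per_droplet(conc, vol_pl)
    }, 0)
    names(lambda) <- vapply(mix$species, function(s) s$species_id, "")
    if (is.null(lambda_phage)) {
      phage_conc <- mix$phage_titer_pfu_per_ml * mix$phage_volume_ul /
        total_ul
      lambda_phage <- phage_conc * vol_pl * 1e-9
    }
  }
  if (is.null(lambda_phage)) lambda_phage <- 0
  with_seed(seed, {
    a <- geometry$diameter_um / 2
    c_axis <- geometry$height_um / 2
    cells <- new_cell_df()
    next_id <- 1L
    for (sp_id in names(lambda)) {
      n <- stats::rpois(1, lambda[[sp_id]])
      if (n == 0) next
      sp <- species_params[[sp_id]]
      if (is.null(sp)) sp <- species_params(sp_id)
      pos <- runif_ellipsoid(n, a, c_axis)
      inter <- draw_interdivision(n, sp)
      cells <- rbind(cells, data.frame(
        id = next_id:(next_id + n - 1L), species = sp_id,
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        morphology = if (sp_id == "PA") "rod" else "cocci",
        stage = "healthy",
        next_division_min = inter * stats::runif(n),  # desynchronized ages
        burst_time_min = NA_real_, burst_draw = NA_real_,
        attached_to = NA_integer_, parent = NA_integer_))
      next_id <- next_id + n
    }
    free_phage <- stats::rpois(1, lambda_phage)
    structure(list(t_min = 0, cells = cells, free_phage = free_phage,
                   initial_phage = free_phage, cumulative_adsorbed = 0L,
                   cumulative_lysed = 0L, cumulative_released = 0L,
                   next_id = next_id, geometry = geometry,
                   species_params = species_params, phage = phage,
                   events = list()),
              class = "sim_state")
  })
}

#' Default per-species parameter set
#' @return named list of [species_params()] for PA and SA.
#' @export
default_species_params <- function() {
  list(PA = species_params("PA"), SA = species_params("SA"))
}

log_event <- function(state, time, event, cell_id, species, detail = NA_real_) {
  state$events[[length(state$events) + 1L]] <-
    data.frame(time_min = time, event = event, cell_id = cell_id,
               species = species, detail = detail)
  state
}

#' Advance the simulation by one time step
#'
#' In order: cell divisions (gamma-distributed interdivision clocks,
#' daughters placed 1 um away, cocci daughters possibly attached), phage
#' adsorption (well-mixed mass action: each susceptible healthy cell is
#' infected with probability `1 - exp(-adsorption_rate * free_phage * dt)`,
#' consuming one phage), the rod-to-spheroplast morphology switch at 70% of
#' the latent period, lysis with Poisson (or fixed) burst release, and
#' reflected random-walk motion confined to the ellipsoid.
#'
#' @param state a `sim_state`.
#' @param dt_min time step (default 0.5 min; must be small relative to the
#'   latent period).
#' @return the advanced `sim_state`.
#' @export
sim_step <- function(state, dt_min = 0.5) {
  if (dt_min <= 0) stop("dt_min must be > 0", call. = FALSE)
  t0 <- state$t_min
  t1 <- t0 + dt_min
  cells <- state$cells
  a <- state$geometry$diameter_um / 2
  c_axis <- state$geometry$height_um / 2
  phg <- state$phage

  # -- divisions (healthy cells whose clock expires in this step)
  div <- which(cells$stage == "healthy" & cells$next_division_min <= t1)
  if (length(div)) {
    daughters <- list()
    for (i in div) {
      sp <- state$species_params[[cells$species[i]]]
      # daughter 1 um away in a uniform random direction, kept inside
      for (try in 1:10) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        px <- cells$x[i] + u[1]; py <- cells$y[i] + u[2]
        pz <- cells$z[i] + u[3]
        if (inside_ellipsoid(px, py, pz, a, c_axis)) break
      }
      if (!inside_ellipsoid(px, py, pz, a, c_axis)) {
        px <- cells$x[i]; py <- cells$y[i]; pz <- cells$z[i]
      }
      attached <- cells$species[i] == "SA" &&
        stats::runif(1) < sp$aggregation_prob
      d <- data.frame(
        id = state$next_id, species = cells$species[i],
        x = px, y = py, z = pz, morphology = cells$morphology[i],
        stage = "healthy",
        next_division_min = t1 + draw_interdivision(1, sp),
        burst_time_min = NA_real_, burst_draw = NA_real_,
        attached_to = if (attached) cells$id[i] else NA_integer_,
        parent = cells$id[i])
      state$next_id <- state$next_id + 1L
      daughters[[length(daughters) + 1L]] <- d
      cells$next_division_min[i] <- t1 + draw_interdivision(1, sp)
      state <- log_event(state, t1, "division", cells$id[i],
                         cells$species[i])
    }
    cells <- rbind(cells, do.call(rbind, daughters))
  }

  # -- phage adsorption / infection
  if (state$free_phage > 0 && phg$adsorption_rate > 0) {
    sus <- which(cells$stage == "healthy" &
                   vapply(cells$species,
                          function(s) state$species_params[[s]]$phage_susceptible,
                          TRUE))
    if (length(sus)) {
      p_inf <- 1 - exp(-phg$adsorption_rate * state$free_phage * dt_min)
      hit <- sus[stats::runif(length(sus)) < p_inf]
      if (length(hit) > state$free_phage)
        hit <- sample(hit, state$free_phage)
      if (length(hit)) {
        cells$stage[hit] <- "infected_latent"
        lat <- phg$latent_min +
          if (phg$latent_sd_min > 0)
            stats::rnorm(length(hit), 0, phg$latent_sd_min) else 0
        cells$burst_time_min[hit] <- t1 + pmax(lat, dt_min)
        cells$burst_draw[hit] <- if (phg$fixed_burst)
          phg$burst_size else stats::rpois(length(hit), phg$burst_size)
        state$free_phage <- state$free_phage - length(hit)
        state$cumulative_adsorbed <- state$cumulative_adsorbed +
          length(hit)
        for (i in hit)
          state <- log_event(state, t1, "infection", cells$id[i],
                             cells$species[i])
      }
    }
  }

  # -- morphology switch: infected rods round up at 70% of the latent period
  inf <- which(cells$stage == "infected_latent" & cells$morphology == "rod")
  if (length(inf)) {
    switch_at <- cells$burst_time_min[inf] - 0.3 * phg$latent_min
    turn <- inf[t1 >= switch_at]
    if (length(turn)) cells$morphology[turn] <- "spheroplast"
  }

  # -- lysis
  burst <- which(cells$stage == "infected_latent" &
                   cells$burst_time_min <= t1)
  if (length(burst)) {
    released <- sum(cells$burst_draw[burst])
    state$free_phage <- state$free_phage + released
    state$cumulative_released <- state$cumulative_released + released
    state$cumulative_lysed <- state$cumulative_lysed + length(burst)
    for (i in burst)
      state <- log_event(state, t1, "burst", cells$id[i],
                         cells$species[i], cells$burst_draw[i])
    cells <- cells[-burst, , drop = FALSE]
  }

  # -- motion: reflected random walk; attached daughters stay put
  if (nrow(cells)) {
    mobile <- which(is.na(cells$attached_to))
    for (i in mobile) {
      sp <- state$species_params[[cells$species[i]]]
      step_um <- sp$speed_um_per_s * 60 * dt_min
      if (step_um <= 0) next
      for (try in 1:10) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        nx <- cells$x[i] + step_um * u[1]
        ny <- cells$y[i] + step_um * u[2]
        nz <- cells$z[i] + step_um * u[3]
        if (inside_ellipsoid(nx, ny, nz, a, c_axis)) {
          cells$x[i] <- nx; cells$y[i] <- ny; cells$z[i] <- nz
          break
        }
      }
    }
  }

  state$cells <- cells
  state$t_min <- t1
  state
}

#' Run a droplet simulation
#'
#' Steps the state with `dt_min` up to `duration_min`, sampling a snapshot of
#' all cells (and the free-phage count) every `frame_interval_min` — the
#' simulated analogue of one Z-stack acquisition per timepoint.
#'
#' @param state a `sim_state` from [load_droplet()].
#' @param duration_min total simulated time.
#' @param dt_min integration step.
#' @param frame_interval_min sampling interval (default 5 min).
#' @param seed optional integer seed (deterministic replay).
#' @return list of class `sim_result`: `truth` (per-frame per-species true
#'   counts and free phage), `frames` (list of cell snapshots), `events`
#'   (event log), `state` (final state).
#' @export
simulate_droplet <- function(state, duration_min, dt_min = 0.5,
                             frame_interval_min = 5, seed = NULL) {
  with_seed(seed, {
    n_frames <- floor(duration_min / frame_interval_min) + 1L
    frames <- vector("list", n_frames)
    truth <- list()
    snap <- function(k) {
      frames[[k + 1L]] <<- state$cells
      for (sp in SPECIES_LEVELS) {
        truth[[length(truth) + 1L]] <<- data.frame(
          t_index = k, time_min = k * frame_interval_min, species = sp,
          true_count = sum(state$cells$species == sp),
          free_phage = state$free_phage)
      }
    }
    snap(0L)
    next_frame <- 1L
    steps <- ceiling(duration_min / dt_min)
    for (s in seq_len(steps)) {
      state <- sim_step(state, dt_min)
      while (next_frame < n_frames &&
             state$t_min + 1e-9 >= next_frame * frame_interval_min) {
        snap(next_frame)
        next_frame <- next_frame + 1L
      }
    }
    events <- if (length(state$events))
      do.call(rbind, c(state$events, make.row.names = FALSE))
    else data.frame(time_min = numeric(), event = character(),
                    cell_id = integer(), species = character(),
                    detail = numeric())
    structure(list(truth = do.call(rbind, c(truth,
                                            make.row.names = FALSE)),
                   frames = frames, events = events, state = state,
                   frame_interval_min = frame_interval_min),
              class = "sim_result")
  })
}

#' Emit a noisy detection stream from a simulation
#'
#' For every frame and Z slice, each cell within half the depth of field of
#' the slice plane yields one detection unless missed; the miss probability
#' interpolates from the droplet center to the boundary, spheroplasts are
#' additionally missed with their own probability, classes flip with
#' `misclass_prob`, and confidences are Beta draws. Static debris sources are
#' fixed 3-D points detected in every frame. Boxes are sized by morphology
#' (rods elongated, cocci and spheroplasts square).
#'
#' @param result a `sim_result` from [simulate_droplet()].
#' @param meta a [zstack_meta()]; its z range should cover the droplet.
#' @param noise a [noise_model()].
#' @param seed optional integer seed.
#' @return detection data frame in the pipeline's dialect, plus attribute
#'   `"debris"` holding the injected debris positions.
#' @export
emit_detections <- function(result, meta = zstack_meta(z0_um = -10),
                            noise = noise_model(), seed = NULL) {
  geometry <- result$state$geometry
  a <- geometry$diameter_um / 2
  c_axis <- geometry$height_um / 2
  half_w <- meta$frame_w_px * meta$microns_per_pixel / 2
  half_h <- meta$frame_h_px * meta$microns_per_pixel / 2
  slice_z <- meta$z0_um + (seq_len(meta$n_slices) - 1L) * meta$dz_um
  dof <- noise$depth_of_field_um / 2
  with_seed(seed, {
    debris <- if (noise$n_static_debris > 0)
      runif_ellipsoid(noise$n_static_debris, a * 0.9, c_axis * 0.9)
    else matrix(numeric(), ncol = 3)
    out <- list()
    for (k in seq_along(result$frames)) {
      cells <- result$frames[[k]]
      t_index <- k - 1L
      pts <- rbind(
        if (nrow(cells)) data.frame(x = cells$x, y = cells$y, z = cells$z,
                                    species = cells$species,
                                    morphology = cells$morphology,
                                    debris = FALSE),
        if (nrow(debris)) data.frame(x = debris[, 1], y = debris[, 2],
                                     z = debris[, 3], species = "PA",
                                     morphology = "debris", debris = TRUE))
      if (is.null(pts) || nrow(pts) == 0) next
      u <- sqrt((pts$x / a)^2 + (pts$y / a)^2 + (pts$z / c_axis)^2)
      u0 <- max(0, 1 - noise$boundary_margin_um / a)
      frac <- pmax(0, pmin(1, (u - u0) / max(1e-9, 1 - u0)))
      p_miss <- noise$miss_prob_center +
        frac * (noise$miss_prob_boundary - noise$miss_prob_center)
      for (zi in seq_along(slice_z)) {
        vis <- which(abs(pts$z - slice_z[zi]) <= dof)
        if (!length(vis)) next
        pm <- p_miss[vis]
        pm[pts$morphology[vis] == "spheroplast"] <-
          pmax(pm[pts$morphology[vis] == "spheroplast"],
               noise$spheroplast_miss_prob)
        pm[pts$debris[vis]] <- 0  # debris is stubbornly always detected
        keep <- vis[stats::runif(length(vis)) >= pm]
        if (!length(keep)) next
        cls <- ifelse(pts$species[keep] == "PA", 0L, 1L)
        flip <- stats::runif(length(keep)) < noise$misclass_prob
        cls[flip] <- 1L - cls[flip]
        rod <- pts$morphology[keep] == "rod"
        w_um <- ifelse(rod, 2.0, 1.0)
        h_um <- rep(1.0, length(keep))
        conf <- stats::rbeta(length(keep), noise$conf_shape1,
                             noise$conf_shape2)
        out[[length(out) + 1L]] <- data.frame(
          t_index = t_index, z_index = zi - 1L, class_id = cls,
          cx = pmin(1, pmax(0, (pts$x[keep] + half_w) / (2 * half_w))),
          cy = pmin(1, pmax(0, (pts$y[keep] + half_h) / (2 * half_h))),
          w = w_um / (2 * half_w), h = h_um / (2 * half_h),
          conf = conf)
      }
    }
    dets <- if (length(out))
      do.call(rbind, c(out, make.row.names = FALSE))
    else parse_detection_file(character())
    attr(dets, "debris") <- debris
    dets
  })
}

#' Write a detection stream as per-slice text files
#'
#' One file per (timepoint, slice), named `d{droplet:02d}_t{t:04d}_z{z:02d}.txt`,
#' lines `class cx cy w h conf`. Empty slices produce empty files so the
#' reader sees the full grid.
#'
#' @param dets detection data frame.
#' @param dir output directory (created if needed).
#' @param meta a [zstack_meta()] (for the slice grid).
#' @param droplet_id droplet index used in filenames.
#' @return invisibly, the vector of files written.
#' @export
write_detection_dir <- function(dets, dir, meta = zstack_meta(),
                                droplet_id = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t_indices <- sort(unique(dets$t_index))
  files <- character()
  for (ti in t_indices) {
    for (zi in seq_len(meta$n_slices) - 1L) {
      f <- file.path(dir, sprintf("d%02d_t%04d_z%02d.txt",
                                  droplet_id, ti, zi))
      sub <- dets[dets$t_index == ti & dets$z_index == zi, , drop = FALSE]
      lines <- if (nrow(sub))
        sprintf("%d %.6f %.6f %.6f %.6f %.4f", sub$class_id, sub$cx,
                sub$cy, sub$w, sub$h, sub$conf)
      else character()
      writeLines(lines, f)
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Simulate a one-step phage growth curve
#'
#' `n_infected` cells are infected synchronously at t = 0; each bursts at the
#' latent period plus Gaussian jitter, releasing a Poisson (or fixed) number
#' of phages. The sampled curve counts plaque-forming units as in the assay:
#' every not-yet-lysed infected cell is one infective center, and released
#' phages count individually afterwards, so the plateau ratio is the mean
#' burst size.
#'
#' @param phage a [phage_params()].
#' @param n_infected number of synchronously infected cells.
#' @param sampling_min sampling interval (default 5 min).
#' @param duration_min assay duration (default 2.5 latent periods).
#' @param jitter_sd_min burst-time jitter; defaults to the phage's
#'   `latent_sd_min`.
#' @param seed optional integer seed.
#' @return data frame with `times_min`, `pfu`.
#' @export
emit_one_step_curve <- function(phage = phage_params(), n_infected = 200L,
                                sampling_min = 5, duration_min = NULL,
                                jitter_sd_min = NULL, seed = NULL) {
  if (n_infected < 1) stop("n_infected must be >= 1", call. = FALSE)
  if (is.null(duration_min)) duration_min <- ceiling(2.5 * phage$latent_min)
  if (is.null(jitter_sd_min)) jitter_sd_min <- phage$latent_sd_min
  with_seed(seed, {
    burst_t <- phage$latent_min +
      if (jitter_sd_min > 0) stats::rnorm(n_infected, 0, jitter_sd_min)
      else rep(0, n_infected)
    releases <- if (phage$fixed_burst) rep(phage$burst_size, n_infected)
                else stats::rpois(n_infected, phage$burst_size)
    times <- seq(0, duration_min, by = sampling_min)
    pfu <- vapply(times, function(tt) {
      done <- burst_t <= tt
      sum(!done) + sum(releases[done])
    }, 0)
    data.frame(times_min = times, pfu = pfu)
  })
}

#' Render one simulated Z-slice image
#'
#' Composites the trap-ring background with dark blobs for every cell within
#' the depth of field of the slice plane: rods as oriented elongated
#' Gaussians, cocci and spheroplasts as round ones, with contrast falling and
#' width growing with axial distance from the plane. Deterministic under
#' `seed`.
#'
#' @param cells cell snapshot (a `sim_result$frames[[k]]` data frame).
#' @param slice_z_um slice height in droplet-centered um.
#' @param meta a [zstack_meta()].
#' @param geometry the droplet geometry (sets the ring radius).
#' @param depth_of_field_um axial visibility range.
#' @param noise_sd pixel noise (grey levels).
#' @param seed optional integer seed.
#' @return integer matrix (`frame_h_px` x `frame_w_px`), values 0..255.
#' @export
render_slice_image <- function(cells, slice_z_um = 0, meta = zstack_meta(),
                               geometry = droplet_geometry(),
                               depth_of_field_um = 3, noise_sd = 2,
                               seed = NULL) {
  half_w <- meta$frame_w_px * meta$microns_per_pixel / 2
  half_h <- meta$frame_h_px * meta$microns_per_pixel / 2
  ring_r_px <- geometry$diameter_um / 2 / meta$microns_per_pixel
  base <- render_trap_image(center_px = c(meta$frame_w_px / 2,
                                          meta$frame_h_px / 2),
                            radius_px = min(ring_r_px,
                                            meta$frame_h_px / 2 - 2),
                            noise_sd = 0, width = meta$frame_w_px,
                            height = meta$frame_h_px)
  img <- matrix(as.numeric(base), nrow = nrow(base))
  if (!is.null(cells) && nrow(cells)) {
    vis <- which(abs(cells$z - slice_z_um) <= depth_of_field_um / 2)
    if (length(vis)) {
      xs <- matrix(seq_len(meta$frame_w_px), nrow = meta$frame_h_px,
                   ncol = meta$frame_w_px, byrow = TRUE)
      ys <- matrix(seq_len(meta$frame_h_px), nrow = meta$frame_h_px,
                   ncol = meta$frame_w_px)
      for (i in vis) {
        px <- (cells$x[i] + half_w) / meta$microns_per_pixel
        py <- (cells$y[i] + half_h) / meta$microns_per_pixel
        dz <- abs(cells$z[i] - slice_z_um)
        blur <- 1 + dz            # px; grows with defocus
        contrast <- 90 / (1 + dz) # px; falls with defocus
        rod <- cells$morphology[i] == "rod"
        sx <- if (rod) (2 / meta$microns_per_pixel) / 2 else
          (1 / meta$microns_per_pixel) / 2
        sy <- (1 / meta$microns_per_pixel) / 2
        img <- img - contrast *
          exp(-(((xs - px)^2) / (2 * (sx + blur)^2) +
                  ((ys - py)^2) / (2 * (sy + blur)^2)))
      }
    }
  }
  img <- with_seed(seed, {
    if (noise_sd > 0) img <- img + stats::rnorm(length(img), sd = noise_sd)
    img
  })
  img <- round(img)
  img[img < 0] <- 0; img[img > 255] <- 255
  storage.mode(img) <- "integer"
  img
}
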