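# Stochastic droplet simulator: loading, dynamics, bookkeeping, emission.

test_that("droplet loading follows Poisson occupancy at the mixed dilution", {
  # lambda = 0 -> never any cells of that species
  st <- load_droplet(lambda = c(PA = 0, SA = 3), lambda_phage = 0, seed = 1)
  expect_equal(sum(st$cells$species == "PA"), 0)
  # sampled mean over many loads approaches lambda (law of large numbers)
  set.seed(77)
  n <- 3000
  counts <- vapply(seq_len(n), function(i) {
    nrow(load_droplet(lambda = c(PA = 2), lambda_phage = 0)$cells)
  }, 0)
  expect_lt(abs(mean(counts) - 2), 3 * sqrt(2 / n))
  # mixture dilution: equal volumes of PA at 4e7 and SA at 1.5e7 CFU/mL
  mix <- inoculum_mix(species = list(
    list(species_id = "PA", cfu_per_ml = 4e7, volume_ul = 100),
    list(species_id = "SA", cfu_per_ml = 1.5e7, volume_ul = 100)))
  set.seed(78)
  tot <- c(PA = 0, SA = 0)
  for (i in 1:3000) {
    cs <- load_droplet(mix = mix)$cells
    tot["PA"] <- tot["PA"] + sum(cs$species == "PA")
    tot["SA"] <- tot["SA"] + sum(cs$species == "SA")
  }
  lam_pa <- expected_cells_per_droplet(2e7, ellipsoid_volume_pl(
    droplet_geometry()))
  expect_lt(abs(tot[["PA"]] / 3000 - lam_pa), 3 * sqrt(lam_pa / 3000))
  # ratio SA:PA tracks the CFU ratio 1.5:4
  expect_lt(abs(tot[["SA"]] / tot[["PA"]] - 1.5 / 4), 0.08)
})

test_that("all cells stay inside the droplet and replay is bit-identical", {
  st <- load_droplet(lambda = c(PA = 6, SA = 6), lambda_phage = 0,
                     seed = 10)
  res <- simulate_droplet(st, duration_min = 60, seed = 20)
  a <- droplet_geometry()$diameter_um / 2
  c_axis <- droplet_geometry()$height_um / 2
  for (fr in res$frames) {
    if (nrow(fr))
      expect_true(all((fr$x / a)^2 + (fr$y / a)^2 +
                        (fr$z / c_axis)^2 <= 1 + 1e-9))
  }
  st2 <- load_droplet(lambda = c(PA = 6, SA = 6), lambda_phage = 0,
                      seed = 10)
  res2 <- simulate_droplet(st2, duration_min = 60, seed = 20)
  expect_identical(res$events, res2$events)
  expect_identical(res$truth, res2$truth)
})

test_that("phage bookkeeping is exact integer conservation", {
  st <- load_droplet(lambda = c(PA = 10), lambda_phage = 50, seed = 30)
  init <- st$free_phage
  for (i in 1:400) {
    st <- sim_step(st, 0.5)
    expect_identical(st$free_phage,
                     init + st$cumulative_released - st$cumulative_adsorbed)
  }
  expect_gt(st$cumulative_lysed, 0)  # infections actually happened
})

test_that("a fixed-burst lysis releases exactly the burst size", {
  st <- load_droplet(lambda = c(PA = 5), lambda_phage = 0, seed = 41)
  expect_gt(nrow(st$cells), 0)
  st$free_phage <- 5
  st$initial_phage <- 5
  st$phage <- phage_params(burst_size = 45, latent_sd_min = 0,
                           adsorption_rate = 10, fixed_burst = TRUE)
  # prevent divisions from interfering
  st$cells$next_division_min <- 1e9
  st$cells <- st$cells[1, , drop = FALSE]
  st <- sim_step(st, 0.5)          # certain infection at this rate
  expect_equal(st$cells$stage, "infected_latent")
  expect_equal(st$free_phage, 4)
  for (i in seq_len(100)) st <- sim_step(st, 0.5)
  expect_equal(nrow(st$cells), 0)
  expect_equal(st$free_phage, 4 + 45)
  expect_equal(st$cumulative_released, 45)
})

test_that("insusceptible cocci are untouched by a phage pool (seed-paired)", {
  mk <- function(phage_pool) {
    st <- load_droplet(lambda = c(SA = 8), lambda_phage = 0, seed = 55)
    st$free_phage <- phage_pool
    st$initial_phage <- phage_pool
    simulate_droplet(st, duration_min = 60, seed = 66)
  }
  with_phage <- mk(500)
  without <- mk(0)
  expect_identical(with_phage$events, without$events)
  expect_identical(
    with_phage$truth$true_count[with_phage$truth$species == "SA"],
    without$truth$true_count[without$truth$species == "SA"])
})

test_that("infected rods pass through a spheroplast stage before lysis", {
  st <- load_droplet(lambda = c(PA = 8), lambda_phage = 200, seed = 70)
  st$phage <- phage_params(adsorption_rate = 1, latent_sd_min = 0)
  saw_spheroplast <- FALSE
  for (i in 1:120) {
    st <- sim_step(st, 0.5)
    if (any(st$cells$morphology == "spheroplast")) saw_spheroplast <- TRUE
  }
  expect_true(saw_spheroplast)
  expect_gt(st$cumulative_lysed, 0)
})

test_that("halving dt does not shift the recovered doubling time", {
  td_for_dt <- function(dt) {
    mean_counts <- NULL
    for (s in 1:6) {
      st <- load_droplet(lambda = c(PA = 5), lambda_phage = 0,
                         seed = 300 + s)
      res <- simulate_droplet(st, duration_min = 100, dt_min = dt,
                              seed = 400 + s)
      pa <- res$truth[res$truth$species == "PA", ]
      mean_counts <- if (is.null(mean_counts)) pa$true_count
                     else mean_counts + pa$true_count
    }
    tt <- seq(0, 100, 5)
    fit <- stats::lm(log(mean_counts / 6) ~ tt)
    log(2) / coef(fit)[2]
  }
  expect_lt(abs(td_for_dt(0.5) / td_for_dt(0.25) - 1), 0.10)
})

test_that("each visible cell spans >= 5 consecutive slices before misses", {
  cells <- sparse_cells()
  res <- make_static_result(cells, n_frames = 1)
  dets <- emit_detections(res, droplet_meta(), noiseless(), seed = 81)
  for (i in seq_len(nrow(cells))) {
    x_um <- cells$x[i] + 640 * 0.17 / 2
    mine <- dets[abs(dets$cx * 640 * 0.17 - x_um) < 0.5, ]
    expect_gte(nrow(mine), 5)
    zs <- sort(mine$z_index)
    expect_true(all(diff(zs) == 1))
  }
})

test_that("injected static debris is exactly what static removal deletes", {
  # seeded run in which the three debris sources stay clear of real cells,
  # the precondition for exact removal (a debris point merging with a
  # passing cell is legitimately not a static track at that frame)
  st <- load_droplet(lambda = c(PA = 4), lambda_phage = 0, seed = 901)
  res <- simulate_droplet(st, duration_min = 60, seed = 911)
  meta <- droplet_meta()
  dets <- emit_detections(res, meta, noiseless(n_static_debris = 3),
                          seed = 921)
  debris <- attr(dets, "debris")
  expect_equal(nrow(debris), 3)
  with_static <- count_droplet(dets, meta, static_persistence = Inf)
  cleaned <- count_droplet(dets, meta)
  removed <- nrow(with_static$cells) - nrow(cleaned$cells)
  n_frames <- length(res$frames)
  expect_equal(removed, 3 * n_frames)
  # none of the surviving cell points sits on a debris position
  for (i in 1:3) {
    d <- sqrt((cleaned$cells$x_um - (debris[i, 1] + 640 * 0.17 / 2))^2 +
                (cleaned$cells$y_um - (debris[i, 2] + 480 * 0.17 / 2))^2 +
                (cleaned$cells$z_um - debris[i, 3])^2)
    expect_true(all(d > 0.5))
  }
})

test_that("one-step curve has the assay's step shape and plateau ratio", {
  # zero jitter, fixed burst 45, 10 cells: 10 -> 450 exactly at the latent
  cur <- emit_one_step_curve(phage_params(latent_sd_min = 0,
                                          fixed_burst = TRUE),
                             n_infected = 10, sampling_min = 1, seed = 7)
  expect_equal(cur$pfu[cur$times_min < 37], rep(10, 37))
  expect_equal(cur$pfu[cur$times_min >= 37][1], 450)
  expect_equal(estimate_burst_size(cur$times_min, cur$pfu), 45)
  expect_equal(estimate_latent_period(cur$times_min, cur$pfu), 37)
})

test_that("rendered slices compose the ring and respond to focus", {
  empty <- render_slice_image(NULL, slice_z = 0, noise_sd = 0)
  ring <- render_trap_image(center_px = c(320, 240),
                            radius_px = min(30 / 0.17, 238),
                            noise_sd = 0)
  expect_identical(empty, ring)
  one <- sparse_cells()[2, ]
  in_plane <- render_slice_image(one, slice_z = one$z, noise_sd = 0)
  off_plane <- render_slice_image(one, slice_z = one$z + 1.4, noise_sd = 0)
  # darker (stronger) blob at the cell pixel when the slice is at its plane
  px <- round((one$x + 640 * 0.17 / 2) / 0.17)
  py <- round((one$y + 480 * 0.17 / 2) / 0.17)
  expect_lt(in_plane[py, px], off_plane[py, px])
  a <- render_slice_image(sparse_cells(), slice_z = 0, seed = 4)
  b <- render_slice_image(sparse_cells(), slice_z = 0, seed = 4)
  expect_identical(a, b)
})
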