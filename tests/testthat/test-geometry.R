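# Droplet geometry, encapsulation statistics, calibration and MOI.

test_that("ellipsoid volume matches the platform droplet and scales exactly", {
  expect_equal(ellipsoid_volume_pl(droplet_geometry(60, 6)), 11.30973,
               tolerance = 1e-6)
  expect_equal(round(ellipsoid_volume_pl(droplet_geometry(60, 6))), 11)
  # sphere special case
  expect_equal(ellipsoid_volume_pl(droplet_geometry(2, 2)),
               (4 / 3) * pi / 1000, tolerance = 1e-12)
  # linear in height, quadratic in diameter (exact algebra)
  v0 <- ellipsoid_volume_pl(droplet_geometry(60, 6))
  expect_equal(ellipsoid_volume_pl(droplet_geometry(60, 3)), v0 / 2)
  expect_equal(ellipsoid_volume_pl(droplet_geometry(30, 6)), v0 / 4)
  for (d in c(10, 45, 80)) {
    h <- d / 10
    v <- ellipsoid_volume_pl(droplet_geometry(d, h))
    expect_equal(v, (4 / 3) * pi * (d / 2)^2 * (h / 2) / 1000)
  }
  expect_error(droplet_geometry(-60, 6), "must be > 0")
  expect_error(droplet_geometry(6, 60), "height")
})

test_that("OD600 to CFU calibration is linear through the origin", {
  cal <- species_calibration("PA", cfu_per_ml_per_od = 1e8)
  expect_equal(od_to_cfu(cal, 0), 0)
  expect_equal(od_to_cfu(cal, 0.5), 5e7)
  expect_equal(od_to_cfu(cal, 1.0), 2 * od_to_cfu(cal, 0.5))
  expect_error(od_to_cfu(cal, -0.1), "nonnegative")
  # default PA slope is the through-origin least-squares fit to the pairs
  pairs <- calibration_pairs("PA")
  slope <- sum(pairs$od600 * pairs$cfu_per_ml) / sum(pairs$od600^2)
  expect_equal(species_calibration("PA")$cfu_per_ml_per_od, slope)
  # prediction at OD 0.11 is commensurate with that row's plate count (6e7);
  # the calibration data scatter allows ~25% deviation
  pred <- od_to_cfu(species_calibration("PA"), 0.11)
  expect_lt(abs(pred - 6e7) / 6e7, 0.30)
})

test_that("expected cells per droplet converts pL and CFU/mL correctly", {
  expect_equal(expected_cells_per_droplet(4e8, 11.31), 4.524)
  expect_equal(expected_cells_per_droplet(0, 11.31), 0)
  expect_equal(expected_cells_per_droplet(8e8, 11.31),
               2 * expected_cells_per_droplet(4e8, 11.31))
})

test_that("occupancy distribution is the Poisson pmf", {
  expect_equal(unname(occupancy_distribution(0, 5)), c(1, rep(0, 5)))
  expect_equal(unname(occupancy_distribution(1, 0)), exp(-1))
  # Monte-Carlo oracle at lambda = 2: cumulative P(k <= 5) vs frequency
  set.seed(71)
  draws <- rpois(1e5, 2)
  p5 <- sum(occupancy_distribution(2, 5))
  freq <- mean(draws <= 5)
  se <- sqrt(p5 * (1 - p5) / 1e5)
  expect_lt(abs(freq - p5), 3 * se)
  # law of large numbers for the sampled mean
  expect_lt(abs(mean(draws) - 2), 3 * sqrt(2 / 1e5))
  expect_error(occupancy_distribution(-1), ">= 0")
})

test_that("MOI reproduces the exactly-consistent lysis conditions", {
  rows <- lysis_conditions()
  moi_of <- function(row, scale = 1) {
    compute_moi(inoculum_mix(
      species = list(list(species_id = "PA", cfu_per_ml = row$pa_cfu_per_ml,
                          volume_ul = row$cell_volume_ul * scale)),
      phage_titer_pfu_per_ml = row$phage_titer_pfu_per_ml,
      phage_volume_ul = row$phage_volume_ul * scale))
  }
  expect_equal(moi_of(rows[rows$experiment == "PA lysis 1", ]), 20)
  expect_equal(moi_of(rows[rows$experiment == "Poly lysis 1", ]), 2.5)
  # invariant to simultaneous scaling of all volumes
  r <- rows[1, ]
  expect_equal(moi_of(r, scale = 7.3), moi_of(r))
  # equal particle and cell counts
  eq <- inoculum_mix(species = list(list(species_id = "PA",
                                         cfu_per_ml = 1e8,
                                         volume_ul = 50)),
                     phage_titer_pfu_per_ml = 1e8, phage_volume_ul = 50)
  expect_equal(compute_moi(eq), 1)
  expect_error(compute_moi(inoculum_mix(
    species = list(list(species_id = "PA", cfu_per_ml = 0,
                        volume_ul = 100)),
    phage_titer_pfu_per_ml = 1e8, phage_volume_ul = 10)), "undefined")
})

test_that("multi-species MOI sums host cells", {
  mix <- inoculum_mix(
    species = list(list(species_id = "PA", cfu_per_ml = 2e8,
                        volume_ul = 100),
                   list(species_id = "SA", cfu_per_ml = 2e8,
                        volume_ul = 100)),
    phage_titer_pfu_per_ml = 4e8, phage_volume_ul = 100)
  expect_equal(compute_moi(mix), 1)
})
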