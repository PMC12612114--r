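# Detection parsing, physical conversion, Z-stack deduplication, species
# voting, static removal, smoothing and time assignment.

test_that("detection files parse with validation and line diagnostics", {
  d <- parse_detection_file("0 0.5 0.5 0.02 0.05 0.91")
  expect_equal(nrow(d), 1)
  expect_equal(d$class_id, 0L)
  expect_equal(d$conf, 0.91)
  expect_equal(nrow(parse_detection_file(character())), 0)
  expect_error(parse_detection_file("1 1.5 0.5 0.02 0.05 0.9"),
               "cx.*out of range")
  expect_error(parse_detection_file(c("0 0.5 0.5 0.1 0.1 0.9",
                                      "0 0.5 0.5 0.1 0.1")),
               "line 2")
  expect_error(parse_detection_file("2 0.5 0.5 0.1 0.1 0.9"), "class_id")
})

test_that("confidence filter is strictly greater-than", {
  d <- parse_detection_file(c("0 0.5 0.5 0.1 0.1 0.39",
                              "0 0.5 0.5 0.1 0.1 0.40",
                              "0 0.5 0.5 0.1 0.1 0.41"))
  expect_equal(filter_confidence(d)$conf, 0.41)
  expect_equal(nrow(filter_confidence(d, 1)), 0)
  expect_equal(nrow(filter_confidence(d, 0)), 3)
})

test_that("physical conversion follows the pixel grid and slice spacing", {
  meta <- zstack_meta(microns_per_pixel = 0.17, z0_um = -10)
  d <- parse_detection_file("0 0.5 0.5 0.02 0.05 0.9", z_index = 0L)
  p <- to_physical(d, meta)
  expect_equal(p$x_um, 0.5 * 640 * 0.17)
  expect_equal(p$y_um, 0.5 * 480 * 0.17)
  expect_equal(p$z_um, -10)
  meta2 <- zstack_meta(microns_per_pixel = 0.34, z0_um = -10)
  expect_equal(to_physical(d, meta2)$x_um, 2 * p$x_um)
  d2 <- parse_detection_file("0 0.5 0.5 0.02 0.05 0.9", z_index = 7L)
  expect_equal(to_physical(d2, meta)$z_um, -10 + 7 * 0.5)
})

test_that("exclusion sphere merges same-cell slices and keeps distinct cells", {
  meta <- zstack_meta(microns_per_pixel = 1, z0_um = 0)
  mk <- function(x_px, z_index, cls = 0)
    data.frame(t_index = 0L, z_index = z_index, class_id = cls,
               cx = x_px / 640, cy = 0.5, w = 0.01, h = 0.01, conf = 0.9)
  # 1 um apart in adjacent slices -> one cell
  two_close <- rbind(mk(100, 0L), mk(100.87, 1L))  # ~1 um euclidean
  expect_equal(nrow(merge_zstack(two_close, meta)), 1)
  # 4 um apart -> two cells
  two_far <- rbind(mk(100, 0L), mk(104, 1L))
  expect_equal(nrow(merge_zstack(two_far, meta)), 2)
  # output count never exceeds input; equality when all separations large
  far <- do.call(rbind, lapply(0:5, function(i) mk(100 + 10 * i, 0L)))
  expect_equal(nrow(merge_zstack(far, meta)), 6)
})

test_that("greedy linkage equals single-linkage components on clustered data", {
  meta <- zstack_meta(microns_per_pixel = 1, z0_um = 0)
  set.seed(5)
  for (rep in 1:60) {
    inst <- random_cluster_instance(sample(2:8, 1))
    dets <- data.frame(t_index = 0L, z_index = 0L, class_id = 0L,
                       cx = 0.5, cy = 0.5, w = 0.01, h = 0.01, conf = 0.9,
                       x_um = inst[, 1], y_um = inst[, 2], z_um = inst[, 3])
    got <- nrow(merge_zstack(dets, meta))
    oracle <- max(phagedrop:::single_linkage_components(inst[, 1:3], 1.5))
    expect_equal(got, oracle)
    expect_equal(got, max(inst[, 4]))
  }
})

test_that("deduplication is permutation-stable under the documented order", {
  meta <- zstack_meta(microns_per_pixel = 1, z0_um = 0)
  set.seed(8)
  inst <- random_cluster_instance(5)
  dets <- data.frame(t_index = 0L, z_index = 0L, class_id = 0L,
                     cx = 0.5, cy = 0.5, w = 0.01, h = 0.01, conf = 0.9,
                     x_um = inst[, 1], y_um = inst[, 2], z_um = inst[, 3])
  ref <- merge_zstack(dets, meta)
  for (i in 1:5) {
    perm <- dets[sample(nrow(dets)), , drop = FALSE]
    got <- merge_zstack(perm, meta)
    expect_equal(got[order(got$x_um), -5], ref[order(ref$x_um), -5],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("species voting follows the majority with confidence tie-break", {
  expect_equal(vote_class(c(0, 0, 1)), "PA")
  expect_equal(vote_class(1L), "SA")
  expect_equal(vote_class(c(0, 1), confs = c(0.6, 0.9)), "SA")
  expect_equal(vote_class(c(0, 1), confs = c(0.9, 0.6)), "PA")
  expect_error(vote_class(integer()), "empty")
})

test_that("static tracks are removed, moving cells retained", {
  static <- data.frame(species = "PA", x_um = 10, y_um = 10, z_um = 0,
                       t_min = seq(0, 45, 5), n_detections = 3L,
                       pa_vote_fraction = 1, mean_confidence = 0.9)
  mover <- data.frame(species = "PA", x_um = 10 + 2 * (0:9), y_um = 30,
                      z_um = 0, t_min = seq(0, 45, 5), n_detections = 3L,
                      pa_vote_fraction = 1, mean_confidence = 0.9)
  both <- rbind(static, mover)
  kept <- remove_static(both, displacement_tol_um = 0.5,
                        min_persistence = 5)
  expect_equal(nrow(kept), 10)
  expect_true(all(kept$y_um == 30))
  # a short static episode below the persistence threshold survives
  brief <- static[1:3, ]
  expect_equal(nrow(remove_static(rbind(brief, mover), 0.5, 5)), 13)
  # counts never increase
  expect_lte(nrow(kept), nrow(both))
})

test_that("moving average matches the documented window geometry", {
  const <- data.frame(time_min = seq(0, 55, 5), species = "PA",
                      raw_count = 7)
  sm <- moving_average_counts(const, window = 8)
  expect_true(all(sm$smoothed_count == 7))
  expect_true(all(sm$smoothed_sd == 0))
  ramp <- data.frame(time_min = seq(0, 75, 5), species = "PA",
                     raw_count = 0:15)
  sm <- moving_average_counts(ramp, window = 8)
  # 0-based index 7 covers values 4..11
  expect_equal(sm$smoothed_count[8], 7.5)
  # full interior windows preserve the local mean: identity at window 1
  sm1 <- moving_average_counts(ramp, window = 1)
  expect_equal(sm1$smoothed_count, as.numeric(ramp$raw_count))
  # smoothed values stay within the raw range
  expect_true(all(sm$smoothed_count >= min(ramp$raw_count) &
                    sm$smoothed_count <= max(ramp$raw_count)))
  expect_error(moving_average_counts(const, window = 99), "window")
})

test_that("time assignment is zero-based, sorted, and validated", {
  expect_equal(assign_times(c("10:00:00", "10:05:00", "10:17:30")),
               c(0, 5, 17.5))
  expect_equal(assign_times("10:00:00"), 0)
  expect_warning(t2 <- assign_times(c("10:05:00", "10:00:00")),
                 "out of order")
  expect_equal(t2, c(0, 5))
  expect_error(assign_times(c("10:00:00", "not-a-time")), "unparseable")
})

test_that("detection directory round-trips through the text dialect", {
  res <- make_static_result(sparse_cells(), n_frames = 3)
  meta <- droplet_meta()
  dets <- emit_detections(res, meta, noiseless(), seed = 31)
  dir <- file.path(tempdir(), "dets-roundtrip")
  write_detection_dir(dets, dir, meta, droplet_id = 7L)
  back <- read_detection_dir(dir, droplet_id = 7L)
  expect_equal(nrow(back), nrow(dets))
  expect_equal(sort(back$cx), sort(dets$cx), tolerance = 1e-5)
  unlink(dir, recursive = TRUE)
})
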