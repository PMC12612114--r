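# Shared fixture builders for the test suite. All fixtures are generated in
# code; nothing is read from disk.

# A sim_result whose frames repeat a hand-placed static cell layout --
# bypasses the stochastic simulator for exact end-to-end identity checks.
make_static_result <- function(cells, n_frames = 10,
                               geometry = droplet_geometry()) {
  structure(list(frames = rep(list(cells), n_frames),
                 state = list(geometry = geometry),
                 frame_interval_min = 5),
            class = "sim_result")
}

# Hand-placed, well-separated (> 3 um pairwise) cells inside the ellipsoid.
sparse_cells <- function() {
  data.frame(id = 1:5,
             species = c("PA", "PA", "SA", "PA", "SA"),
             x = c(-20, 0, 15, 10, -8),
             y = c(0, 10, -12, 18, -20),
             z = c(-2, 0, 1, 2, -1),
             morphology = c("rod", "rod", "cocci", "rod", "cocci"),
             stage = "healthy", next_division_min = 1e9,
             burst_time_min = NA_real_, burst_draw = NA_real_,
             attached_to = NA_integer_, parent = NA_integer_)
}

# Noise model that emits every visible detection with near-certain high
# confidence: the "zero-noise" identity path.
noiseless <- function(n_static_debris = 0L) {
  noise_model(miss_prob_center = 0, miss_prob_boundary = 0,
              misclass_prob = 0, n_static_debris = n_static_debris,
              conf_shape1 = 60, conf_shape2 = 1)
}

# Stack metadata whose z range covers the droplet (z = 0 at -10 um).
droplet_meta <- function() zstack_meta(z0_um = -10)

# Clustered random instance for deduplication tests: cluster centers >= 4 um
# apart, members within 0.5 um of the center, so greedy linkage and
# single-linkage components agree and the true partition is known.
random_cluster_instance <- function(n_clusters, max_members = 4) {
  centers <- matrix(NA_real_, 0, 3)
  while (nrow(centers) < n_clusters) {
    p <- c(runif(1, -20, 20), runif(1, -15, 15), runif(1, -2.5, 2.5))
    if (nrow(centers) == 0 ||
        min(sqrt(colSums((t(centers) - p)^2))) > 4) {
      centers <- rbind(centers, p)
    }
  }
  pts <- do.call(rbind, lapply(seq_len(n_clusters), function(i) {
    k <- sample(max_members, 1)
    offs <- matrix(runif(3 * k, -0.5 / sqrt(3), 0.5 / sqrt(3)), ncol = 3)
    cbind(sweep(offs, 2, centers[i, ], "+"), cluster = i)
  }))
  pts
}
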