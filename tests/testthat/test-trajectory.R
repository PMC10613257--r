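one_frame <- function(rows) as_trajectory(build_toy(rows), frame_spacing = 0.1)

const_series <- function(values, dt = 0.1) {
  structure(list(times = (seq_along(values) - 1) * dt, values = values,
                 pair = c("a", "b")), class = "distance_series")
}

test_that("COM distances follow the unweighted C-alpha mean", {
  tr <- one_frame(rbind(atom_df(1, "GLY", "CA", "C", 0, 0, 0),
                        atom_df(2, "GLY", "CA", "C", 3, 4, 0)))
  a <- domain_definition("a", c(1, 1))
  b <- domain_definition("b", c(2, 2))
  expect_equal(com_distance_series(tr, a, b)$values, 5)

  tr2 <- one_frame(rbind(atom_df(1, "GLY", "CA", "C", 0, 0, 0),
                         atom_df(2, "GLY", "CA", "C", 6, 0, 0),
                         atom_df(3, "GLY", "CA", "C", 2, 0, 0)))
  b2 <- domain_definition("b", c(2, 3))
  expect_equal(com_distance_series(tr2, a, b2)$values, 4)  # COM at (4,0,0)
  expect_error(com_distance_series(tr2, domain_definition("far", c(50, 60)),
                                   b2), "far")
})

test_that("COM series is symmetric and matches planted separations", {
  gen <- make_dumbbell_trajectory(dumbbell_spec(n_frames = 200, seed = 13))
  tr <- gen$trajectory; tru <- gen$truth
  d_ab <- com_distance_series(tr, tru$domain_a, tru$domain_b)
  d_ba <- com_distance_series(tr, tru$domain_b, tru$domain_a)
  expect_equal(d_ab$values, d_ba$values)
  # per-frame random rigid transforms are already baked in by the generator
  expect_lt(max(abs(d_ab$values - tru$separations)), 1e-6)
})

test_that("a constant-separation dumbbell yields a constant series", {
  sp <- dumbbell_spec(n_frames = 100, jitter_sd = 0,
                      transition_probs = diag(2), start_state = "closed",
                      seed = 17)
  gen <- make_dumbbell_trajectory(sp)
  d <- com_distance_series(gen$trajectory, gen$truth$domain_a,
                           gen$truth$domain_b)
  expect_lt(max(abs(d$values - 54)), 1e-6)
})

test_that("exponential moving average follows its recurrence", {
  # alpha = 2/(span_frames + 1) = 0.5 when the span covers 3 frames
  d <- const_series(c(0, 1, 1, 1))
  sm <- exponential_moving_average(d, span = 0.3)
  expect_equal(sm$values, c(0, 0.5, 0.75, 0.875))
  # constant series is a fixed point
  cs <- const_series(rep(7, 50))
  expect_equal(exponential_moving_average(cs, span = 1)$values, rep(7, 50))
  # first output equals first input
  set.seed(3)
  rnd <- const_series(runif(30, 50, 60))
  expect_equal(exponential_moving_average(rnd, span = 1)$values[1],
               rnd$values[1])
  expect_error(exponential_moving_average(rnd, span = 0.01),
               "frame spacing")
})

test_that("longer EMA spans lag harder behind a step", {
  d <- const_series(c(rep(0, 10), rep(1, 40)))
  fast <- exponential_moving_average(d, span = 0.5)$values
  slow <- exponential_moving_average(d, span = 3)$values
  expect_true(all(slow[15:50] <= fast[15:50] + 1e-12))
})

test_that("block averaging partitions the tail and keeps its identities", {
  # eight 50-frame blocks holding constants 1..8 (dt = 1 ns)
  d <- const_series(rep(1:8, each = 50), dt = 1)
  bs <- block_average(d, n_blocks = 8, block_len = 50, tail_len = 400)
  expect_equal(bs$block_means, 1:8)
  expect_equal(bs$mean, 4.5)
  expect_equal(bs$sd, sd(1:8))
  # constant series: sd exactly 0
  bc <- block_average(const_series(rep(3.7, 4000)), 8, 50, 400)
  expect_equal(bc$mean, 3.7)
  expect_equal(bc$sd, 0)
  # identities on random input
  set.seed(5)
  dr <- const_series(rnorm(5000, 60, 3))
  br <- block_average(dr, 8, 50, 400)
  expect_equal(br$mean, mean(br$block_means))
  expect_equal(br$sd, sd(br$block_means))
  expect_equal(br$n_blocks * br$block_len, br$tail_len)
})

test_that("block averaging rejects impossible partitions", {
  d <- const_series(rnorm(5000, 60, 3))
  expect_error(block_average(d, 7, 50, 400), "non-divisible")
  expect_error(block_average(const_series(rnorm(100)), 8, 50, 400),
               "shorter than")
})

test_that("block mean estimates an iid Gaussian mean within sampling error", {
  set.seed(29)
  d <- const_series(rnorm(4000, 62.9, 5))
  bs <- block_average(d, 8, 50, 400)
  expect_lt(abs(bs$mean - 62.9), 3 * 5 / sqrt(4000))
})

test_that("replicate aggregation pools block means", {
  d1 <- const_series(rep(60, 4000)); d2 <- const_series(rep(62, 4000))
  d3 <- const_series(rep(64, 4000))
  bs <- lapply(list(d1, d2, d3), block_average)
  agg <- aggregate_replicates(bs)
  expect_equal(agg$mean, 62)
  expect_equal(agg$sd, sd(rep(c(60, 62, 64), each = 8)))
  # single replicate: identity
  one <- aggregate_replicates(list(bs[[1]]))
  expect_equal(one$mean, bs[[1]]$mean)
  expect_equal(length(one$block_means), 8)
  # planted block means: direct pooled arithmetic
  set.seed(31)
  ds <- lapply(1:3, function(i) const_series(rnorm(4000, 60 + i, 2)))
  bss <- lapply(ds, block_average)
  agg2 <- aggregate_replicates(bss)
  pooled <- unlist(lapply(bss, `[[`, "block_means"))
  expect_equal(agg2$mean, mean(pooled))
  expect_equal(agg2$sd, sd(pooled))
  # mismatched schemes are rejected
  expect_error(aggregate_replicates(list(bs[[1]],
    block_average(d1, 4, 100, 400))), "mismatched")
})

test_that("the KDE is a normalised fixed-bandwidth Gaussian estimate", {
  k <- kde_density(rep(42, 100), bandwidth = 3)
  expect_equal(kde_modes(k), 42, tolerance = 0.1)
  integ <- sum(diff(k$grid) * (head(k$density, -1) + tail(k$density, -1)) / 2)
  expect_equal(integ, 1, tolerance = 1e-3)
  # against the closed-form mixture: two well-separated clusters
  set.seed(37)
  v <- c(rnorm(4000, 38, 0.5), rnorm(4000, 63, 0.5))
  k2 <- kde_density(v, bandwidth = 3, from = 20, to = 80, n = 2048)
  m <- kde_modes(k2)
  expect_equal(length(m), 2)
  expect_lt(abs(m[1] - 38), 0.5)
  expect_lt(abs(m[2] - 63), 0.5)
  expect_error(kde_density(numeric(0)), "at least one")
})

test_that("state classification applies the reference + half-sd cutoff", {
  d <- const_series(c(62.9, 50, 56.6, 56.7))
  cls <- classify_states(d, reference_distance = 54, reference_sd = 5.3)
  expect_equal(cls$cutoff, 56.65)
  expect_identical(cls$labels, c("open", "closed", "closed", "open"))
  expect_equal(cls$open_fraction, 0.5)
  # all frames below the cutoff
  low <- classify_states(const_series(rep(50, 10)), 54, 5.3)
  expect_equal(low$open_fraction, 0)
  # monotone: raising the reference never increases the open fraction
  set.seed(41)
  dr <- const_series(rnorm(500, 58, 4))
  fr <- vapply(seq(50, 66, by = 2),
               function(r) classify_states(dr, r, 5.3)$open_fraction,
               numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("classification recovers the hidden states exactly when noiseless", {
  sp <- dumbbell_spec(n_frames = 2000, jitter_sd = 0, seed = 43)
  gen <- make_dumbbell_trajectory(sp)
  d <- com_distance_series(gen$trajectory, gen$truth$domain_a,
                           gen$truth$domain_b)
  # cutoff between the means: labels must equal the ground truth
  cls <- classify_states(d, reference_distance = 54, reference_sd = 9)
  expect_identical(cls$labels, gen$truth$states)
  expect_equal(cls$open_fraction, mean(gen$truth$states == "open"))
})

test_that("rmsd_vs_start removes rigid motion and sees real deformation", {
  # rigidly moved frames: all zero
  set.seed(47)
  base <- matrix(rnorm(3 * 20, sd = 5), ncol = 3)
  nfr <- 6
  coords <- array(NA_real_, dim = c(20, 3, nfr))
  for (f in seq_len(nfr)) {
    tr <- random_rigid()
    coords[, , f] <- sweep(base %*% t(tr$R), 2, tr$t, "+")
  }
  atoms <- data.frame(chain = "A", res_index = 1:20, res_name = "GLY",
                      atom_name = "CA", element = "C", het = FALSE)
  traj <- as_trajectory(new_structure(atoms, coords))
  r <- rmsd_vs_start(traj, domain_definition("all", c(1, 20)))
  expect_equal(r$values[1], 0, tolerance = 1e-9)
  expect_lt(max(r$values), 1e-9)

  # planted per-atom displacement: agree with the rotation-search oracle
  disp <- matrix(rnorm(3 * 20, sd = 2), ncol = 3)
  coords2 <- coords[, , 1:2]
  coords2[, , 2] <- base + disp
  traj2 <- as_trajectory(new_structure(atoms, coords2))
  r2 <- rmsd_vs_start(traj2, domain_definition("all", c(1, 20)))
  frame1 <- coords2[, , 1]
  expect_equal(r2$values[2], oracle_min_rmsd(base + disp, frame1),
               tolerance = 1e-3)
})

test_that("trajectory construction validates its time base", {
  gen <- make_dumbbell_trajectory(dumbbell_spec(n_frames = 4, seed = 3))
  s <- gen$trajectory$structure
  expect_error(as_trajectory(s, times = c(0, 1, 2, 2.5)), "uniform")
  expect_error(as_trajectory(s, times = c(0, 1)), "length")
  tr <- as_trajectory(s, frame_spacing = 0.5)
  expect_equal(tr$times, c(0, 0.5, 1, 1.5))
})
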