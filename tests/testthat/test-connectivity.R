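test_that("torus distance wraps per axis and attains the known maximum", {
  expect_equal(torus_distance(c(0, 0), c(49, 0), 50), 1)
  expect_equal(torus_distance(c(0, 0), c(3, 4), 50), 5)
  # maximum over all pairs from the origin on a side-50 torus
  co <- expand.grid(x = 0:49, y = 0:49)
  d <- torus_distance(cbind(0, 0)[rep(1, nrow(co)), ], as.matrix(co), 50)
  expect_equal(max(d), 25 * sqrt(2))
  expect_error(torus_distance(c(0, 0), c(50, 0), 50), "coordinates")
})

test_that("local connections: exact out-degree, cutoff, no self-edges or duplicates", {
  spec <- lattice_spec(50)
  cfg <- connectivity_config(seed = 7)
  set.seed(cfg$seed)
  e <- build_local_connections(spec, cfg, "exc")
  expect_equal(nrow(e), 50^2 * 5)
  expect_true(all(table(e$src) == 5))
  expect_true(all(e$src != e$dst))
  expect_false(any(duplicated(paste(e$src, e$dst))))
  d <- torus_distance(wcresonance:::unit_coords(e$src, 50),
                      wcresonance:::unit_coords(e$dst, 50), 50)
  expect_true(all(d <= 14))  # 700 um cutoff at 50 um spacing
  expect_true(all(e$weight == cfg$ce_strength))
  # k = 0 gives an empty edge set
  e0 <- build_local_connections(spec, connectivity_config(k_exc = 0), "exc")
  expect_equal(nrow(e0), 0)
})

test_that("accepted local offsets follow the rejection-sampled Gaussian law", {
  # independent naive oracle: draw offsets one at a time with the same
  # rejection rule (non-self, rounded radius within cutoff)
  oracle_radii <- function(n, sigma = 5, cutoff = 14, seed = 99) {
    set.seed(seed)
    out <- numeric(0)
    while (length(out) < n) {
      dx <- rnorm(1, 0, sigma)
      dx <- sign(dx) * floor(abs(dx) + 0.5)
      dy <- rnorm(1, 0, sigma)
      dy <- sign(dy) * floor(abs(dy) + 0.5)
      r <- sqrt(dx^2 + dy^2)
      if (r > 0 && r <= cutoff) out <- c(out, r)
    }
    out[seq_len(n)]
  }
  spec <- lattice_spec(50)
  set.seed(3)
  e <- build_local_connections(spec, connectivity_config(seed = 3), "exc")
  pkg_r <- torus_distance(wcresonance:::unit_coords(e$src, 50),
                          wcresonance:::unit_coords(e$dst, 50), 50)
  orc_r <- oracle_radii(length(pkg_r))
  # compare binned distributions; duplicate-rejection within a unit's 5
  # targets perturbs the law only slightly
  br <- c(0, 2, 4, 6, 8, 10, 14.5)
  p1 <- table(cut(pkg_r, br)) / length(pkg_r)
  p2 <- table(cut(orc_r, br)) / length(orc_r)
  expect_lt(max(abs(as.numeric(p1) - as.numeric(p2))), 0.02)
})

test_that("long-range edges: count, distance rule, fraction zero is a no-op", {
  spec <- lattice_spec(50)
  cfg <- connectivity_config(seed = 21)
  net <- build_network(spec, cfg, delay_per_step = 10)
  expect_equal(net$n_long_range, round(0.25 * 50^2 * 5))
  expect_equal(nrow(net$exc), 50^2 * 5 + 3125)
  lr <- net$exc[(50^2 * 5 + 1):nrow(net$exc), ]
  d <- torus_distance(wcresonance:::unit_coords(lr$src, 50),
                      wcresonance:::unit_coords(lr$dst, 50), 50)
  expect_true(all(d > 14))
  cfg0 <- connectivity_config(long_range_fraction = 0, seed = 21)
  net0 <- build_network(spec, cfg0, delay_per_step = 10)
  expect_equal(nrow(net0$exc), 50^2 * 5)
})

test_that("delays are round-half-away distance times rate; zero rate clears them", {
  net <- toy_network_3x3()
  net10 <- assign_delays(net, 10)
  d <- torus_distance(wcresonance:::unit_coords(net$exc$src, 3),
                      wcresonance:::unit_coords(net$exc$dst, 3), 3)
  expect_equal(net10$exc$delay, as.integer(floor(10 * d + 0.5)))
  # adjacent units at rate 10 get delay 10
  adj <- which(d == 1)
  expect_true(all(net10$exc$delay[adj] == 10L))
  net0 <- assign_delays(net10, 0)
  expect_true(all(net0$exc$delay == 0L) && all(net0$inh$delay == 0L))
  # distance 5 at rate 10 gives 50 steps (long-range needs sites beyond the
  # 14-step cutoff, which a side-20 torus barely has, so local edges only)
  spec <- lattice_spec(20)
  n2 <- build_network(spec,
                      connectivity_config(long_range_fraction = 0, seed = 2),
                      10)
  d2 <- torus_distance(wcresonance:::unit_coords(n2$exc$src, 20),
                       wcresonance:::unit_coords(n2$exc$dst, 20), 20)
  i5 <- which(abs(d2 - 5) < 1e-12)
  expect_true(length(i5) > 0 && all(n2$exc$delay[i5] == 50L))
})

test_that("lateral inhibition zeroes outward excitation, maximizes outward inhibition", {
  spec <- lattice_spec(20)
  net <- build_network(spec,
                       connectivity_config(long_range_fraction = 0, seed = 31),
                       10)
  mask <- subnetwork_mask(spec, 8)
  out_e <- mask[net$exc$src] & !mask[net$exc$dst]
  out_i <- mask[net$inh$src] & !mask[net$inh$dst]
  net2 <- apply_lateral_inhibition(net, mask)
  expect_equal(sum(net2$exc$weight[out_e]), 0)
  expect_true(all(net2$inh$weight[out_i] == 1))
  # untouched edges keep their weights; modified count = boundary census
  expect_equal(net2$exc$weight[!out_e], net$exc$weight[!out_e])
  expect_equal(sum(net2$exc$weight != net$exc$weight), sum(out_e))
  expect_equal(sum(net2$inh$weight != net$inh$weight), sum(out_i))
  # whole-lattice mask changes nothing
  net3 <- apply_lateral_inhibition(net, subnetwork_mask(spec))
  expect_identical(net3$exc$weight, net$exc$weight)
})

test_that("sub-network stats: edge conservation, monotone growth, degenerate masks", {
  spec <- lattice_spec(30)
  net <- build_network(spec, connectivity_config(seed = 41), 10)
  full <- subnetwork_connectivity_stats(net, subnetwork_mask(spec))
  expect_equal(full$mean_degree,
               (nrow(net$exc) + nrow(net$inh)) / 30^2)
  expect_equal(full$mean_degree, 5 * (1 + 0.25) + 5, tolerance = 1e-6)
  small <- subnetwork_connectivity_stats(net, subnetwork_mask(spec, 2))
  expect_lte(small$mean_degree, full$mean_degree)
  one <- subnetwork_connectivity_stats(net, subnetwork_mask(spec, 1))
  expect_equal(one$mean_degree, 0)
  expect_error(subnetwork_connectivity_stats(
    net, structure(rep(FALSE, 900), class = "wc_mask")), "empty")
})

test_that("fixed seed reproduces the network bit-identically; serialization round-trips", {
  spec <- lattice_spec(12)
  cfg5 <- connectivity_config(long_range_fraction = 0, seed = 5)
  a <- build_network(spec, cfg5, 10)
  b <- build_network(spec, cfg5, 10)
  expect_identical(a$exc, b$exc)
  expect_identical(a$inh, b$inh)
  c_ <- build_network(spec, connectivity_config(long_range_fraction = 0,
                                                seed = 6), 10)
  expect_false(identical(a$exc, c_$exc))
  path <- tempfile(fileext = ".txt")
  write_network(a, path)
  a2 <- read_network(path)
  expect_equal(a2$exc, a$exc)
  expect_equal(a2$inh, a$inh)
  expect_equal(a2$spec$side, a$spec$side)
  unlink(path)
})
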