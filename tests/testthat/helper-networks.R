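# Small fixtures built in code.

# hand-built 3x3 network with assorted delays and both edge kinds
toy_network_3x3 <- function(delays_exc = c(0L, 1L, 3L, 5L),
                            delays_inh = c(0L, 2L, 4L)) {
  spec <- lattice_spec(3, macrocolumn_side = 2)
  exc <- data.frame(src = c(1L, 2L, 5L, 9L),
                    dst = c(2L, 5L, 9L, 1L),
                    weight = c(0.15, 0.15, 0.15, 0.15),
                    delay = delays_exc)
  inh <- data.frame(src = c(3L, 4L, 7L),
                    dst = c(1L, 9L, 5L),
                    weight = c(0.10, 0.10, 0.10),
                    delay = delays_inh)
  structure(list(spec = spec, cfg = connectivity_config(seed = 1L),
                 exc = exc, inh = inh, n_long_range = 0L,
                 macrocolumn_of = wcresonance:::macrocolumn_labels(spec),
                 delay_per_step = 1),
            class = "wc_network")
}

# network of isolated units (no edges) on a small lattice
isolated_network <- function(side = 2) {
  build_network(lattice_spec(side),
                connectivity_config(k_exc = 0, k_inh = 0,
                                    long_range_fraction = 0, seed = 1L),
                delay_per_step = 0)
}

single_unit_mask <- function(side = 2) {
  m <- rep(FALSE, side^2)
  m[1] <- TRUE
  structure(m, side = as.integer(side), sub_side = 1L, class = "wc_mask")
}
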