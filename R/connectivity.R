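#' Lattice geometry of the simulated cortical sheet
#'
#' Units sit on a \code{side x side} square lattice with periodic boundary
#' conditions; one unit represents a ~50 um cortical minicolumn, so
#' \code{spacing} micrometers separate neighbouring units. Units are grouped
#' into \code{macrocolumn_side x macrocolumn_side} blocks ("macrocolumns")
#' that share a common noise source during simulation.
#'
#' @param side Units per lattice side (>= 2).
#' @param spacing Micrometers per lattice step (default 50).
#' @param macrocolumn_side Units per macrocolumn side (default 10); blocks
#'   truncate at the lattice edge when it does not divide \code{side}.
#' @return An object of class \code{wc_lattice}.
#' @export
lattice_spec <- function(side, spacing = 50, macrocolumn_side = 10) {
  stopifnot(side >= 2, spacing > 0, macrocolumn_side >= 1)
  structure(list(side = as.integer(side), spacing = spacing,
                 macrocolumn_side = as.integer(macrocolumn_side),
                 periodic = TRUE),
            class = "wc_lattice")
}

#' Connectivity generation parameters
#'
#' Local out-connections are drawn with a Gaussian fall-off of SD
#' \code{sigma_local} micrometers, hard-truncated at \code{cutoff}
#' micrometers, with exactly \code{k_exc} excitatory and \code{k_inh}
#' inhibitory local targets per unit. Sparse long-range excitatory edges are
#' added on top, numbering \code{long_range_fraction} of the local excitatory
#' edge count, with uniformly random endpoints beyond the local cutoff.
#' Edge weights are \code{ce_strength} (excitatory, E-to-E) and
#' \code{ci_strength} (inhibitory, E-to-I).
#'
#' @param sigma_local Gaussian SD of local connection offsets, micrometers.
#' @param cutoff Hard radius for local connections, micrometers.
#' @param k_exc,k_inh Local excitatory / inhibitory out-degree per unit.
#' @param long_range_fraction Long-range edges as a fraction of the local
#'   excitatory edge count, in [0, 1].
#' @param ce_strength,ci_strength Connection weights (non-negative).
#' @param seed Integer seed for the connectivity RNG.
#' @return An object of class \code{wc_connectivity_config}.
#' @export
connectivity_config <- function(sigma_local = 250, cutoff = 700,
                                k_exc = 5, k_inh = 5,
                                long_range_fraction = 0.25,
                                ce_strength = 0.15, ci_strength = 0.10,
                                seed = 1L) {
  stopifnot(long_range_fraction >= 0, long_range_fraction <= 1,
            cutoff >= sigma_local, ce_strength >= 0, ci_strength >= 0,
            k_exc >= 0, k_inh >= 0)
  structure(list(sigma_local = sigma_local, cutoff = cutoff,
                 k_exc = as.integer(k_exc), k_inh = as.integer(k_inh),
                 long_range_fraction = long_range_fraction,
                 ce_strength = ce_strength, ci_strength = ci_strength,
                 seed = as.integer(seed)),
            class = "wc_connectivity_config")
}

#' Torus distance between lattice coordinates
#'
#' Euclidean distance with per-axis wrap-around, consistent with the
#' periodic boundary conditions: each axis offset is
#' \code{min(|a - b|, side - |a - b|)}.
#'
#' @param a,b Coordinate pairs (vectors \code{c(x, y)} with entries in
#'   \code{[0, side)}) or two-column matrices of coordinates.
#' @param side Lattice side length.
#' @return Distance(s) in lattice steps.
#' @examples
#' torus_distance(c(0, 0), c(49, 0), 50)  # wrap adjacency: 1
#' @export
torus_distance <- function(a, b, side) {
  a <- matrix(a, ncol = 2)
  b <- matrix(b, ncol = 2)
  if (any(a < 0) || any(a >= side) || any(b < 0) || any(b >= side))
    stop("coordinates must lie in [0, side)")
  d <- abs(a - b)
  d <- pmin(d, side - d)
  sqrt(d[, 1]^2 + d[, 2]^2)
}

# round half away from zero (base round() is round-half-even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# unit index <-> coordinates; 1-based index, 0-based coords, row-major in x
unit_index <- function(x, y, side) as.integer(y) * side + as.integer(x) + 1L
unit_coords <- function(idx, side) {
  cbind(x = (idx - 1L) %% side, y = (idx - 1L) %/% side)
}

#' Build local Gaussian-falloff connections
#'
#' For every unit, draws exactly \code{k} distinct local out-edges: target
#' offsets come from an isotropic 2-D Gaussian with SD
#' \code{sigma_local/spacing} lattice steps, rounded to the nearest lattice
#' site. Draws landing on the source unit, duplicating an already accepted
#' target of the same unit, or farther than \code{cutoff/spacing} steps are
#' rejected and redrawn. Sampling is vectorized over all pending draws.
#'
#' @param spec A \code{\link{lattice_spec}}.
#' @param cfg A \code{\link{connectivity_config}}.
#' @param kind \code{"exc"} or \code{"inh"}; selects the out-degree target
#'   (\code{k_exc}/\code{k_inh}) and weight
#'   (\code{ce_strength}/\code{ci_strength}).
#' @return A data frame with columns \code{src}, \code{dst} (unit indices),
#'   \code{weight} and \code{delay} (initialized to 0; see
#'   \code{\link{assign_delays}}).
#' @export
build_local_connections <- function(spec, cfg, kind = c("exc", "inh")) {
  kind <- match.arg(kind)
  k <- if (kind == "exc") cfg$k_exc else cfg$k_inh
  w <- if (kind == "exc") cfg$ce_strength else cfg$ci_strength
  n <- spec$side^2
  if (k == 0)
    return(data.frame(src = integer(0), dst = integer(0),
                      weight = numeric(0), delay = integer(0)))
  sigma_steps <- cfg$sigma_local / spec$spacing
  cutoff_steps <- cfg$cutoff / spec$spacing
  n_in_disc <- sum(outer(-floor(cutoff_steps):floor(cutoff_steps),
                         -floor(cutoff_steps):floor(cutoff_steps),
                         function(dx, dy) sqrt(dx^2 + dy^2) <= cutoff_steps &
                           !(dx == 0 & dy == 0)))
  if (k > n_in_disc)
    stop("k = ", k, " exceeds the ", n_in_disc, " sites within the cutoff")

  co <- unit_coords(seq_len(n), spec$side)
  src <- rep(seq_len(n), each = k)
  dst <- integer(length(src))
  pending <- seq_along(src)
  for (round_i in 1:1000) {
    m <- length(pending)
    if (m == 0) break
    dx <- round_half_up(stats::rnorm(m, 0, sigma_steps))
    dy <- round_half_up(stats::rnorm(m, 0, sigma_steps))
    ok <- !(dx == 0 & dy == 0) & sqrt(dx^2 + dy^2) <= cutoff_steps
    s <- src[pending]
    tx <- (co[s, 1] + dx) %% spec$side
    ty <- (co[s, 2] + dy) %% spec$side
    dst[pending[ok]] <- unit_index(tx[ok], ty[ok], spec$side)
    # reject duplicates within each source unit's accepted set
    filled <- dst > 0L
    key <- paste(src, dst)
    dup <- duplicated(key) & filled
    dst[dup] <- 0L
    pending <- which(dst == 0L)
  }
  if (length(pending) > 0)
    stop("local connection sampling did not fill all slots")
  data.frame(src = src, dst = dst, weight = w,
             delay = rep(0L, length(src)))
}

#' Add sparse long-range excitatory connections
#'
#' Adds \code{round(long_range_fraction * n_local_exc)} excitatory edges
#' whose endpoints are drawn uniformly over all units, rejecting self-edges,
#' duplicates of existing excitatory edges, and targets inside the local
#' cutoff disc of the source (so "long-range" is well defined). Long-range
#' edges carry the excitatory weight \code{ce_strength}.
#'
#' @param network A \code{wc_network} with local excitatory edges built.
#' @param cfg A \code{\link{connectivity_config}}.
#' @param n_add Explicit edge count; defaults to
#'   \code{round(long_range_fraction * nrow(network$exc))}.
#' @return The network with long-range edges appended to \code{$exc}.
#' @export
add_long_range_connections <- function(network, cfg, n_add = NULL) {
  if (is.null(n_add))
    n_add <- round(cfg$long_range_fraction * nrow(network$exc))
  if (n_add == 0) return(network)
  spec <- network$spec
  n <- spec$side^2
  cutoff_steps <- cfg$cutoff / spec$spacing
  existing <- paste(network$exc$src, network$exc$dst)
  src <- integer(0); dst <- integer(0)
  for (round_i in 1:1000) {
    m <- n_add - length(src)
    if (m == 0) break
    s <- sample.int(n, m, replace = TRUE)
    d <- sample.int(n, m, replace = TRUE)
    dist <- torus_distance(unit_coords(s, spec$side),
                           unit_coords(d, spec$side), spec$side)
    ok <- s != d & dist > cutoff_steps
    key <- paste(s, d)
    ok <- ok & !(key %in% existing) & !duplicated(key) &
      !(key %in% paste(src, dst))
    src <- c(src, s[ok]); dst <- c(dst, d[ok])
  }
  if (length(src) < n_add)
    stop("long-range sampling did not reach the requested count")
  network$exc <- rbind(network$exc,
                       data.frame(src = src, dst = dst,
                                  weight = cfg$ce_strength,
                                  delay = rep(0L, n_add)))
  network$n_long_range <- n_add
  network
}

#' Build the full lattice network
#'
#' Convenience constructor running \code{\link{build_local_connections}} for
#' both edge kinds, \code{\link{add_long_range_connections}}, and
#' \code{\link{assign_delays}}, all under \code{cfg$seed} so a fixed seed
#' yields a bit-identical network.
#'
#' @param spec A \code{\link{lattice_spec}}.
#' @param cfg A \code{\link{connectivity_config}}.
#' @param delay_per_step Integration steps of transmission delay per lattice
#'   step of torus distance (default 10).
#' @param n_long_range Optional fixed long-range edge count overriding
#'   \code{cfg$long_range_fraction}; used by scans that hold long-range
#'   connectivity constant while local degree varies.
#' @return An object of class \code{wc_network}: a list with \code{spec},
#'   edge data frames \code{exc} and \code{inh} (columns \code{src},
#'   \code{dst}, \code{weight}, \code{delay}), \code{macrocolumn_of}, and
#'   the generating configuration.
#' @examples
#' net <- build_network(lattice_spec(10), connectivity_config(seed = 42))
#' nrow(net$exc)  # 10*10*5 local + 25% long-range = 625
#' @export
build_network <- function(spec, cfg, delay_per_step = 10,
                          n_long_range = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  exc <- build_local_connections(spec, cfg, "exc")
  inh <- build_local_connections(spec, cfg, "inh")
  net <- structure(list(spec = spec, cfg = cfg, exc = exc, inh = inh,
                        n_long_range = 0L,
                        macrocolumn_of = macrocolumn_labels(spec),
                        delay_per_step = delay_per_step),
                   class = "wc_network")
  net <- add_long_range_connections(net, cfg, n_add = n_long_range)
  assign_delays(net, delay_per_step)
}

# macrocolumn id per unit (1-based), 10x10 blocks truncating at edges
macrocolumn_labels <- function(spec) {
  co <- unit_coords(seq_len(spec$side^2), spec$side)
  per_side <- ceiling(spec$side / spec$macrocolumn_side)
  as.integer(co[, 1] %/% spec$macrocolumn_side +
               per_side * (co[, 2] %/% spec$macrocolumn_side) + 1L)
}

#' Assign distance-proportional transmission delays
#'
#' Sets each edge's delay to
#' \code{round(delay_per_step * torus_distance(src, dst))} integration
#' steps, rounding half away from zero. \code{delay_per_step = 0} gives
#' instantaneous transmission on every edge.
#'
#' @param network A \code{wc_network}.
#' @param delay_per_step Steps of delay per lattice step of distance (>= 0).
#' @return The network with updated \code{delay} columns.
#' @export
assign_delays <- function(network, delay_per_step) {
  stopifnot(delay_per_step >= 0)
  side <- network$spec$side
  for (kind in c("exc", "inh")) {
    e <- network[[kind]]
    if (nrow(e) == 0) next
    d <- torus_distance(unit_coords(e$src, side), unit_coords(e$dst, side),
                        side)
    network[[kind]]$delay <- as.integer(round_half_up(delay_per_step * d))
  }
  network$delay_per_step <- delay_per_step
  network
}

#' Centred square sub-network mask
#'
#' @param spec A \code{\link{lattice_spec}}.
#' @param sub_side Side of the centred square, in units; \code{NULL} or
#'   \code{spec$side} selects the whole lattice.
#' @return Logical vector over units (class \code{wc_mask}).
#' @export
subnetwork_mask <- function(spec, sub_side = NULL) {
  if (is.null(sub_side)) sub_side <- spec$side
  stopifnot(sub_side >= 1, sub_side <= spec$side)
  lo <- floor((spec$side - sub_side) / 2)
  co <- unit_coords(seq_len(spec$side^2), spec$side)
  m <- co[, 1] >= lo & co[, 1] < lo + sub_side &
    co[, 2] >= lo & co[, 2] < lo + sub_side
  structure(m, side = spec$side, sub_side = sub_side, class = "wc_mask")
}

#' Lateral inhibition of the surround
#'
#' Confines activity to the masked area: every existing excitatory edge from
#' a masked unit to a unit outside the mask has its weight set to 0, and
#' every inhibitory edge with that orientation has its weight set to 1.
#' No new edges are created and all other edges are untouched.
#'
#' @param network A \code{wc_network}.
#' @param mask A \code{\link{subnetwork_mask}} over the same lattice.
#' @return The modified network.
#' @export
apply_lateral_inhibition <- function(network, mask) {
  stopifnot(length(mask) == network$spec$side^2)
  cross_e <- mask[network$exc$src] & !mask[network$exc$dst]
  network$exc$weight[cross_e] <- 0
  cross_i <- mask[network$inh$src] & !mask[network$inh$dst]
  network$inh$weight[cross_i] <- 1
  network
}

#' Connectivity statistics of a sub-network
#'
#' Considers only edges (excitatory and inhibitory together) with both
#' endpoints inside the mask. Mean degree is that edge count divided by the
#' number of masked units; mean delay is averaged over the same edges.
#'
#' @param network A \code{wc_network} with delays assigned.
#' @param mask A \code{\link{subnetwork_mask}}.
#' @return Named list \code{list(mean_degree =, mean_delay =, n_edges =,
#'   n_units =)}; \code{mean_delay} is \code{NaN} when the mask contains no
#'   internal edges.
#' @export
subnetwork_connectivity_stats <- function(network, mask) {
  n_units <- sum(mask)
  if (n_units == 0) stop("empty mask")
  inside <- function(e) mask[e$src] & mask[e$dst]
  sel_e <- inside(network$exc)
  sel_i <- inside(network$inh)
  n_edges <- sum(sel_e) + sum(sel_i)
  delays <- c(network$exc$delay[sel_e], network$inh$delay[sel_i])
  list(mean_degree = n_edges / n_units,
       mean_delay = if (n_edges > 0) mean(delays) else NaN,
       n_edges = n_edges, n_units = n_units)
}

#' Write / read a network as a plain-text edge list
#'
#' One edge per line, \code{"src_x src_y dst_x dst_y kind weight delay"},
#' preceded by header comment lines carrying the lattice geometry and
#' generation seed. The round trip is bit-exact.
#'
#' @param network A \code{wc_network}.
#' @param path File path.
#' @return \code{write_network} returns \code{path} invisibly;
#'   \code{read_network} returns the reconstructed \code{wc_network}.
#' @export
write_network <- function(network, path) {
  spec <- network$spec
  hdr <- c(sprintf("# wc_network side=%d spacing=%g macrocolumn_side=%d",
                   spec$side, spec$spacing, spec$macrocolumn_side),
           sprintf("# seed=%d delay_per_step=%g n_long_range=%d",
                   network$cfg$seed, network$delay_per_step,
                   network$n_long_range),
           "# src_x src_y dst_x dst_y kind weight delay")
  fmt <- function(e, kind) {
    if (nrow(e) == 0) return(character(0))
    s <- unit_coords(e$src, spec$side)
    d <- unit_coords(e$dst, spec$side)
    sprintf("%d %d %d %d %s %.17g %d", s[, 1], s[, 2], d[, 1], d[, 2],
            kind, e$weight, e$delay)
  }
  writeLines(c(hdr, fmt(network$exc, "E"), fmt(network$inh, "I")), path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  gv <- function(key, line) {
    toks <- strsplit(sub("^#\\s*", "", line), "\\s+")[[1]]
    hit <- toks[startsWith(toks, paste0(key, "="))][1]
    as.numeric(sub(".*=", "", hit))
  }
  h1 <- hdr[1]; h2 <- hdr[2]
  side <- gv("side", h1)
  spacing <- gv("spacing", h1)
  mcs <- gv("macrocolumn_side", h1)
  seed <- gv("seed", h2)
  dps <- gv("delay_per_step", h2)
  nlr <- gv("n_long_range", h2)
  spec <- lattice_spec(side, spacing, mcs)
  f <- utils::read.table(text = body, col.names = c("sx", "sy", "dx", "dy",
                                                    "kind", "weight", "delay"))
  mk <- function(sel) data.frame(
    src = unit_index(f$sx[sel], f$sy[sel], side),
    dst = unit_index(f$dx[sel], f$dy[sel], side),
    weight = f$weight[sel], delay = as.integer(f$delay[sel]))
  structure(list(spec = spec,
                 cfg = connectivity_config(seed = seed),
                 exc = mk(f$kind == "E"), inh = mk(f$kind == "I"),
                 n_long_range = as.integer(nlr),
                 macrocolumn_of = macrocolumn_labels(spec),
                 delay_per_step = dps),
            class = "wc_network")
}

# save/restore the global RNG state so builders can seed locally
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}
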