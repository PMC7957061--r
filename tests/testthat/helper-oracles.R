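# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (triple loops, direct formulas) so they check the
# implementation through a different code path.

AVO <- 6.02214076e23

ecs_astro_map <- c(ecs = 0L, astrocyte = 1L)

# plain volume from an integer array with the default six-role map
vol_of <- function(lab, pitch = c(6, 6, 30),
                   map = c(ecs = 0L, astrocyte = 1L, bouton = 2L, spine = 3L,
                           dendrite_shaft = 4L, other = 5L)) {
  label_volume(lab, pitch_nm = pitch, label_map = map)
}

# triple-loop enumeration of all exposed faces of label `id`
brute_surface <- function(vol, id) {
  L <- vol$labels
  d <- dim(L)
  p <- vol$pitch_nm
  face_area <- c(p[2] * p[3], p[1] * p[3], p[1] * p[2])
  area <- 0
  faces <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (L[i, j, k] != id) next
    nbs <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    for (t in seq_along(nbs)) {
      nb <- nbs[[t]]
      if (any(nb < 1) || any(nb > d)) next   # sample-boundary face
      if (L[nb[1], nb[2], nb[3]] != id) {
        faces <- faces + 1L
        area <- area + face_area[ceiling(t / 2)]
      }
    }
  }
  list(n_faces = faces, area_nm2 = area)
}

# voxels marked ECS by one 6 nm in-plane erosion pass (neighbourhood scan)
brute_erosion_marked <- function(vol) {
  L <- vol$labels
  d <- dim(L)
  ecs <- vol$label_map[["ecs"]]
  marked <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (L[i, j, k] == ecs) next
    for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
      if (nb[1] < 1 || nb[1] > d[1] || nb[2] < 1 || nb[2] > d[2]) next
      if (L[nb[1], nb[2], k] != L[i, j, k]) {
        marked[i, j, k] <- TRUE
        break
      }
    }
  }
  marked
}

# a random multi-compartment blob fixture (seeded by the caller)
random_fixture <- function(n = 14, pitch = c(6, 6, 30), p_labels = NULL) {
  lab <- array(sample(0:3, n^3, replace = TRUE,
                      prob = p_labels %||% c(0.55, 0.2, 0.15, 0.1)),
               c(n, n, n))
  vol_of(lab, pitch)
}

# continuous-time Gillespie sampler: time-weighted occupancy of one molecule
gillespie_occupancy <- function(scheme, ctx, t_total_ms) {
  tr <- evaluate_rates(scheme, ctx)
  states <- scheme$states
  occ <- setNames(numeric(length(states)), states)
  s <- 1L
  t <- 0
  while (t < t_total_ms) {
    out <- tr[tr$from == states[s], ]
    tot <- sum(out$rate_eff)
    tau <- stats::rexp(1, tot)
    occ[s] <- occ[s] + min(tau, t_total_ms - t)
    t <- t + tau
    if (t >= t_total_ms) break
    s <- match(out$to[sample.int(nrow(out), 1, prob = out$rate_eff)], states)
  }
  occ / sum(occ)
}

# slab-in-ECS fixture with exact exposed area (full-xy slab, z faces only)
unit_area_fixture <- function(nx = 200L, ny = 100L, nz = 20L,
                              pitch = c(5, 5, 25), z_layers = 9:13) {
  lab <- array(0L, c(nx, ny, nz))
  lab[, , z_layers] <- 1L
  label_volume(lab, pitch_nm = pitch, label_map = ecs_astro_map)
}
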