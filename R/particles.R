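#' Diffusion parameters for the particle engine
#'
#' @param d_glu_um2_ms glutamate diffusion coefficient (default 0.33 um^2/ms).
#' @param d_ca_um2_ms intracellular calcium diffusion coefficient (default
#'   0.22 um^2/ms; a configurable choice, as cytosolic Ca2+ mobility is not a
#'   sharply defined literature constant).
#' @param dt_ms time step, ms (default 1 us).
#' @return a `calf_diffusion_params`.
#' @export
diffusion_params <- function(d_glu_um2_ms = 0.33, d_ca_um2_ms = 0.22,
                             dt_ms = 1e-3) {
  if (d_glu_um2_ms < 0 || d_ca_um2_ms < 0) abort("Diffusion coefficients must be >= 0.")
  if (dt_ms <= 0) abort("`dt_ms` must be positive.")
  structure(list(d_glu_um2_ms = d_glu_um2_ms, d_ca_um2_ms = d_ca_um2_ms,
                 dt_ms = dt_ms),
            class = "calf_diffusion_params")
}

# per-axis Gaussian step sd in nm for an Euler-Maruyama diffusion step
step_sd_nm <- function(d_um2_ms, dt_ms) sqrt(2 * d_um2_ms * dt_ms) * 1e3

#' Construct a particle pool
#'
#' Tracks explicit positions of diffusing particles of one species together
#' with free/bound/removed bookkeeping and the baseline count used by the
#' boundary floor rule.
#'
#' @param species `"glu"` or `"ca"`.
#' @param positions n x 3 matrix of positions, nm.
#' @param home_role compartment the species is confined to (`"ecs"` for
#'   glutamate, `"astrocyte"` for calcium).
#' @param baseline_count baseline population fixed at initialisation.
#' @return a `calf_pool`.
#' @export
particle_pool <- function(species = c("glu", "ca"), positions,
                          home_role = if (species == "glu") "ecs" else "astrocyte",
                          baseline_count = nrow(positions)) {
  species <- match.arg(species)
  positions <- matrix(as.double(positions), ncol = 3)
  structure(list(species = species, pos = positions,
                 status = rep(0L, nrow(positions)),
                 owner = rep(NA_integer_, nrow(positions)),
                 home_role = home_role,
                 baseline_count = as.integer(baseline_count),
                 boundary_removed = 0L),
            class = "calf_pool")
}

#' Number of free particles in a pool
#' @param pool a `calf_pool`.
#' @return integer count.
#' @export
n_free <- function(pool) sum(pool$status == 0L)

#' Initialise a particle pool from a target concentration
#'
#' Places `round(conc * compartment volume * N_A)` particles uniformly at
#' random inside the compartment's voxels and records that count as the
#' pool's baseline. Seed the R RNG beforehand for reproducibility.
#'
#' @param vol a [label_volume()].
#' @param species `"glu"` or `"ca"`.
#' @param role compartment role to fill.
#' @param conc_molar concentration in mol/L.
#' @return a [particle_pool()].
#' @export
init_pool_from_concentration <- function(vol, species, role, conc_molar) {
  stopifnot(inherits(vol, "calf_volume"))
  mask <- role_mask(vol, role)
  vox <- which(mask)
  if (!length(vox)) abort(sprintf("Compartment `%s` has zero volume.", role))
  v_l <- length(vox) * voxel_volume_l(vol)
  n <- count_from_concentration(conc_molar, v_l)
  if (n == 0L) {
    return(particle_pool(species, matrix(numeric(0), ncol = 3),
                         home_role = role, baseline_count = 0L))
  }
  pick <- vox[sample.int(length(vox), n, replace = TRUE)]
  d <- dim(vol$labels)
  k <- (pick - 1L) %/% (d[1] * d[2])
  rem <- (pick - 1L) %% (d[1] * d[2])
  j <- rem %/% d[1]
  i <- rem %% d[1]
  p <- vol$pitch_nm
  pos <- cbind((i + runif(n)) * p[1], (j + runif(n)) * p[2], (k + runif(n)) * p[3])
  particle_pool(species, pos, home_role = role, baseline_count = n)
}

#' Advance free particles by Gaussian random-walk steps
#'
#' Each free particle receives an independent per-axis Gaussian displacement
#' with standard deviation `sqrt(2 D dt)`. A particle whose new position
#' leaves its home compartment is returned to its previous position; one that
#' leaves the sample volume is removed, unless the species count is at or
#' below its baseline, in which case it is returned. With `vol = NULL` the
#' walk is unconfined.
#'
#' @param pool a [particle_pool()].
#' @param vol a [label_volume()] or `NULL` for unbounded diffusion.
#' @param params a [diffusion_params()].
#' @param n_steps number of 1-step sweeps.
#' @return the updated pool (with `boundary_removed` accumulated).
#' @export
diffuse_step <- function(pool, vol, params = diffusion_params(), n_steps = 1L) {
  stopifnot(inherits(pool, "calf_pool"))
  d_coef <- if (pool$species == "glu") params$d_glu_um2_ms else params$d_ca_um2_ms
  sd_nm <- step_sd_nm(d_coef, params$dt_ms)
  if (nrow(pool$pos) == 0L || sd_nm == 0) return(pool)
  if (is.null(vol)) {
    free <- pool$status == 0L
    n <- sum(free)
    for (s in seq_len(n_steps)) {
      pool$pos[free, ] <- pool$pos[free, , drop = FALSE] +
        matrix(rnorm(3 * n, sd = sd_nm), ncol = 3)
    }
    return(pool)
  }
  res <- diffuse_pool_cpp(pool$pos, pool$status, vol$labels, dim(vol$labels),
                          vol$pitch_nm, role_id(vol, pool$home_role),
                          sd_nm, as.integer(n_steps), pool$baseline_count)
  pool$pos <- res$pos
  pool$status <- res$status
  pool$boundary_removed <- pool$boundary_removed + res$boundary_removed
  pool
}

#' Local concentration in a cubic microdomain
#'
#' Counts free particles inside the axis-aligned box of edge `box_edge_nm`
#' centred at `center_nm` and divides by the box volume belonging to the
#' pool's home compartment (clipped at the sample boundary), as a molar
#' concentration. This is the 50 nm microdomain rule used to drive the
#' glutamate-binding rate of each EAAT molecule.
#'
#' @param pool a [particle_pool()].
#' @param vol a [label_volume()].
#' @param center_nm box centre, nm.
#' @param box_edge_nm box edge, nm (default 50).
#' @return concentration in mol/L (0 for an empty box; `NaN` if the box
#'   contains none of the home compartment).
#' @export
local_concentration <- function(pool, vol, center_nm, box_edge_nm = 50) {
  stopifnot(inherits(pool, "calf_pool"), inherits(vol, "calf_volume"))
  h <- box_edge_nm / 2
  free <- pool$status == 0L
  inside <- free &
    abs(pool$pos[, 1] - center_nm[1]) <= h &
    abs(pool$pos[, 2] - center_nm[2]) <= h &
    abs(pool$pos[, 3] - center_nm[3]) <= h
  v_nm3 <- box_region_volume_cpp(vol$labels, dim(vol$labels), vol$pitch_nm,
                                 matrix(center_nm, ncol = 3), box_edge_nm,
                                 role_id(vol, pool$home_role))
  concentration_from_count(sum(inside), nm3_to_litre(v_nm3[1]))
}

#' Candidate ECS voxel centres for a synaptic release site
#'
#' ECS voxels whose centre lies within `spread_radius_nm` of the centroid.
#' @keywords internal
release_candidates <- function(vol, centroid_nm, spread_radius_nm = 100) {
  mask <- role_mask(vol, "ecs")
  d <- dim(vol$labels)
  axc <- axis_centres(d, vol$pitch_nm)
  d2 <- dist2_array(axc[[1]], axc[[2]], axc[[3]], centroid_nm)
  cand <- which(mask & d2 <= spread_radius_nm^2)
  if (!length(cand)) {
    abort(sprintf("No ECS voxel within %g nm of the release centroid.",
                  spread_radius_nm))
  }
  k <- (cand - 1L) %/% (d[1] * d[2])
  rem <- (cand - 1L) %% (d[1] * d[2])
  j <- rem %/% d[1]
  i <- rem %% d[1]
  p <- vol$pitch_nm
  cbind((i + 0.5) * p[1], (j + 0.5) * p[2], (k + 0.5) * p[3])
}

#' Release glutamate at the synapse centroid
#'
#' Adds `n` new free glutamate molecules distributed uniformly over the ECS
#' voxels nearest the centroid (within `spread_radius_nm`); the pool count
#' increases by exactly `n` and the baseline is unchanged.
#'
#' @param pool a glutamate [particle_pool()].
#' @param vol a [label_volume()].
#' @param centroid_nm release point (the PSD centroid), nm; must lie inside
#'   the sample.
#' @param n number of molecules (default 5000).
#' @param spread_radius_nm radius of the candidate ECS voxel set.
#' @return the updated pool.
#' @export
release_glutamate <- function(pool, vol, centroid_nm, n = 5000,
                              spread_radius_nm = 100) {
  stopifnot(inherits(pool, "calf_pool"), pool$species == "glu")
  ext <- volume_extent_nm(vol)
  if (any(centroid_nm < 0) || any(centroid_nm >= ext)) {
    abort("Release centroid lies outside the sample volume.")
  }
  if (n == 0) return(pool)
  cand <- release_candidates(vol, centroid_nm, spread_radius_nm)
  pick <- sample.int(nrow(cand), n, replace = TRUE)
  jit <- matrix(runif(3 * n) - 0.5, ncol = 3) *
    matrix(vol$pitch_nm, n, 3, byrow = TRUE)
  new_pos <- cand[pick, , drop = FALSE] + jit
  pool$pos <- rbind(pool$pos, new_pos)
  pool$status <- c(pool$status, rep(0L, n))
  pool$owner <- c(pool$owner, rep(NA_integer_, n))
  pool
}

#' Well-mixed intracellular sodium pool
#'
#' At 15 mM a leaflet-sized astrocyte segment holds on the order of a million
#' sodium ions, so particle noise is negligible and sodium is carried as a
#' single concentration updated by transporter stoichiometry.
#'
#' @param astro_volume_l astrocytic volume, litres.
#' @param concentration_mM current concentration (default 15).
#' @param baseline_mM baseline concentration.
#' @return a `calf_sodium`.
#' @export
sodium_pool <- function(astro_volume_l, concentration_mM = 15,
                        baseline_mM = concentration_mM) {
  if (concentration_mM < 0) abort("Sodium concentration must be >= 0.")
  structure(list(concentration_mM = concentration_mM,
                 astro_volume_l = astro_volume_l,
                 baseline_mM = baseline_mM,
                 mM_per_ion = 1e3 / (AVOGADRO * astro_volume_l)),
            class = "calf_sodium")
}

#' Apply transporter events to the particle pools and sodium pool
#'
#' Binding events sequester the nearest eligible free particle (glutamate
#' within the transporter's microdomain box, calcium within
#' `ca_bind_radius_nm` of the site); unbinding restores it at the transporter
#' position; completed-cycle translocations move glutamate into a cytosolic
#' tally or delete/create calcium according to direction; sodium changes by
#' the event stoichiometry over the astrocytic volume and is floored at 0.
#' A binding event with no eligible particle is cancelled and returned in
#' `$cancelled` so the caller can veto the state change.
#'
#' @param pools list with `glu` and/or `ca` [particle_pool()]s.
#' @param sodium a [sodium_pool()].
#' @param events event tibble from [step_population()] (needs `x`, `y`, `z`
#'   position columns).
#' @param box_edge_nm glutamate microdomain edge.
#' @param ca_bind_radius_nm calcium capture radius.
#' @return list: updated `pools`, `sodium`, `cyto_glu` translocation count,
#'   `ca_influx`/`ca_efflux` counts, and the `cancelled` events.
#' @export
apply_transporter_events <- function(pools, sodium, events,
                                     box_edge_nm = 50, ca_bind_radius_nm = 150) {
  stopifnot(inherits(sodium, "calf_sodium"))
  cancelled <- events[0, ]
  cyto_glu <- 0L; ca_influx <- 0L; ca_efflux <- 0L
  if (nrow(events)) stopifnot(all(c("x", "y", "z") %in% names(events)))
  for (r in seq_len(nrow(events))) {
    ev <- events[r, ]
    pos <- c(ev$x, ev$y, ev$z)
    ok <- TRUE
    if (ev$action == "glu_bind") {
      p <- pools$glu
      h <- box_edge_nm / 2
      elig <- which(p$status == 0L &
                      abs(p$pos[, 1] - pos[1]) <= h &
                      abs(p$pos[, 2] - pos[2]) <= h &
                      abs(p$pos[, 3] - pos[3]) <= h)
      if (!length(elig)) {
        ok <- FALSE
      } else {
        d2 <- rowSums((p$pos[elig, , drop = FALSE] -
                         matrix(pos, length(elig), 3, byrow = TRUE))^2)
        sel <- elig[which.min(d2)]
        p$status[sel] <- 1L
        p$owner[sel] <- ev$molecule
        pools$glu <- p
      }
    } else if (ev$action == "glu_release_out") {
      p <- pools$glu
      sel <- which(p$status == 1L & p$owner == ev$molecule)
      if (length(sel)) {
        sel <- sel[1]
        p$status[sel] <- 0L
        p$owner[sel] <- NA_integer_
        p$pos[sel, ] <- pos
        pools$glu <- p
      }
    } else if (ev$action == "glu_release_in") {
      p <- pools$glu
      sel <- which(p$status == 1L & p$owner == ev$molecule)
      if (length(sel)) {
        sel <- sel[1]
        p$status[sel] <- 2L
        p$owner[sel] <- NA_integer_
        cyto_glu <- cyto_glu + 1L
        pools$glu <- p
      }
    } else if (ev$action == "ca_bind_in") {
      p <- pools$ca
      d2 <- rowSums((p$pos - matrix(pos, nrow(p$pos), 3, byrow = TRUE))^2)
      elig <- which(p$status == 0L & d2 <= ca_bind_radius_nm^2)
      if (!length(elig)) {
        ok <- FALSE
      } else {
        sel <- elig[which.min(d2[elig])]
        p$status[sel] <- 1L
        p$owner[sel] <- ev$molecule
        pools$ca <- p
      }
    } else if (ev$action == "ca_release_in") {
      p <- pools$ca
      sel <- which(p$status == 1L & p$owner == ev$molecule)
      if (length(sel)) {
        sel <- sel[1]
        p$status[sel] <- 0L
        p$owner[sel] <- NA_integer_
        p$pos[sel, ] <- pos
      } else {
        # carrier loaded from the extracellular bath: calcium entry
        p$pos <- rbind(p$pos, pos)
        p$status <- c(p$status, 0L)
        p$owner <- c(p$owner, NA_integer_)
        ca_influx <- ca_influx + 1L
      }
      pools$ca <- p
    } else if (ev$action == "ca_release_out") {
      p <- pools$ca
      sel <- which(p$status == 1L & p$owner == ev$molecule)
      if (length(sel)) {
        sel <- sel[1]
        p$status[sel] <- 2L
        p$owner[sel] <- NA_integer_
        ca_efflux <- ca_efflux + 1L
        pools$ca <- p
      }
    }
    if (ok && ev$na_delta != 0) {
      sodium$concentration_mM <- max(
        0, sodium$concentration_mM + ev$na_delta * sodium$mM_per_ion)
    }
    if (!ok) cancelled <- dplyr::bind_rows(cancelled, ev)
  }
  list(pools = pools, sodium = sodium, cyto_glu = cyto_glu,
       ca_influx = ca_influx, ca_efflux = ca_efflux, cancelled = cancelled)
}

#' Estimate a diffusion coefficient from simulated free particles
#'
#' Runs unconfined Gaussian random walks with the engine's step rule and
#' regresses mean squared displacement on `6 t` through the origin.
#'
#' @param n_particles number of particles.
#' @param d_um2_ms true diffusion coefficient used for the walk.
#' @param dt_ms time step, ms.
#' @param n_steps number of steps.
#' @return list: `d_hat` (um^2/ms) and the `msd` tibble (`time_ms`,
#'   `msd_um2`).
#' @export
estimate_diffusion_coefficient <- function(n_particles = 10000,
                                           d_um2_ms = 0.33,
                                           dt_ms = 1e-3, n_steps = 1000) {
  sd_nm <- step_sd_nm(d_um2_ms, dt_ms)
  msd_nm2 <- diffuse_free_msd_cpp(as.integer(n_particles), sd_nm,
                                  as.integer(n_steps))
  t_ms <- seq_len(n_steps) * dt_ms
  msd_um2 <- msd_nm2 / 1e6
  fit <- lm(msd_um2 ~ 0 + t_ms)
  list(d_hat = unname(stats::coef(fit)[1]) / 6,
       msd = tibble(time_ms = t_ms, msd_um2 = msd_um2))
}
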