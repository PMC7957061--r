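#' Full simulation configuration
#'
#' Defaults are the study protocol: constant bath concentrations (140 mM
#' Na+, 3 mM K+, 2 mM Ca2+ outside; 130 mM K+, 3 mM Glu inside), dynamic
#' 0.3 uM ambient glutamate, 15 mM astrocytic Na+ and 100 nM free Ca2+;
#' 10,800 EAAT and 500 NCX molecules per um^2 of astrocytic surface; -70 mV;
#' Q10 = 3 over one decade; 1 us steps with 30 ms kinetic pre-equilibration,
#' 10 ms baseline and release of 5,000 glutamate molecules, running to 30 ms.
#'
#' @param glu_e_mM,na_e_mM,na_i_mM,k_e_mM,k_i_mM,ca_e_mM,ca_i_mM,glu_i_mM
#'   concentrations, mM.
#' @param eaat_per_um2,ncx_per_um2 transporter surface densities, 1/um^2.
#' @param membrane_potential_mv static membrane potential, mV.
#' @param q10,t_ref_c,t_sim_c temperature correction (defaults give factor 3).
#' @param dt_ms engine step, ms.
#' @param t_equilibrate_ms kinetic pre-equilibration length.
#' @param t_release_ms release time within the timed run.
#' @param t_end_ms end of the timed run.
#' @param n_glu_release molecules released.
#' @param release_enabled,eaat_enabled,ncx_enabled protocol switches.
#' @param record_interval_ms trace sampling interval (default 10 us, i.e. a
#'   100 kHz trace).
#' @param d_glu_um2_ms,d_ca_um2_ms diffusion coefficients.
#' @param box_edge_nm EAAT glutamate microdomain edge.
#' @param ca_bind_radius_nm NCX calcium capture radius.
#' @param release_spread_nm radius of the nearest-ECS-voxel release set.
#' @param kinetics_path optional alternative rate-parameter YAML.
#' @param seed run seed.
#' @return a `calf_config` list.
#' @export
simulation_config <- function(glu_e_mM = 3e-4, na_e_mM = 140, na_i_mM = 15,
                              k_e_mM = 3, k_i_mM = 130, ca_e_mM = 2,
                              ca_i_mM = 1e-4, glu_i_mM = 3,
                              eaat_per_um2 = 10800, ncx_per_um2 = 500,
                              membrane_potential_mv = -70,
                              q10 = 3, t_ref_c = 25, t_sim_c = 35,
                              dt_ms = 1e-3, t_equilibrate_ms = 30,
                              t_release_ms = 10, t_end_ms = 30,
                              n_glu_release = 5000,
                              release_enabled = TRUE,
                              eaat_enabled = TRUE, ncx_enabled = TRUE,
                              record_interval_ms = 0.01,
                              d_glu_um2_ms = 0.33, d_ca_um2_ms = 0.22,
                              box_edge_nm = 50, ca_bind_radius_nm = 150,
                              release_spread_nm = 100,
                              kinetics_path = NULL,
                              seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    if (dt_ms <= 0 || t_equilibrate_ms <= 0 || t_end_ms <= 0 ||
        t_release_ms <= 0 || record_interval_ms <= 0) {
      abort("All times must be positive.")
    }
    if (release_enabled && t_release_ms >= t_end_ms) {
      abort("`t_release_ms` must be before `t_end_ms`.")
    }
    if (eaat_per_um2 < 0 || ncx_per_um2 < 0) abort("Densities must be >= 0.")
    if (abs(record_interval_ms / dt_ms - round(record_interval_ms / dt_ms)) > 1e-9) {
      abort("`record_interval_ms` must be a multiple of `dt_ms`.")
    }
  })
  structure(cfg, class = "calf_config")
}

rate_context_from_config <- function(cfg) {
  rate_context(glu_e_mM = cfg$glu_e_mM, na_e_mM = cfg$na_e_mM,
               na_i_mM = cfg$na_i_mM, k_e_mM = cfg$k_e_mM,
               k_i_mM = cfg$k_i_mM, ca_e_mM = cfg$ca_e_mM,
               ca_i_mM = cfg$ca_i_mM, glu_i_mM = cfg$glu_i_mM,
               membrane_potential_mv = cfg$membrane_potential_mv,
               temperature_factor = apply_q10(1, cfg$q10, cfg$t_ref_c, cfg$t_sim_c))
}

ACTION_CODES <- c(none = 0L, glu_bind = 1L, glu_release_out = 2L,
                  glu_release_in = 3L, glu_load_in = 4L, ca_bind_in = 5L,
                  ca_release_in = 6L, ca_release_out = 7L, ca_load_out = 8L)

# Compile a scheme into the CSR per-step-probability form used by the C++
# engine. Dynamic ligands (local glutamate, intracellular Na+ and free Ca2+)
# stay as multipliers unless `pinned` folds them at the context values
# (pre-equilibration).
compile_scheme <- function(scheme, ctx, dt_ms, pinned = FALSE) {
  tr <- scheme$transitions
  volt <- exp(-tr$charge * ctx$membrane_potential_mv / (2 * RT_OVER_F_MV))
  p <- tr$rate * volt * ctx$temperature_factor * dt_ms
  dyn <- integer(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    lig <- tr$ligand[i]
    if (lig == "none") next
    dynamic <- !pinned && lig %in% c("glu_e", "na_i", "ca_i")
    if (dynamic) {
      dyn[i] <- switch(lig,
                       glu_e = 1L,
                       na_i = if (tr$ligand_order[i] == 3L) 3L else 2L,
                       ca_i = 4L)
    } else {
      p[i] <- p[i] * ctx[[lig]]^tr$ligand_order[i]
    }
  }
  ord <- order(match(tr$from, scheme$states))
  from_i <- match(tr$from, scheme$states)[ord]
  n <- length(scheme$states)
  ptr <- integer(n + 1)
  for (s in seq_len(n)) ptr[s + 1] <- ptr[s] + sum(from_i == s)
  list(n_states = n,
       ptr = ptr,
       to = match(tr$to, scheme$states)[ord] - 1L,
       p = p[ord],
       dyn = dyn[ord],
       act = unname(ACTION_CODES[tr$action[ord]]),
       na_delta = as.integer(tr$na_delta[ord]),
       name = scheme$name,
       order = ord)
}

# Exposed astrocytic faces: one row per face with the astro voxel, the face
# centre, the neighbour-voxel centre and label, and the face area.
astro_faces <- function(vol) {
  L <- vol$labels
  astro <- role_id(vol, "astrocyte")
  p <- vol$pitch_nm
  face_area <- c(p[2] * p[3], p[1] * p[3], p[1] * p[2])
  out <- list()
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- shifted(L, ax, s, fill = NA)
      mask <- (L == astro) & !is.na(nb) & nb != astro
      if (!any(mask)) next
      idx <- which(mask, arr.ind = TRUE)
      ctr <- sweep(idx - 0.5, 2, p, `*`)
      fc <- ctr
      fc[, ax] <- fc[, ax] + s * p[ax] / 2
      nbc <- ctr
      nbc[, ax] <- nbc[, ax] + s * p[ax]
      out[[length(out) + 1L]] <- tibble(
        axis = ax, dir = s,
        x = fc[, 1], y = fc[, 2], z = fc[, 3],
        astro_x = ctr[, 1], astro_y = ctr[, 2], astro_z = ctr[, 3],
        nb_x = nbc[, 1], nb_y = nbc[, 2], nb_z = nbc[, 3],
        nb_label = nb[mask],
        area_nm2 = face_area[ax])
    }
  }
  dplyr::bind_rows(out)
}

#' Place transporter molecules on the astrocytic surface
#'
#' Molecule counts are `round(density x total exposed astrocytic area)`;
#' positions are sampled over the ECS-adjacent surface faces with probability
#' proportional to face area (membrane pressed directly against other cells
#' has no aqueous access) and jittered uniformly within each face. Seed the
#' R RNG beforehand for determinism.
#'
#' @param vol a [label_volume()].
#' @param densities named vector, molecules per um^2 (`eaat`, `ncx`).
#' @return a tibble (class `calf_placement`): `species`, membrane position
#'   `x`,`y`,`z`, the ECS-side voxel centre `ecs_*` (glutamate release
#'   point), the astro-side voxel centre `astro_*` (calcium exchange point).
#'   Attribute `area_um2` carries the total exposed area.
#' @export
place_transporters <- function(vol, densities = c(eaat = 10800, ncx = 500)) {
  faces <- astro_faces(vol)
  if (!nrow(faces)) abort("Astrocyte surface area is zero.")
  area_um2 <- sum(faces$area_nm2) / 1e6
  ecs_faces <- faces[faces$nb_label == role_id(vol, "ecs"), ]
  p <- vol$pitch_nm
  rows <- purrr::imap(as.list(densities), function(dens, sp) {
    n <- round(dens * area_um2)
    if (n == 0) return(NULL)
    if (!nrow(ecs_faces)) {
      abort("No ECS-adjacent astrocytic faces available for placement.")
    }
    pick <- sample.int(nrow(ecs_faces), n, replace = TRUE,
                       prob = ecs_faces$area_nm2)
    f <- ecs_faces[pick, ]
    # jitter within the face plane
    jit <- matrix(runif(2 * n) - 0.5, ncol = 2)
    pos <- cbind(f$x, f$y, f$z)
    tang <- lapply(f$axis, function(a) setdiff(1:3, a))
    for (i in seq_len(n)) {
      pos[i, tang[[i]][1]] <- pos[i, tang[[i]][1]] + jit[i, 1] * p[tang[[i]][1]]
      pos[i, tang[[i]][2]] <- pos[i, tang[[i]][2]] + jit[i, 2] * p[tang[[i]][2]]
    }
    tibble(species = sp, x = pos[, 1], y = pos[, 2], z = pos[, 3],
           ecs_x = f$nb_x, ecs_y = f$nb_y, ecs_z = f$nb_z,
           astro_x = f$astro_x, astro_y = f$astro_y, astro_z = f$astro_z)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "area_um2") <- area_um2
  class(out) <- c("calf_placement", class(out))
  out
}

#' Run one full simulation of a synapse
#'
#' Protocol: transporter placement, analytic-steady-state initialisation
#' followed by the stated stochastic pre-equilibration with pinned
#' concentrations, then the timed loop at `dt_ms` with the per-step order
#' move -> transitions (per-EAAT local glutamate; shuffled molecule order)
#' -> bookkeeping, with glutamate release fired at `t_release_ms` when
#' enabled. Fully reproducible from (geometry, config, seed).
#'
#' @param record a [synapse_record()] (or bare [label_volume()] with an
#'   implied central release point).
#' @param cfg a [simulation_config()].
#' @return a `calf_sim`: `$trace` tibble (`time_ms`, `ca_nM`, `glu_uM`,
#'   `na_mM`), `$ledger` named counts, `$events` per-transition counts,
#'   `$config`, `$meta`.
#' @export
run_simulation <- function(record, cfg = simulation_config()) {
  if (inherits(record, "calf_volume")) {
    record <- synapse_record(record, volume_extent_nm(record) / 2)
  }
  stopifnot(inherits(record, "calf_synapse"), inherits(cfg, "calf_config"))
  vol <- record$volume
  set.seed(cfg$seed)
  ctx <- rate_context_from_config(cfg)
  params <- default_kinetic_params(cfg$kinetics_path)

  dens <- c(eaat = if (cfg$eaat_enabled) cfg$eaat_per_um2 else 0,
            ncx = if (cfg$ncx_enabled) cfg$ncx_per_um2 else 0)
  placement <- if (any(dens > 0)) place_transporters(vol, dens) else NULL

  astro_vol_l <- role_volume_l(vol, "astrocyte")
  ecs_vol_l <- role_volume_l(vol, "ecs")

  prep_species <- function(sp, scheme) {
    pl <- placement[placement$species == sp, ]
    if (is.null(placement) || !nrow(pl)) return(NULL)
    p_ss <- steady_state(scheme, ctx)
    states <- sample.int(length(p_ss), nrow(pl), replace = TRUE, prob = p_ss)
    pinned <- compile_scheme(scheme, ctx, cfg$dt_ms, pinned = TRUE)
    n_eq <- as.integer(round(cfg$t_equilibrate_ms / cfg$dt_ms))
    states <- evolve_states_cpp(states, pinned, n_eq)
    live <- compile_scheme(scheme, ctx, cfg$dt_ms, pinned = FALSE)
    list(pl = pl, states = states, compiled = live, scheme = scheme,
         steady = p_ss)
  }
  eaat <- if (dens[["eaat"]] > 0) prep_species("eaat", build_eaat_scheme(params))
  ncx <- if (dens[["ncx"]] > 0) prep_species("ncx", build_ncx_scheme(params))

  glu_pool <- init_pool_from_concentration(vol, "glu", "ecs", cfg$glu_e_mM * 1e-3)
  ca_pool <- init_pool_from_concentration(vol, "ca", "astrocyte", cfg$ca_i_mM * 1e-3)

  eaat_arg <- NULL
  if (!is.null(eaat)) {
    centers <- cbind(eaat$pl$x, eaat$pl$y, eaat$pl$z)
    v_box <- box_region_volume_cpp(vol$labels, dim(vol$labels), vol$pitch_nm,
                                   centers, cfg$box_edge_nm, role_id(vol, "ecs"))
    conv <- ifelse(v_box > 0, 1e3 / (AVOGADRO * nm3_to_litre(v_box)), 0)
    eaat_arg <- list(scheme = eaat$compiled, states = eaat$states,
                     pos = centers,
                     release_pos = cbind(eaat$pl$ecs_x, eaat$pl$ecs_y, eaat$pl$ecs_z),
                     box_conv_mM = conv)
  }
  ncx_arg <- NULL
  if (!is.null(ncx)) {
    ncx_arg <- list(scheme = ncx$compiled, states = ncx$states,
                    pos = cbind(ncx$pl$x, ncx$pl$y, ncx$pl$z),
                    release_pos = cbind(ncx$pl$astro_x, ncx$pl$astro_y, ncx$pl$astro_z),
                    box_conv_mM = numeric(0))
  }

  n_steps <- as.integer(round(cfg$t_end_ms / cfg$dt_ms))
  record_every <- as.integer(round(cfg$record_interval_ms / cfg$dt_ms))
  release_step <- if (cfg$release_enabled)
    as.integer(round(cfg$t_release_ms / cfg$dt_ms)) else -1L
  cand <- if (cfg$release_enabled) {
    release_candidates(vol, record$centroid_nm, cfg$release_spread_nm)
  } else matrix(numeric(0), ncol = 3)

  res <- run_engine_cpp(
    vol$labels, dim(vol$labels), vol$pitch_nm,
    role_id(vol, "ecs"), role_id(vol, "astrocyte"),
    eaat_arg, ncx_arg,
    glu_pool$pos, glu_pool$baseline_count,
    ca_pool$pos, ca_pool$baseline_count,
    cfg$na_i_mM, 1e3 / (AVOGADRO * astro_vol_l), 1e3 / (AVOGADRO * astro_vol_l),
    step_sd_nm(cfg$d_glu_um2_ms, cfg$dt_ms),
    step_sd_nm(cfg$d_ca_um2_ms, cfg$dt_ms),
    n_steps, record_every, release_step, cand,
    if (cfg$release_enabled) as.integer(cfg$n_glu_release) else 0L,
    cfg$box_edge_nm / 2, cfg$ca_bind_radius_nm)

  times <- seq(0, n_steps, by = record_every) * cfg$dt_ms
  trace <- tibble(
    time_ms = times,
    ca_nM = res$records[, 2] * 1e9 / (AVOGADRO * astro_vol_l),
    glu_uM = res$records[, 1] * 1e6 / (AVOGADRO * ecs_vol_l),
    na_mM = res$records[, 3])

  events <- dplyr::bind_rows(
    if (!is.null(eaat)) {
      tr <- eaat$scheme$transitions[eaat$compiled$order, ]
      tibble(scheme = "eaat", from = tr$from, to = tr$to,
             action = tr$action, n = res$eaat_events)
    },
    if (!is.null(ncx)) {
      tr <- ncx$scheme$transitions[ncx$compiled$order, ]
      tibble(scheme = "ncx", from = tr$from, to = tr$to,
             action = tr$action, n = res$ncx_events)
    })

  structure(list(
    trace = trace,
    ledger = res$ledger,
    events = events,
    final_states = list(eaat = res$eaat_states, ncx = res$ncx_states),
    steady = list(eaat = if (!is.null(eaat)) eaat$steady,
                  ncx = if (!is.null(ncx)) ncx$steady),
    config = cfg,
    meta = list(synapse_id = record$id,
                astro_volume_l = astro_vol_l,
                ecs_volume_l = ecs_vol_l,
                area_um2 = if (!is.null(placement)) attr(placement, "area_um2") else NA_real_,
                n_eaat = if (!is.null(eaat)) nrow(eaat$pl) else 0L,
                n_ncx = if (!is.null(ncx)) nrow(ncx$pl) else 0L,
                seed = cfg$seed,
                config_hash = rlang::hash(unclass(cfg)))),
    class = "calf_sim")
}

#' @export
print.calf_sim <- function(x, ...) {
  cat(sprintf("<calf_sim> %s: %.0f EAAT, %.0f NCX, %g ms, seed %d\n",
              x$meta$synapse_id, x$meta$n_eaat, x$meta$n_ncx,
              max(x$trace$time_ms), x$meta$seed))
  invisible(x)
}

#' Check particle-mass conservation of a finished run
#'
#' For each species, free + bound + translocated + boundary-removed counts
#' must balance the baseline plus injected/created particles exactly.
#'
#' @param sim a `calf_sim`.
#' @return one-row tibble with per-species imbalances (all 0 for a
#'   conservative run) and a `balanced` flag.
#' @export
check_ledger <- function(sim) {
  l <- as.list(sim$ledger)
  glu_imbalance <- with(l, glu_free + glu_bound + glu_translocated_in +
                          glu_boundary_removed -
                          (glu_baseline + glu_released + glu_created_out))
  ca_imbalance <- with(l, ca_free + ca_bound + ca_translocated_out +
                         ca_boundary_removed -
                         (ca_baseline + ca_influx_created))
  tibble(glu_imbalance = glu_imbalance, ca_imbalance = ca_imbalance,
         balanced = glu_imbalance == 0 && ca_imbalance == 0)
}

#' Run a grid of simulations over geometries, parameter patches and seeds
#'
#' Executes the Cartesian product geometry x patch x seed. Each run's RNG
#' stream derives from its (seed, geometry id) pair, so patched conditions
#' sharing a seed share their stream and stay comparable step-for-step until
#' the patched behaviour diverges.
#'
#' @param synapses a tibble with `synapse_id` and `synapse` list-column (as
#'   from [make_population()]), or a list of [synapse_record()]s.
#' @param cfg base [simulation_config()].
#' @param patches named list of parameter patches (named lists touching only
#'   existing config fields); an empty list runs the baseline alone.
#' @param seeds integer vector of run seeds.
#' @return tibble: `synapse_id`, `patch`, `seed`, `result` list-column of
#'   `calf_sim`.
#' @export
run_condition_grid <- function(synapses, cfg = simulation_config(),
                               patches = list(), seeds = 1L) {
  if (!is.data.frame(synapses)) {
    synapses <- tibble(
      synapse_id = vapply(seq_along(synapses), function(i) {
        synapses[[i]]$id %||% sprintf("syn%03d", i)
      }, character(1)),
      synapse = synapses)
  }
  if (!length(patches)) patches <- list(baseline = list())
  if (is.null(names(patches)) || any(names(patches) == "")) {
    names(patches) <- paste0("patch", seq_along(patches))
  }
  for (nm in names(patches)) {
    unknown <- setdiff(names(patches[[nm]]), names(cfg))
    if (length(unknown)) {
      abort(sprintf("Patch `%s` touches unknown config field(s): %s",
                    nm, paste(unknown, collapse = ", ")))
    }
  }
  grid <- tidyr::expand_grid(synapse_id = synapses$synapse_id,
                             patch = names(patches), seed = seeds)
  grid$result <- purrr::pmap(grid, function(synapse_id, patch, seed) {
    rec <- synapses$synapse[[match(synapse_id, synapses$synapse_id)]]
    cfg_i <- cfg
    for (nm in names(patches[[patch]])) cfg_i[[nm]] <- patches[[patch]][[nm]]
    cfg_i$seed <- derive_seed(seed, synapse_id)
    run_simulation(rec, cfg_i)
  })
  grid
}
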