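#' Specification for one synthetic tripartite-synapse volume
#'
#' Describes a bouton (sphere capped at the cleft) facing a spine head with
#' neck, an astrocytic leaflet sheet of given thickness wrapping stated
#' fractions of the pre- and postsynaptic perimeters, and inert neuropil
#' filler packed until the extracellular fraction reaches its target.
#'
#' @param bouton_radius_nm presynaptic bouton radius.
#' @param spine_head_radius_nm spine head radius.
#' @param cleft_width_nm synaptic cleft width.
#' @param leaflet_thickness_nm astrocytic sheet thickness.
#' @param wrap_fraction_pre,wrap_fraction_post fraction of the bouton / spine
#'   sphere surface wrapped by the leaflet, in \[0, 1\].
#' @param target_ecs_fraction extracellular volume fraction after filler
#'   packing (default 18%, the post-correction physiological value).
#' @param gap_nm standoff between cell membrane and leaflet (ECS film).
#' @param seed integer seed; identical specs with identical seeds produce
#'   bit-identical volumes.
#' @param vol_shape,pitch_nm grid shape and pitch of the sample volume.
#' @param axon_type,has_terminal,is_multisynaptic,target_is_spine selection
#'   attributes stamped on the resulting record.
#' @return a `calf_synapse_spec` list.
#' @export
synapse_geometry_spec <- function(bouton_radius_nm = 250,
                                  spine_head_radius_nm = 200,
                                  cleft_width_nm = 20,
                                  leaflet_thickness_nm = 120,
                                  wrap_fraction_pre = 0.5,
                                  wrap_fraction_post = 0.5,
                                  target_ecs_fraction = 0.18,
                                  gap_nm = 12,
                                  seed = 1L,
                                  vol_shape = c(201L, 201L, 41L),
                                  pitch_nm = c(6, 6, 30),
                                  axon_type = "excitatory",
                                  has_terminal = TRUE,
                                  is_multisynaptic = FALSE,
                                  target_is_spine = TRUE) {
  spec <- list(bouton_radius_nm = bouton_radius_nm,
               spine_head_radius_nm = spine_head_radius_nm,
               cleft_width_nm = cleft_width_nm,
               leaflet_thickness_nm = leaflet_thickness_nm,
               wrap_fraction_pre = wrap_fraction_pre,
               wrap_fraction_post = wrap_fraction_post,
               target_ecs_fraction = target_ecs_fraction,
               gap_nm = gap_nm, seed = as.integer(seed),
               vol_shape = as.integer(vol_shape), pitch_nm = as.double(pitch_nm),
               axon_type = axon_type, has_terminal = has_terminal,
               is_multisynaptic = is_multisynaptic,
               target_is_spine = target_is_spine)
  with(spec, {
    if (bouton_radius_nm <= 0 || spine_head_radius_nm <= 0 ||
        leaflet_thickness_nm <= 0 || cleft_width_nm < 0 || gap_nm < 0) {
      abort("Radii, thickness and widths must be positive.")
    }
    if (wrap_fraction_pre < 0 || wrap_fraction_pre > 1 ||
        wrap_fraction_post < 0 || wrap_fraction_post > 1) {
      abort("Wrap fractions must lie in [0, 1].")
    }
    if (target_ecs_fraction <= 0 || target_ecs_fraction >= 1) {
      abort("`target_ecs_fraction` must lie in (0, 1).")
    }
  })
  structure(spec, class = "calf_synapse_spec")
}

#' Specification for a synthetic synapse population
#'
#' @param n_synapses number of synapses (>= 1).
#' @param svr_mean,svr_sd normal distribution of target astrocytic SVR,
#'   in 1/um; defaults anchor the population to the leaflet regime
#'   (mean 22, sd 5).
#' @param coverage_shape1,coverage_shape2 Beta marginal for the wrap
#'   fractions; the defaults give broad coverage heterogeneity spanning
#'   \[0, 1\] with abundant asymmetric cases.
#' @param coverage_rho Gaussian-copula correlation between pre- and
#'   postsynaptic wrap.
#' @param ecs_fraction target ECS fraction of every volume.
#' @param seed population seed; per-synapse streams derive from it.
#' @param svr_values optional explicit SVR targets (overrides the normal
#'   draw; length `n_synapses`).
#' @return a `calf_population_spec` list.
#' @export
population_spec <- function(n_synapses,
                            svr_mean = 22, svr_sd = 5,
                            coverage_shape1 = 1.2, coverage_shape2 = 1.2,
                            coverage_rho = 0.4,
                            ecs_fraction = 0.18,
                            seed = 1L,
                            svr_values = NULL) {
  if (n_synapses < 1) abort("`n_synapses` must be >= 1.")
  if (svr_mean <= 0) abort("`svr_mean` must be positive.")
  if (!is.null(svr_values) && length(svr_values) != n_synapses) {
    abort("`svr_values` must have length `n_synapses`.")
  }
  structure(list(n_synapses = as.integer(n_synapses), svr_mean = svr_mean,
                 svr_sd = svr_sd, coverage_shape1 = coverage_shape1,
                 coverage_shape2 = coverage_shape2, coverage_rho = coverage_rho,
                 ecs_fraction = ecs_fraction, seed = as.integer(seed),
                 svr_values = svr_values),
            class = "calf_population_spec")
}

#' Calibration slab fixture with closed-form SVR
#'
#' An astrocyte slab spanning the full xy cross-section, `thickness_nm` thick
#' along z, embedded in ECS. Because only the two z faces are exposed and
#' boundary faces are excluded, the measured SVR is exactly `2/thickness`.
#'
#' @param thickness_nm slab thickness; must be a multiple of the z pitch and
#'   leave at least one ECS layer on either side.
#' @param vol_shape,pitch_nm grid shape and pitch.
#' @return a [label_volume()].
#' @export
make_slab_fixture <- function(thickness_nm,
                              vol_shape = c(201L, 201L, 41L),
                              pitch_nm = c(6, 6, 30)) {
  dz <- pitch_nm[3]
  nz <- vol_shape[3]
  if (abs(thickness_nm / dz - round(thickness_nm / dz)) > 1e-9 || thickness_nm <= 0) {
    abort(sprintf("`thickness_nm` (%g) must be a positive multiple of the z pitch (%g nm).",
                  thickness_nm, dz))
  }
  n_slab <- as.integer(round(thickness_nm / dz))
  if (n_slab > nz - 2L) {
    abort(sprintf("Slab of %g nm does not fit in a %d-layer volume with ECS margins.",
                  thickness_nm, nz))
  }
  labels <- array(0L, vol_shape)
  k0 <- (nz - n_slab) %/% 2L
  labels[, , (k0 + 1L):(k0 + n_slab)] <- 1L
  label_volume(labels, pitch_nm = pitch_nm,
               label_map = c(ecs = 0L, astrocyte = 1L))
}

# voxel-centre coordinate vectors, nm
axis_centres <- function(shape, pitch) {
  lapply(1:3, function(ax) (seq_len(shape[ax]) - 0.5) * pitch[ax])
}

# full 3D array of squared distance to point p from per-axis centre vectors
dist2_array <- function(cx, cy, cz, p) {
  outer(outer((cx - p[1])^2, (cy - p[2])^2, "+"), (cz - p[3])^2, "+")
}

# broadcast an ny x nz matrix over the x axis
broadcast_yz <- function(m, nx) {
  array(rep(m, each = nx), c(nx, nrow(m), ncol(m)))
}

# broadcast the x-axis vector over y, z
broadcast_x <- function(v, ny, nz) array(v, c(length(v), ny, nz))

#' Generate one synthetic tripartite-synapse volume
#'
#' Realises a [synapse_geometry_spec()]: bouton and spine spheres capped at
#' the cleft plane, a spine neck and axon shaft reaching the sample boundary,
#' an astrocytic leaflet shell at `gap_nm` standoff wrapping polar caps of
#' the stated surface fractions, and (optionally) randomly packed ellipsoidal
#' neuropil filler until the target ECS fraction is reached. The centroid is
#' the cleft centre.
#'
#' @param spec a [synapse_geometry_spec()].
#' @param fill pack neuropil filler (`TRUE`); disabled internally during
#'   thickness calibration, where filler cannot change the astrocytic SVR.
#' @return a [synapse_record()].
#' @export
make_tripartite <- function(spec, fill = TRUE) {
  stopifnot(inherits(spec, "calf_synapse_spec"))
  fields <- tripartite_fields(spec)
  labels <- place_leaflet(fields, spec$leaflet_thickness_nm,
                          spec$wrap_fraction_pre, spec$wrap_fraction_post,
                          spec$gap_nm, spec$target_ecs_fraction)
  lmap <- default_label_map()
  if (fill) {
    labels <- withr::with_seed(spec$seed, {
      pack_filler(labels, lmap, spec$pitch_nm, fields$ext,
                  spec$target_ecs_fraction)
    })
  }
  vol <- label_volume(labels, pitch_nm = spec$pitch_nm, label_map = lmap)
  synapse_record(vol, centroid_nm = fields$ctr,
                 axon_type = spec$axon_type,
                 has_terminal = spec$has_terminal,
                 is_multisynaptic = spec$is_multisynaptic,
                 target_is_spine = spec$target_is_spine)
}

# Deterministic geometric substrate shared by every leaflet thickness: cell
# labels plus the signed surface distances and polar-cap cosines used to
# carve the astrocytic shell. Computed once per spec so thickness calibration
# does not rebuild the distance fields.
tripartite_fields <- function(spec) {
  shape <- spec$vol_shape
  pitch <- spec$pitch_nm
  ext <- shape * pitch
  ctr <- ext / 2
  rb <- spec$bouton_radius_nm
  rs <- spec$spine_head_radius_nm
  cw2 <- spec$cleft_width_nm / 2
  bx <- ctr[1] + cw2 + 0.6 * rb
  sx <- ctr[1] - cw2 - 0.6 * rs
  if (bx + 0.4 * rb > ext[1] || sx - 0.4 * rs < 0 ||
      ctr[2] - max(rb, rs) < 0 || ctr[2] + max(rb, rs) > ext[2]) {
    abort("Unrealizable geometry spec: mandatory segments do not fit the volume.")
  }
  ax <- axis_centres(shape, pitch)
  cx <- ax[[1]]; cy <- ax[[2]]; cz <- ax[[3]]
  db <- sqrt(dist2_array(cx, cy, cz, c(bx, ctr[2], ctr[3])))
  ds <- sqrt(dist2_array(cx, cy, cz, c(sx, ctr[2], ctr[3])))
  ryz2 <- broadcast_yz(outer((cy - ctr[2])^2, (cz - ctr[3])^2, "+"), shape[1])
  X <- broadcast_x(cx, shape[2], shape[3])

  lmap <- default_label_map()
  labels <- array(lmap[["ecs"]], shape)
  bouton <- db <= rb & X >= ctr[1] + cw2
  spine <- ds <= rs & X <= ctr[1] - cw2
  if (!any(bouton) || !any(spine)) {
    abort("Unrealizable geometry spec: bouton or spine has no voxels.")
  }
  labels[spine] <- lmap[["spine"]]
  labels[bouton] <- lmap[["bouton"]]
  # spine neck toward -x boundary, axon shaft toward +x boundary
  neck <- X <= sx & ryz2 <= (0.35 * rs)^2 & labels == lmap[["ecs"]]
  labels[neck] <- lmap[["spine"]]
  shaft <- X >= bx & ryz2 <= (0.4 * rb)^2 & labels == lmap[["ecs"]]
  labels[shaft] <- lmap[["other"]]

  list(cells = labels, ext = ext, ctr = ctr,
       sb = db - rb, ss = ds - rs,
       ub = (X - bx) / pmax(db, 1e-9),   # cos angle from bouton back pole
       us = (sx - X) / pmax(ds, 1e-9))   # cos angle from spine back pole
}

# Carve the astrocytic leaflet into the ECS of a cells-only label array: a
# shell at [gap, gap + th] from the nearer sphere surface, restricted to
# polar caps (axes pointing away from the cleft) whose surface fractions are
# the wrap fractions. The shell volume is capped so the target ECS fraction
# stays reachable, trimming the least polar voxels (which narrows the wrap
# but preserves the thickness, hence the surface-to-volume ratio).
place_leaflet <- function(fields, th, wrap_pre, wrap_post, gap, target_ecs) {
  lmap <- default_label_map()
  labels <- fields$cells
  pre <- fields$sb >= gap & fields$sb <= gap + th &
    fields$ub >= 1 - 2 * wrap_pre & wrap_pre > 0
  post <- fields$ss >= gap & fields$ss <= gap + th &
    fields$us >= 1 - 2 * wrap_post & wrap_post > 0
  astro <- (pre | post) & labels == lmap[["ecs"]]
  n_cells <- sum(labels != lmap[["ecs"]])
  n_astro_max <- floor((1 - target_ecs - 0.02) * length(labels)) - n_cells
  if (sum(astro) > max(n_astro_max, 0L)) {
    sc <- pmax(ifelse(pre, fields$ub, -Inf), ifelse(post, fields$us, -Inf))
    sc[!astro] <- -Inf
    if (n_astro_max > 0L) {
      thr <- sort(sc[astro], decreasing = TRUE)[n_astro_max]
      astro <- astro & sc >= thr
    } else {
      astro[] <- FALSE
    }
  }
  labels[astro] <- lmap[["astrocyte"]]
  labels
}

# Pack axis-aligned random ellipsoids of inert neuropil ("other") into the
# ECS until its fraction reaches the target, protecting a thin ECS film
# around every existing structure so the extracellular network stays
# connected and tortuous rather than collapsing onto membranes.
pack_filler <- function(labels, lmap, pitch, ext, target, protect_xy = 2L,
                        protect_z = 1L, max_blobs = 800L) {
  ecs_id <- lmap[["ecs"]]
  other_id <- lmap[["other"]]
  non_ecs <- labels != ecs_id
  prot <- non_ecs
  for (s in c(-1L, 1L)) {
    for (r in seq_len(protect_xy)) {
      prot <- prot | shifted(non_ecs, 1L, s * r, fill = FALSE) |
        shifted(non_ecs, 2L, s * r, fill = FALSE)
    }
    for (r in seq_len(protect_z)) {
      prot <- prot | shifted(non_ecs, 3L, s * r, fill = FALSE)
    }
  }
  n_tot <- length(labels)
  n_ecs <- sum(labels == ecs_id)
  shape <- dim(labels)
  axc <- axis_centres(shape, pitch)
  for (b in seq_len(max_blobs)) {
    if (n_ecs / n_tot <= target + 0.004) break
    cen <- runif(3) * ext
    semi <- c(runif(2, 60, 150), runif(1, 60, 150))
    lo <- pmax(1L, ceiling((cen - semi) / pitch))
    hi <- pmin(shape, floor((cen + semi) / pitch) + 1L)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    ex <- ((axc[[1]][ix] - cen[1]) / semi[1])^2
    ey <- ((axc[[2]][iy] - cen[2]) / semi[2])^2
    ez <- ((axc[[3]][iz] - cen[3]) / semi[3])^2
    inside <- outer(outer(ex, ey, "+"), ez, "+") <= 1
    sub <- labels[ix, iy, iz, drop = FALSE]
    psub <- prot[ix, iy, iz, drop = FALSE]
    fillable <- inside & sub == ecs_id & !psub
    n_fill <- sum(fillable)
    if (n_fill == 0L) next
    sub[fillable] <- other_id
    labels[ix, iy, iz] <- sub
    n_ecs <- n_ecs - n_fill
  }
  labels
}

#' Generate a synthetic synapse population
#'
#' Draws per-synapse SVR targets (normal, or explicit via `svr_values`) and
#' wrap fractions (correlated Beta marginals via a Gaussian copula), then
#' calibrates each leaflet thickness so the *measured* SVR, not the analytic
#' one, matches its target: specs are realised, measured with the package's
#' own morphometrics, and thickness is iterated until measured SVR is within
#' 5% of target (voxelisation bias would otherwise shift the population).
#' Filler is packed only once per synapse, after calibration, since it cannot
#' change the astrocytic surface or volume.
#'
#' @param pop a [population_spec()].
#' @param contact_dist_nm coverage contact distance for the manifest.
#' @return a tibble with one row per synapse: `synapse_id`, a `synapse`
#'   list-column of [synapse_record()]s, the target SVR, the calibrated
#'   thickness, and measured morphometrics columns.
#' @export
make_population <- function(pop, contact_dist_nm = 12) {
  stopifnot(inherits(pop, "calf_population_spec"))
  draws <- withr::with_seed(pop$seed, {
    svr_t <- pop$svr_values %||%
      pmax(3, rnorm(pop$n_synapses, pop$svr_mean, pop$svr_sd))
    z1 <- rnorm(pop$n_synapses)
    z2 <- pop$coverage_rho * z1 +
      sqrt(1 - pop$coverage_rho^2) * rnorm(pop$n_synapses)
    list(svr_t = svr_t,
         wrap_pre = stats::qbeta(stats::pnorm(z1), pop$coverage_shape1, pop$coverage_shape2),
         wrap_post = stats::qbeta(stats::pnorm(z2), pop$coverage_shape1, pop$coverage_shape2),
         rb = runif(pop$n_synapses, 200, 300),
         rs = runif(pop$n_synapses, 150, 250))
  })
  rows <- purrr::map(seq_len(pop$n_synapses), function(i) {
    target <- draws$svr_t[i]
    # curved-shell face counting carries the Manhattan factor ~1.5, so the
    # slab relation t = 2/svr starts at roughly 3/svr here
    t_nm <- min(1000, max(15, 3000 / target))
    seed_i <- derive_seed(pop$seed, "synapse", i)
    spec_of <- function(t) synapse_geometry_spec(
      bouton_radius_nm = draws$rb[i], spine_head_radius_nm = draws$rs[i],
      leaflet_thickness_nm = t,
      wrap_fraction_pre = max(draws$wrap_pre[i], 0.02),
      wrap_fraction_post = max(draws$wrap_post[i], 0.02),
      target_ecs_fraction = pop$ecs_fraction, seed = seed_i)
    spec0 <- spec_of(t_nm)
    fields <- tripartite_fields(spec0)
    astro_id <- default_label_map()[["astrocyte"]]
    vox_um3 <- prod(spec0$pitch_nm) / 1e9
    for (it in 1:4) {
      labels <- place_leaflet(fields, t_nm, spec0$wrap_fraction_pre,
                              spec0$wrap_fraction_post, spec0$gap_nm,
                              spec0$target_ecs_fraction)
      s <- surface_cpp(labels, dim(labels), spec0$pitch_nm, astro_id)
      if (s$n_voxels == 0) break
      svr_m <- (s$area_nm2 / 1e6) / (s$n_voxels * vox_um3)
      if (abs(svr_m / target - 1) <= 0.05) break
      t_nm <- min(1000, max(15, t_nm * svr_m / target))
    }
    rec <- make_tripartite(spec_of(t_nm), fill = TRUE)
    rec$id <- sprintf("syn%03d", i)
    morph <- measure_morphometrics(rec$volume, contact_dist_nm)
    dplyr::bind_cols(
      tibble(synapse_id = rec$id, synapse = list(rec),
             svr_target = target, leaflet_thickness_nm = t_nm,
             wrap_pre = draws$wrap_pre[i], wrap_post = draws$wrap_post[i]),
      morph)
  })
  dplyr::bind_rows(rows)
}
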