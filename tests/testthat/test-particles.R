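test_that("pool initialisation converts concentration to a rounded count", {
  # slab astrocyte: known voxel count, so the expected count follows from
  # N = round(conc * V * N_A) computed independently here
  v <- make_slab_fixture(120)
  n_vox <- sum(v$labels == 1L)
  v_l <- n_vox * prod(v$pitch_nm) * 1e-24
  withr::with_seed(1, {
    pool <- init_pool_from_concentration(v, "ca", "astrocyte", 1e-7)
    expect_equal(nrow(pool$pos), round(1e-7 * v_l * AVO))
    expect_equal(pool$baseline_count, nrow(pool$pos))
    # all particles start inside astrocyte voxels
    idx <- floor(sweep(pool$pos, 2, v$pitch_nm, `/`)) + 1
    expect_true(all(v$labels[idx] == 1L))
    # ambient glutamate in the ECS
    g <- init_pool_from_concentration(v, "glu", "ecs", 3e-7)
    ecs_l <- sum(v$labels == 0L) * prod(v$pitch_nm) * 1e-24
    expect_equal(nrow(g$pos), round(3e-7 * ecs_l * AVO))
  })
  empty <- init_pool_from_concentration(v, "ca", "astrocyte", 0)
  expect_equal(nrow(empty$pos), 0)
  expect_equal(empty$baseline_count, 0L)
  lab <- array(1L, c(3, 3, 3))
  v_noecs <- label_volume(lab, label_map = c(ecs = 0L, astrocyte = 1L))
  expect_error(init_pool_from_concentration(v_noecs, "glu", "ecs", 1e-6),
               "zero volume")
})

test_that("diffusion obeys D = 0, stays in its compartment and honours the baseline floor", {
  v <- make_slab_fixture(300)
  withr::with_seed(2, {
    pool <- init_pool_from_concentration(v, "ca", "astrocyte", 5e-6)
    frozen <- diffuse_step(pool, v, diffusion_params(d_ca_um2_ms = 0),
                           n_steps = 50)
    expect_identical(frozen$pos, pool$pos)
    # confinement: after many steps every free particle is still astrocytic
    moved <- diffuse_step(pool, v, diffusion_params(), n_steps = 400)
    idx <- floor(sweep(moved$pos[moved$status == 0L, ], 2, v$pitch_nm, `/`)) + 1
    expect_true(all(v$labels[idx] == 1L))
    # a pool at baseline never shrinks through the boundary
    expect_equal(sum(moved$status == 0L), pool$baseline_count)
    expect_equal(moved$boundary_removed, 0)
    # above baseline, escaping glutamate is removed down toward baseline
    g <- init_pool_from_concentration(v, "glu", "ecs", 3e-7)
    g2 <- release_glutamate(g, v, dim(v$labels) * v$pitch_nm / 2, n = 2000,
                            spread_radius_nm = 300)
    g3 <- diffuse_step(g2, v, diffusion_params(), n_steps = 2000)
    expect_gt(g3$boundary_removed, 0)
    expect_gte(sum(g3$status == 0L), g$baseline_count)
    expect_equal(sum(g3$status == 0L) + g3$boundary_removed,
                 g$baseline_count + 2000)
  })
})

test_that("unconfined random walks recover the configured diffusion coefficient", {
  withr::with_seed(4, {
    est <- estimate_diffusion_coefficient(n_particles = 4000,
                                          d_um2_ms = 0.33, n_steps = 400)
    expect_equal(est$d_hat, 0.33, tolerance = 0.06)
    # MSD is linear in t: regression through origin explains almost all variance
    fit <- summary(lm(msd_um2 ~ 0 + time_ms, data = est$msd))
    expect_gt(fit$r.squared, 0.99)
  })
})

test_that("local concentration counts the 50 nm microdomain against its ECS volume", {
  # pure-ECS volume at fine pitch: a full 50 nm box holds 1.25e-19 L
  lab <- array(0L, c(40, 40, 40))
  v <- label_volume(lab, c(5, 5, 5), c(ecs = 0L))
  ctr <- c(100, 100, 100)
  pool <- particle_pool("glu", matrix(ctr, ncol = 3), home_role = "ecs")
  got <- local_concentration(pool, v, ctr, 50)
  expect_equal(got, 1 / (AVO * 1.25e-19), tolerance = 1e-9)  # 13.28 uM
  empty <- particle_pool("glu", matrix(numeric(0), ncol = 3), home_role = "ecs")
  expect_equal(local_concentration(empty, v, ctr, 50), 0)
  # law of large numbers: averaging local over many probe sites recovers the
  # global concentration
  withr::with_seed(6, {
    big <- init_pool_from_concentration(v, "glu", "ecs", 2e-4)
    sites <- matrix(runif(3 * 200, 50, 150), ncol = 3)
    locs <- vapply(seq_len(200), function(i) {
      local_concentration(big, v, sites[i, ], 50)
    }, numeric(1))
    expect_equal(mean(locs), 2e-4, tolerance = 0.05)
  })
})

test_that("glutamate release adds exactly n molecules inside nearby ECS voxels", {
  rec <- make_tripartite(synapse_geometry_spec(seed = 8))
  v <- rec$volume
  withr::with_seed(9, {
    pool <- init_pool_from_concentration(v, "glu", "ecs", 3e-7)
    n0 <- nrow(pool$pos)
    out <- release_glutamate(pool, v, rec$centroid_nm, n = 5000)
    expect_equal(nrow(out$pos), n0 + 5000)
    expect_equal(out$baseline_count, pool$baseline_count)
    new_idx <- floor(sweep(out$pos[(n0 + 1):(n0 + 5000), ], 2,
                           v$pitch_nm, `/`)) + 1
    expect_true(all(v$labels[new_idx] == v$label_map[["ecs"]]))
    expect_identical(release_glutamate(pool, v, rec$centroid_nm, n = 0), pool)
  })
  # a release point with no reachable ECS is an explicit error
  solid <- label_volume(array(1L, c(30, 30, 5)),
                        label_map = c(ecs = 0L, astrocyte = 1L))
  pool2 <- particle_pool("glu", matrix(numeric(0), ncol = 3), home_role = "ecs")
  expect_error(release_glutamate(pool2, solid, c(90, 90, 75), n = 10),
               "No ECS voxel")
})

test_that("transporter-event bookkeeping is exactly invertible and stoichiometric", {
  v <- make_slab_fixture(120)
  astro_l <- sum(v$labels == 1L) * prod(v$pitch_nm) * 1e-24
  na <- sodium_pool(astro_l, 15)
  pos <- c(600, 600, 620)
  glu <- particle_pool("glu", matrix(pos + c(10, 0, 0), ncol = 3),
                       home_role = "ecs")
  ca <- particle_pool("ca", matrix(pos + c(0, 10, 0), ncol = 3),
                      home_role = "astrocyte")
  ev <- function(action, na_delta = 0, mol = 1L) {
    tibble::tibble(step = 1L, molecule = mol, from = "a", to = "b",
                   action = action, na_delta = na_delta,
                   x = pos[1], y = pos[2], z = pos[3])
  }
  # bind then unbind restores the free count and parks the particle at the site
  st <- apply_transporter_events(list(glu = glu, ca = ca), na, ev("glu_bind"))
  expect_equal(sum(st$pools$glu$status == 0L), 0)
  st2 <- apply_transporter_events(st$pools, st$sodium, ev("glu_release_out"))
  expect_equal(sum(st2$pools$glu$status == 0L), 1)
  expect_equal(unname(st2$pools$glu$pos[1, ]), pos)
  # one completed forward EAAT cycle: +3 Na+ over the astrocytic volume
  st3 <- apply_transporter_events(st2$pools, st2$sodium, ev("none", na_delta = 3))
  expect_equal(st3$sodium$concentration_mM - 15,
               3e3 / (AVO * astro_l), tolerance = 1e-6)
  # reverse NCX cycle delivers one cytosolic calcium ion
  st4 <- apply_transporter_events(st3$pools, st3$sodium, ev("ca_release_in",
                                                            mol = 99L))
  expect_equal(sum(st4$pools$ca$status == 0L), 2)
  expect_equal(st4$ca_influx, 1L)
  # a bind with no eligible particle is cancelled and logged
  far <- ev("ca_bind_in")
  far$x <- 5000
  st5 <- apply_transporter_events(st4$pools, st4$sodium, far)
  expect_equal(nrow(st5$cancelled), 1)
})

test_that("confinement makes the mean squared displacement sublinear in time", {
  # in a 120 nm slab the z excursion saturates within a few steps and the
  # sample boundary bounds xy, so MSD grows much slower than the free-space
  # factor 10 between t = 0.1 ms and t = 1 ms
  withr::with_seed(31, {
    v <- make_slab_fixture(120)
    pool <- init_pool_from_concentration(v, "ca", "astrocyte", 2e-6)
    p0 <- pool$pos
    msd_of <- function(p) mean(rowSums((p$pos - p0)^2))
    p100 <- diffuse_step(pool, v, diffusion_params(), n_steps = 100)
    p1000 <- diffuse_step(p100, v, diffusion_params(), n_steps = 900)
    ratio <- msd_of(p1000) / msd_of(p100)
    expect_gt(ratio, 1)
    expect_lt(ratio, 8)
  })
})
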