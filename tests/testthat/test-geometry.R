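test_that("label volume invariants are enforced", {
  lab <- array(0L, c(4, 4, 4))
  expect_error(label_volume(lab, pitch_nm = c(6, -6, 30)), "positive")
  expect_error(label_volume(lab, label_map = c(astrocyte = 1L)), "ecs")
  expect_error(label_volume(array(7L, c(2, 2, 2))), "not in")
  expect_error(label_volume(array(0L, c(4, 4))), "3D")
  v <- label_volume(lab)
  expect_identical(dim(v), c(4L, 4L, 4L))
  expect_identical(v$pitch_nm, c(6, 6, 30))
})

test_that("ECS correction erodes cell rims in-plane and matches a neighbourhood-scan oracle", {
  # 5-voxel-wide astrocyte slab in xy, 6 nm shrink -> 3 voxels wide
  lab <- array(0L, c(21, 21, 5))
  lab[9:13, , ] <- 1L
  v <- vol_of(lab)
  marked <- brute_erosion_marked(v)
  out <- apply_ecs_correction(v, 6)
  expect_equal(sum(out$labels[, 11, 3] == 1L), 3L)
  ecs_before <- sum(v$labels == 0L)
  ecs_after <- sum(out$labels == 0L)
  expect_identical(ecs_after - ecs_before, sum(marked))
  # voxels that changed are exactly the marked ones, and they became ECS
  changed <- v$labels != out$labels
  expect_identical(changed, marked)
  expect_true(all(out$labels[changed] == 0L))
})

test_that("ECS correction is monotone, only relabels to ECS, and rejects bad shrink distances", {
  v <- vol_of(array(0L, c(8, 8, 3)))
  expect_identical(apply_ecs_correction(v, 6)$labels, v$labels)  # pure ECS
  expect_error(apply_ecs_correction(v, 7), "multiple")
  expect_error(apply_ecs_correction(v, -6), "multiple")
  withr::with_seed(5, {
    for (i in 1:5) {
      rv <- random_fixture(12)
      out <- apply_ecs_correction(rv, 6)
      f0 <- compartment_fractions(rv)
      f1 <- compartment_fractions(out)
      ecs0 <- f0$fraction[f0$role == "ecs"]
      ecs1 <- f1$fraction[f1$role == "ecs"]
      expect_gte(ecs1, ecs0)
      changed <- rv$labels != out$labels
      expect_true(all(out$labels[changed] == 0L))
      # strict increase: random fixtures always have adjacent distinct segments
      expect_gt(ecs1, ecs0)
    }
  })
})

test_that("compartment fractions are exact voxel tallies summing to one", {
  lab <- array(0L, c(4, 4, 4))
  lab[1:2, , ] <- 1L   # half astrocyte
  v <- vol_of(lab)
  fr <- compartment_fractions(v)
  expect_equal(fr$fraction[fr$role == "ecs"], 0.5)
  expect_equal(fr$fraction[fr$role == "astrocyte"], 0.5)
  expect_equal(sum(fr$fraction), 1)
  v_all <- vol_of(array(1L, c(3, 3, 3)))
  fr2 <- compartment_fractions(v_all)
  expect_equal(fr2$fraction[fr2$role == "astrocyte"], 1)
  withr::with_seed(9, {
    rv <- random_fixture(10)
    fr3 <- compartment_fractions(rv)
    tal <- table(factor(rv$labels, levels = 0:5)) / length(rv$labels)
    expect_equal(fr3$fraction, as.vector(tal), tolerance = 1e-12)
  })
})

test_that("surface area, volume and SVR match closed forms and the face-enumeration oracle", {
  # single isolated 6 x 6 x 30 nm voxel: 792 nm^2, 1080 nm^3, ~733 1/um
  lab <- array(0L, c(5, 5, 5))
  lab[3, 3, 3] <- 1L
  s <- astro_surface_area_volume(vol_of(lab))
  expect_equal(s$area_um2, 792e-6)
  expect_equal(s$volume_um3, 1080e-9)
  expect_equal(s$svr_um_inv, 792 / 1080 * 1000)
  # full-xy slabs: svr = 2/t exactly (boundary faces excluded)
  for (t_nm in c(60, 90, 600)) {
    sv <- astro_surface_area_volume(make_slab_fixture(t_nm))
    expect_equal(sv$svr_um_inv, 2 / (t_nm / 1000), tolerance = 1e-12)
  }
  # random connected blobs against the brute-force oracle
  withr::with_seed(31, {
    for (i in 1:3) {
      rv <- random_fixture(9)
      got <- astro_surface_area_volume(rv)
      want <- brute_surface(rv, 1L)
      expect_equal(got$area_um2, want$area_nm2 / 1e6, tolerance = 1e-12)
    }
  })
  expect_error(astro_surface_area_volume(vol_of(array(0L, c(3, 3, 3)))),
               "no astrocyte")
})

test_that("voxelised sphere SVR converges to the face-count (Manhattan) limit", {
  # summed axis-aligned face areas over-estimate a curved surface by 3/2,
  # so the voxelised estimate approaches 1.5 * 3/r, not 3/r
  ratios <- vapply(c(8L, 12L, 16L), function(rv) {
    n <- 2L * rv + 7L
    ax <- (seq_len(n) - 0.5) * 6
    c0 <- n * 6 / 2
    d2 <- outer(outer((ax - c0)^2, (ax - c0)^2, "+"), (ax - c0)^2, "+")
    lab <- array(0L, c(n, n, n))
    lab[d2 <= (rv * 6)^2] <- 1L
    v <- label_volume(lab, c(6, 6, 6), ecs_astro_map)
    s <- astro_surface_area_volume(v)
    s$svr_um_inv / (3 / (rv * 6 / 1000))
  }, numeric(1))
  expect_true(all(abs(ratios - 1.5) < 0.15))
})

test_that("coverage hits its endpoints, tracks the wrap solid angle and grows with contact distance", {
  n <- 101L
  ax <- (seq_len(n) - 0.5) * 6
  c0 <- n * 6 / 2
  d2 <- outer(outer((ax - c0)^2, (ax - c0)^2, "+"), (ax - c0)^2, "+")
  dist <- sqrt(d2)
  X <- array(ax, c(n, n, n))
  r_b <- 150
  # fully wrapped: shell one in-plane ECS voxel away
  lab_full <- array(0L, c(n, n, n))
  lab_full[d2 <= r_b^2] <- 2L
  lab_full[dist > r_b + 6 & dist <= r_b + 48] <- 1L
  v_full <- label_volume(lab_full, c(6, 6, 6),
                         c(ecs = 0L, astrocyte = 1L, bouton = 2L))
  expect_equal(synaptic_coverage(v_full, "bouton", 12), 1)
  # no astrocyte at all
  lab_none <- array(0L, c(n, n, n))
  lab_none[d2 <= r_b^2] <- 2L
  v_none <- label_volume(lab_none, c(6, 6, 6),
                         c(ecs = 0L, bouton = 2L, spine = 3L))
  expect_equal(synaptic_coverage(v_none, "bouton", 12), 0)
  expect_error(synaptic_coverage(v_none, "spine"), "absent")
  # hemispherical wrap ~ half the surface, within voxelisation error
  lab_h <- array(0L, c(n, n, n))
  lab_h[d2 <= r_b^2] <- 2L
  lab_h[dist >= r_b + 12 & dist <= r_b + 60 & (X - c0) >= 0] <- 1L
  v_h <- label_volume(lab_h, c(6, 6, 6),
                      c(ecs = 0L, astrocyte = 1L, bouton = 2L))
  expect_equal(synaptic_coverage(v_h, "bouton", 18), 0.5, tolerance = 0.16)
  # non-decreasing in contact distance, always within [0, 1]
  covs <- vapply(c(6, 12, 18, 24, 36, 60), function(cd) {
    synaptic_coverage(v_h, "bouton", cd)
  }, numeric(1))
  expect_true(all(diff(covs) >= 0))
  expect_true(all(covs >= 0 & covs <= 1))
})

test_that("five-criterion selection matches an independent filter and keeps order", {
  lab_hi <- array(0L, c(6, 6, 6)); lab_hi[1:3, , ] <- 1L   # astro 50%
  lab_lo <- array(0L, c(10, 10, 10)); lab_lo[1:4, 1, 1] <- 1L # astro 0.4%
  lab_019 <- array(0L, c(10, 10, 10))
  lab_019[seq_len(19)] <- 1L                                  # exactly 1.9%
  lab_02 <- array(0L, c(10, 10, 10))
  lab_02[seq_len(20)] <- 1L                                   # exactly 2.0%
  mk <- function(lab, ...) synapse_record(vol_of(lab), c(10, 10, 10), ...)
  # criterion-5 boundary: 1.9% excluded, 2.0% (inclusive) kept
  expect_length(select_synapses(list(mk(lab_019))), 0)
  expect_length(select_synapses(list(mk(lab_02))), 1)
  withr::with_seed(41, {
    recs <- lapply(1:40, function(i) {
      mk(if (runif(1) < 0.5) lab_hi else lab_lo,
         axon_type = sample(c("excitatory", "inhibitory"), 1),
         has_terminal = runif(1) < 0.7,
         is_multisynaptic = runif(1) < 0.3,
         target_is_spine = runif(1) < 0.7)
    })
    kept <- select_synapses(recs)
    # independent brute-force AND of the five criteria
    want <- Filter(function(r) {
      astro <- mean(r$volume$labels == 1L)
      r$axon_type == "excitatory" && r$has_terminal &&
        !r$is_multisynaptic && r$target_is_spine && astro >= 0.02
    }, recs)
    expect_identical(kept, want)
  })
  # missing attribute is reported by record
  bad <- mk(lab_hi)
  bad$has_terminal <- NULL
  expect_error(select_synapses(list(bad)), "has_terminal")
})
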