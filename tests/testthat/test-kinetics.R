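eaat <- build_eaat_scheme()
ncx <- build_ncx_scheme()
ctx0 <- rate_context()

test_that("scheme structure: cycle lengths, reversibility and ion stoichiometry", {
  expect_equal(n_cycle_steps(eaat), 13)
  expect_equal(nrow(eaat$transitions), 26)  # every step reversible
  expect_equal(n_cycle_steps(ncx), 6)
  expect_equal(nrow(ncx$transitions), 12)
  # EAAT forward cycle: 3 Na+, 1 H+, 1 Glu in; 1 K+ out
  s <- cycle_stoichiometry(eaat)
  expect_equal(s[["na_in"]], 3)
  expect_equal(s[["h_in"]], 1)
  expect_equal(s[["glu_in"]], 1)
  expect_equal(s[["k_out"]], 1)
  expect_equal(cycle_stoichiometry(eaat, "reverse"), -s)
  # NCX: 3 Na+ in per 1 Ca2+ out
  sn <- cycle_stoichiometry(ncx)
  expect_equal(sn[["na_in"]], 3)
  expect_equal(sn[["ca_out"]], 1)
  # the declared stoichiometry is realised by the per-transition Na ledger
  fwd <- function(sch) {
    st <- sch$states
    nxt <- st[c(2:length(st), 1)]
    tr <- sch$transitions
    sum(tr$na_delta[paste(tr$from, tr$to) %in% paste(st, nxt)])
  }
  expect_equal(fwd(eaat), 3)
  expect_equal(fwd(ncx), 3)
  # glutamate sequestration flags sit on the binding/unbinding transitions
  expect_true("glu_bind" %in% eaat$transitions$action)
  expect_true("ca_bind_in" %in% ncx$transitions$action)
  # every effective rate is nonnegative at physiological context
  expect_true(all(evaluate_rates(eaat, ctx0)$rate_eff >= 0))
  expect_true(all(evaluate_rates(ncx, ctx0)$rate_eff >= 0))
})

test_that("parameter-file validation reports what is missing or unknown", {
  p <- default_kinetic_params()
  broken <- p$ncx
  broken$transitions <- broken$transitions[-3, ]   # drop one direction
  expect_error(kinetic_scheme("ncx", broken$states, broken$transitions),
               "missing transitions.*in_ca -> out_ca")
  bad_lig <- p$ncx$transitions
  bad_lig$ligand[1] <- "mg_i"
  expect_error(kinetic_scheme("ncx", p$ncx$states, bad_lig), "Unknown ligand")
  # YAML loader: a transition without a rate names itself
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(eaat = list(
    states = c("a", "b"),
    transitions = list(list(from = "a", to = "b", units = "per_ms")))), tmp)
  expect_error(default_kinetic_params(tmp), "a -> b")
})

test_that("steady state solves closed forms and rejects degenerate generators", {
  toy <- kinetic_scheme("toy", c("s1", "s2"),
                        data.frame(from = c("s1", "s2"), to = c("s2", "s1"),
                                   rate = c(2, 1), units = "per_ms"))
  p <- steady_state(toy, rate_context(temperature_factor = 1))
  expect_equal(unname(p), c(1 / 3, 2 / 3), tolerance = 1e-12)
  # symmetric ring: uniform occupancy
  st <- paste0("r", 1:5)
  ring <- kinetic_scheme("ring", st,
                         data.frame(from = c(st, st[c(2:5, 1)]),
                                    to = c(st[c(2:5, 1)], st),
                                    rate = 1, units = "per_ms"))
  pr <- steady_state(ring, rate_context(temperature_factor = 1))
  expect_equal(unname(pr), rep(0.2, 5), tolerance = 1e-12)
  dead <- kinetic_scheme("dead", c("s1", "s2"),
                         data.frame(from = c("s1", "s2"), to = c("s2", "s1"),
                                    rate = 0, units = "per_ms"))
  expect_error(steady_state(dead, ctx0), "Degenerate")
  # EAAT/NCX steady states are proper distributions
  for (sch in list(eaat, ncx)) {
    p <- steady_state(sch, ctx0)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
  }
})

test_that("Q10 scaling is exact", {
  expect_equal(apply_q10(5, 3, 25, 25), 5)
  expect_equal(apply_q10(1, 3, 25, 35), 3)
  expect_equal(apply_q10(c(1, 2), 3, 20, 35), c(1, 2) * 3^1.5)
  expect_equal(apply_q10(1, 3, 20, 35), 5.196152, tolerance = 1e-6)
  expect_error(apply_q10(1, q10 = -1), "positive")
})

test_that("stochastic stepping reproduces analytic occupancies and Bernoulli frequencies", {
  # EAAT at baseline: 1000 molecules x 1000 steps from the analytic steady
  # state stay within 3 Monte-Carlo SE of it
  withr::with_seed(17, {
    p_ss <- steady_state(eaat, ctx0)
    n_mol <- 1000L
    pop <- transporter_population(
      eaat, states = sample.int(13, n_mol, replace = TRUE, prob = p_ss))
    out <- step_population(pop, ctx0, n_steps = 1000L)
    emp <- tabulate(out$pop$states, nbins = 13)
    for (k in 1:13) {
      se <- sqrt(n_mol * p_ss[k] * (1 - p_ss[k]))
      expect_lt(abs(emp[k] - n_mol * p_ss[k]), 3 * se + 3)
    }
  })
  # single transition k = 10/ms at dt = 1 us over 1e6 molecule-steps
  toy <- kinetic_scheme("toy", c("s1", "s2"),
                        data.frame(from = c("s1", "s2"), to = c("s2", "s1"),
                                   rate = c(10, 10), units = "per_ms"))
  count_events <- function(tf) {
    withr::with_seed(23, {
      pop <- transporter_population(toy, n = 10000L)
      acc <- 0L
      for (rep in 1:100) {
        pop$states <- rep(1L, 10000L)  # refresh so every step starts in s1
        out <- step_population(pop, rate_context(temperature_factor = tf),
                               n_steps = 1L)
        acc <- acc + sum(out$events$from == "s1")
      }
      acc
    })
  }
  n1 <- count_events(1)
  p_hat <- n1 / 1e6
  expect_lt(abs(p_hat - 0.01), 3 * sqrt(0.01 * 0.99 / 1e6))
  # temperature factor 3 triples the empirical frequency (small-p regime)
  n3 <- count_events(3)
  expect_equal(n3 / n1, 3, tolerance = 0.05)
  # all-zero rates produce no events
  dead <- kinetic_scheme("dead", c("s1", "s2"),
                         data.frame(from = c("s1", "s2"), to = c("s2", "s1"),
                                    rate = 0, units = "per_ms"))
  outd <- step_population(transporter_population(dead, n = 50L),
                          ctx0, n_steps = 20L)
  expect_equal(nrow(outd$events), 0)
  # rate * dt >= 1 is a named time-step violation
  fast <- kinetic_scheme("fast", c("s1", "s2"),
                         data.frame(from = c("s1", "s2"), to = c("s2", "s1"),
                                    rate = c(2000, 1), units = "per_ms"))
  expect_error(step_population(transporter_population(fast, n = 2L),
                               rate_context(temperature_factor = 1)),
               "Time-step violation.*s1")
})

test_that("analytic occupancy agrees with a continuous-time Gillespie oracle", {
  withr::with_seed(29, {
    occ <- gillespie_occupancy(ncx, ctx0, t_total_ms = 400)
    p <- steady_state(ncx, ctx0)
    expect_lt(max(abs(occ - p)), 0.025)
  })
})

test_that("NCX cycle flux vanishes at the reversal potential and switches sign with Na_i", {
  vrev <- ncx_reversal_potential_mv(ctx0)
  expect_equal(vrev, -85.6, tolerance = 0.01)
  ctx_rev <- rate_context(membrane_potential_mv = vrev)
  gross <- {
    p <- steady_state(ncx, ctx_rev)
    tr <- evaluate_rates(ncx, ctx_rev)
    p[["in_apo"]] * tr$rate_eff[tr$from == "in_apo" & tr$to == "in_ca"]
  }
  expect_lt(abs(cycle_flux(ncx, ctx_rev)), 1e-8 * gross)
  # at -70 mV: forward (Ca extrusion) below the reversal Na_i, reverse above
  expect_gt(cycle_flux(ncx, rate_context(na_i_mM = 10)), 0)
  expect_lt(cycle_flux(ncx, rate_context(na_i_mM = 15)), 0)
  expect_lt(cycle_flux(ncx, rate_context(na_i_mM = 20)), 0)
  # reverse-mode magnitude grows with Na_i
  expect_lt(cycle_flux(ncx, rate_context(na_i_mM = 20)),
            cycle_flux(ncx, rate_context(na_i_mM = 15)))
})

test_that("pre-equilibration returns valid, seed-deterministic state vectors", {
  withr::with_seed(3, s1 <- pre_equilibrate(ncx, ctx0, 200, t_ms = 2))
  withr::with_seed(3, s2 <- pre_equilibrate(ncx, ctx0, 200, t_ms = 2))
  expect_identical(s1, s2)
  expect_true(all(s1 >= 1 & s1 <= 6))
})
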