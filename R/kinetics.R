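LIGANDS <- c("none", "na_e", "na_i", "k_e", "k_i", "glu_e", "glu_i",
             "h", "ca_e", "ca_i")
ACTIONS <- c("none", "glu_bind", "glu_release_out", "glu_release_in",
             "glu_load_in", "ca_bind_in", "ca_release_in", "ca_release_out",
             "ca_load_out")
RATE_UNITS <- c("per_ms", "per_mM_ms", "per_mM3_ms")

#' Local ion and ligand concentrations seen by a transporter
#'
#' Concentrations are in mM, the membrane potential in mV and the temperature
#' correction is a dimensionless multiplier already resolved from Q10 (see
#' [apply_q10()]). Defaults are the study's baseline: 140/3/2 mM Na/K/Ca
#' outside, 15/130 mM Na/K inside, 3 mM cytosolic glutamate, 0.3 uM ambient
#' extracellular glutamate, 100 nM cytosolic calcium, pH 7.3, -70 mV, and one
#' Q10 = 3 decade.
#'
#' @param glu_e_mM,na_e_mM,na_i_mM,k_e_mM,k_i_mM,ca_e_mM,ca_i_mM,glu_i_mM,h_mM
#'   concentrations in mM.
#' @param membrane_potential_mv membrane potential, mV.
#' @param temperature_factor multiplicative rate correction (> 0).
#' @return a `calf_rate_context`.
#' @export
rate_context <- function(glu_e_mM = 3e-4,
                         na_e_mM = 140, na_i_mM = 15,
                         k_e_mM = 3, k_i_mM = 130,
                         ca_e_mM = 2, ca_i_mM = 1e-4,
                         glu_i_mM = 3,
                         h_mM = 10^(-7.3) * 1e3,
                         membrane_potential_mv = -70,
                         temperature_factor = 3) {
  ctx <- list(none = 1, glu_e = glu_e_mM, na_e = na_e_mM, na_i = na_i_mM,
              k_e = k_e_mM, k_i = k_i_mM, ca_e = ca_e_mM, ca_i = ca_i_mM,
              glu_i = glu_i_mM, h = h_mM,
              membrane_potential_mv = membrane_potential_mv,
              temperature_factor = temperature_factor)
  conc <- unlist(ctx[setdiff(LIGANDS, "none")])
  if (any(!is.finite(conc)) || any(conc < 0)) {
    abort("All concentrations must be finite and non-negative.")
  }
  if (!is.finite(temperature_factor) || temperature_factor <= 0) {
    abort("`temperature_factor` must be positive.")
  }
  structure(ctx, class = "calf_rate_context")
}

#' Q10 temperature scaling of reaction rates
#'
#' @param base_rates numeric rates.
#' @param q10 rate ratio per 10 degree C (> 0), default 3.
#' @param t_ref_c temperature the base rates refer to, degrees C.
#' @param t_sim_c simulated temperature, degrees C. The defaults span one
#'   decade, so the factor is exactly `q10`.
#' @return scaled rates.
#' @export
apply_q10 <- function(base_rates, q10 = 3, t_ref_c = 25, t_sim_c = 35) {
  if (!is.finite(q10) || q10 <= 0) abort("`q10` must be positive.")
  base_rates * q10^((t_sim_c - t_ref_c) / 10)
}

#' Construct a Markov kinetic scheme for a membrane transporter
#'
#' A ring of states with reversible steps; each directed transition carries a
#' base rate, an optional ligand-concentration factor, an optional charge
#' moved into the cell (symmetric Eyring voltage factor
#' `exp(-q V / (2 RT/F))`), a particle-bookkeeping action, and the change in
#' intracellular sodium count it causes.
#'
#' @param name scheme name.
#' @param states ordered character vector of state names (the cycle order).
#' @param transitions data frame with columns `from`, `to`, `rate`, `units`,
#'   and optionally `ligand`, `charge`, `action`, `na_delta`.
#' @param stoichiometry named list: net species moved per completed forward
#'   cycle.
#' @return a `calf_scheme`.
#' @export
kinetic_scheme <- function(name, states, transitions, stoichiometry = list()) {
  states <- as.character(states)
  if (anyDuplicated(states)) abort("State names must be unique.")
  tr <- as_tibble(transitions)
  for (col in c("ligand", "action")) {
    if (is.null(tr[[col]])) tr[[col]] <- NA_character_
    tr[[col]][is.na(tr[[col]])] <- "none"
  }
  for (col in c("charge", "na_delta")) {
    if (is.null(tr[[col]])) tr[[col]] <- 0
    tr[[col]][is.na(tr[[col]])] <- 0
  }
  bad_state <- setdiff(c(tr$from, tr$to), states)
  if (length(bad_state)) {
    abort(paste0("Transitions reference unknown states: ",
                 paste(unique(bad_state), collapse = ", ")))
  }
  if (!all(tr$units %in% RATE_UNITS)) {
    abort(paste0("Rate units must be one of: ", paste(RATE_UNITS, collapse = ", ")))
  }
  if (!all(tr$ligand %in% LIGANDS)) {
    abort(paste0("Unknown ligand(s): ",
                 paste(setdiff(tr$ligand, LIGANDS), collapse = ", ")))
  }
  if (!all(tr$action %in% ACTIONS)) {
    abort(paste0("Unknown action(s): ",
                 paste(setdiff(tr$action, ACTIONS), collapse = ", ")))
  }
  if (any(!is.finite(tr$rate)) || any(tr$rate < 0)) {
    abort("All base rates must be finite and non-negative.")
  }
  # a ring scheme must have both directions of every consecutive step
  n <- length(states)
  ring <- tibble(from = states, to = states[c(2:n, 1)])
  have <- paste(tr$from, tr$to)
  missing_fwd <- ring[!paste(ring$from, ring$to) %in% have, ]
  missing_bwd <- ring[!paste(ring$to, ring$from) %in% have, ]
  if (nrow(missing_fwd) || nrow(missing_bwd)) {
    msgs <- c(sprintf("%s -> %s", missing_fwd$from, missing_fwd$to),
              sprintf("%s -> %s", missing_bwd$to, missing_bwd$from))
    abort(paste0("Incomplete rate set; missing transitions: ",
                 paste(msgs, collapse = ", ")))
  }
  tr$ligand_order <- ifelse(tr$units == "per_mM3_ms", 3L,
                            ifelse(tr$units == "per_mM_ms", 1L, 0L))
  if (any(tr$ligand_order > 0 & tr$ligand == "none")) {
    abort("Concentration-dependent rates must name a ligand.")
  }
  structure(list(name = name, states = states, transitions = tr,
                 stoichiometry = stoichiometry),
            class = "calf_scheme")
}

#' @export
print.calf_scheme <- function(x, ...) {
  cat(sprintf("<calf_scheme> %s: %d states, %d directed transitions (%d steps)\n",
              x$name, length(x$states), nrow(x$transitions), length(x$states)))
  invisible(x)
}

#' Number of steps in the transport cycle
#' @param scheme a `calf_scheme`.
#' @return integer.
#' @export
n_cycle_steps <- function(scheme) length(scheme$states)

#' Net species stoichiometry of a transport cycle
#'
#' @param scheme a `calf_scheme`.
#' @param direction `"forward"` (cycle order of `states`) or `"reverse"`
#'   (its exact negation).
#' @return named numeric vector of species moved into the cell per completed
#'   cycle (negative = moved out), e.g. `na_in`, `glu_in`, `k_out`.
#' @export
cycle_stoichiometry <- function(scheme, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  s <- unlist(scheme$stoichiometry)
  if (direction == "reverse") s <- -s
  s
}

#' Load the shipped transporter rate-parameter file
#'
#' @param path optional path to an edited YAML file with the same schema.
#' @return named list with an entry per scheme (`eaat`, `ncx`), each holding
#'   `states`, `transitions` (tibble) and `stoichiometry`.
#' @export
default_kinetic_params <- function(path = NULL) {
  path <- path %||% system.file("extdata", "kinetics.yaml", package = "calfluct")
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(sch) {
    if (is.null(sch$states) || is.null(sch$transitions)) {
      abort("Each scheme needs `states` and `transitions`.")
    }
    tr <- dplyr::bind_rows(lapply(sch$transitions, function(t) {
      if (is.null(t$rate) || is.null(t$from) || is.null(t$to) || is.null(t$units)) {
        abort(sprintf("Transition %s -> %s is missing a rate, from, to or units field.",
                      t$from %||% "?", t$to %||% "?"))
      }
      tibble(from = t$from, to = t$to, rate = as.double(t$rate),
             units = t$units, ligand = t$ligand %||% "none",
             charge = as.double(t$charge %||% 0),
             action = t$action %||% "none",
             na_delta = as.double(t$na_delta %||% 0))
    }))
    list(states = unlist(sch$states), transitions = tr,
         stoichiometry = sch$stoichiometry %||% list())
  })
  out
}

#' Build the glutamate-transporter (EAAT) kinetic scheme
#'
#' A 13-step alternating-access cycle with separate binding/unbinding of
#' 3 Na+, 1 H+ and 1 Glu on the extracellular side and K+ countertransport;
#' the glutamate-binding transition is flagged for particle sequestration.
#'
#' @param params parameter list from [default_kinetic_params()].
#' @return a `calf_scheme`.
#' @export
build_eaat_scheme <- function(params = default_kinetic_params()) {
  kinetic_scheme("eaat", params$eaat$states, params$eaat$transitions,
                 params$eaat$stoichiometry)
}

#' Build the sodium-calcium exchanger (NCX) kinetic scheme
#'
#' A 6-step consecutive cycle exchanging 3 Na+ (in) for 1 Ca2+ (out) per
#' forward cycle; the cytosolic calcium-binding transition is flagged for
#' particle sequestration, so reverse cycles create cytosolic free calcium.
#'
#' @param params parameter list from [default_kinetic_params()].
#' @return a `calf_scheme`.
#' @export
build_ncx_scheme <- function(params = default_kinetic_params()) {
  kinetic_scheme("ncx", params$ncx$states, params$ncx$transitions,
                 params$ncx$stoichiometry)
}

#' Effective transition rates under a concentration/voltage/temperature context
#'
#' `rate_eff = base * [ligand]^order * exp(-q V / (2 RT/F)) * temperature_factor`,
#' in 1/ms.
#'
#' @param scheme a `calf_scheme`.
#' @param ctx a [rate_context()].
#' @return the scheme's transition tibble with a `rate_eff` column.
#' @export
evaluate_rates <- function(scheme, ctx) {
  stopifnot(inherits(scheme, "calf_scheme"), inherits(ctx, "calf_rate_context"))
  tr <- scheme$transitions
  lig <- vapply(seq_len(nrow(tr)), function(i) {
    if (tr$ligand[i] == "none") 1 else ctx[[tr$ligand[i]]]^tr$ligand_order[i]
  }, numeric(1))
  volt <- exp(-tr$charge * ctx$membrane_potential_mv / (2 * RT_OVER_F_MV))
  tr$rate_eff <- tr$rate * lig * volt * ctx$temperature_factor
  if (any(!is.finite(tr$rate_eff)) || any(tr$rate_eff < 0)) {
    abort("Effective rates must be finite and non-negative under this context.")
  }
  tr
}

#' Generator matrix of a scheme under a context
#'
#' `Q[j, i]` is the rate from state i to state j; columns sum to zero, so the
#' master equation reads `dp/dt = Q p`.
#'
#' @inheritParams evaluate_rates
#' @return an n x n matrix with state dimnames.
#' @export
generator_matrix <- function(scheme, ctx) {
  tr <- evaluate_rates(scheme, ctx)
  n <- length(scheme$states)
  Q <- matrix(0, n, n, dimnames = list(scheme$states, scheme$states))
  fi <- match(tr$from, scheme$states)
  ti <- match(tr$to, scheme$states)
  for (i in seq_len(nrow(tr))) {
    Q[ti[i], fi[i]] <- Q[ti[i], fi[i]] + tr$rate_eff[i]
    Q[fi[i], fi[i]] <- Q[fi[i], fi[i]] - tr$rate_eff[i]
  }
  Q
}

# reachability over positive-rate directed edges
is_strongly_connected <- function(scheme, ctx) {
  tr <- evaluate_rates(scheme, ctx)
  tr <- tr[tr$rate_eff > 0, ]
  n <- length(scheme$states)
  reach <- function(edges_from, edges_to) {
    seen <- rep(FALSE, n); seen[1] <- TRUE; frontier <- 1L
    while (length(frontier)) {
      nxt <- unique(edges_to[edges_from %in% frontier])
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    all(seen)
  }
  fi <- match(tr$from, scheme$states); ti <- match(tr$to, scheme$states)
  reach(fi, ti) && reach(ti, fi)
}

#' Analytic steady-state occupancy of a kinetic scheme
#'
#' Solves `Q p = 0`, `sum(p) = 1`. Strong connectivity of the positive-rate
#' graph guarantees existence and uniqueness.
#'
#' @inheritParams evaluate_rates
#' @return named probability vector over states.
#' @export
steady_state <- function(scheme, ctx) {
  Q <- generator_matrix(scheme, ctx)
  if (all(Q == 0)) abort("Degenerate generator: all rates are zero under this context.")
  if (!is_strongly_connected(scheme, ctx)) {
    abort("The rate graph is not strongly connected under this context; steady state is not unique.")
  }
  n <- nrow(Q)
  A <- rbind(Q, rep(1, n))
  b <- c(rep(0, n), 1)
  p <- qr.solve(A, b)
  p <- pmax(p, 0)
  p <- p / sum(p)
  setNames(p, scheme$states)
}

#' Net steady-state cycle flux
#'
#' Net probability flux per molecule around the ring (positive = forward
#' cycle direction), measured across the first step; at steady state the net
#' flux is identical across every step of a ring.
#'
#' @inheritParams evaluate_rates
#' @return flux in cycles per ms per molecule.
#' @export
cycle_flux <- function(scheme, ctx) {
  p <- steady_state(scheme, ctx)
  tr <- evaluate_rates(scheme, ctx)
  s1 <- scheme$states[1]; s2 <- scheme$states[2]
  kf <- sum(tr$rate_eff[tr$from == s1 & tr$to == s2])
  kb <- sum(tr$rate_eff[tr$from == s2 & tr$to == s1])
  unname(p[s1] * kf - p[s2] * kb)
}

#' NCX reversal potential
#'
#' `V_rev = 3 E_Na - 2 E_Ca`; for membrane potentials above it the exchanger
#' runs in reverse mode (Ca2+ entry), below it in forward mode (Ca2+
#' extrusion).
#'
#' @param ctx a [rate_context()].
#' @return potential in mV.
#' @export
ncx_reversal_potential_mv <- function(ctx) {
  e_na <- RT_OVER_F_MV * log(ctx$na_e / ctx$na_i)
  e_ca <- RT_OVER_F_MV / 2 * log(ctx$ca_e / ctx$ca_i)
  3 * e_na - 2 * e_ca
}

#' A population of transporter molecules sharing one kinetic scheme
#'
#' @param scheme a `calf_scheme`.
#' @param n number of molecules (ignored when `states` given).
#' @param states integer state indices (default: all in state 1).
#' @param positions optional n x 3 matrix of surface positions in nm.
#' @return a `calf_transporters`.
#' @export
transporter_population <- function(scheme, n = NULL, states = NULL,
                                   positions = NULL) {
  stopifnot(inherits(scheme, "calf_scheme"))
  if (is.null(states)) {
    if (is.null(n)) abort("Give either `n` or `states`.")
    states <- rep(1L, n)
  }
  states <- as.integer(states)
  if (any(states < 1L | states > length(scheme$states))) {
    abort("State indices out of range.")
  }
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    stopifnot(nrow(positions) == length(states), ncol(positions) == 3)
  }
  structure(list(scheme = scheme, states = states, positions = positions),
            class = "calf_transporters")
}

#' Advance a transporter population by fixed Bernoulli steps
#'
#' Each molecule makes at most one transition per `dt_ms` with probability
#' `rate_eff * dt` per candidate transition; the total exit probability of
#' every state must stay below 1 (time-step violation otherwise). Contexts
#' may be shared or given per molecule (e.g. local glutamate); seed the R RNG
#' beforehand for reproducibility.
#'
#' @param pop a [transporter_population()].
#' @param ctx a [rate_context()] or a list of contexts, one per molecule.
#' @param dt_ms time step in ms (default 1 us).
#' @param n_steps number of steps.
#' @return list with the updated `pop` and `events`, a tibble of fired
#'   transitions (step, molecule, from, to, action, na_delta, and molecule
#'   position columns when the population carries positions).
#' @export
step_population <- function(pop, ctx, dt_ms = 1e-3, n_steps = 1L) {
  stopifnot(inherits(pop, "calf_transporters"))
  n_mol <- length(pop$states)
  scheme <- pop$scheme
  ctx_list <- if (inherits(ctx, "calf_rate_context")) list(ctx) else ctx
  grp <- if (length(ctx_list) == 1L) rep(1L, n_mol) else {
    if (length(ctx_list) != n_mol) abort("Need one context per molecule.")
    seq_len(n_mol)
  }
  # per-context transition probability matrix: states x transitions
  n_states <- length(scheme$states)
  mats <- lapply(ctx_list, function(cx) {
    tr <- evaluate_rates(scheme, cx)
    p <- tr$rate_eff * dt_ms
    tot <- tapply(p, factor(tr$from, levels = scheme$states), sum, default = 0)
    if (any(tot >= 1)) {
      bad <- names(tot)[which.max(tot)]
      viol <- tr[tr$from == bad, ]
      abort(sprintf(
        "Time-step violation: exit probability %.3f >= 1 from state `%s` (e.g. transition %s -> %s).",
        max(tot), bad, viol$from[1], viol$to[1]))
    }
    list(p = p, from = match(tr$from, scheme$states),
         to = match(tr$to, scheme$states), tr = tr)
  })
  events <- vector("list", n_steps)
  states <- pop$states
  for (s in seq_len(n_steps)) {
    u <- runif(n_mol)
    fired_mol <- integer(0); fired_tr <- integer(0)
    for (g in unique(grp)) {
      m <- mats[[g]]
      idx <- which(grp == g)
      # cumulative probabilities per transition within each state's list
      for (st in unique(states[idx])) {
        mm <- idx[states[idx] == st]
        trs <- which(m$from == st)
        if (!length(trs)) next
        cum <- cumsum(m$p[trs])
        sel <- findInterval(u[mm], c(0, cum), left.open = TRUE,
                            rightmost.closed = FALSE)
        hit <- sel >= 1 & sel <= length(trs) & u[mm] < cum[length(cum)]
        if (any(hit)) {
          fired_mol <- c(fired_mol, mm[hit])
          fired_tr <- c(fired_tr, trs[sel[hit]])
        }
      }
    }
    if (length(fired_mol)) {
      m0 <- mats[[1]]$tr
      ev <- tibble(step = s, molecule = fired_mol,
                   from = m0$from[fired_tr], to = m0$to[fired_tr],
                   action = m0$action[fired_tr],
                   na_delta = m0$na_delta[fired_tr])
      if (!is.null(pop$positions)) {
        ev$x <- pop$positions[fired_mol, 1]
        ev$y <- pop$positions[fired_mol, 2]
        ev$z <- pop$positions[fired_mol, 3]
      }
      events[[s]] <- ev
      states[fired_mol] <- match(m0$to[fired_tr], scheme$states)
    }
  }
  pop$states <- states
  list(pop = pop, events = dplyr::bind_rows(events))
}

#' Stochastically pre-equilibrate a cohort of transporter molecules
#'
#' Samples initial states from the analytic steady state, then evolves each
#' molecule independently for `t_ms` with pinned concentrations at fixed
#' Bernoulli steps (the protocol used before the timed phase of a
#' simulation). Seed the R RNG beforehand for reproducibility.
#'
#' @param scheme a `calf_scheme`.
#' @param ctx a [rate_context()].
#' @param n_molecules cohort size.
#' @param t_ms equilibration time (default 30 ms).
#' @param dt_ms step (default 1 us).
#' @return integer vector of state indices (length `n_molecules`).
#' @export
pre_equilibrate <- function(scheme, ctx, n_molecules, t_ms = 30, dt_ms = 1e-3) {
  p_ss <- steady_state(scheme, ctx)
  states <- sample.int(length(p_ss), n_molecules, replace = TRUE, prob = p_ss)
  compiled <- compile_scheme(scheme, ctx, dt_ms, pinned = TRUE)
  evolve_states_cpp(states, compiled, as.integer(round(t_ms / dt_ms)))
}
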