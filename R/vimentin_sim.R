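#' Vimentin filament model parameters
#'
#' Coarse-grained lattice of `n_parallel` dimer-level elements per
#' cross-section (16 for vimentin, whose cross-section holds 32 monomers)
#' times `n_serial` axial repeats.  Strong lateral connections prevent
#' subunit sliding; instead the alpha-helical element of each dimer unfolds
#' under force.  Element states:
#'
#' * `ALPHA` - folded helix, rest length `len_alpha`, stiffness `k_alpha`;
#'   unfolds irreversibly at Bell rate
#'   `nu_unfold * exp((f - f_unfold) * x_unfold / kBT)`.
#' * `UNFOLDED` - extended polypeptide, rest `len_unfold` (longest),
#'   stiffness `k_unfold`; converts to a random coil when the local tension
#'   falls below `refold_f` during relaxation (never back to `ALPHA`).
#' * `COIL` - soft persistent state, compact rest `len_coil` (marginally
#'   longer than the folded helix) at stiffness
#'   `k_coil < k_alpha`; on later cycles it opens reversibly to an extended
#'   coil of rest `len_coil_ext` at a lower force threshold `f_coil`, so
#'   repeated cycles retain (smaller) hysteresis while the filament keeps
#'   its original length.
#'
#' Unfolding and coil-opening thresholds are mildly quenched-random
#' (uniform within `+- f_spread/2` of their means), giving the gradual
#' plateau onset seen in measured force-strain curves.  Defaults are
#' calibrated so the first stretch is linear up to a strain near 0.15,
#' shows a plateau of about 250 pN up to a strain near 0.8, and stiffens
#' beyond.
#'
#' @param n_serial Axial repeats per protofilament.
#' @param n_parallel Dimer-level elements per cross-section.
#' @param len_alpha,len_unfold,len_coil,len_coil_ext Rest lengths of the
#'   folded, unfolded, compact-coil and extended-coil states, nm.
#' @param k_alpha,k_unfold,k_coil Element stiffnesses, pN/nm.
#' @param f_unfold Mean unfolding threshold tension, pN.
#' @param f_coil Mean coil-opening threshold tension, pN.
#' @param f_spread Width of the quenched unfolding-threshold
#'   distribution, pN.
#' @param f_coil_spread Width of the coil-opening threshold
#'   distribution, pN.
#' @param x_unfold Bell distance of the unfolding transition, nm.
#' @param x_coil Bell distance of the coil open/close transitions, nm.
#' @param nu_unfold,nu_coil Attempt rates at threshold, 1/s.
#' @param nu_coil_close Coil re-closing rate at tension `f_close`, 1/s.
#' @param f_close Tension scale below which extended coils re-close, pN.
#' @param refold_f Tension below which unfolded elements convert to the
#'   coil state, pN.
#' @param nu_refold Conversion rate below `refold_f`, 1/s.
#' @param destabilize Enable the high-force destabilization rule: if more
#'   than `destab_frac` of the elements in any cross-section have left the
#'   `ALPHA` state, the filament ruptures during the next cycle.  Off by
#'   default.
#' @param destab_frac Cross-section fraction triggering destabilization.
#' @param rate_cap Numerical ceiling on any single rate, 1/s.
#' @return An object of class `vimentin_params`.
#' @export
vimentin_params <- function(n_serial = 20, n_parallel = 16,
                            len_alpha = 43, len_unfold = 76,
                            len_coil = 43.5, len_coil_ext = 63,
                            k_alpha = 2.42, k_unfold = 8.0, k_coil = 1.5,
                            f_unfold = 19, f_coil = 13.5, f_spread = 6,
                            f_coil_spread = 2,
                            x_unfold = 2.5, x_coil = 6,
                            nu_unfold = 6, nu_coil = 1,
                            nu_coil_close = 5, f_close = 2.5,
                            refold_f = 1.2, nu_refold = 30,
                            destabilize = FALSE, destab_frac = 0.9,
                            rate_cap = 1000) {
  stopifnot(n_serial >= 2, n_parallel >= 2,
            len_unfold > len_alpha, k_coil < k_alpha,
            f_unfold > 0, f_coil > 0, x_unfold >= 0)
  structure(as.list(environment()), class = "vimentin_params")
}

# element states
V_ALPHA <- 0L; V_UNF <- 1L; V_COIL <- 2L; V_COIL_EXT <- 3L

vimentin_state <- function(cfg) {
  ns <- cfg$n_serial; np <- cfg$n_parallel
  half <- cfg$f_spread / 2
  list(
    st = matrix(V_ALPHA, ns, np),
    f_u = matrix(stats::runif(ns * np, cfg$f_unfold - half,
                              cfg$f_unfold + half), ns, np),
    f_ce = matrix(stats::runif(ns * np, cfg$f_coil - cfg$f_coil_spread / 2,
                               cfg$f_coil + cfg$f_coil_spread / 2), ns, np),
    L0 = ns * cfg$len_alpha, L_rest = ns * cfg$len_alpha,
    d_prev = NA_real_, went_down = FALSE, cycle_ctr = 1L,
    destab_cycle = NA_integer_)
}

# mean-field chain: tension shared equally among parallel paths, so all
# paths carry the tension of the average chain (mean rest length and mean
# compliance over protofilaments)
vimentin_mech <- function(state, cfg) {
  rest_tab <- c(cfg$len_alpha, cfg$len_unfold, cfg$len_coil,
                cfg$len_coil_ext)
  kinv_tab <- 1 / c(cfg$k_alpha, cfg$k_unfold, cfg$k_coil, cfg$k_coil)
  list(R = sum(rest_tab[state$st + 1L]) / cfg$n_parallel,
       C = sum(kinv_tab[state$st + 1L]) / cfg$n_parallel)
}

#' One Monte Carlo step of the vimentin unfolding model
#'
#' Advances unfolding/refolding/coil kinetics over `dt` at fixed imposed
#' distance `d`; see [vimentin_params()] for the state machine.  The step
#' is subdivided so no single-step probability exceeds `params$p_max`.
#'
#' @param state Model state from `vimentin_state()`.
#' @param d Imposed end-to-end distance, nm.
#' @param dt Time step, s (0 = evaluate force only).
#' @param cfg A [vimentin_params()].
#' @param params A [mechanical_params()].
#' @return `list(state, F, events, rupture)`.
#' @export
vimentin_step <- function(state, d, dt, cfg, params) {
  ns <- cfg$n_serial; np <- cfg$n_parallel
  kBT <- params$kBT
  # cycle bookkeeping for the destabilization rule
  if (!is.na(state$d_prev)) {
    if (d < state$d_prev) state$went_down <- TRUE
    else if (d > state$d_prev && state$went_down) {
      state$went_down <- FALSE
      state$cycle_ctr <- state$cycle_ctr + 1L
    }
  }
  state$d_prev <- d
  mech <- vimentin_mech(state, cfg)
  tq <- max(0, (d - mech$R) / mech$C)
  rupture <- FALSE
  ev_type <- character(0); ev_pf <- integer(0); ev_site <- integer(0)
  ev_f <- numeric(0)
  if (cfg$destabilize && !is.na(state$destab_cycle) &&
      state$cycle_ctr > state$destab_cycle && tq > 0) {
    return(list(state = state, F = 0, events =
                  data.frame(type = "rupture", pf = NA_integer_,
                             site = NA_integer_, tension = np * tq),
                rupture = TRUE))
  }
  if (dt > 0) {
    t_left <- dt
    while (t_left > 0) {
      r <- matrix(0, ns, np)
      a <- state$st == V_ALPHA
      r[a] <- pmin(cfg$rate_cap,
                   cfg$nu_unfold * exp((tq - state$f_u[a]) *
                                         cfg$x_unfold / kBT))
      u <- state$st == V_UNF
      if (tq < cfg$refold_f) r[u] <- cfg$nu_refold
      cc <- state$st == V_COIL
      r[cc] <- pmin(cfg$rate_cap,
                    cfg$nu_coil * exp((tq - state$f_ce[cc]) *
                                        cfg$x_coil / kBT))
      ce <- state$st == V_COIL_EXT
      r[ce] <- pmin(cfg$rate_cap,
                    cfg$nu_coil_close * exp((cfg$f_close - tq) *
                                              cfg$x_coil / kBT))
      rmax <- max(r)
      dt_sub <- min(t_left, if (rmax > 0)
        -log1p(-params$p_max) / rmax else t_left)
      p <- -expm1(-r * dt_sub)
      hits <- which(p > 0 & stats::runif(ns * np) < p)
      if (length(hits) > 1L) hits <- sample(hits)
      for (h in hits) {
        i <- (h - 1L) %% ns + 1L; j <- (h - 1L) %/% ns + 1L
        s <- state$st[h]
        nxt <- if (s == V_ALPHA) V_UNF else if (s == V_UNF) V_COIL
        else if (s == V_COIL) V_COIL_EXT else V_COIL
        state$st[h] <- nxt
        ev_type <- c(ev_type,
                     c("unfold", "refold_coil", "coil_open",
                       "coil_close")[s + 1L])
        ev_pf <- c(ev_pf, j); ev_site <- c(ev_site, i)
        ev_f <- c(ev_f, tq)
      }
      if (length(hits)) mech <- vimentin_mech(state, cfg)
      tq <- max(0, (d - mech$R) / mech$C)
      t_left <- t_left - dt_sub
    }
    if (cfg$destabilize && is.na(state$destab_cycle)) {
      non_alpha <- rowMeans(state$st != V_ALPHA)
      if (any(non_alpha > cfg$destab_frac))
        state$destab_cycle <- state$cycle_ctr
    }
  }
  state$L_rest <- mech$R
  events <- if (length(ev_type))
    data.frame(type = ev_type, pf = ev_pf, site = ev_site, tension = ev_f)
  else NULL
  list(state = state, F = np * tq, events = events, rupture = rupture)
}

#' Simulate stretch-relax cycles of a vimentin filament
#'
#' Runs the alpha-helix unfolding Monte Carlo model through the given
#' loading protocol.  Deterministic for a given seed.
#'
#' @param protocol A [protocol_spec()]; use `dmax_rule = "plateau"` to fix
#'   the maximum distance at the detected plateau onset (the experimental
#'   convention for vimentin).
#' @param params A [mechanical_params()].
#' @param cfg A [vimentin_params()].
#' @param seed Integer seed for the replicate.
#' @return An `if_sim` list (see [run_protocol()]) with added elements
#'   `cfg`, `seed` and `L0_model`.
#' @export
simulate_vimentin <- function(protocol = protocol_spec(dmax_rule = "plateau"),
                              params = mechanical_params(),
                              cfg = vimentin_params(), seed = 1) {
  set.seed(seed)
  state <- vimentin_state(cfg)
  stepper <- function(state, d, dt) vimentin_step(state, d, dt, cfg, params)
  out <- run_protocol(protocol, stepper, state, params)
  out$cfg <- cfg; out$seed <- seed; out$L0_model <- state$L0
  out
}
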