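#' Keratin filament model parameters
#'
#' Coarse-grained lattice of `n_parallel` protofilaments (longitudinally
#' connected dimer chains; 8 for keratin, whose cross-section holds 16
#' monomers = 8 dimers) times `n_serial` axial repeats.  Two kinds of
#' force-activated elements live on each protofilament:
#'
#' *Sliding interfaces.*  Each axial interface carries one lateral
#' interaction that ruptures under the protofilament tension.  The ruptured
#' dimer slides by one axial period `period`; with probability `p_neighbor`
#' (around 10%) it rebinds to the *neighbouring* dimer at the shifted
#' periodic site - a permanent slip elongating that protofilament - and
#' otherwise it rebinds to its original partner across the shifted period,
#' leaving a strained tether that pulls the dimer back once the tension
#' falls during relaxation, so those events carry no net slip over a closed
#' cycle.  Rebinding is immediate either way, and because the filament is
#' periodic the re-formed bond has the same properties as the original one:
#' once the load has come off a permanently shifted interface (re-arming at
#' the same low-tension kinetics as a back-slide), it can rupture and slide
#' again on a later stretch, so permanent slip accumulates without bound
#' while at most one period of recoverable slack is open per interface at
#' any time.
#'
#' *Helix elements.*  A small portion of alpha-helical segments can open
#' near peak force, releasing `helix_ext` nm of contour length, and re-close
#' at low tension, recovering their length.  They cycle with the load, so
#' they contribute hysteresis - largest while the peak force is high -
#' but neither elongation nor softening.
#'
#' Interface strengths are quenched-random: an element with threshold `f_c`
#' opens at Bell rate `nu0 * exp((f - f_c) * x_open / kBT)` under
#' protofilament tension `f` (heterogeneous zero-force rates; the spread
#' represents the distribution of lateral binding strengths along an
#' assembled filament).  Sliding thresholds are drawn from a mixture:
#' a fraction `frac_weak` uniformly on `[f_weak_min, f_weak_max]` and the
#' rest uniformly on `[f_weak_max, f_strong_max]`, so that low-force cycles
#' engage only the weak tail while high-force cycles engage every
#' interface.  Back-slides and helix re-closing follow the mirrored law
#' `nu_rev * exp((f_back - f) * x_open / kBT)`.
#'
#' Longitudinal springs are linear at stiffness `spring_k` per dimer up to
#' an elastic strain of `stiffen_strain`, beyond which the chain stiffens
#' by `stiffen_factor`.  Defaults are calibrated so the first stretch of
#' the default filament reaches 250 pN near strain 0.55.
#'
#' @param n_serial Axial repeats (sliding interfaces) per protofilament.
#' @param n_parallel Protofilaments per cross-section.
#' @param period Axial slide distance of a rupture event, nm.
#' @param dimer_rest Rest length contributed by one dimer, nm (sets the
#'   initial filament length `n_serial * dimer_rest`).
#' @param spring_k Longitudinal spring stiffness per dimer, pN/nm.
#' @param stiffen_strain Elastic strain at which springs stiffen.
#' @param stiffen_factor Stiffness multiplier past `stiffen_strain`.
#' @param frac_weak Fraction of sliding interfaces in the weak band.
#' @param f_weak_min,f_weak_max,f_strong_max Bounds of the threshold
#'   mixture, pN.
#' @param nu0 Opening rate at threshold tension, 1/s.
#' @param x_open Bell distance of the opening transitions, nm.
#' @param nu_rev Back-slide rate at tension `f_back`, 1/s.
#' @param f_back Tension scale below which tethered dimers slide back, pN.
#' @param p_neighbor Probability that a ruptured dimer rebinds to the
#'   neighbouring dimer (permanent slip).  Default 0.10.
#' @param n_helix Helix elements per protofilament.
#' @param nu0_helix Helix opening rate at threshold tension, 1/s.
#' @param x_helix Bell distance of the helix transitions, nm.
#' @param helix_ext Contour length released by an open helix element, nm.
#' @param f_helix_min,f_helix_max Helix opening threshold band, pN.
#' @param nu_rev_helix Helix re-closing rate at tension `f_back_helix`, 1/s.
#' @param f_back_helix Tension scale for helix re-closing, pN.
#' @param rate_cap Numerical ceiling on any single rate, 1/s.
#' @return An object of class `keratin_params`.
#' @export
keratin_params <- function(n_serial = 20, n_parallel = 8, period = 50,
                           dimer_rest = 43,
                           spring_k = 1.32, stiffen_strain = 0.7,
                           stiffen_factor = 6,
                           frac_weak = 0.35,
                           f_weak_min = 23, f_weak_max = 34,
                           f_strong_max = 105,
                           nu0 = 1.5, x_open = 1.3,
                           nu_rev = 3, f_back = 3,
                           p_neighbor = 0.10,
                           n_helix = 12, helix_ext = 28,
                           f_helix_min = 24.5, f_helix_max = 28,
                           nu0_helix = 5, x_helix = 4, nu_rev_helix = 3, f_back_helix = 3,
                           rate_cap = 1000) {
  stopifnot(n_serial >= 2, n_parallel >= 2, period > 0,
            dimer_rest > 0, spring_k > 0,
            f_weak_min > 0, f_weak_max > f_weak_min,
            f_strong_max > f_weak_max,
            frac_weak >= 0, frac_weak <= 1,
            nu0 >= 0, x_open >= 0, nu_rev >= 0,
            p_neighbor >= 0, p_neighbor <= 1,
            n_helix >= 0, helix_ext >= 0)
  structure(as.list(environment()), class = "keratin_params")
}

# piecewise-linear protofilament tension at imposed distance d
# L_j: protofilament rest length(s); knee: elastic extension (nm) beyond
# which the chain stiffens by factor m (set by the original contour
# length, so hysteresis loops keep their shape when the rest length grows)
pf_tension <- function(d, L_j, k_pf, knee, m) {
  e <- d - L_j
  t <- k_pf * e
  over <- e > knee
  t[over] <- k_pf * knee + m * k_pf * (e[over] - knee)
  t[e <= 0] <- 0
  t
}

# interface states: 0 = bound at the registered site (eligible to rupture),
# 1 = slid with a strained tether holding one period of recoverable slack,
# 2 = permanently shifted, refractory until the load comes off
keratin_state <- function(cfg) {
  ns <- cfg$n_serial; np <- cfg$n_parallel; nh <- cfg$n_helix
  nr <- ns + nh
  f_slide <- matrix(0, ns, np)
  weak <- matrix(stats::runif(ns * np) < cfg$frac_weak, ns, np)
  f_slide[weak] <- stats::runif(sum(weak), cfg$f_weak_min, cfg$f_weak_max)
  f_slide[!weak] <- stats::runif(sum(!weak), cfg$f_weak_max, cfg$f_strong_max)
  f_c <- rbind(f_slide,
               if (nh > 0) matrix(stats::runif(nh * np, cfg$f_helix_min,
                                               cfg$f_helix_max), nh, np))
  is_helix <- c(rep(FALSE, ns), rep(TRUE, nh))
  L0 <- ns * cfg$dimer_rest
  list(f_c = f_c, slip = matrix(0L, nr, np),
       perm_units = matrix(0L, nr, np),
       is_helix = is_helix,
       nu0_row = ifelse(is_helix, cfg$nu0_helix, cfg$nu0),
       x_row = ifelse(is_helix, cfg$x_helix, cfg$x_open),
       delta_row = ifelse(is_helix, cfg$helix_ext, cfg$period),
       nu_rev_row = ifelse(is_helix, cfg$nu_rev_helix, cfg$nu_rev),
       f_back_row = ifelse(is_helix, cfg$f_back_helix, cfg$f_back),
       p_perm_row = ifelse(is_helix, 0, cfg$p_neighbor),
       L0 = L0, L_rest = L0)
}

# mean-field filament rest length: initial length plus permanent slip plus
# currently open recoverable slack, averaged over the parallel paths
keratin_rest_length <- function(state, np) {
  state$L0 + (sum(state$delta_row * state$perm_units) +
                sum(state$delta_row * (state$slip == 1L))) / np
}

keratin_force <- function(state, d, cfg) {
  cfg$n_parallel *
    pf_tension(d, keratin_rest_length(state, cfg$n_parallel),
               cfg$spring_k / cfg$n_serial,
               cfg$stiffen_strain * state$L0, cfg$stiffen_factor)
}

#' One Monte Carlo step of the keratin sliding model
#'
#' Advances rupture/slide/rebind and helix open/close kinetics over `dt` at
#' fixed imposed distance `d`; see [keratin_params()] for the element
#' rules.  The step is subdivided so no single-step probability exceeds
#' `params$p_max`, and simultaneous events are resolved in random order
#' with the load re-evaluated after each.
#'
#' @param state Model state from `keratin_state()`.
#' @param d Imposed end-to-end distance, nm.
#' @param dt Time step, s (0 = evaluate force only).
#' @param cfg A [keratin_params()].
#' @param params A [mechanical_params()].
#' @return `list(state, F, events, rupture = FALSE)`.
#' @export
keratin_step <- function(state, d, dt, cfg, params) {
  ns <- cfg$n_serial; np <- cfg$n_parallel
  nr <- nrow(state$f_c)
  k_pf <- cfg$spring_k / ns
  kBT <- params$kBT
  knee <- cfg$stiffen_strain * state$L0
  ev_type <- character(0); ev_pf <- integer(0); ev_site <- integer(0)
  ev_f <- numeric(0)
  L_r <- keratin_rest_length(state, np)
  tq <- pf_tension(d, L_r, k_pf, knee, cfg$stiffen_factor)
  if (dt > 0) {
    t_left <- dt
    while (t_left > 0) {
      fwd_ok <- state$slip == 0L
      rev_ok <- state$slip >= 1L  # back-slide (1) or re-arm (2)
      r <- matrix(0, nr, np)
      nu0m <- matrix(state$nu0_row, nr, np)
      xm <- matrix(state$x_row, nr, np)
      r[fwd_ok] <- pmin(cfg$rate_cap,
                        nu0m[fwd_ok] * exp((tq - state$f_c[fwd_ok]) *
                                             xm[fwd_ok] / kBT))
      rr <- matrix(state$nu_rev_row, nr, np) *
        exp((matrix(state$f_back_row, nr, np) - tq) * xm / kBT)
      r[rev_ok] <- pmin(cfg$rate_cap, rr[rev_ok])
      rmax <- max(r)
      dt_sub <- min(t_left, if (rmax > 0)
        -log1p(-params$p_max) / rmax else t_left)
      p <- -expm1(-r * dt_sub)
      hits <- which(p > 0 & stats::runif(nr * np) < p)
      if (length(hits) > 1L) hits <- sample(hits)
      first <- TRUE
      for (h in hits) {
        i <- (h - 1L) %% nr + 1L; j <- (h - 1L) %/% nr + 1L
        if (!first) {
          # re-evaluate under the current load share
          t_new <- pf_tension(d, keratin_rest_length(state, np), k_pf,
                              knee, cfg$stiffen_factor)
          r_new <- if (state$slip[h] == 0L)
            min(cfg$rate_cap, state$nu0_row[i] * exp((t_new - state$f_c[h]) *
                                                       state$x_row[i] / kBT))
          else
            min(cfg$rate_cap,
                state$nu_rev_row[i] * exp((state$f_back_row[i] - t_new) *
                                            state$x_row[i] / kBT))
          p_new <- -expm1(-r_new * dt_sub)
          if (stats::runif(1) >= min(1, p_new / p[h])) next
        }
        first <- FALSE
        helix <- state$is_helix[i]
        if (state$slip[h] == 0L) {
          if (!helix && stats::runif(1) < cfg$p_neighbor) {
            state$perm_units[h] <- state$perm_units[h] + 1L
            state$slip[h] <- 2L  # refractory until the load comes off
            ev_type <- c(ev_type, "slip_perm")
          } else {
            state$slip[h] <- 1L
            ev_type <- c(ev_type, if (helix) "helix_open" else "slip_temp")
          }
        } else {
          was_perm <- state$slip[h] == 2L
          state$slip[h] <- 0L
          ev_type <- c(ev_type,
                       if (helix) "helix_close"
                       else if (was_perm) "rearm" else "slip_back")
        }
        ev_pf <- c(ev_pf, j); ev_site <- c(ev_site, i); ev_f <- c(ev_f, tq)
      }
      if (length(hits)) L_r <- keratin_rest_length(state, np)
      tq <- pf_tension(d, L_r, k_pf, knee, cfg$stiffen_factor)
      t_left <- t_left - dt_sub
    }
  }
  state$L_rest <- state$L0 + cfg$period * sum(state$perm_units) / np
  events <- if (length(ev_type))
    data.frame(type = ev_type, pf = ev_pf, site = ev_site, tension = ev_f)
  else NULL
  list(state = state, F = np * tq, events = events, rupture = FALSE)
}

#' Simulate stretch-relax cycles of a keratin filament
#'
#' Runs the sliding-and-rebinding Monte Carlo model through the given
#' loading protocol.  Deterministic for a given seed.
#'
#' @param protocol A [protocol_spec()].
#' @param params A [mechanical_params()].
#' @param cfg A [keratin_params()].
#' @param seed Integer seed for the replicate.
#' @return An `if_sim` list (see [run_protocol()]) with added elements
#'   `cfg`, `seed` and `L0_model`.
#' @examples
#' sim <- simulate_keratin(protocol_spec("const_dmax", "LF", n_cycles = 2),
#'                         seed = 1)
#' head(sim$traces)
#' @export
simulate_keratin <- function(protocol = protocol_spec(),
                             params = mechanical_params(),
                             cfg = keratin_params(), seed = 1) {
  set.seed(seed)
  state <- keratin_state(cfg)
  stepper <- function(state, d, dt) keratin_step(state, d, dt, cfg, params)
  out <- run_protocol(protocol, stepper, state, params)
  out$cfg <- cfg; out$seed <- seed; out$L0_model <- state$L0
  out
}
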