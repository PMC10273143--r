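#' Loading protocol specification
#'
#' Encodes the four loading programs used in the cyclic-stretching study:
#' constant maximum distance (`const_dmax`) or constant maximum force
#' (`const_fmax`), each in the low-force (LF, trigger 250 pN) or high-force
#' (HF, trigger 900 pN) regime.
#'
#' In `const_dmax` mode the maximum distance is fixed at the point where the
#' first-cycle force first reaches `F_trigger` (`dmax_rule = "force"`,
#' keratin), at the plateau onset detected on the first stretch
#' (`dmax_rule = "plateau"`, vimentin), or given directly
#' (`dmax_rule = "fixed"` with `d_max` in nm).  In `const_fmax` mode every
#' stretch ends at the first attainment of `F_trigger`.
#'
#' @param mode `"const_dmax"` or `"const_fmax"`.
#' @param regime `"LF"` or `"HF"`; sets the default `F_trigger` (250 or
#'   900 pN).
#' @param n_cycles Number of stretch-relax cycles (>= 1).
#' @param F_trigger Trigger force in pN (default by regime).
#' @param d_max Fixed maximum distance in nm (only with
#'   `dmax_rule = "fixed"`).
#' @param dmax_rule How the first cycle sets `d_max` in `const_dmax` mode.
#' @param pulling_speed Optional override of the model pulling speed, nm/s.
#' @param relax_to Distance at which each relax branch ends; defaults to the
#'   starting distance.
#' @param slope_drop,slope_window Plateau detector settings: fire when the
#'   local slope over a `slope_window`-strain window falls below
#'   `slope_drop` times the initial elastic slope.
#' @param onset_margin Extra strain imposed beyond the detected onset in
#'   `dmax_rule = "plateau"` mode, so the stretch halts once the plateau is
#'   clearly established rather than at the first detector firing.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(mode = c("const_dmax", "const_fmax"),
                          regime = c("LF", "HF"),
                          n_cycles = 8, F_trigger = NULL, d_max = NA_real_,
                          dmax_rule = c("force", "plateau", "fixed"),
                          pulling_speed = NULL, relax_to = NA_real_,
                          slope_drop = 0.5, slope_window = 0.05,
                          onset_margin = 0.10) {
  mode <- match.arg(mode); regime <- match.arg(regime)
  dmax_rule <- match.arg(dmax_rule)
  if (is.null(F_trigger)) F_trigger <- if (regime == "LF") 250 else 900
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (F_trigger <= 0) stop("F_trigger must be positive")
  if (dmax_rule == "fixed" && !is.finite(d_max))
    stop("dmax_rule = 'fixed' requires a finite d_max")
  structure(list(mode = mode, regime = regime, n_cycles = as.integer(n_cycles),
                 F_trigger = F_trigger, d_max = d_max, dmax_rule = dmax_rule,
                 pulling_speed = pulling_speed, relax_to = relax_to,
                 slope_drop = slope_drop, slope_window = slope_window,
                 onset_margin = onset_margin),
            class = "protocol_spec")
}

protocol_error <- function(msg) {
  stop(structure(class = c("ifmech_protocol_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Maximum distance from the first trigger-force crossing
#'
#' Returns the smallest end-to-end distance at which the first-cycle
#' stretch reaches `F_trigger`, linearly interpolated between samples (the
#' first upward crossing is used on noisy traces).
#'
#' @param first_stretch Data frame with `d_nm` and `F_pN` (time-ordered).
#' @param F_trigger Trigger force in pN (default 250).
#' @return `d_max` in nm.
#' @export
calibrate_dmax_keratin <- function(first_stretch, F_trigger = 250) {
  d <- first_stretch$d_nm; F <- first_stretch$F_pN
  if (F[1] >= F_trigger) return(d[1])
  x <- first_upcross(d, F, F_trigger)
  if (is.na(x)) protocol_error(paste0("force never reaches F_trigger = ",
                                      F_trigger, " pN"))
  as.numeric(x)
}

# local slope of F vs eps over [eps_hi - window, eps_hi]
local_slope <- function(eps, F, eps_hi, window) {
  sel <- eps >= eps_hi - window & eps <= eps_hi
  if (sum(sel) < 3) return(NA_real_)
  unname(stats::lm.fit(cbind(1, eps[sel]), F[sel])$coefficients[2])
}

#' Maximum distance from the plateau onset of a first stretch
#'
#' Operational plateau detector: the onset is the first strain at which the
#' running local slope (least-squares fit over a `window`-strain span) falls
#' below `drop` times the initial elastic slope (fit over the first
#' `window` of strain above zero force).
#'
#' @param first_stretch Data frame with `d_nm` and `F_pN`.
#' @param L0 Reference length in nm; estimated from the 5 pN crossing when
#'   omitted.
#' @param drop Slope-drop threshold (default 0.5).
#' @param window Fitting window in strain units (default 0.05).
#' @return `d_max` in nm with attribute `eps_onset`.
#' @export
calibrate_dmax_vimentin <- function(first_stretch, L0 = NULL, drop = 0.5,
                                    window = 0.05) {
  d <- first_stretch$d_nm; F <- first_stretch$F_pN
  if (is.null(L0)) {
    L0 <- first_upcross(d, F, 5)
    if (is.na(L0)) protocol_error("cannot set a reference length: 5 pN never reached")
  }
  eps <- (d - L0) / L0
  s0 <- local_slope(eps, F, window, window)
  if (!is.finite(s0) || s0 <= 0) protocol_error("no initial elastic slope")
  cand <- which(eps > 2 * window)
  for (i in cand) {
    s <- local_slope(eps[seq_len(i)], F[seq_len(i)], eps[i], window)
    if (is.finite(s) && s < drop * s0)
      return(structure(d[i], eps_onset = eps[i], L0 = L0))
  }
  protocol_error("no plateau onset detected (slope never fell below threshold)")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drive a filament stepper through a stretch-relax protocol
#'
#' Generic cycle driver shared by the keratin and vimentin simulators.  The
#' `stepper` advances the Monte Carlo state over one time step at a fixed
#' imposed distance and reports the current tension; the driver imposes the
#' distance ramps, applies the protocol triggers and records the traces.
#'
#' @param spec A [protocol_spec()].
#' @param stepper `function(state, d, dt)` returning
#'   `list(state =, F =, events = data.frame or NULL, rupture = logical)`.
#' @param state Initial model state; must contain `L_rest` (nm), the
#'   filament rest length used to choose the start distance.
#' @param params A [mechanical_params()].
#' @param d_start Start distance of every cycle (default `0.98 * L_rest`).
#' @param max_strain Safety cap on the imposed strain (protocol error when a
#'   trigger is never reached below it).
#' @return List of class `if_sim` with elements `traces` (columns `cycle`,
#'   `branch`, `t_s`, `d_nm`, `F_pN`), `events`, `d_max`, `state`,
#'   `rupture`, `spec`.
#' @export
run_protocol <- function(spec, stepper, state, params,
                         d_start = NULL, max_strain = 6) {
  stopifnot(inherits(spec, "protocol_spec"),
            inherits(params, "mechanical_params"))
  v <- spec$pulling_speed %||% params$pulling_speed
  dt <- params$dt
  L_rest0 <- state$L_rest
  d_start <- d_start %||% (0.98 * L_rest0)
  relax_to <- if (is.finite(spec$relax_to)) spec$relax_to else d_start
  d_cap <- L_rest0 * (1 + max_strain)
  d_max <- if (spec$dmax_rule == "fixed") spec$d_max else NA_real_

  cyc <- list(); evs <- list(); tnow <- 0; rupture <- FALSE
  n_guess <- 4096L
  for (cycle in seq_len(spec$n_cycles)) {
    for (br in c("stretch", "relax")) {
      tv <- numeric(n_guess); dv <- numeric(n_guess); fv <- numeric(n_guess)
      n <- 0L; d <- if (br == "stretch") d_start else d
      push <- function(t, dd, ff) {
        n <<- n + 1L
        if (n > length(tv)) {
          tv <<- c(tv, numeric(length(tv))); dv <<- c(dv, numeric(length(dv)))
          fv <<- c(fv, numeric(length(fv)))
        }
        tv[n] <<- t; dv[n] <<- dd; fv[n] <<- ff
      }
      # initial sample of the branch
      st0 <- stepper(state, d, 0)
      push(tnow, d, st0$F)
      F_prev <- st0$F; d_prev <- d
      repeat {
        if (br == "stretch") {
          d_new <- d + v * dt
          clipped <- FALSE
          if (is.finite(d_max) && d_new >= d_max) { d_new <- d_max; clipped <- TRUE }
          dt_eff <- (d_new - d) / v
          if (dt_eff <= 0) dt_eff <- dt
        } else {
          d_new <- d - v * dt
          clipped <- FALSE
          if (d_new <= relax_to) { d_new <- relax_to; clipped <- TRUE }
          dt_eff <- (d - d_new) / v
          if (dt_eff <= 0) dt_eff <- dt
        }
        res <- stepper(state, d_new, dt_eff)
        state <- res$state; tnow <- tnow + dt_eff
        push(tnow, d_new, res$F)
        if (!is.null(res$events) && nrow(res$events)) {
          res$events$t_s <- tnow; res$events$cycle <- cycle; res$events$branch <- br
          evs[[length(evs) + 1L]] <- res$events
        }
        if (isTRUE(res$rupture)) { rupture <- TRUE; break }
        if (br == "stretch") {
          end_force <- (spec$mode == "const_fmax") ||
            (spec$mode == "const_dmax" && !is.finite(d_max) &&
               spec$dmax_rule == "force")
          if (end_force && res$F >= spec$F_trigger) {
            dcross <- d_prev + (spec$F_trigger - F_prev) * (d_new - d_prev) /
              max(res$F - F_prev, 1e-12)
            if (spec$mode == "const_dmax" && !is.finite(d_max)) d_max <- dcross
            break
          }
          if (spec$mode == "const_dmax" && !is.finite(d_max) &&
              spec$dmax_rule == "plateau" && n %% 20L == 0L) {
            L0e <- first_upcross(dv[seq_len(n)], fv[seq_len(n)], 5)
            if (is.finite(L0e)) {
              eps <- (dv[seq_len(n)] - L0e) / L0e
              if (eps[n] > 2 * spec$slope_window) {
                s0 <- local_slope(eps, fv[seq_len(n)], spec$slope_window,
                                  spec$slope_window)
                s1 <- local_slope(eps, fv[seq_len(n)], eps[n],
                                  spec$slope_window)
                if (is.finite(s0) && is.finite(s1) &&
                    s1 < spec$slope_drop * s0)
                  d_max <- d_new + spec$onset_margin * L0e
              }
            }
          }
          if (clipped) break
          if (d_new >= d_cap)
            protocol_error("trigger never reached below the strain cap")
        } else if (clipped) break
        F_prev <- res$F; d_prev <- d_new; d <- d_new
      }
      d <- d_new
      cyc[[length(cyc) + 1L]] <- data.frame(
        cycle = cycle, branch = br, t_s = tv[seq_len(n)],
        d_nm = dv[seq_len(n)], F_pN = fv[seq_len(n)])
      if (rupture) break
    }
    if (rupture) break
  }
  traces <- do.call(rbind, cyc)
  events <- if (length(evs)) do.call(rbind, evs) else
    data.frame(t_s = numeric(0), cycle = integer(0), branch = character(0),
               type = character(0), pf = integer(0), site = integer(0),
               tension = numeric(0))
  structure(list(traces = traces, events = events, d_max = d_max,
                 state = state, rupture = rupture, spec = spec,
                 d_start = d_start),
            class = "if_sim")
}
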