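#' @title Force-strain cycle analysis
#' @description Every derived quantity reported from stretch-relax cycles:
#'   reference length, effective length from the 100-150 pN window fit,
#'   window stiffnesses, corrected strain, hysteresis energies, per-cycle
#'   elongation increments and cohort summaries.
#' @name curve_analysis
NULL

# trapezoid rule on sampled (x, y)
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# first upward crossing of `level` in y(x), linearly interpolated
first_upcross <- function(x, y, level) {
  above <- y >= level
  if (above[1]) return(structure(NA_real_, started_above = TRUE))
  hit <- which(!above[-length(above)] & above[-1])
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  x[i] + (level - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
}

assert_traces <- function(traces) {
  need <- c("cycle", "branch", "t_s", "d_nm", "F_pN")
  miss <- setdiff(need, names(traces))
  if (length(miss))
    stop("trace table lacks column(s): ", paste(miss, collapse = ", "))
  invisible(traces)
}

branch_of <- function(traces, cycle, branch) {
  out <- traces[traces$cycle == cycle & traces$branch == branch, , drop = FALSE]
  out[order(out$t_s), , drop = FALSE]
}

#' Reference length of a filament at a threshold force
#'
#' The original filament length `L0` is the end-to-end distance at which the
#' first-cycle stretch first reaches `F_ref` (default 5 pN), linearly
#' interpolated between samples.  All strains of that filament are computed
#' against this single `L0`.
#'
#' @param traces Trace table (`cycle`, `branch`, `t_s`, `d_nm`, `F_pN`).
#' @param F_ref Threshold force in pN.
#' @return `L0` in nm.
#' @export
reference_length <- function(traces, F_ref = 5) {
  assert_traces(traces)
  s1 <- branch_of(traces, min(traces$cycle), "stretch")
  if (nrow(s1) < 2) stop("first-cycle stretch branch missing or too short")
  if (s1$F_pN[1] >= F_ref)
    stop("force starts at or above F_ref; pre-tension too high for a reference length")
  L0 <- first_upcross(s1$d_nm, s1$F_pN, F_ref)
  if (is.na(L0)) stop("force never reaches F_ref = ", F_ref, " pN")
  as.numeric(L0)
}

#' Convert a trace table to force-strain form
#'
#' @param traces Trace table.
#' @param L0 Reference length in nm; computed with [reference_length()] when
#'   omitted.
#' @return The table with added `eps` (strain) column and attribute `L0`.
#' @export
force_strain <- function(traces, L0 = NULL) {
  assert_traces(traces)
  if (is.null(L0)) L0 <- reference_length(traces)
  traces$eps <- (traces$d_nm - L0) / L0
  attr(traces, "L0") <- L0
  traces
}

#' Linear fit in a force window: stiffness and effective length
#'
#' Ordinary least squares of `F` on strain restricted to samples with
#' `F` in `[F_lo, F_hi]` on one branch.  The slope is the stretching
#' stiffness `kappa_f` (pN per unit strain) and the x-intercept is the
#' effective length `eps_e` (strain units), i.e. the accumulated plastic
#' elongation.
#'
#' @param eps Strain samples of the branch.
#' @param F Matching forces in pN.
#' @param F_lo,F_hi Window bounds in pN (defaults 100 and 150).
#' @param min_points Minimum number of in-window samples (default 5); fewer
#'   yields `NA` estimates rather than an error.
#' @param refine Number of window-refinement passes.  After the initial fit,
#'   window membership is re-decided from the *fitted* force and the line is
#'   re-fitted; selecting on the fitted rather than the measured force keeps
#'   force noise at the window edges from attenuating the slope.  On a
#'   noiseless trace the refinement is a no-op.
#' @return List with `kappa_f`, `eps_e` and `n` (points used).
#' @export
fit_force_window <- function(eps, F, F_lo = 100, F_hi = 150, min_points = 5,
                             refine = 2) {
  ok <- is.finite(F) & is.finite(eps)
  sel <- F >= F_lo & F <= F_hi & ok
  n <- sum(sel)
  if (n < min_points)
    return(list(kappa_f = NA_real_, eps_e = NA_real_, n = n))
  cf <- stats::lm.fit(cbind(1, eps[sel]), F[sel])$coefficients
  for (k in seq_len(refine)) {
    pred <- cf[1] + cf[2] * eps
    sel2 <- pred >= F_lo & pred <= F_hi & ok
    if (sum(sel2) >= min_points && !identical(sel2, sel)) {
      sel <- sel2
      cf <- stats::lm.fit(cbind(1, eps[sel]), F[sel])$coefficients
    }
  }
  kappa <- unname(cf[2])
  list(kappa_f = kappa, eps_e = unname(-cf[1] / kappa), n = sum(sel))
}

#' Linear-fit stiffness in a strain window
#'
#' Slope of the least-squares line of `F` on strain over a fixed strain
#' window (default 0.1-0.3).  With `corrected = TRUE` the window is applied
#' to the corrected strain `eps - eps_e`, re-zeroing by the accumulated
#' plastic elongation.
#'
#' @inheritParams fit_force_window
#' @param eps_lo,eps_hi Strain window bounds.
#' @param corrected Use corrected strain?
#' @param eps_e Effective length used for the correction.
#' @return Stiffness `kappa_eps` in pN per unit strain (`NA` if the window
#'   holds fewer than `min_points` samples).
#' @export
fit_strain_window <- function(eps, F, eps_lo = 0.1, eps_hi = 0.3,
                              corrected = FALSE, eps_e = 0, min_points = 5) {
  x <- if (corrected) eps - eps_e else eps
  sel <- x >= eps_lo & x <= eps_hi & is.finite(F) & is.finite(x)
  if (sum(sel) < min_points) return(NA_real_)
  unname(stats::lm.fit(cbind(1, x[sel]), F[sel])$coefficients[2])
}

#' Hysteresis energies of one stretch-relax cycle
#'
#' Input energy is the work done on the filament along the stretch branch,
#' `E_in = integral F dd` (trapezoid rule); the relax branch returns
#' `E_return`; their difference is the dissipated energy.  Both integrals
#' are evaluated on the common distance support of the two branches,
#' excluding non-overlapping tails.  The absolute dissipated energy per
#' length is reported in kBT per micrometre of initial filament length.
#'
#' @param stretch,relax Data frames with `d_nm` and `F_pN` (time-ordered).
#' @param L0 Reference length in nm.
#' @param kBT Thermal energy in pN nm.
#' @return List with `E_in`, `E_dis` (pN nm), `E_rel` (fraction) and
#'   `E_abs_per_len` (kBT/um).  `E_rel` is `NA` when `E_in <= 0`.
#' @export
hysteresis_energy <- function(stretch, relax, L0, kBT = 4.114) {
  ds <- stretch$d_nm; Fs <- stretch$F_pN
  dr <- rev(relax$d_nm); Fr <- rev(relax$F_pN)  # ascending distance
  lo <- max(min(ds), min(dr)); hi <- min(max(ds), max(dr))
  if (!(hi > lo)) stop("stretch and relax branches share no distance support")
  clip <- function(d, F) {
    keep <- d > lo & d < hi
    d2 <- c(lo, d[keep], hi)
    F2 <- c(stats::approx(d, F, lo, ties = mean)$y, F[keep],
            stats::approx(d, F, hi, ties = mean)$y)
    list(d = d2, F = F2)
  }
  s <- clip(ds, Fs); r <- clip(dr, Fr)
  E_in <- trapz(s$d, s$F)
  E_ret <- trapz(r$d, r$F)
  E_dis <- E_in - E_ret
  E_rel <- if (E_in > 0) E_dis / E_in else NA_real_
  list(E_in = E_in, E_dis = E_dis, E_rel = E_rel,
       E_abs_per_len = E_dis / kBT / (L0 / 1000))
}

#' Per-cycle metrics of a filament's trace
#'
#' Applies the full analysis to every cycle: effective length and stiffness
#' from the force-window fit on the stretch branch, strain-window stiffness
#' (raw and corrected), maximum strain, hysteresis energies and the
#' cycle-to-cycle elongation increment.  A cycle failing a fit precondition
#' yields `NA` for that metric, never an error.
#'
#' @param traces Trace table for one filament.
#' @param F_ref Reference-length threshold, pN.
#' @param F_lo,F_hi Force-window bounds, pN.
#' @param eps_lo,eps_hi Strain-window bounds.
#' @param kBT Thermal energy, pN nm.
#' @return Data frame of class `cycle_metrics`, one row per cycle with
#'   columns `cycle`, `eps_e`, `kappa_f`, `kappa_eps`, `kappa_eps_c`,
#'   `eps_max`, `E_in`, `E_dis`, `E_rel`, `E_abs_per_len`, `delta_eps_e`.
#' @export
cycle_metrics <- function(traces, F_ref = 5, F_lo = 100, F_hi = 150,
                          eps_lo = 0.1, eps_hi = 0.3, kBT = 4.114) {
  traces <- force_strain(traces)
  L0 <- attr(traces, "L0")
  cycles <- sort(unique(traces$cycle))
  rows <- lapply(cycles, function(cc) {
    st <- branch_of(traces, cc, "stretch")
    rx <- branch_of(traces, cc, "relax")
    fw <- fit_force_window(st$eps, st$F_pN, F_lo, F_hi)
    ke <- fit_strain_window(st$eps, st$F_pN, eps_lo, eps_hi)
    kec <- if (is.na(fw$eps_e)) NA_real_ else
      fit_strain_window(st$eps, st$F_pN, eps_lo, eps_hi,
                        corrected = TRUE, eps_e = fw$eps_e)
    en <- if (nrow(rx) >= 2 && nrow(st) >= 2)
      tryCatch(hysteresis_energy(st, rx, L0, kBT),
               error = function(e) NULL) else NULL
    data.frame(cycle = cc, eps_e = fw$eps_e, kappa_f = fw$kappa_f,
               kappa_eps = ke, kappa_eps_c = kec,
               eps_max = max(st$eps),
               E_in = if (is.null(en)) NA_real_ else en$E_in,
               E_dis = if (is.null(en)) NA_real_ else en$E_dis,
               E_rel = if (is.null(en)) NA_real_ else en$E_rel,
               E_abs_per_len = if (is.null(en)) NA_real_ else en$E_abs_per_len)
  })
  out <- do.call(rbind, rows)
  out$delta_eps_e <- c(NA_real_, diff(out$eps_e))
  attr(out, "L0") <- L0
  class(out) <- c("cycle_metrics", class(out))
  out
}

#' Regression of effective length on maximum strain
#'
#' Pools `(eps_max, eps_e)` pairs across filaments and cycles (by default
#' cycles 4-15) and fits a least-squares line restricted to
#' `eps_max > eps_threshold` (default 0.4).  The slope measures how much a
#' filament type elongates per unit of applied maximum strain.
#'
#' @param metrics A `cycle_metrics` table or row-bound collection thereof.
#' @param eps_threshold Lower bound on `eps_max` for the fit.
#' @param cycles Cycle window to pool (default `4:15`).
#' @param min_points Minimum pairs required (default 5).
#' @return List with `slope`, `intercept`, `n`.
#' @export
elongation_vs_maxstrain <- function(metrics, eps_threshold = 0.4,
                                    cycles = 4:15, min_points = 5) {
  sel <- metrics$cycle %in% cycles & metrics$eps_max > eps_threshold &
    is.finite(metrics$eps_e)
  n <- sum(sel)
  if (n < min_points)
    return(list(slope = NA_real_, intercept = NA_real_, n = n))
  cf <- stats::lm.fit(cbind(1, metrics$eps_max[sel]),
                      metrics$eps_e[sel])$coefficients
  list(slope = unname(cf[2]), intercept = unname(cf[1]), n = n)
}

#' Cohort summary: median and quartiles per cycle
#'
#' @param metrics Row-bound `cycle_metrics` of several filaments.
#' @param var Metric column to summarise.
#' @return Data frame with `cycle`, `median`, `q25`, `q75`, `n` (linear
#'   interpolation between order statistics, quantile type 7).
#' @export
cohort_summary <- function(metrics, var = "eps_e") {
  sp <- split(metrics[[var]], metrics$cycle)
  out <- data.frame(
    cycle = as.numeric(names(sp)),
    median = vapply(sp, function(v) stats::median(v, na.rm = TRUE), 0),
    q25 = vapply(sp, function(v)
      unname(stats::quantile(v, 0.25, na.rm = TRUE, type = 7)), 0),
    q75 = vapply(sp, function(v)
      unname(stats::quantile(v, 0.75, na.rm = TRUE, type = 7)), 0),
    n = vapply(sp, function(v) sum(is.finite(v)), 0))
  rownames(out) <- NULL
  out[order(out$cycle), , drop = FALSE]
}

#' Freedman-Diaconis histogram bin width
#'
#' `width = 2 * IQR * n^(-1/3)`.  A zero interquartile range falls back to
#' `range/sqrt(n)` and flags the fallback in an attribute.
#'
#' @param values Numeric sample, length >= 2.
#' @return Bin width (attribute `fallback` set when IQR was zero).
#' @export
fd_binwidth <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need at least two finite values")
  iqr <- stats::IQR(values, type = 7)
  if (iqr > 0) return(2 * iqr * n^(-1 / 3))
  structure(diff(range(values)) / sqrt(n), fallback = TRUE)
}

#' Pairs of elongation increment and relative dissipated energy
#'
#' Emits the per-cycle `(delta_eps_e, E_rel)` pairs used to relate energy
#' dissipation to subunit sliding, with the Spearman rank correlation as a
#' convenience.
#'
#' @param metrics Row-bound `cycle_metrics` (column `filament` optional).
#' @return List with `pairs` (data frame) and `rank_correlation`.
#' @export
dissipation_vs_delta_eps <- function(metrics) {
  sel <- is.finite(metrics$delta_eps_e) & is.finite(metrics$E_rel)
  pairs <- data.frame(delta_eps_e = metrics$delta_eps_e[sel],
                      E_rel = metrics$E_rel[sel])
  rc <- if (nrow(pairs) >= 3)
    suppressWarnings(stats::cor(pairs$delta_eps_e, pairs$E_rel,
                                method = "spearman")) else NA_real_
  list(pairs = pairs, rank_correlation = rc)
}
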