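#' Ground-truth description for synthetic optical-tweezers traces
#'
#' Defines a noiseless force-strain template plus injected per-cycle
#' effective lengths, from which [generate_cycle()] produces stretch-relax
#' traces with additive Gaussian force noise.  Because every parameter is
#' known, the analysis pipeline can be validated end to end without a
#' simulator.
#'
#' Templates (all pass through zero force at zero corrected strain and
#' therefore contain the 5 pN reference-length crossing):
#'
#' * `"linear"` - `F = kappa * (eps - eps_e)`.
#' * `"keratin_like"` - linear at `kappa` up to `stiffen_onset` (default
#'   strain 0.7), then `stiffen_factor` times stiffer.
#' * `"vimentin_like"` - linear at `kappa` up to the plateau onset
#'   (default strain 0.15), a force plateau with small residual slope up to
#'   the plateau end (default 0.8), then a stiff rise.
#'
#' The relax branch follows the template scaled by `relax_fraction`, so the
#' injected relative dissipated energy of a full cycle is exactly
#' `1 - relax_fraction` in the noiseless limit.
#'
#' @param template Template name.
#' @param kappa_true Elastic stiffness in pN per unit strain.
#' @param eps_e_schedule Per-cycle true effective lengths (strain units);
#'   non-decreasing for `"keratin_like"`, all zero for `"vimentin_like"`.
#' @param eps_max Maximum applied strain per cycle (recycled).
#' @param plateau Plateau bounds in strain for `"vimentin_like"`.
#' @param plateau_slope Residual plateau slope, pN per unit strain.
#' @param stiffen_onset,stiffen_factor Stiffening of `"keratin_like"` and
#'   of the post-plateau rise.
#' @param relax_fraction Relax-branch force as a fraction of the stretch
#'   template (0 < fraction <= 1).
#' @param noise_sd Gaussian force noise SD, pN.
#' @param L0 True reference length, nm.
#' @param pulling_speed Ramp speed, nm/s (sets the time stamps).
#' @param n_samples Samples per branch.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(template = c("linear", "keratin_like",
                                         "vimentin_like"),
                            kappa_true = 500,
                            eps_e_schedule = 0,
                            eps_max = 0.55,
                            plateau = c(0.15, 0.8),
                            plateau_slope = 30,
                            stiffen_onset = 0.7, stiffen_factor = 4,
                            relax_fraction = 0.5,
                            noise_sd = 2, L0 = 860,
                            pulling_speed = 500, n_samples = 400) {
  template <- match.arg(template)
  if (plateau[1] >= plateau[2])
    stop("infeasible template: plateau bounds inverted")
  if (kappa_true <= 0 || L0 <= 0) stop("kappa_true and L0 must be positive")
  if (relax_fraction <= 0 || relax_fraction > 1)
    stop("relax_fraction must be in (0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (template == "keratin_like" && is.unsorted(eps_e_schedule))
    stop("eps_e_schedule must be non-decreasing for keratin_like")
  structure(as.list(environment()), class = "synthetic_truth")
}

# noiseless template force at corrected strain eps_c (vectorised)
template_force <- function(truth, eps_c) {
  k <- truth$kappa_true
  F <- switch(truth$template,
    linear = k * eps_c,
    keratin_like = {
      on <- truth$stiffen_onset
      ifelse(eps_c <= on, k * eps_c,
             k * on + truth$stiffen_factor * k * (eps_c - on))
    },
    vimentin_like = {
      p1 <- truth$plateau[1]; p2 <- truth$plateau[2]
      F1 <- k * p1
      F2 <- F1 + truth$plateau_slope * (p2 - p1)
      ifelse(eps_c <= p1, k * eps_c,
             ifelse(eps_c <= p2, F1 + truth$plateau_slope * (eps_c - p1),
                    F2 + truth$stiffen_factor * k * (eps_c - p2)))
    })
  pmax(0, F)
}

#' Generate one synthetic stretch-relax cycle
#'
#' The noiseless curve passes exactly through the template shifted by the
#' cycle's true effective length; Gaussian noise is added to force only
#' (distance is the commanded coordinate in a tweezers experiment).
#'
#' @param truth A [synthetic_truth()].
#' @param cycle_index Cycle number (>= 1); indexes `eps_e_schedule`.
#' @param t0 Start time in s.
#' @return Trace table rows (`cycle`, `branch`, `t_s`, `d_nm`, `F_pN`) for
#'   the stretch and relax branches.
#' @export
generate_cycle <- function(truth, cycle_index = 1, t0 = 0) {
  stopifnot(inherits(truth, "synthetic_truth"), cycle_index >= 1)
  sched <- truth$eps_e_schedule
  eps_e <- sched[min(length(sched), cycle_index)]
  emax <- rep(truth$eps_max, length.out = cycle_index)[cycle_index]
  eps0 <- -0.02
  n <- truth$n_samples
  eps_up <- seq(eps0, emax, length.out = n)
  eps_dn <- rev(eps_up)
  d_up <- truth$L0 * (1 + eps_up); d_dn <- truth$L0 * (1 + eps_dn)
  dt <- (d_up[2] - d_up[1]) / truth$pulling_speed
  F_up <- template_force(truth, eps_up - eps_e) +
    stats::rnorm(n, 0, truth$noise_sd)
  F_dn <- truth$relax_fraction * template_force(truth, eps_dn - eps_e) +
    stats::rnorm(n, 0, truth$noise_sd)
  t_up <- t0 + seq_len(n) * dt
  t_dn <- t_up[n] + seq_len(n) * dt
  rbind(
    data.frame(cycle = cycle_index, branch = "stretch", t_s = t_up,
               d_nm = d_up, F_pN = F_up),
    data.frame(cycle = cycle_index, branch = "relax", t_s = t_dn,
               d_nm = d_dn, F_pN = F_dn))
}

#' Generate a synthetic filament cohort with a truth manifest
#'
#' Per-filament seeds are derived from the master seed, so two runs with
#' the same master seed produce identical cohorts.  Each element of
#' `truth_list` is recycled over the filaments.
#'
#' @param truth_list A [synthetic_truth()] or list of them.
#' @param n_filaments Number of filaments (0 allowed: empty cohort).
#' @param n_cycles Cycles per filament.
#' @param seed Master seed.
#' @param dir Optional directory: traces are written as
#'   `filament_<i>.csv` and the manifest as `manifest.json`.
#' @return List with `traces` (list of trace tables), `manifest` (list of
#'   per-filament truth records) and, when `dir` is given, `files`.
#' @export
generate_cohort <- function(truth_list, n_filaments, n_cycles = 8,
                            seed = 1, dir = NULL) {
  if (inherits(truth_list, "synthetic_truth")) truth_list <- list(truth_list)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, max(1L, n_filaments))
  traces <- list(); manifest <- list(); files <- character(0)
  if (n_filaments > 0) {
    for (i in seq_len(n_filaments)) {
      truth <- truth_list[[(i - 1L) %% length(truth_list) + 1L]]
      set.seed(sub_seeds[i])
      tr <- do.call(rbind, lapply(seq_len(n_cycles), function(cc)
        generate_cycle(truth, cc, t0 = (cc - 1) * 10)))
      traces[[i]] <- tr
      manifest[[i]] <- c(list(filament = i, seed = sub_seeds[i]),
                         truth[setdiff(names(truth), "")])
      if (!is.null(dir)) {
        f <- file.path(dir, sprintf("filament_%03d.csv", i))
        utils::write.csv(tr, f, row.names = FALSE)
        files <- c(files, f)
      }
    }
  }
  if (!is.null(dir)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(dir, "manifest.json"))
  }
  list(traces = traces, manifest = manifest, files = files)
}

#' Add measurement noise to a simulated trace
#'
#' Overlays the optical-tweezers force-detection noise model used by the
#' synthetic generator (additive white Gaussian noise on force only) onto a
#' noiseless simulated trace, so simulator output can be analysed under
#' measurement conditions.
#'
#' @param traces Trace table.
#' @param sd Force noise standard deviation, pN (default 2).
#' @param seed Optional seed for reproducibility.
#' @return The trace table with noisy `F_pN`.
#' @export
with_force_noise <- function(traces, sd = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  traces$F_pN <- traces$F_pN + stats::rnorm(nrow(traces), 0, sd)
  traces
}
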