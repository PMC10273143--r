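#' Simulate a cohort of replicate filaments
#'
#' Runs `n` independent replicates of a filament simulator under one
#' protocol, derives per-replicate seeds from the master seed, and returns
#' per-cycle metrics for each filament together with the raw simulations.
#'
#' @param model `"keratin"` or `"vimentin"`.
#' @param n Number of replicate filaments.
#' @param protocol A [protocol_spec()].
#' @param params A [mechanical_params()].
#' @param cfg Model parameters ([keratin_params()] or [vimentin_params()]);
#'   defaults chosen by `model`.
#' @param seed Master seed.
#' @param keep_sims Keep the full simulation objects (traces can be large)?
#' @return List with `metrics` (row-bound [cycle_metrics()] with a
#'   `filament` column), `sims` (list or NULL) and `seeds`.
#' @export
simulate_cohort <- function(model = c("keratin", "vimentin"), n = 20,
                            protocol = NULL,
                            params = mechanical_params(), cfg = NULL,
                            seed = 1, keep_sims = FALSE) {
  model <- match.arg(model)
  if (is.null(protocol))
    protocol <- if (model == "keratin") protocol_spec()
                else protocol_spec(dmax_rule = "plateau")
  if (is.null(cfg))
    cfg <- if (model == "keratin") keratin_params() else vimentin_params()
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2L, n)
  simfun <- if (model == "keratin") simulate_keratin else simulate_vimentin
  sims <- vector("list", n)
  mets <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- simfun(protocol, params, cfg, seed = seeds[i])
    m <- cycle_metrics(sim$traces)
    m$filament <- i
    mets[[i]] <- m
    if (keep_sims) sims[[i]] <- sim
  }
  list(metrics = do.call(rbind, mets),
       sims = if (keep_sims) sims else NULL,
       seeds = seeds, model = model, protocol = protocol)
}
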