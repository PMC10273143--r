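#' @title Trace and configuration input/output
#' @description CSV dialect for force-distance-time traces
#'   (`cycle,branch,t_s,d_nm,F_pN`), YAML/JSON run configurations and
#'   structured run logs.
#' @name cli_io
NULL

TRACE_COLUMNS <- c("cycle", "branch", "t_s", "d_nm", "F_pN")

schema_error <- function(msg) {
  stop(structure(class = c("ifmech_schema_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Write a trace table to CSV
#'
#' @param traces Trace table (`cycle`, `branch`, `t_s`, `d_nm`, `F_pN`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  assert_traces(traces)
  utils::write.csv(traces[, TRACE_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a trace CSV, validating the schema
#'
#' Expects the header `cycle,branch,t_s,d_nm,F_pN`.  A missing column
#' raises a schema error; a non-numeric value raises a parse error naming
#' the offending line.
#'
#' @param path CSV file.
#' @return Trace data frame.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) schema_error(paste0("no such trace file: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(TRACE_COLUMNS, names(df))
  if (length(miss))
    schema_error(paste0(path, ": missing column(s) ",
                        paste(miss, collapse = ", ")))
  for (col in c("cycle", "t_s", "d_nm", "F_pN")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))[1]
      stop(structure(class = c("ifmech_parse_error", "error", "condition"),
                     list(message = sprintf(
                       "%s: non-numeric value in column '%s' at data line %d",
                       path, col, bad), call = sys.call(-1))))
    }
  }
  if (!all(df$branch %in% c("stretch", "relax")))
    schema_error(paste0(path, ": branch must be 'stretch' or 'relax'"))
  df
}

#' Read a run configuration (YAML, with JSON fallback)
#'
#' @param path Configuration file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e)
                    tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                             error = function(e2)
                               stop("config is neither valid YAML nor JSON: ",
                                    path)))
  if (!is.list(cfg)) stop("config must be a mapping: ", path)
  cfg
}

#' Hash of a configuration for reproducibility logs
#'
#' Serialises the configuration to canonical JSON and returns its MD5.
#'
#' @param cfg Named list.
#' @return Character hash.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Write a structured run log
#'
#' Records the replicate seed (and the master seed it was derived from),
#' the configuration hash, the package version and per-cycle summary lines
#' (peak force, peak distance, event counts) next to the run outputs.
#'
#' @param sim An `if_sim` result.
#' @param cfg Configuration list used for the run.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(sim, cfg, path) {
  tr <- sim$traces
  per_cycle <- lapply(split(tr, tr$cycle), function(cc) {
    ev <- sim$events[sim$events$cycle == cc$cycle[1], , drop = FALSE]
    list(cycle = cc$cycle[1],
         peak_force_pN = max(cc$F_pN),
         peak_distance_nm = max(cc$d_nm),
         n_events = nrow(ev))
  })
  log <- list(seed = sim$seed,
              master_seed = cfg$seed,
              config_hash = config_hash(cfg),
              package_version = as.character(utils::packageVersion("ifmech")),
              d_max_nm = sim$d_max,
              rupture = sim$rupture,
              cycles = unname(per_cycle))
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# protocol/model constructors from a plain config list
protocol_from_config <- function(pc) {
  pc <- pc[names(pc) %in% names(formals(protocol_spec))]
  do.call(protocol_spec, pc)
}

model_from_config <- function(mc) {
  type <- mc$type %||% "keratin"
  mc$type <- NULL
  maker <- switch(type, keratin = keratin_params, vimentin = vimentin_params,
                  stop("unknown model type: ", type))
  mc <- mc[names(mc) %in% names(formals(maker))]
  list(type = type, cfg = do.call(maker, mc))
}
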