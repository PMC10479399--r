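# Configuration and file I/O: track tables as CSV, results as versioned
# JSON, run configuration from YAML or JSON with defaults equal to the
# package's published parameter values.

.TRACK_COLS <- c("track_id", "frame", "t_s", "x_nm", "y_nm")

#' Read speckle tracks from a CSV file
#'
#' Expects columns `track_id`, `frame`, `t_s`, `x_nm`, `y_nm`. Frames are
#' re-sorted by time within each track (with a warning if re-ordering was
#' needed); non-finite positions are a format error.
#'
#' @param path CSV file path.
#' @return A track data.frame.
#' @export
read_tracks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.TRACK_COLS, names(df))
  if (length(missing))
    stop("track file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  bad <- which(!is.finite(df$x_nm) | !is.finite(df$y_nm) | !is.finite(df$t_s))
  if (length(bad))
    stop("track file ", path, ": non-finite values at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  ord <- order(df$track_id, df$t_s)
  if (any(ord != seq_len(nrow(df)))) {
    warning("tracks re-sorted by time within track_id", call. = FALSE)
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
  }
  df[.TRACK_COLS]
}

#' Write speckle tracks to CSV
#'
#' @param tracks Track data.frame (see [read_tracks()] for columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(all(.TRACK_COLS %in% names(tracks)))
  write.csv(tracks[.TRACK_COLS], path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis/simulation result as versioned JSON
#'
#' The payload is wrapped with a schema identifier, the package version, the
#' seed and a hash of the configuration so a run can be reproduced from its
#' output alone. Serialization is deterministic; NaN/Inf observables are
#' serialized as nulls and flagged.
#'
#' @param results A (nested) list of numeric/character results.
#' @param path Output JSON path.
#' @param seed Seed used for the run, if any.
#' @param config The configuration list used for the run, if any.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, seed = NULL, config = NULL) {
  has_na <- function(x) {
    if (is.list(x)) any(vapply(x, has_na, logical(1)))
    else is.numeric(x) && any(!is.finite(x))
  }
  payload <- list(
    schema = "talinclutch/results/v1",
    package_version = as.character(packageVersion("talinclutch")),
    seed = seed,
    config_hash = if (is.null(config)) NULL else
      sum(utf8ToInt(paste(deparse(config), collapse = ""))) %% 2^31,
    has_nonfinite = has_na(results),
    results = results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

.CONFIG_DEFAULTS <- list(
  mechanics = list(k_folded = 1e4, l_folded0 = 2, kuhn_b = 0.38,
                   n_res = 145, temperature = 300),
  chain = list(n_total = 12, n_unfoldable = 12, theta0 = 45, v_retro = 20),
  unfolding = list(k0 = 1e-4, dx = 4),
  unbinding = list(model = "slip", k0 = 0.17, dx = 0.51,
                   k10_0 = 0.194, k12_0 = 0.142, k21_0 = 1, k20_0 = 5.5e-6,
                   x10 = 0, x20 = 2.5, x12 = 0.4, x21 = -1.6),
  simulation = list(dt_me = 1e-3, dt_sim = 1e-6, zeta = 1e-4, seed = 1,
                    n_realizations = 1, t_max = 120, p_terminate = 0.999,
                    compliance_k3 = NULL),
  analysis = list(mode = "coarse_2s", motion_threshold = NULL,
                  flow_axis = c(1, 0), localization_sd = 18.6,
                  bleach_per_frame = 0.0071, frame_interval = 2))

#' Parse a run configuration from YAML or JSON
#'
#' Missing keys are filled with the package defaults (the published model
#' parameter values); unknown sections or keys are rejected with the path to
#' the offending key. Returns validated parameter objects ready to pass to
#' the simulation and analysis functions.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON file; an empty file yields the
#'   all-defaults configuration.
#' @return A list of class `talin_run_config` with elements `mech`
#'   ([mechanical_params()]), `chain` ([chain_config()]), `unfold`
#'   ([bell_params()]), `unbind` ([bell_params()] or
#'   [catch_slip_params()]), `simulation`, `analysis` and `raw`.
#' @export
parse_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config root must be a mapping")
  bad_sec <- setdiff(names(raw), names(.CONFIG_DEFAULTS))
  if (length(bad_sec))
    stop("unknown config section(s): ", paste(bad_sec, collapse = ", "))
  cfg <- .CONFIG_DEFAULTS
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), names(.CONFIG_DEFAULTS[[sec]]))
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
    cfg[[sec]] <- modifyList(cfg[[sec]], raw[[sec]])
  }
  mech <- do.call(mechanical_params, cfg$mechanics)
  chain <- do.call(chain_config, cfg$chain)   # validates theta0, M <= N
  unfold <- bell_params(cfg$unfolding$k0, cfg$unfolding$dx)
  unbind <- if (identical(cfg$unbinding$model, "catch_slip"))
    catch_slip_params(cfg$unbinding$k10_0, cfg$unbinding$k12_0,
                      cfg$unbinding$k21_0, cfg$unbinding$k20_0,
                      cfg$unbinding$x10, cfg$unbinding$x20,
                      cfg$unbinding$x12, cfg$unbinding$x21)
  else bell_params(cfg$unbinding$k0, cfg$unbinding$dx)
  structure(list(mech = mech, chain = chain, unfold = unfold,
                 unbind = unbind, simulation = cfg$simulation,
                 analysis = cfg$analysis, raw = cfg),
            class = "talin_run_config")
}
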