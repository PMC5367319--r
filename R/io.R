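# Run configuration, deterministic seed derivation, and readers/writers for
# trajectory artifacts.

.CONFIG_KEYS <- c("model", "u", "m", "eps", "l", "zc", "irreversible_bonds",
                  "dt", "t_max", "record_stride", "reps", "seed", "out",
                  "z0", "gc0")
.MODELS <- c("two_island", "three_island", "oracle", "sweep_threshold",
             "sweep_epsilon", "ratio_sd")

#' Derive a per-replicate RNG seed from a master seed
#'
#' Counter-based scheme: replicate `k` of a run with master seed `s` gets the
#' seed `(s + k * 48271) mod (2^31 - 1) + 1`, so any replicate is reproducible
#' on its own without running replicates `1..k-1`.
#'
#' @param master Master seed (integer).
#' @param k Replicate (or cell) index, >= 0.
#' @return A positive integer seed below 2^31.
#' @export
replicate_seed <- function(master, k) {
  if (anyNA(master) || anyNA(k)) stop("seed and index must be non-missing")
  ((as.double(master) %% 2147483647 + as.double(k) * 48271) %%
     2147483647) + 1
}

#' Load a run configuration from a YAML file
#'
#' The file holds model selection, parameters and numerical controls as flat
#' keys (`m` may be a scalar or a named map). Unknown keys and out-of-range
#' values raise descriptive errors; missing numerical controls are filled with
#' defaults.
#'
#' @param path Path to a YAML file.
#' @param overrides Named list merged over the file values (e.g. parsed CLI
#'   flags).
#' @return A list of class `run_config` with elements `model`, `params`
#'   (an [island_params()]), `dt`, `t_max`, `record_stride`, `reps`, `seed`,
#'   `out`, `z0`, `gc0`.
#' @export
load_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a key-value document")
  raw[names(overrides)] <- overrides
  unknown <- setdiff(names(raw), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(raw$u)) stop("config key 'u' is required")
  model <- raw$model %||% "three_island"
  if (!model %in% .MODELS)
    stop("config key 'model' must be one of: ",
         paste(.MODELS, collapse = ", "))
  m <- raw$m %||% 0
  if (is.list(m)) m <- unlist(m)
  params <- island_params(u = raw$u, m = m, eps = raw$eps %||% 0.01,
                          l = raw$l %||% Inf, zc = raw$zc %||% 1,
                          irreversible_bonds =
                            raw$irreversible_bonds %||% FALSE)
  num1 <- function(key, default, lower = 0) {
    v <- raw[[key]] %||% default
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= lower)
      stop("config key '", key, "' must be a number > ", lower)
    v
  }
  cfg <- list(model = model, params = params,
              dt = num1("dt", 1), t_max = num1("t_max", 1e6),
              record_stride = as.integer(num1("record_stride", 1)),
              reps = as.integer(num1("reps", 1)),
              seed = if (is.null(raw$seed)) NULL else as.integer(raw$seed),
              out = raw$out, z0 = raw$z0 %||% 0,
              gc0 = as.numeric(unlist(raw$gc0 %||% c(1, 0, 0, 0, 0))))
  if (length(cfg$gc0) != 5L) stop("config key 'gc0' must have 5 entries")
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration to YAML
#'
#' Inverse of [load_run_config()]: `load_run_config(save_run_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param cfg A `run_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(cfg, path) {
  if (!inherits(cfg, "run_config")) stop("'cfg' must be a run_config")
  p <- cfg$params
  lst <- list(model = cfg$model, u = p$u, m = as.list(p$m), eps = p$eps,
              l = if (is.finite(p$l)) p$l else "Inf", zc = p$zc,
              irreversible_bonds = p$irreversible_bonds,
              dt = cfg$dt, t_max = cfg$t_max,
              record_stride = cfg$record_stride, reps = cfg$reps,
              seed = cfg$seed, out = cfg$out, z0 = cfg$z0,
              gc0 = as.list(cfg$gc0))
  lst <- lst[!vapply(lst, is.null, logical(1L))]
  yaml::write_yaml(lst, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the fixed column order of three-island trajectory files
.TRAJ_COLS3 <- c("t", paste0("z", 1:5), "zAB", "zBC", "zCA", "bonds_open")

#' Write a trajectory to CSV or JSON
#'
#' CSV files carry the seed and the parameter set as leading `#` comment
#' lines and use full float precision, so a read-back reproduces the values
#' exactly. JSON files carry a `meta` object and a `records` table.
#'
#' @param traj An `island_trajectory` (or plain data frame with the
#'   trajectory schema).
#' @param path Output path.
#' @param format `"csv"` or `"json"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv")
  format <- match.arg(format, c("csv", "json"))
  params <- attr(traj, "params")
  meta <- list(model = attr(traj, "model") %||% "trajectory",
               seed = attr(traj, "seed"))
  if (!is.null(params))
    meta$params <- list(l = if (is.finite(params$l)) params$l else "Inf",
                        u = params$u, eps = params$eps, zc = params$zc,
                        m = as.list(params$m))
  df <- as.data.frame(traj)
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                             digits = NA)), con)
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                     con, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(list(meta = meta, records = df), path,
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default guesses from the extension.
#' @return A data frame with the trajectory records; metadata (if present) in
#'   attribute `meta`.
#' @export
read_trajectory <- function(path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv")
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    first <- readLines(path, n = 1L)
    meta <- NULL
    if (startsWith(first, "# "))
      meta <- jsonlite::fromJSON(sub("^# ", "", first))
    df <- utils::read.csv(path, comment.char = "#")
  } else {
    obj <- jsonlite::fromJSON(path)
    meta <- obj$meta
    df <- as.data.frame(obj$records)
  }
  attr(df, "meta") <- meta
  df
}
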