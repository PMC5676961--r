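## Configuration loading, seeding, and serialisation shared by all modules.
## All randomness flows through label-separated seeded streams, so the
## generative process and the agent's action sampling can be reproduced
## independently (required by the shared-process design of the precision
## sweep).

#' Create a label-separated deterministic random stream
#'
#' Streams with the same \code{(seed, label)} reproduce the same draws;
#' different labels give effectively independent streams.  Streams carry
#' their own RNG state and never touch the global generator.
#'
#' @param seed integer master seed.
#' @param stream_label character label (e.g. \code{"process"}, \code{"agent"}).
#' @return an environment of class \code{"seeded_stream"}.
#' @export
seeded_stream <- function(seed, stream_label = "default") {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  h <- 5381
  for (ch in utf8ToInt(as.character(stream_label)))
    h <- (h * 33 + ch) %% 2147483647
  sub <- as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
  e <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(sub, kind = "Mersenne-Twister")
  e$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  e$seed <- seed
  e$label <- stream_label
  class(e) <- "seeded_stream"
  e
}

#' Draw uniform variates from a stream
#'
#' @param stream a [seeded_stream()].
#' @param n number of draws.
#' @return numeric vector of draws in (0, 1).
#' @export
stream_runif <- function(stream, n = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream$state, envir = globalenv())
  out <- stats::runif(n)
  stream$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  out
}

#' Sample indices through a stream
#'
#' @param stream a [seeded_stream()].
#' @param n upper bound (samples from \code{1:n}).
#' @param size number of draws.
#' @param prob optional probability weights.
#' @return integer vector.
#' @export
stream_sample <- function(stream, n, size = 1L, prob = NULL) {
  if (is.null(prob)) prob <- rep(1 / n, n)
  p <- norm_dist(prob)
  cp <- cumsum(p)
  vapply(stream_runif(stream, size), function(r)
    as.integer(findInterval(r, cp + 1e-15) + 1L), 1L)
}

## default run configuration -------------------------------------------------

default_config <- function() {
  list(
    task = "delay",
    model = list(
      retrocue_validity = 0.9,
      n_total_scenes = 3L,
      likelihood_precision = 0.85,
      steps_per_epoch = 5L
    ),
    inference = list(
      n_iter = 32L,
      step_size = 0.25,
      entropy_threshold = 0.03,
      beta_prior = 1,
      plan_horizon = 1L,
      action_mode = "deterministic",
      alpha = 16
    ),
    experiment = list(
      n_per_condition = 50L,
      set_sizes = c(3L, 4L, 5L),
      validities = c(0.9, 0.5),
      betas = c(0.25, 1, 4),
      n_reps = 16L
    ),
    seed = 1L,
    out_dir = "results"
  )
}

#' Load and validate a run configuration
#'
#' Reads a JSON or YAML file (dispatch on extension), fills defaults,
#' rejects unknown keys, and checks the invariants the simulator depends
#' on (probability bounds, positive precisions).
#'
#' @param path file path, or `NULL` for pure defaults.
#' @return validated configuration list of class \code{"run_config"}, with
#'   its hash in attribute \code{"hash"}.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    ext <- tolower(tools::file_ext(path))
    user <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
    else jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (is.null(user)) user <- list()
  }
  def <- default_config()
  check_keys <- function(u, d, where) {
    unknown <- setdiff(names(u), names(d))
    if (length(unknown))
      stop("unknown config key", if (length(unknown) > 1) "s", " at ", where,
           ": ", paste(unknown, collapse = ", "), call. = FALSE)
    for (k in names(u))
      if (is.list(d[[k]]) && is.list(u[[k]]))
        check_keys(u[[k]], d[[k]], paste0(where, "$", k))
  }
  check_keys(user, def, "config")
  cfg <- utils::modifyList(def, user)
  v <- cfg$model$retrocue_validity
  if (v < 0.5 || v > 1)
    stop("model$retrocue_validity = ", v, " violates the bound [0.5, 1]",
         call. = FALSE)
  if (!cfg$model$n_total_scenes %in% 3:5)
    stop("model$n_total_scenes must be 3, 4 or 5", call. = FALSE)
  a <- cfg$model$likelihood_precision
  if (a <= 0 || a > 1)
    stop("model$likelihood_precision must lie in (0, 1]", call. = FALSE)
  if (cfg$inference$step_size <= 0 || cfg$inference$step_size > 1)
    stop("inference$step_size must lie in (0, 1]", call. = FALSE)
  if (cfg$inference$beta_prior <= 0)
    stop("inference$beta_prior must be positive", call. = FALSE)
  if (cfg$inference$n_iter < 1)
    stop("inference$n_iter must be at least 1", call. = FALSE)
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Serialise a configuration to JSON
#'
#' Round-trips through [load_config()]: \code{load(dump(cfg))} is
#' identical to \code{cfg}.
#'
#' @param cfg a configuration list.
#' @param path output path (".json").
#' @return invisibly, the path.
#' @export
dump_config <- function(cfg, path) {
  attr(cfg, "hash") <- NULL
  cfg <- unclass(cfg)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' FNV-1a over the canonical JSON serialisation; embedded in every output
#' so results are traceable to the exact settings that produced them.
#'
#' @param cfg configuration list.
#' @return character hash.
#' @export
config_hash <- function(cfg) {
  attr(cfg, "hash") <- NULL
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  h1 <- 5381; h2 <- 52711
  for (ch in utf8ToInt(as.character(s))) {
    h1 <- (h1 * 33 + ch) %% 2147483647
    h2 <- (h2 * 31 + ch) %% 2147483629
  }
  paste0(sprintf("%08x", h1), sprintf("%08x", h2))
}

#' Export a trial record's unit dynamics to tidy CSV
#'
#' One row per (time, iteration, factor, unit): the policy-averaged belief
#' \code{s_bar} and its increment \code{nu_dot} per gradient iteration,
#' plus per-time summaries (free energies, policy posterior, beta).
#'
#' @param record a [run_level_trial()] record.
#' @param path output CSV path (units file); summaries are written next to
#'   it with suffix \code{"_summary.csv"}.
#' @param trial trial identifier column.
#' @param level level identifier column.
#' @return invisibly, the paths written.
#' @export
export_trial_csv <- function(record, path, trial = 1L, level = 1L) {
  rows <- list()
  for (t in seq_len(record$n_steps)) {
    st <- record$steps[[t]]
    if (is.null(st)) next
    for (f in seq_along(st$xn)) {
      xn <- st$xn[[f]]; vn <- st$vn[[f]]
      ni <- dim(xn)[1]; ns <- dim(xn)[2]
      for (i in seq_len(ni)) {
        rows[[length(rows) + 1L]] <- data.frame(
          trial = trial, level = level, time = t, iteration = i,
          factor = f, unit = seq_len(ns),
          s_bar = xn[i, , t], nu_dot = vn[i, , t])
      }
    }
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  spath <- sub("\\.csv$", "_summary.csv", path)
  ts <- seq_len(record$n_steps)
  sm <- data.frame(trial = trial, level = level, time = ts,
                   beta = record$beta[ts],
                   iters_to_converge = record$iters[ts])
  for (p in seq_len(nrow(record$F_pi))) {
    sm[[paste0("F_pi", p)]] <- record$F_pi[p, ts]
    sm[[paste0("G_pi", p)]] <- record$G_pi[p, ts]
    sm[[paste0("q_pi", p)]] <- record$q_pi[p, ts]
  }
  utils::write.csv(sm, spath, row.names = FALSE)
  invisible(c(path, spath))
}
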