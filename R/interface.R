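# Run configuration and the command-line entry point.

.config_keys <- c("battery", "condition", "observers", "trials", "seed",
                  "out", "mode", "overrides")

.override_bounds <- list(
  rho_agent = c(0, 1), rho_true = c(0, 1), p_changeup = c(0, 1),
  q_hit = c(0, 1), gamma = c(0, Inf), eta = c(1e-12, Inf),
  persistence = c(1e-12, 1)
)

#' Validate a run configuration
#'
#' Rejects unknown keys, requires exactly one of `battery`/`condition`,
#' checks that names exist in the registry, and bounds-checks numeric
#' overrides (e.g. believed cue reliability must lie in `[0, 1]`). Error
#' messages name the offending field.
#'
#' @param config Named list, typically read from YAML via
#'   [read_run_config()].
#' @return The validated config, invisibly.
#' @export
validate_run_config <- function(config) {
  unknown <- setdiff(names(config), .config_keys)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  has_b <- !is.null(config$battery)
  has_c <- !is.null(config$condition)
  if (has_b == has_c) {
    stop("config must set exactly one of 'battery' or 'condition'")
  }
  if (has_b && !config$battery %in% names(list_batteries())) {
    stop(sprintf("battery: unknown battery '%s'", config$battery))
  }
  if (has_c && !config$condition %in% list_conditions()) {
    stop(sprintf("condition: unknown condition '%s'", config$condition))
  }
  for (key in c("observers", "trials")) {
    v <- config[[key]]
    if (!is.null(v) && (!is.numeric(v) || v < 1)) {
      stop(sprintf("%s: must be a positive integer", key))
    }
  }
  if (!is.null(config$seed) &&
      (!is.numeric(config$seed) || config$seed != round(config$seed))) {
    stop("seed: must be an integer")
  }
  if (!is.null(config$mode) && !config$mode %in% c("sample", "argmax")) {
    stop("mode: must be 'sample' or 'argmax'")
  }
  ov <- config$overrides
  if (!is.null(ov)) {
    if (is.null(names(ov)) || any(names(ov) == "")) {
      stop("overrides: must be a named list")
    }
    for (key in names(ov)) {
      b <- .override_bounds[[key]]
      if (!is.null(b)) {
        v <- ov[[key]]
        if (!is.numeric(v) || any(v < b[1L]) || any(v > b[2L])) {
          stop(sprintf("overrides.%s: must lie in [%g, %g]", key, b[1L], b[2L]))
        }
      }
    }
  }
  invisible(config)
}

#' Read and validate a YAML run configuration
#'
#' @param path Path to a YAML file with keys among `battery`, `condition`,
#'   `observers`, `trials`, `seed`, `out`, `mode`, `overrides`.
#' @return The validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  config <- yaml::read_yaml(path)
  validate_run_config(config)
  config
}

# Parse `--flag value` pairs and repeatable `--set key=value` overrides.
.parse_cli_args <- function(args) {
  flags <- list()
  overrides <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--set") {
      kv <- strsplit(args[i + 1L], "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) stop("--set expects key=value")
      val <- utils::type.convert(kv[2L], as.is = TRUE)
      overrides[[kv[1L]]] <- val
      i <- i + 2L
    } else if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args)) stop(sprintf("flag %s needs a value", a))
      flags[[key]] <- utils::type.convert(args[i + 1L], as.is = TRUE)
      i <- i + 2L
    } else {
      stop(sprintf("unexpected argument '%s'", a))
    }
  }
  list(flags = flags, overrides = overrides)
}

.cli_config <- function(parsed) {
  flags <- parsed$flags
  config <- if (!is.null(flags$config)) yaml::read_yaml(flags$config) else list()
  for (key in c("battery", "condition", "mode", "out")) {
    if (!is.null(flags[[key]])) config[[key]] <- flags[[key]]
  }
  if (!is.null(flags$observers)) config$observers <- flags$observers
  if (!is.null(flags$trials)) config$trials <- flags$trials
  if (!is.null(flags$seed)) config$seed <- flags$seed
  if (length(parsed$overrides)) {
    config$overrides <- utils::modifyList(
      if (is.null(config$overrides)) list() else config$overrides,
      parsed$overrides
    )
  }
  config
}

#' Command-line entry point
#'
#' Subcommands: `run` (execute a battery or single condition and write CSV /
#' JSON artifacts plus a provenance log), `list-conditions` (print the
#' registry), and `validate-config` (check a YAML config). Flags for `run`:
#' `--battery`, `--condition`, `--observers`, `--trials`, `--seed`, `--out`,
#' `--mode`, `--config <yaml>`, and repeatable `--set key=value` overrides.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   calling script's trailing arguments).
#' @return Integer exit status (0 on success), invisibly. Invalid
#'   configuration raises a classed error whose message names the field when
#'   called programmatically; the shell wrapper converts it to a nonzero
#'   exit.
#' @export
cli_run <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: anticipatr <run|list-conditions|validate-config> [flags]\n")
    return(invisible(1L))
  }
  sub <- args[1L]
  rest <- args[-1L]
  if (sub == "list-conditions") {
    bats <- list_batteries()
    for (b in names(bats)) {
      cat(sprintf("%s:\n", b))
      for (nm in bats[[b]]) cat(sprintf("  %s\n", nm))
    }
    return(invisible(0L))
  }
  if (sub == "validate-config") {
    parsed <- .parse_cli_args(rest)
    path <- parsed$flags$config
    if (is.null(path)) stop("validate-config requires --config <yaml>")
    validate_run_config(yaml::read_yaml(path))
    cat("config ok\n")
    return(invisible(0L))
  }
  if (sub != "run") stop(sprintf("unknown subcommand '%s'", sub))

  parsed <- .parse_cli_args(rest)
  config <- .cli_config(parsed)
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out)) config$out <- "results"
  validate_run_config(config)

  seed <- as.integer(config$seed)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  overrides <- if (is.null(config$overrides)) list() else config$overrides

  if (!is.null(config$battery)) {
    results <- run_battery(
      config$battery, base_seed = seed,
      n_observers = config$observers, n_trials = config$trials,
      mode = config$mode, overrides = overrides
    )
  } else {
    res <- run_batch(
      make_condition(config$condition, overrides),
      n_observers = config$observers, n_trials = config$trials,
      base_seed = seed, mode = config$mode
    )
    results <- structure(
      stats::setNames(list(res), config$condition),
      class = "aip_battery", battery = res$condition$battery, base_seed = seed
    )
  }
  paths <- write_battery(results, out)

  resolved <- config[order(names(config))]
  yaml::write_yaml(resolved, file.path(out, "config.yaml"))
  log_lines <- c(
    sprintf("anticipatr %s", as.character(utils::packageVersion("anticipatr"))),
    sprintf("R %s", getRversion()),
    sprintf("seed %d", seed),
    sprintf("config_hash %s", rlang::hash(resolved)),
    sprintf("artifacts %s", paste(basename(paths), collapse = ", "))
  )
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(0L)
}
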