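#' Write / read baseline probability tables and transition matrices
#'
#' Plain-CSV interchange for the generator's inputs. Baseline tables use
#' columns `arm,dimension,level,probability`; transition files use
#' `arm,dimension,from_level,to_level,probability`. Both carry a
#' `#`-prefixed YAML preamble with the `version`.
#'
#' @param probs A [baseline_probs][new_baseline_probs] object.
#' @param file Path.
#' @return `file` invisibly (writers); the parsed object (readers).
#' @export
write_baseline_probs <- function(probs, file) {
  stopifnot(inherits(probs, "baseline_probs"))
  rows <- character()
  for (arm in c("control", "intervention")) {
    m <- probs[[arm]]
    for (d in EQ5D_DIMENSIONS) {
      rows <- c(rows, sprintf("%s,%s,%d,%s", arm, d, seq_len(ncol(m)),
                              vapply(m[d, ], format, "", digits = 17)))
    }
  }
  writeLines(c(sprintf("# version: \"%s\"", probs$version),
               "arm,dimension,level,probability", rows), file)
  invisible(file)
}

#' @rdname write_baseline_probs
#' @export
read_baseline_probs <- function(file) {
  lines <- readLines(file)
  meta <- yaml::yaml.load(paste(sub("^#[ ]?", "",
                                    lines[startsWith(lines, "#")]),
                                collapse = "\n"))
  df <- utils::read.csv(text = paste(lines[!startsWith(lines, "#")],
                                     collapse = "\n"),
                        stringsAsFactors = FALSE)
  L <- n_levels(meta$version)
  get_arm <- function(arm) {
    m <- matrix(0, 5L, L, dimnames = list(EQ5D_DIMENSIONS, NULL))
    sub <- df[df$arm == arm, ]
    m[cbind(match(sub$dimension, EQ5D_DIMENSIONS), sub$level)] <- sub$probability
    m
  }
  new_baseline_probs(meta$version, get_arm("control"), get_arm("intervention"))
}

#' @rdname write_baseline_probs
#' @param transitions A [transition_model][new_transition_model].
#' @export
write_transitions <- function(transitions, file) {
  stopifnot(inherits(transitions, "transition_model"))
  rows <- character()
  for (arm in c("control", "intervention")) {
    for (d in EQ5D_DIMENSIONS) {
      m <- transitions[[arm]][[d]]
      idx <- expand.grid(f = seq_len(nrow(m)), t = seq_len(ncol(m)))
      rows <- c(rows, sprintf("%s,%s,%d,%d,%s", arm, d, idx$f, idx$t,
                              vapply(m[cbind(idx$f, idx$t)], format, "",
                                     digits = 17)))
    }
  }
  writeLines(c(sprintf("# version: \"%s\"", transitions$version),
               sprintf("# shift: %s", format(transitions$shift, digits = 17)),
               "arm,dimension,from_level,to_level,probability", rows), file)
  invisible(file)
}

#' @rdname write_baseline_probs
#' @export
read_transitions <- function(file) {
  lines <- readLines(file)
  meta <- yaml::yaml.load(paste(sub("^#[ ]?", "",
                                    lines[startsWith(lines, "#")]),
                                collapse = "\n"))
  df <- utils::read.csv(text = paste(lines[!startsWith(lines, "#")],
                                     collapse = "\n"),
                        stringsAsFactors = FALSE)
  L <- n_levels(meta$version)
  get_arm <- function(arm) {
    mats <- lapply(EQ5D_DIMENSIONS, function(d) {
      sub <- df[df$arm == arm & df$dimension == d, ]
      m <- matrix(0, L, L)
      m[cbind(sub$from_level, sub$to_level)] <- sub$probability
      m
    })
    stats::setNames(mats, EQ5D_DIMENSIONS)
  }
  new_transition_model(meta$version, get_arm("control"),
                       get_arm("intervention"),
                       shift = meta$shift %||% 0)
}

.file_digest <- function(path) unname(tools::md5sum(path))

#' Run the full simulation-to-comparison pipeline from a YAML config
#'
#' Reads a config, validates it, writes a run manifest first (seeds,
#' substreams, package version, config and data-file digests), then runs
#' [run_factorial()] and serializes `table_utilities.csv`,
#' `table_qalys.csv`, `table_cua.csv`, and `summary.json` into `out_dir`.
#' Two runs from the same config are byte-identical apart from the
#' manifest's timestamp.
#'
#' Config keys: `seed` (required integer); optional `countries`,
#' `versions`, `n_per_arm`, `bootstrap_replications`, `wtp`, `horizon`,
#' `mcid`, `scenarios` (vector of scenario ids 1-36), `tariff_files`
#' (country -> version -> path), `crosswalk_files` (direction -> path).
#'
#' @param config_file Path to the YAML config.
#' @param out_dir Output directory (created if missing).
#' @return The [run_factorial()] result, invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(config_file, out_dir) {
  cfg <- yaml::read_yaml(config_file)
  if (is.null(cfg$seed)) stop("config error at $seed: a master seed is required")
  for (k in names(cfg)) {
    if (!k %in% c("seed", "countries", "versions", "n_per_arm",
                  "bootstrap_replications", "wtp", "horizon", "mcid",
                  "scenarios", "tariff_files", "crosswalk_files")) {
      stop("config error: unknown key $", k)
    }
  }
  countries <- cfg$countries %||% c("NL", "US", "JP")
  versions <- cfg$versions %||% c("3L", "5L")
  wtp <- cfg$wtp %||% c(0, 20000, 30000, 50000)

  tariffs <- crosswalks <- NULL
  digests <- list(config = .file_digest(config_file))
  if (!is.null(cfg$tariff_files)) {
    tariffs <- lapply(cfg$tariff_files, function(by_v) lapply(by_v, read_tariff))
    digests$tariffs <- lapply(cfg$tariff_files,
                              function(by_v) lapply(by_v, .file_digest))
  }
  if (!is.null(cfg$crosswalk_files)) {
    crosswalks <- lapply(cfg$crosswalk_files, read_crosswalk)
    digests$crosswalks <- lapply(cfg$crosswalk_files, .file_digest)
  }

  scen <- enumerate_scenarios()
  if (!is.null(cfg$scenarios)) {
    if (!all(cfg$scenarios %in% scen$scenario)) {
      stop("config error at $scenarios: ids must be in 1..36")
    }
    scen <- scen[scen$scenario %in% cfg$scenarios, ]
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "eq5dcua",
    package_version = as.character(utils::packageVersion("eq5dcua")),
    created = format(Sys.time(), tz = "UTC"),
    master_seed = cfg$seed,
    substreams = list(
      population = "substream(seed, '<condition> <severity>')",
      scenario = "substream(seed, '<condition> <severity> <band>')",
      bootstrap = "substream(scenario_seed, 'cua <country> <version>')"
    ),
    digests = digests,
    settings = list(countries = countries, versions = versions,
                    n_per_arm = cfg$n_per_arm %||% 150L,
                    bootstrap_replications = cfg$bootstrap_replications %||% 2000L,
                    wtp = wtp, horizon = cfg$horizon %||% 1,
                    mcid = cfg$mcid %||% 0.074,
                    scenarios = scen$scenario)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  res <- run_factorial(
    scenarios = scen, countries = countries, versions = versions,
    n_per_arm = cfg$n_per_arm %||% 150L,
    B = cfg$bootstrap_replications %||% 2000L,
    wtp = wtp, horizon = cfg$horizon %||% 1, seed = cfg$seed,
    mcid = cfg$mcid %||% 0.074, tariffs = tariffs, crosswalks = crosswalks
  )
  utils::write.csv(res$utilities, file.path(out_dir, "table_utilities.csv"),
                   row.names = FALSE)
  utils::write.csv(res$qalys, file.path(out_dir, "table_qalys.csv"),
                   row.names = FALSE)
  utils::write.csv(res$cua, file.path(out_dir, "table_cua.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(res$errors)) {
    utils::write.csv(res$errors, file.path(out_dir, "errors.csv"),
                     row.names = FALSE)
    warning(sprintf("%d scenario run(s) failed; see errors.csv",
                    nrow(res$errors)))
  }
  invisible(res)
}

#' Generate a self-consistent fixture set
#'
#' Writes a toy tariff, a crosswalk whose lookup is generated from its own
#' matrices (so [consistency_check()] reports a maximum difference of 0), a
#' baseline probability table, a transition model, and a small simulated
#' trial CSV into `out_dir`.
#'
#' @param out_dir Writable directory.
#' @param seed Integer seed for the toy trial.
#' @return Named list of file paths, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  terms <- data.frame(
    dimension = c("MO", "SC", "UA", "PD", "AD", NA),
    level = c(2L, 2L, 2L, 3L, 2L, 2L),
    indicator = c(rep("level_dummy", 5), "any_level_ge"),
    coefficient = c(0.05, 0.04, 0.03, 0.20, 0.06, 0.07),
    offset = 0L
  )
  tf <- new_tariff("FIX", "3L", terms, note = "fixture tariff (synthetic)")
  paths$tariff <- file.path(out_dir, "tariff_fixture.csv")
  write_tariff(tf, paths$tariff)

  spread <- function(Ls, Lt) {
    t(vapply(1:Ls, function(s) {
      centre <- 1 + (s - 1) * (Lt - 1) / (Ls - 1)
      w <- exp(-2 * (seq_len(Lt) - centre)^2)
      w / sum(w)
    }, numeric(Lt)))
  }
  mats <- stats::setNames(rep(list(spread(5, 3)), 5), EQ5D_DIMENSIONS)
  xw <- new_crosswalk("5L_to_3L", mats)
  xw <- new_crosswalk("5L_to_3L", mats,
                      lookup = lookup_from_matrices(xw, list(tf)))
  paths$crosswalk <- file.path(out_dir, "crosswalk_fixture.csv")
  paths$crosswalk_lookup <- file.path(out_dir, "crosswalk_fixture_lookup.csv")
  write_crosswalk(xw, paths$crosswalk, paths$crosswalk_lookup)

  probs <- baseline_probabilities("low_back_pain", "moderate", "3L")
  paths$baseline <- file.path(out_dir, "baseline_probs_fixture.csv")
  write_baseline_probs(probs, paths$baseline)

  trans <- calibrate_effect_size(control_transitions("3L"), probs, "medium",
                                 builtin_tariff("NL", "3L"))
  paths$transitions <- file.path(out_dir, "transitions_fixture.csv")
  write_transitions(trans, paths$transitions)

  cfg <- scenario_config("low_back_pain", "moderate", "medium",
                         n_per_arm = 25L, seed = seed)
  dat <- simulate_trial(cfg, "3L")
  paths$trial <- file.path(out_dir, "trial_fixture.csv")
  utils::write.csv(dat, paths$trial, row.names = FALSE)

  invisible(paths)
}
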