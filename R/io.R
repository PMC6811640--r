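# Trace CSV input/output, run configuration, and result serialization.

check_trace_frame <- function(traces) {
  needed <- c("cell_id", "time_s", "fluorescence")
  if (!is.data.frame(traces) || !all(needed %in% names(traces))) {
    stop("traces must be a data.frame with columns ",
         paste(needed, collapse = ", "))
  }
  invisible(traces)
}

#' Read photobleaching traces from CSV
#'
#' Reads a long-format trace file with header
#' `cell_id,time_s,fluorescence`, groups rows by cell, sorts by time, and
#' validates the grid: numeric values, no duplicate `(cell, time)` pairs,
#' and (optionally) uniform spacing.
#'
#' @param path CSV file path.
#' @param dt Expected uniform frame spacing in seconds, or `NULL` to skip
#'   the check.
#' @param tol Relative tolerance for the spacing check.
#'
#' @return A validated long-format data.frame ordered by cell and time.
#' @export
read_traces <- function(path, dt = NULL, tol = 1e-6) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("cell_id", "time_s", "fluorescence")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("trace file is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!is.numeric(df$time_s) || !is.numeric(df$fluorescence)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$time_s))) |
                   is.na(suppressWarnings(as.numeric(df$fluorescence))))
    stop("non-numeric time_s or fluorescence values at rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  dup <- duplicated(df[, c("cell_id", "time_s")])
  if (any(dup)) {
    first <- df$cell_id[which(dup)[1]]
    stop("duplicate (cell, time) rows for cell '", first, "' at row ",
         which(dup)[1])
  }
  df <- df[order(df$cell_id, df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(dt)) {
    for (id in unique(df$cell_id)) {
      d <- diff(df$time_s[df$cell_id == id])
      if (any(abs(d - dt) > tol * dt)) {
        stop("cell '", id, "' does not have uniform spacing dt = ", dt)
      }
    }
  }
  df
}

#' Write traces (and optional ground truth) to disk
#'
#' @param traces Long-format traces.
#' @param path CSV output path.
#' @param truth Optional list of ground-truth parameters; written as a
#'   JSON sidecar at `paste0(path, ".truth.json")`.
#'
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, truth = NULL) {
  check_trace_frame(traces)
  utils::write.csv(traces, path, row.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(path)
}

#' Default run configuration
#'
#' Collects every tunable of the two workflows, with the package's
#' standard experiment geometry (45 frames at 10-s intervals) and sampler
#' defaults (10 chains, kernel variance 1e-2 for posterior combination).
#'
#' @param seed Integer seed.
#' @param dt Frame spacing (s).
#' @param n_frames Frames per cell.
#' @param drop_first Leading frames to discard in the Bayesian workflow.
#' @param estimator An [estimator_config()].
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @param sigma_K Kernel sd (log scale) for posterior combination.
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, dt = 10, n_frames = 45, drop_first = 5,
                       estimator = estimator_config(),
                       priors = prior_spec(), mcmc = mcmc_config(),
                       sigma_K = 0.1) {
  stopifnot(dt > 0, n_frames >= 2, drop_first >= 0,
            drop_first < n_frames, sigma_K > 0)
  structure(
    list(seed = as.integer(seed), dt = dt, n_frames = n_frames,
         drop_first = drop_first, estimator = estimator, priors = priors,
         mcmc = mcmc, sigma_K = sigma_K),
    class = "run_config"
  )
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file of overrides and merges it onto [run_config()]
#' defaults. Unknown top-level keys are rejected, and every numeric field
#' passes the same bound checks as the defaults.
#'
#' @param path YAML file path.
#'
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("seed", "dt", "n_frames", "drop_first", "estimator",
             "priors", "mcmc", "sigma_K")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  defaults <- run_config()
  merged <- utils::modifyList(unclass(defaults), raw)
  run_config(seed = merged$seed, dt = merged$dt,
             n_frames = merged$n_frames, drop_first = merged$drop_first,
             estimator = merged$estimator, priors = merged$priors,
             mcmc = merged$mcmc, sigma_K = merged$sigma_K)
}

config_hash <- function(config) {
  # stable content hash without extra dependencies
  s <- paste(utils::capture.output(utils::str(config, digits.d = 12)),
             collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 977)))
}

#' Write a results object to JSON with provenance
#'
#' Serializes results together with the configuration hash and seed, so a
#' run can be matched to the exact settings that produced it.
#'
#' @param results Serializable list.
#' @param path Output path (`.json`).
#' @param config A `run_config` (optional).
#'
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, config = NULL) {
  payload <- list(results = results)
  if (!is.null(config)) {
    payload$provenance <- list(config_hash = config_hash(config),
                               seed = config$seed)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `estimate`, `infer`, `numbers`
#' and `combine` over the package's functions; a thin launcher script is
#' installed at `system.file("cli", "bleachcount.R", package =
#' "bleachcount")`. Returns (rather than calls `quit()` with) the exit
#' status so it is testable in-process.
#'
#' @param argv Character vector of arguments, e.g.
#'   `c("simulate", "--cells", "5", "--seed", "1", "--out", "x.csv")`.
#'
#' @return Integer exit status (0 on success, 2 on usage error).
#' @export
cli_main <- function(argv = character()) {
  usage <- paste(
    "usage: bleachcount <command> [options]",
    "commands:",
    "  simulate --cells N --seed S --out traces.csv [--frames 45] [--dt 10]",
    "  estimate --traces traces.csv [--wildtype wt.csv] --out est.json [--seed S]",
    "           [--config cfg.yaml]",
    "  infer    --traces traces.csv --out samples.csv [--seed S] [--iterations N]",
    "           [--chains N] [--drop-first K] [--config cfg.yaml]",
    "  numbers  --samples samples.csv (--y V | --ybar V [--ncells N]) --out post.json",
    "  combine  --samples a.csv,b.csv,... --out combined.csv [--seed S]",
    sep = "\n")
  if (length(argv) < 1) {
    message(usage)
    return(2L)
  }
  cmd <- argv[1]
  opts <- parse_cli_opts(argv[-1])
  if (is.null(opts)) {
    message(usage)
    return(2L)
  }
  get_opt <- function(name, default = NULL, numeric = FALSE) {
    if (!name %in% names(opts)) return(default)
    v <- opts[[name]]
    if (numeric) as.numeric(v) else v
  }
  tryCatch({
    switch(cmd,
      simulate = {
        n <- get_opt("cells", numeric = TRUE)
        seed <- get_opt("seed", 1, numeric = TRUE)
        out <- get_opt("out")
        frames <- get_opt("frames", 45, numeric = TRUE)
        dt <- get_opt("dt", 10, numeric = TRUE)
        if (is.null(n) || is.null(out)) stop("simulate needs --cells/--out")
        sim <- simulate_cohort(n, times = seq(0, by = dt,
                                              length.out = frames),
                               seed = seed)
        truth <- list(
          noise = unclass(sim$noise),
          cells = stats::setNames(lapply(sim$cells, unclass),
                                  unique(sim$traces$cell_id)))
        write_traces(sim$traces, out, truth = truth)
        message("wrote ", nrow(sim$traces), " rows to ", out)
        0L
      },
      estimate = {
        tr <- read_traces(get_opt("traces"))
        wt <- get_opt("wildtype")
        wildtype <- if (!is.null(wt)) read_traces(wt) else NULL
        cfg_path <- get_opt("config")
        cfg <- if (!is.null(cfg_path)) load_config(cfg_path) else
          run_config()
        res <- estimate_numbers(tr, wildtype = wildtype,
                                config = cfg$estimator,
                                seed = get_opt("seed", cfg$seed,
                                               numeric = TRUE))
        out <- get_opt("out")
        if (is.null(out)) stop("estimate needs --out")
        write_results(list(
          mode = res$pooled$mode,
          n_estimates = res$pooled$n_total,
          n_positive = res$pooled$n_positive,
          cells = res$cells,
          kde = res$pooled$kde), out)
        message(sprintf("mode = %.4g molecules from %d estimates",
                        res$pooled$mode, res$pooled$n_total))
        0L
      },
      infer = {
        tr <- read_traces(get_opt("traces"))
        cfg_path <- get_opt("config")
        base <- if (!is.null(cfg_path)) load_config(cfg_path)$mcmc else
          mcmc_config()
        mcfg <- utils::modifyList(base, list(
          n_chains = get_opt("chains", base$n_chains, numeric = TRUE),
          iterations = get_opt("iterations", base$iterations,
                               numeric = TRUE),
          drop_first = get_opt("drop-first", base$drop_first,
                               numeric = TRUE)))
        post <- run_inference(tr, config = mcfg,
                              seed = get_opt("seed", 1, numeric = TRUE))
        out <- get_opt("out")
        if (is.null(out)) stop("infer needs --out")
        utils::write.csv(post$samples, out, row.names = FALSE)
        message("wrote ", nrow(post$samples), " posterior draws to ", out)
        0L
      },
      numbers = {
        samples <- utils::read.csv(get_opt("samples"))
        out <- get_opt("out")
        if (is.null(out)) stop("numbers needs --out")
        y <- get_opt("y", numeric = TRUE)
        ybar <- get_opt("ybar", numeric = TRUE)
        post <- if (!is.null(y)) {
          number_posterior_single(y, samples)
        } else if (!is.null(ybar)) {
          population_mean_posterior(ybar,
                                    N = get_opt("ncells", 1,
                                                numeric = TRUE),
                                    samples = samples)
        } else stop("numbers needs --y or --ybar")
        write_results(list(grid = post$grid, density = post$density,
                           mode = post$mode, ci95 = post$ci95), out)
        message(sprintf("posterior mode = %.4g molecules", post$mode))
        0L
      },
      combine = {
        paths <- strsplit(get_opt("samples"), ",")[[1]]
        sets <- lapply(paths, utils::read.csv)
        out <- get_opt("out")
        if (is.null(out)) stop("combine needs --out")
        combined <- combine_replicates(
          sets, seed = get_opt("seed", 1, numeric = TRUE))
        utils::write.csv(combined, out, row.names = FALSE)
        message("wrote ", nrow(combined), " combined draws to ", out)
        0L
      },
      {
        message(usage)
        2L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) return(NULL)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1], "--")) return(NULL)
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  opts
}
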