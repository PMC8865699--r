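#' Validate an experiment configuration
#'
#' Configurations are plain YAML with unit-suffixed keys and explicit
#' integer seeds (no silent entropy). Unknown keys are rejected with their
#' full path; all violations are reported at once.
#'
#' @param config a named list as returned by [yaml::read_yaml()]
#' @return the config, invisibly; errors list every violation
#' @export
validate_config <- function(config) {
  schema <- list(
    experiment = NULL,
    network = c("n_e", "n_i", "scaled_preset", "seed", "tau_m_ms",
                "v_th_mv", "v_r_mv", "t_ref_ms", "delay_ms", "j_mv", "g",
                "nu_ext_hz"),
    plasticity = c("tau_ca_s", "beta_a", "beta_d", "nu_target_hz",
                   "delta_t_s_ms", "enabled"),
    protocol = c("t_growth_s", "cycles", "stim_s", "relax_s", "mult",
                 "ensemble_fraction", "ensemble_seed", "record_every_s",
                 "decay_s", "eta", "record_spikes_s"),
    sim = c("dt_ms", "dt_ode_ms", "record_every_s"),
    seeds = c("construction", "drive", "rewiring", "analysis"),
    output_dir = NULL)
  problems <- character()
  for (key in names(config)) {
    if (!key %in% names(schema)) {
      problems <- c(problems, sprintf("unknown key: %s", key))
      next
    }
    allowed <- schema[[key]]
    if (!is.null(allowed) && is.list(config[[key]])) {
      bad <- setdiff(names(config[[key]]), allowed)
      problems <- c(problems,
                    sprintf("unknown key: %s.%s", key, bad))
    }
  }
  if (!"experiment" %in% names(config))
    problems <- c(problems, "missing key: experiment")
  else if (!config$experiment %in%
           c("grow", "repeated_stimulation", "conditioning",
             "meanfield_repeated_stimulation", "meanfield_formation_decay"))
    problems <- c(problems,
                  sprintf("unknown experiment type: %s", config$experiment))
  if (!is.null(config$seeds)) {
    nonint <- names(config$seeds)[!vapply(config$seeds, function(s)
      is.numeric(s) && s == round(s), logical(1))]
    problems <- c(problems,
                  sprintf("seeds.%s must be an explicit integer", nonint))
  }
  if (length(problems) > 0)
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  invisible(config)
}

#' Run an experiment from a configuration file
#'
#' Reads and validates a YAML configuration, dispatches to the matching
#' protocol, and writes a deterministic artifact set into the output
#' directory: block-connectivity means (\code{block_means.tsv}), population
#' rates (\code{rates.tsv}), calcium means (\code{calcium.tsv}), the final
#' EE connectivity (\code{ee_connectivity.tsv}), spikes when recorded
#' (\code{spikes.tsv}), and a run manifest (\code{manifest.json}) carrying
#' the configuration hash, package version and seeds.
#'
#' @param config_path path to a YAML configuration
#' @param output_dir overrides the configured output directory
#' @return invisibly, the list of written files
#' @export
run_experiment <- function(config_path, output_dir = NULL) {
  config <- yaml::read_yaml(config_path)
  validate_config(config)
  out_dir <- output_dir %||% config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- lapply(config$seeds %||%
                    list(construction = 1, drive = 2, rewiring = 3,
                         analysis = 4), as.integer)
  lif_args <- config$network[intersect(names(config$network),
                                       names(formals(lif_params)))]
  params <- do.call(lif_params, lif_args %||% list())
  pro <- config$protocol %||% list()
  dt_ms <- (config$sim %||% list())$dt_ms %||% 0.1
  files <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
    files <<- c(files, path)
  }
  if (config$experiment %in% c("meanfield_repeated_stimulation",
                               "meanfield_formation_decay")) {
    model <- meanfield_model(params = params,
                             nu_target_hz = config$plasticity$nu_target_hz
                               %||% 8,
                             beta_a = config$plasticity$beta_a %||% 2,
                             beta_d = config$plasticity$beta_d %||% 2,
                             tau_ca_s = config$plasticity$tau_ca_s %||% 10,
                             eta = pro$eta %||% 0.7)
    ep <- if (config$experiment == "meanfield_repeated_stimulation") {
      cycles <- pro$cycles %||% 8
      data.frame(duration_s = rep(c(pro$stim_s %||% 150,
                                    pro$relax_s %||% 150), cycles),
                 mult_e1 = rep(c(pro$mult %||% 1.05, 1), cycles),
                 mult_e2 = 1)
    } else {
      data.frame(duration_s = c(pro$stim_s %||% 150, pro$relax_s %||% 5500),
                 mult_e1 = c(pro$mult %||% 1.1, 1), mult_e2 = 1)
    }
    tr <- integrate_model(model, ep,
                          record_every_s = pro$record_every_s %||% 5)
    emit(tr, "trajectory.tsv")
  } else {
    net_args <- config$network %||% list()
    plast <- do.call(plasticity_params,
                     config$plasticity %||% list())
    maker <- if (isTRUE(net_args$scaled_preset)) scaled_network
             else new_network
    net <- maker(net_args$n_e %||% 1000, net_args$n_i %||% 250,
                 params = params, plasticity = plast,
                 seed = seeds$construction)
    run_seeds <- list(drive = seeds$drive, rewire = seeds$rewiring)
    out <- switch(
      config$experiment,
      grow = grow_network(net, pro$t_growth_s %||% 500, dt_ms = dt_ms,
                          seeds = run_seeds,
                          record = list(conn_every_s =
                                          pro$record_every_s %||% 10)),
      repeated_stimulation = {
        g <- grow_network(net, pro$t_growth_s %||% 500, dt_ms = dt_ms,
                          seeds = run_seeds)
        repeated_stimulation(
          g$net, ensemble = pro$ensemble_fraction %||% 0.1,
          cycles = pro$cycles %||% 8, stim_s = pro$stim_s %||% 150,
          relax_s = pro$relax_s %||% 150, mult = pro$mult %||% 1.05,
          record_every_s = pro$record_every_s %||% 15, dt_ms = dt_ms,
          seeds = run_seeds,
          ensemble_seed = pro$ensemble_seed %||% seeds$analysis)
      },
      conditioning = conditioning_experiment(
        net, t_growth_s = pro$t_growth_s %||% 100, dt_ms = dt_ms,
        seeds = run_seeds,
        ensemble_seed = pro$ensemble_seed %||% seeds$analysis))
    emit(out$conn_series, "block_means.tsv")
    emit(out$rates, "rates.tsv")
    emit(out$calcium_series, "calcium.tsv")
    ee <- out$net$conn$ee
    emit(as.data.frame(ee), "ee_connectivity.tsv")
    if (nrow(out$spikes) > 0) emit(out$spikes, "spikes.tsv")
    if (!is.null(out$readout_rates_hz))
      emit(data.frame(episode = names(out$readout_rates_hz),
                      rate_hz = as.numeric(out$readout_rates_hz)),
           "readout_rates.tsv")
  }
  manifest <- list(package = "engramnet",
                   version = as.character(utils::packageVersion("engramnet")),
                   experiment = config$experiment,
                   config_md5 = unname(tools::md5sum(config_path)),
                   seeds = seeds, dt_ms = dt_ms, files = basename(files))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(files, manifest_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analysis dispatcher for stored artifacts
#'
#' Runs one of the analysis operations on files or in-memory data and
#' returns a data frame (optionally also written as columnar text with a
#' provenance header).
#'
#' @param what one of \code{"overlap"}, \code{"decay-fit"},
#'   \code{"stability"}, \code{"meanfield"}, \code{"line-attractor"}
#' @param ... arguments of the dispatched operation: \code{overlap} needs
#'   \code{spikes} (file or data frame), \code{pattern} (index vector) and
#'   \code{n}; \code{decay-fit} needs \code{series} (file or data frame
#'   with \code{time_s}, \code{value}); \code{stability} and
#'   \code{meanfield} accept a \code{model}; \code{line-attractor} needs
#'   \code{x} values
#' @param out optional output file path
#' @return the result data frame
#' @export
analyze <- function(what = c("overlap", "decay-fit", "stability",
                             "meanfield", "line-attractor"), ..., out = NULL) {
  what <- match.arg(what)
  args <- list(...)
  get_table <- function(x) {
    if (is.character(x)) {
      if (!file.exists(x)) stop("input file does not exist: ", x)
      read.table(x, header = TRUE, sep = "\t")
    } else x
  }
  res <- switch(
    what,
    "overlap" = {
      spikes <- get_table(args$spikes)
      pat <- make_pattern(args$pattern, args$n)
      overlap(pat, spikes, bin_ms = args$bin_ms %||% 10)
    },
    "decay-fit" = {
      ser <- get_table(args$series)
      fit <- decay_time_constant(ser$time_s, ser$value)
      data.frame(tau_s = fit$tau_s, c_inf = fit$c_inf,
                 amplitude = fit$amplitude)
    },
    "stability" = {
      model <- args$model %||% meanfield_model()
      op <- operating_point(model)
      data.frame(
        quantity = c("k_star", "c_bar", "nu_i_hz", "j_ee", "tau_diffusion_s",
                     "c_crit", "turnover_per_day"),
        value = c(op$k, op$c, op$nu_i, op$j_ee,
                  slow_mode_timescale(model$tau_ca_s, model$nu_target_hz,
                                      model$eta, model$n_e1 + model$n_e2,
                                      op$c, model$beta_a, model$beta_d),
                  critical_connectivity(model, op),
                  turnover_ratio(model$tau_ca_s, model$nu_target_hz,
                                 model$eta, model$n_e1 + model$n_e2, op$c,
                                 model$beta_a, model$beta_d)))
    },
    "meanfield" = {
      model <- args$model %||% meanfield_model()
      ep <- args$episodes %||% data.frame(duration_s = 100, mult_e1 = 1,
                                          mult_e2 = 1)
      integrate_model(model, ep)
    },
    "line-attractor" = {
      model <- args$model %||% meanfield_model()
      k_star <- equilibrium_indegree(model$nu_target_hz, model)$k
      do.call(rbind, lapply(args$x, function(xx) {
        y <- line_attractor_point(xx, model, k_star)
        data.frame(x = xx, t(y))
      }))
    })
  if (!is.null(out)) {
    con <- file(out, "w")
    writeLines(sprintf("# engramnet %s :: analyze %s",
                       utils::packageVersion("engramnet"), what), con)
    write.table(res, con, quote = FALSE, row.names = FALSE, sep = "\t")
    close(con)
  }
  res
}
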