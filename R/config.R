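#' Default run configuration
#'
#' Nested configuration with sections mirroring the package's modules. The
#' plasticity defaults are the phenomenological constants of the learning
#' rule (eta = 1.5 s, gamma = 10 mV, sigma^2 = 0.036 mV^2/ms, tau_ubar =
#' 30 s) and the synapse defaults are the published AMPA/NMDA conductance
#' time courses; units are embedded in the key names to prevent unit bugs.
#'
#' @return Nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    neuron = list(
      n_compartments = 60L, total_length_um = 800, diam_um = 2,
      axial_resistivity_ohm_cm = 110, membrane_resistance_ohm_cm2 = 30000,
      membrane_capacitance_uf_cm2 = 1, resting_potential_mv = -70,
      dt_ms = 0.1, soma_diameter_um = 20,
      ap_threshold_mv = -60, ap_amplitude_mv = 85, ap_rise_ms = 0.3,
      ap_decay_ms = 3.5, ap_gmax_ns = 3000,
      threshold_adapt_inc_mv = 1, threshold_adapt_tau_ms = 300,
      injection_amplitude_pa = 2000, injection_duration_ms = 3,
      refractory_ms = 18
    ),
    synapse = list(
      ampa = list(tau_r_ms = 0.55, tau_d1_ms = 2.0, tau_d2_ms = 8.0,
                  lambda = 0.8, n_norm = 2.00),
      nmda = list(tau_r_ms = 4.05, tau_d1_ms = 27.6, tau_d2_ms = 147.4,
                  lambda = 0.5, n_norm = 1.36),
      mg = list(mg_out_mm = 1, alpha_per_mv = 0.062, beta_mm = 3.57),
      e_rev_mv = 0,
      w_ampa_ps = 200, w_nmda_ps = 500, distance_um = 200,
      spine = list(neck_length_um = 1, neck_diam_um = 0.1,
                   head_length_um = 0.6, head_diam_um = 0.3)
    ),
    plasticity = list(
      eta_s = 1.5, gamma_mv = 10, sigma2_mv2_ms = 0.036, tau_ubar_s = 30,
      measure = "skewness", mode = "multiplicative", c_eff_pf = 1.5
    ),
    protocol = list(
      delay_ms = 10, n_pairs = 7L, rep_frequency_hz = 1,
      frequencies_hz = c(0.1, 5, 10, 20, 30, 40, 50),
      pre_rate_hz = 10, post_rate_hz = 10, duration_s = 30,
      priming = FALSE, command_mv = -40, n_stim = 100L, stim_rate_hz = 2,
      n_syn = 100L, population_pre_rate_hz = 3, w0_mv = 0.16,
      population_duration_s = 300, n_trials = 10L
    ),
    seed = 1L,
    output_dir = "."
  ), class = "run_config")
}

# internal: recursive merge with unknown-key rejection
merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    here <- if (nzchar(path)) paste0(path, "$", key) else key
    if (!key %in% names(base)) {
      stop("unknown configuration key: ", here, call. = FALSE)
    }
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]])) {
        stop("configuration section ", here, " must be a mapping",
             call. = FALSE)
      }
      base[[key]] <- merge_config(base[[key]], user[[key]], here)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

# internal: value checks on a merged config
validate_config <- function(cfg) {
  pos <- function(x, name) {
    if (!is.numeric(x) || any(x <= 0)) {
      stop("configuration value must be positive: ", name, call. = FALSE)
    }
  }
  n <- cfg$neuron
  pos(n$dt_ms, "neuron$dt_ms")
  pos(n$total_length_um, "neuron$total_length_um")
  for (r in c("ampa", "nmda")) {
    k <- cfg$synapse[[r]]
    pos(unlist(k[c("tau_r_ms", "tau_d1_ms", "tau_d2_ms")]),
        paste0("synapse$", r, " time constants"))
  }
  p <- cfg$plasticity
  pos(c(p$eta_s, p$gamma_mv, p$tau_ubar_s, p$c_eff_pf),
      "plasticity constants")
  if (p$sigma2_mv2_ms < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (!p$measure %in% c("skewness", "kurtosis")) {
    stop("plasticity$measure must be skewness or kurtosis", call. = FALSE)
  }
  if (!p$mode %in% c("multiplicative", "additive")) {
    stop("plasticity$mode must be multiplicative or additive", call. = FALSE)
  }
  invisible(cfg)
}

#' Load a run configuration
#'
#' Reads a YAML configuration, fills unset keys with [default_config()]
#' values, rejects unknown keys and validates values. An empty file yields
#' the full default configuration.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @seealso [write_config()] for the lossless inverse.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(unclass(default_config()), user)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

#' Write a run configuration to YAML
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# internal: convert config sections to the constructor objects
config_objects <- function(cfg) {
  n <- cfg$neuron
  cable <- cable_config(
    n_compartments = n$n_compartments, total_length = n$total_length_um,
    diam = n$diam_um, axial_resistivity = n$axial_resistivity_ohm_cm,
    membrane_resistance = n$membrane_resistance_ohm_cm2,
    membrane_capacitance = n$membrane_capacitance_uf_cm2,
    resting_potential = n$resting_potential_mv, dt = n$dt_ms,
    soma_diameter = n$soma_diameter_um
  )
  soma <- soma_spec(
    ap_threshold = n$ap_threshold_mv, amplitude = n$ap_amplitude_mv,
    rise = n$ap_rise_ms, decay = n$ap_decay_ms, ap_gmax = n$ap_gmax_ns,
    threshold_adapt_inc = n$threshold_adapt_inc_mv,
    threshold_adapt_tau = n$threshold_adapt_tau_ms,
    injection_amplitude = n$injection_amplitude_pa,
    injection_duration = n$injection_duration_ms,
    refractory = n$refractory_ms
  )
  p <- cfg$plasticity
  plast <- plasticity_config(
    params = gradient_params(sigma2 = p$sigma2_mv2_ms, gamma = p$gamma_mv,
                             eta = p$eta_s, measure = p$measure),
    tau_ubar = p$tau_ubar_s, mode = p$mode, c_eff = p$c_eff_pf
  )
  list(cable = cable, soma = soma, plast = plast)
}

#' Run a protocol from a configuration
#'
#' Command-style front end over the protocol runners: executes one of
#' `stdp`, `freq-sweep`, `rate`, `vclamp` or `population` with parameters
#' taken from the configuration, and writes a results CSV plus a JSON run
#' manifest (configuration hash, seed, package version) to the output
#' directory. All randomness derives from the single seed in the
#' configuration, so a manifest suffices to reproduce a run byte for byte.
#'
#' @param subcommand One of `"stdp"`, `"freq-sweep"`, `"rate"`, `"vclamp"`,
#'   `"population"`.
#' @param config A `run_config`, a path to a YAML file, or `NULL` for
#'   defaults.
#' @param seed Optional integer overriding the configuration seed.
#' @param output_dir Optional output directory override.
#' @return (Invisibly) a list with the result data frame and the paths
#'   written.
#' @export
run_command <- function(subcommand, config = NULL, seed = NULL,
                        output_dir = NULL) {
  subcommands <- c("stdp", "freq-sweep", "rate", "vclamp", "population")
  if (!subcommand %in% subcommands) {
    stop("unknown subcommand '", subcommand, "'; expected one of: ",
         paste(subcommands, collapse = ", "), call. = FALSE)
  }
  cfg <- if (is.null(config)) {
    default_config()
  } else if (is.character(config)) {
    load_config(config)
  } else {
    validate_config(config)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  obj <- config_objects(cfg)
  pr <- cfg$protocol
  syn <- cfg$synapse

  df <- switch(subcommand,
    "stdp" = {
      r <- run_stdp_pairing(delay = pr$delay_ms, n_pairs = pr$n_pairs,
                            rep_frequency = pr$rep_frequency_hz,
                            distance = syn$distance_um,
                            w_ampa = syn$w_ampa_ps, w_nmda = syn$w_nmda_ps,
                            priming = isTRUE(pr$priming),
                            cable = obj$cable, soma = obj$soma,
                            plast = obj$plast)
      data.frame(delay = pr$delay_ms, n_pairs = pr$n_pairs,
                 rep_frequency = pr$rep_frequency_hz,
                 distance = syn$distance_um,
                 epsp_before = r$epsp_before, epsp_after = r$epsp_after,
                 relative_change = r$relative_change)
    },
    "freq-sweep" = {
      r <- run_frequency_sweep(delays = c(pr$delay_ms, -pr$delay_ms),
                               frequencies = pr$frequencies_hz,
                               n_pairs = 100, distance = 150, w_ampa = 0,
                               w_nmda = syn$w_nmda_ps, cable = obj$cable,
                               soma = obj$soma, plast = obj$plast)
      r
    },
    "rate" = {
      r <- run_rate_protocol(post_rate = pr$post_rate_hz,
                             pre_rate = pr$pre_rate_hz,
                             duration = pr$duration_s,
                             priming = isTRUE(pr$priming),
                             distance = syn$distance_um,
                             w_ampa = syn$w_ampa_ps, w_nmda = syn$w_nmda_ps,
                             cable = obj$cable, soma = obj$soma,
                             plast = obj$plast, seed = cfg$seed)
      data.frame(pre_rate = pr$pre_rate_hz, post_rate = pr$post_rate_hz,
                 priming = isTRUE(pr$priming),
                 epsp_before = r$epsp_before, epsp_after = r$epsp_after,
                 relative_change = r$relative_change)
    },
    "vclamp" = {
      r <- run_voltage_clamp(command = pr$command_mv, n_stim = pr$n_stim,
                             stim_rate = pr$stim_rate_hz, distance = 700,
                             w_ampa = 0, w_nmda = syn$w_nmda_ps,
                             cable = obj$cable, soma = obj$soma,
                             plast = obj$plast)
      data.frame(command = pr$command_mv, n_stim = pr$n_stim,
                 epsp_before = r$epsp_before, epsp_after = r$epsp_after,
                 relative_change = r$relative_change)
    },
    "population" = {
      pop <- run_population(n_syn = pr$n_syn,
                            distance = syn$distance_um,
                            pre_rate = pr$population_pre_rate_hz,
                            w0 = pr$w0_mv,
                            duration = pr$population_duration_s,
                            mode = cfg$plasticity$mode,
                            n_trials = pr$n_trials, seed = cfg$seed,
                            cable = obj$cable, soma = obj$soma,
                            plast = obj$plast)
      do.call(rbind, lapply(seq_along(pop$trials), function(tr) {
        data.frame(
          trial = tr,
          checkpoint_s = pop$checkpoints,
          skewness = vapply(pop$checkpoints, function(ck) {
            population_skewness(population_strengths(pop, ck)[[tr]])
          }, numeric(1)),
          n_excluded = vapply(pop$checkpoints, function(ck) {
            sum(population_strengths(pop, ck)[[tr]] > 10)
          }, numeric(1))
        )
      }))
    }
  )

  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(cfg$output_dir, paste0(subcommand, "_results.csv"))
  manifest_path <- file.path(cfg$output_dir,
                             paste0(subcommand, "_manifest.json"))
  ok <- FALSE
  on.exit(if (!ok) unlink(c(csv_path, manifest_path)), add = TRUE)
  utils::write.csv(df, csv_path, row.names = FALSE)
  cfg_tmp <- tempfile(fileext = ".yml")
  write_config(cfg, cfg_tmp)
  manifest <- list(
    subcommand = subcommand,
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_tmp)),
    package_version = as.character(utils::packageVersion("sparsehebb"))
  )
  unlink(cfg_tmp)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  ok <- TRUE
  invisible(list(results = df, csv = csv_path, manifest = manifest_path))
}
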