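#' @name config
#' @title Model configuration files
#' @description
#' A `cell_model` round-trips through a YAML document whose keys embed their
#' units (`*_mV`, `*_ms`, `*_S_cm2`, `*_mM`, `*_um`, ...). Unknown keys are
#' rejected, numeric sanity checks (positivity, non-zero slopes) are applied
#' on load, and every channel block may carry a `provenance` tag
#' (`paper` | `calibrated` | `default`) recording where its conductance came
#' from. JSON documents with the same structure are accepted.
NULL

config_known_top <- c("geometry", "passive", "calcium", "channels",
                      "provenance")

gate_to_cfg <- function(g) {
  if (is.null(g)) return(NULL)
  out <- list(kind = g$kind)
  if (g$kind == "boltzmann") {
    out$v_half_mV <- g$v_half
    out$slope_mV <- g$slope
  } else {
    out$ca_half_mM <- g$ca_half
    out$hill_n <- g$hill_n
  }
  if (is.numeric(g$tau)) out$tau_ms <- g$tau
  else out$tau_table <- list(v_mV = g$tau$v, tau_ms = g$tau$tau)
  out$power <- g$power
  out
}

cfg_to_gate <- function(cfg, where) {
  if (is.null(cfg)) return(NULL)
  known <- c("kind", "v_half_mV", "slope_mV", "ca_half_mM", "hill_n",
             "tau_ms", "tau_table", "power")
  check_keys(cfg, known, where)
  tau <- if (!is.null(cfg$tau_table)) {
    list(v = as.numeric(cfg$tau_table$v_mV),
         tau = as.numeric(cfg$tau_table$tau_ms))
  } else {
    cfg$tau_ms %||% 1
  }
  gate_params(kind = cfg$kind, v_half = cfg$v_half_mV, slope = cfg$slope_mV,
              tau = tau, power = cfg$power %||% 1,
              ca_half = cfg$ca_half_mM, hill_n = cfg$hill_n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_keys <- function(x, known, where) {
  extra <- setdiff(names(x), known)
  if (length(extra) > 0L) {
    stop(sprintf("unknown key(s) in %s: %s (expected one of: %s)",
                 where, paste(extra, collapse = ", "),
                 paste(known, collapse = ", ")))
  }
}

#' Serialize a model to a configuration list / YAML file
#'
#' @param model A `cell_model`.
#' @param provenance Optional named character vector of provenance tags
#'   keyed by channel name (including `bk`, `trpm4`).
#' @return A nested list mirroring the YAML schema.
#' @export
model_to_config <- function(model, provenance = NULL) {
  stopifnot(inherits(model, "cell_model"))
  ch_cfg <- lapply(model$channels, function(ch) {
    out <- list(gmax_S_cm2 = ch$gmax, e_rev_mV = ch$e_rev)
    if (ch$carries_ca) out$carries_ca <- TRUE
    a <- gate_to_cfg(ch$activation)
    if (!is.null(a)) out$activation <- a
    h <- gate_to_cfg(ch$inactivation)
    if (!is.null(h)) out$inactivation <- h
    out
  })
  bk <- model$bk
  ch_cfg$bk <- list(gmax_S_cm2 = bk$gmax, e_k_mV = bk$e_k,
                    k_on = bk$k_on, k_coff = bk$k_coff, k_ooff = bk$k_ooff,
                    co_rates = bk$co_rates, oc_rates = bk$oc_rates,
                    a_efold_mV = bk$a_efold, b_efold_mV = bk$b_efold,
                    conducting_states = bk_state_names[6:10][bk$conducting],
                    ca_unbinding = bk$ca_unbinding)
  trp <- model$trpm4
  ch_cfg$trpm4 <- list(gmax_S_cm2 = trp$gmax, e_rev_mV = trp$e_rev,
                       ca_half_mM = trp$ca_half, hill_n = trp$hill_n,
                       tau_m_ms = trp$tau_m, power = trp$power)
  if (!is.null(trp$inactivation)) {
    ch_cfg$trpm4$inactivation <- gate_to_cfg(trp$inactivation)
  }
  if (!is.null(provenance)) {
    for (nm in names(provenance)) {
      ch_cfg[[nm]]$provenance <- unname(provenance[[nm]])
    }
  }
  list(
    geometry = list(length_um = model$geometry$length_um,
                    diameter_um = model$geometry$diameter_um),
    passive = list(c_specific_uF_cm2 = model$passive$c_specific_uF_cm2,
                   r_membrane_kohm_cm2 = model$passive$r_membrane_kohm_cm2,
                   r_cytoplasm_ohm_cm = model$passive$r_cytoplasm_ohm_cm),
    calcium = list(ca_rest_mM = model$calcium$ca_rest,
                   tau_removal_ms = model$calcium$tau_removal,
                   depth_um = model$calcium$depth_um,
                   clamp = model$calcium$clamp),
    channels = ch_cfg
  )
}

#' @rdname model_to_config
#' @param path Output file path (`.yaml`/`.yml` or `.json`).
#' @export
write_model_config <- function(model, path, provenance = NULL) {
  cfg <- model_to_config(model, provenance)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path, precision = 15)
  }
  invisible(path)
}

#' Load a model configuration
#'
#' Reads a YAML (or JSON) configuration, validates it against the schema
#' (unknown keys rejected, positivity checks via the constructors) and
#' builds the `cell_model`.
#'
#' @param path Path to a configuration file.
#' @return A `cell_model` with attribute `"provenance"`.
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  config_to_model(cfg)
}

#' @rdname load_model_config
#' @param cfg A configuration list (as from [model_to_config()]).
#' @export
config_to_model <- function(cfg) {
  check_keys(cfg, config_known_top, "config")
  check_keys(cfg$geometry, c("length_um", "diameter_um"), "geometry")
  check_keys(cfg$passive, c("c_specific_uF_cm2", "r_membrane_kohm_cm2",
                            "r_cytoplasm_ohm_cm"), "passive")
  check_keys(cfg$calcium, c("ca_rest_mM", "tau_removal_ms", "depth_um",
                            "clamp"), "calcium")
  geom <- cell_geometry(cfg$geometry$length_um, cfg$geometry$diameter_um)
  pas <- passive_properties(cfg$passive$c_specific_uF_cm2,
                            cfg$passive$r_membrane_kohm_cm2,
                            cfg$passive$r_cytoplasm_ohm_cm)
  calcium <- ca_pool_params(cfg$calcium$ca_rest_mM, cfg$calcium$tau_removal_ms,
                            cfg$calcium$depth_um, isTRUE(cfg$calcium$clamp))
  chans <- cfg$channels
  if (is.null(chans$bk) || is.null(chans$trpm4)) {
    stop("config must define channels: bk and trpm4")
  }
  prov <- character(0)
  bkc <- chans$bk
  check_keys(bkc, c("gmax_S_cm2", "e_k_mV", "k_on", "k_coff", "k_ooff",
                    "co_rates", "oc_rates", "a_efold_mV", "b_efold_mV",
                    "conducting_states", "ca_unbinding", "provenance"),
             "channels$bk")
  conducting <- bk_state_names[6:10] %in%
    (bkc$conducting_states %||% bk_state_names[7:10])
  bk <- bk_params(gmax = bkc$gmax_S_cm2, e_k = bkc$e_k_mV %||% -75,
                  k_on = bkc$k_on %||% 335, k_coff = bkc$k_coff %||% 26,
                  k_ooff = bkc$k_ooff %||% 26,
                  co_rates = unlist(bkc$co_rates %||%
                                      bk_params()$co_rates),
                  oc_rates = unlist(bkc$oc_rates %||%
                                      bk_params()$oc_rates),
                  a_efold = bkc$a_efold_mV %||% 25,
                  b_efold = bkc$b_efold_mV %||% 25,
                  conducting = conducting,
                  ca_unbinding = bkc$ca_unbinding %||% "printed")
  if (!is.null(bkc$provenance)) prov["bk"] <- bkc$provenance
  tc <- chans$trpm4
  check_keys(tc, c("gmax_S_cm2", "e_rev_mV", "ca_half_mM", "hill_n",
                   "tau_m_ms", "power", "inactivation", "provenance"),
             "channels$trpm4")
  trp <- trpm4_params(gmax = tc$gmax_S_cm2, e_rev = tc$e_rev_mV %||% -40,
                      ca_half = tc$ca_half_mM, hill_n = tc$hill_n,
                      tau_m = tc$tau_m_ms %||% 10, power = tc$power %||% 1,
                      inactivation = cfg_to_gate(tc$inactivation,
                                                 "channels$trpm4$inactivation"))
  if (!is.null(tc$provenance)) prov["trpm4"] <- tc$provenance
  hh_names <- setdiff(names(chans), c("bk", "trpm4"))
  hh <- lapply(hh_names, function(nm) {
    cc <- chans[[nm]]
    check_keys(cc, c("gmax_S_cm2", "e_rev_mV", "carries_ca", "activation",
                     "inactivation", "provenance"),
               sprintf("channels$%s", nm))
    if (!is.null(cc$provenance)) prov[nm] <<- cc$provenance
    hh_channel(nm, gmax = cc$gmax_S_cm2, e_rev = cc$e_rev_mV,
               activation = cfg_to_gate(cc$activation,
                                        sprintf("channels$%s$activation", nm)),
               inactivation = cfg_to_gate(cc$inactivation,
                                          sprintf("channels$%s$inactivation",
                                                  nm)),
               carries_ca = isTRUE(cc$carries_ca))
  })
  names(hh) <- hh_names
  model <- cell_model(geometry = geom, passive = pas, channels = hh,
                      bk = bk, trpm4 = trp, calcium = calcium)
  attr(model, "provenance") <- prov
  model
}

# small deterministic polynomial hash over the serialized object (hex
# string); keeps run manifests dependency-free
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

#' Write a simulation trace to CSV (plus a JSON run manifest)
#'
#' The CSV carries a fixed column order with units embedded in the header
#' (`t_ms`, `v_mV`, `cai_mM`, per-channel `i_*_uA_cm2`, `bk_open`,
#' `i_stim_nA`) at full floating precision. A `<path>.manifest.json` sidecar
#' records the step size, sample count, stimulus, package version and a hash
#' of the trace and stimulus.
#'
#' @param result A `dsm_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(result, path) {
  stopifnot(inherits(result, "dsm_trace"))
  df <- as.data.frame(result)
  nm <- names(df)
  nm[nm == "t"] <- "t_ms"
  nm[nm == "v"] <- "v_mV"
  nm[nm == "cai"] <- "cai_mM"
  nm[nm == "i_stim"] <- "i_stim_nA"
  ic <- grepl("^i_", nm) & nm != "i_stim_nA"
  nm[ic] <- paste0(nm[ic], "_uA_cm2")
  names(df) <- nm
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  stim <- attr(result, "stimulus")
  manifest <- list(
    package = "dsmcell",
    version = as.character(utils::packageVersion("dsmcell")),
    dt_ms = attr(result, "step_dt"),
    sample_dt_ms = attr(result, "dt"),
    n_samples = nrow(df),
    t_stop_ms = df$t_ms[nrow(df)],
    stimulus = if (is.null(stim)) NULL else unclass(stim),
    hash = config_hash(list(df, stim))
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path CSV path.
#' @return A data.frame with plain column names (`t`, `v`, `cai`, ...).
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- names(df)
  nm[nm == "t_ms"] <- "t"
  nm[nm == "v_mV"] <- "v"
  nm[nm == "cai_mM"] <- "cai"
  nm[nm == "i_stim_nA"] <- "i_stim"
  nm <- sub("_uA_cm2$", "", nm)
  names(df) <- nm
  class(df) <- c("dsm_trace", "data.frame")
  attr(df, "dt") <- if (nrow(df) > 1) df$t[2] - df$t[1] else NA_real_
  df
}

#' Generate the package's standard fixtures
#'
#' Writes deterministic plain-text fixtures into a directory: synthetic
#' TRPM4 activation-curve CSVs at known Hill parameters (with the generating
#' parameters recorded in comment headers), short golden voltage traces for
#' the default model under no-stimulus / pulse / alpha protocols, and a
#' hand-built triangular spike trace for feature-extraction tests.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed controlling the activation-curve noise.
#' @return Character vector of the files written.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  write_activation <- function(file, ca_half, hill_n, noise_sd, seed_i) {
    d <- simulate_activation_curve(n = 30, ca_half = ca_half, hill_n = hill_n,
                                   noise_sd = noise_sd, seed = seed_i)
    con <- file(file, "w")
    writeLines(sprintf(
      "# synthetic TRPM4 activation curve: ca_half_mM=%g hill_n=%g noise_sd=%g seed=%d",
      ca_half, hill_n, noise_sd, seed_i), con)
    writeLines("cai_mM,activation", con)
    writeLines(sprintf("%.10g,%.10g", d$cai, d$activation), con)
    close(con)
    file
  }
  files <- c(files,
             write_activation(file.path(out_dir, "activation_clean.csv"),
                              1e-3, 2, 0, seed),
             write_activation(file.path(out_dir, "activation_noisy.csv"),
                              1e-3, 2, 0.02, seed + 1L))
  model <- default_dsm_model()
  protocols <- list(rest = NULL,
                    pulse = pulse_stimulus(0.8, onset = 20, duration = 10,
                                           unit_nA = 0.1),
                    alpha = alpha_synapse(0.012, tau_alpha = 0.4124,
                                          onset = 20))
  for (nm in names(protocols)) {
    tr <- simulate_cell(model, protocols[[nm]], t_stop = 60, dt = 0.04,
                        record_every = 5L)
    f <- file.path(out_dir, sprintf("golden_%s.csv", nm))
    write_trace(tr, f)
    files <- c(files, f, paste0(f, ".manifest.json"))
  }
  tri <- toy_spike_trace()
  f <- file.path(out_dir, "toy_spike.csv")
  utils::write.csv(tri, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  files
}

# hand-built piecewise-linear spike: flat rest, slow ramp, fast rise to a
# peak, fall and recovery -- every feature known by construction
toy_spike_trace <- function(rest = -52, thr = -38, peak = 10, dt = 0.1,
                            onset = 600) {
  t_rest <- seq(0, onset, by = dt)
  ramp <- seq(rest, thr, by = 1 * dt)          # 1 mV/ms: below criterion
  rise <- seq(thr, peak, by = 20 * dt)         # 20 mV/ms: above criterion
  fall <- seq(peak, rest - 6, by = -10 * dt)
  rec <- seq(rest - 6, rest, by = 0.5 * dt)
  # drop duplicated joint samples so local maxima are unique
  v <- c(rep(rest, length(t_rest)), ramp[-1], rise[-1], fall[-1], rec[-1])
  data.frame(t = seq_along(v) * dt - dt, v = v)
}
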