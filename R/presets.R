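# Figure-scenario presets and the run engine: every preset is a plain
# run-config list that regenerates the corresponding scenario's data table
# through the scan engines; run_scenario() writes the tables plus a
# machine-readable manifest.

preset_registry <- function() {
  elementary <- function(k_fw, k_bw, kd_R, kd_P, conc_M, alpha_grid) {
    list(scenario = "elementary", k_fw = k_fw, k_bw = k_bw,
         kd_reactant = kd_R, kd_product = kd_P, conc_M = conc_M,
         alpha_grid = alpha_grid)
  }
  conc_fig4 <- c(3e-6, 1e-5, 3e-5, 1e-4, 3e-4, 1e-3, 1e-2, 1e-1, 1)
  alpha01 <- seq(0, 1, by = 0.05)
  list(
    # elementary-reaction landscapes
    fig2a = elementary(2, 2, 1e-6, 1e-6, 1e-3, 0.5),
    fig2b = elementary(2, 2, 1e-5, 1e-6, 1e-3, 0.5),
    fig2c = elementary(2, 2, 1e-6, 1e-5, 1e-3, 0.5),
    fig2d = elementary(2, 2, 1e-8, 1e-9, 1e-3, 0.5),
    fig2e = elementary(2, 2, 1e-9, 1e-8, 1e-3, 0.5),
    fig3a = elementary(2, 2, 1e-5, 1e-6, 1e-3, 0),
    fig3b = elementary(2, 2, 1e-5, 1e-6, 1e-3, 1),
    fig3c = elementary(2, 2, 1e-5, 1e-6, 1e-3, seq(-1, 2, by = 0.05)),
    fig4a = elementary(2, 2, 1e-5, 1e-6, 1e-3, 0.5),
    fig5a = elementary(100, 100, 1e-6, 1e-5, 1e-3, 1),
    # full-cycle gain scans
    fig4b = list(scenario = "positive", selectivity = 10,
                 conc_list = conc_fig4, alpha_grid = alpha01),
    fig4c = list(scenario = "positive", selectivity = 100,
                 conc_list = conc_fig4, alpha_grid = alpha01),
    fig4d = list(scenario = "positive", selectivity = 1000,
                 conc_list = conc_fig4, alpha_grid = alpha01),
    fig4e = list(scenario = "dose_response",
                 selectivities = c(10, 100, 1000),
                 conc_grid = 10^seq(-8, 0, length.out = 33), alpha = 1),
    fig4f = list(scenario = "selectivity_scan", alpha = 0.5,
                 conc_M = 1e-5,
                 selectivity_grid = 10^seq(1, 4, by = 0.25)),
    fig4g = list(scenario = "selectivity_scan", alpha = 1, conc_M = 1e-5,
                 selectivity_grid = 10^seq(1, 4, by = 0.25)),
    fig4h = list(scenario = "capped", cap = 20,
                 selectivities = c(10, 100, 1000), alpha_grid = alpha01,
                 conc_M = 1),
    # negative-modulator inhibition scans
    fig5b = list(scenario = "negative", selectivities = 10,
                 alpha_grid = alpha01, conc_grid = conc_fig4),
    fig5c = list(scenario = "negative", selectivities = 100,
                 alpha_grid = alpha01, conc_grid = conc_fig4),
    fig5d = list(scenario = "negative", selectivities = 1000,
                 alpha_grid = alpha01, conc_grid = conc_fig4),
    fig5e = list(scenario = "negative", selectivities = c(10, 100, 1000),
                 alpha_grid = 1,
                 conc_grid = 10^seq(-8, 0, length.out = 33)),
    fig5f = list(scenario = "negative", selectivities = c(10, 100, 1000),
                 alpha_grid = 1,
                 conc_grid = 10^seq(-8, 0, length.out = 33),
                 renormalize = TRUE),
    # composite occluded-state reaction
    fig6 = list(scenario = "composite", lifetime = 1e-5, branching = 0.5,
                k_fw_composite = 100, k_bw_composite = 100,
                alpha1 = 0.5, alpha2 = 0.5,
                kd_reactant = 1e-6, kd_intermediate = 5e-6,
                kd_product = 1e-5, conc_M = 1e-3)
  )
}

#' Names of the registered figure-scenario presets
#'
#' @return Character vector of preset names.
#' @export
preset_names <- function() names(preset_registry())

#' Retrieve a figure-scenario run configuration
#'
#' Each preset is a run configuration (a named list with a `scenario`
#' field plus scenario-specific parameters) that regenerates the data
#' table of the corresponding modulator scenario: elementary-reaction
#' landscapes, positive-modulator gain scans, dose-response curves,
#' selectivity scans, the capped-cycle scan, negative-modulator inhibition
#' scans, and the composite occluded-state reaction.
#'
#' @param name Preset identifier, one of [preset_names()].
#' @return A run-config list (class `run_config`).
#' @examples
#' preset("fig4b")$selectivity # 10
#' @export
preset <- function(name) {
  reg <- preset_registry()
  if (!name %in% names(reg)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  cfg <- reg[[name]]
  cfg$name <- name
  structure(cfg, class = "run_config")
}

#' Save / load a run configuration as YAML
#'
#' Numeric fields are serialized with 17 significant digits so that the
#' round trip preserves them exactly.
#'
#' @param config A run-config list.
#' @param path File path.
#' @return `save_run_config` returns the path invisibly;
#'   `load_run_config` the configuration.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

#' Execute a run configuration
#'
#' Dispatches on the configuration's `scenario`, writes the resulting
#' tables (CSV/TSV) and summaries (JSON) into `out_dir`, logs the
#' detailed-balance report for every constructed scheme, and records every
#' file with its MD5 checksum in `manifest.json` together with the
#' configuration hash and package version. Re-running an identical
#' configuration reproduces byte-identical numeric tables.
#'
#' @param config A run-config list from [preset()] or
#'   [load_run_config()].
#' @param out_dir Output directory (created if missing).
#' @param temperature Temperature in kelvin for the thermodynamic context.
#' @return The manifest, invisibly.
#' @export
run_scenario <- function(config, out_dir, temperature = 293.15) {
  stopifnot(is.list(config), !is.null(config$scenario))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  ctx <- thermo_context(temperature)
  stem <- if (!is.null(config$name)) config$name else config$scenario
  files <- character()
  log_lines <- character()
  add_balance_log <- function(scheme, label) {
    rep <- check_detailed_balance(scheme)
    log_lines <<- c(log_lines,
                    sprintf("[%s] detailed balance: %s (%d loops, max |ratio-1| = %.3g)",
                            label, if (rep$pass) "PASS" else "FAIL",
                            nrow(rep$loops),
                            max(abs(rep$loops$ratio - 1))))
  }

  sc_cfg <- config$scenario
  if (sc_cfg == "elementary") {
    rxn <- elementary_reaction(config$k_fw, config$k_bw)
    b <- modulator_binding(config$kd_reactant, config$kd_product,
                           config$conc_M)
    tab <- enumerate_balanced_pairs(rxn, b, config$alpha_grid, ctx)
    f <- file.path(out_dir, paste0(stem, "_landscape.tsv"))
    write_landscape_tsv(tab, f)
    files <- c(files, f)
  } else if (sc_cfg == "positive") {
    g <- gain_vs_alpha(config$selectivity, config$conc_list,
                       config$alpha_grid)
    add_balance_log(build_positive_scheme(1, selectivity =
                                            config$selectivity), stem)
    f <- file.path(out_dir, paste0(stem, "_gain.csv"))
    files <- c(files, write_scan_csv(g, f))
  } else if (sc_cfg == "capped") {
    g <- capped_gain_scan(config$cap, config$selectivities,
                          config$alpha_grid, config$conc_M)
    add_balance_log(cap_second_step(build_positive_scheme(1), config$cap),
                    stem)
    f <- file.path(out_dir, paste0(stem, "_gain.csv"))
    files <- c(files, write_scan_csv(g, f))
  } else if (sc_cfg == "dose_response") {
    dr <- dose_response(config$selectivities, config$conc_grid,
                        config$alpha)
    f <- file.path(out_dir, paste0(stem, "_dose_response.csv"))
    files <- c(files, write_scan_csv(dr, f))
  } else if (sc_cfg == "selectivity_scan") {
    g <- gain_vs_selectivity(config$alpha, config$conc_M,
                             config$selectivity_grid)
    f <- file.path(out_dir, paste0(stem, "_gain_vs_selectivity.csv"))
    write_numeric_csv(g, f)
    files <- c(files, f)
  } else if (sc_cfg == "negative") {
    inh <- inhibition_scan(config$selectivities, config$alpha_grid,
                           config$conc_grid)
    add_balance_log(build_negative_scheme(max(config$selectivities), 1),
                    stem)
    if (isTRUE(config$renormalize)) {
      # rescale each curve to 1 = no inhibition, 0 = maximal inhibition
      inh$grid <- do.call(rbind, lapply(
        split(inh$grid, list(inh$grid$selectivity, inh$grid$alpha),
              drop = TRUE),
        function(d) {
          resid <- min(d$normalized_uptake)
          d$normalized_uptake <- (d$normalized_uptake - resid) /
            (1 - resid)
          d
        }))
      rownames(inh$grid) <- NULL
    }
    f <- file.path(out_dir, paste0(stem, "_inhibition.csv"))
    files <- c(files, write_scan_csv(inh, f))
  } else if (sc_cfg == "composite") {
    cr <- composite_from_observables(
      config$lifetime, config$branching, config$k_fw_composite,
      config$k_bw_composite, config$alpha1, config$alpha2,
      config$kd_reactant, config$kd_intermediate, config$kd_product)
    red <- composite_reduce(cr, config$conc_M, ctx)
    out <- list(
      alpha_app = alpha_app(cr, config$conc_M, ctx),
      alpha_app_backward = alpha_app(cr, config$conc_M, ctx,
                                     derivation = "backward"),
      k_fw_composite = red$k_fw, k_bw_composite = red$k_bw,
      k_fw_modulated = red$k_fw_mod, k_bw_modulated = red$k_bw_mod,
      intermediate_lifetime_s = cr$intermediate_lifetime,
      qssa_ok = red$qssa_ok)
    f <- file.path(out_dir, paste0(stem, "_composite.json"))
    jsonlite::write_json(out, f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  } else {
    stop("unknown scenario '", sc_cfg, "'", call. = FALSE)
  }

  cfg_file <- file.path(out_dir, paste0(stem, "_config.yaml"))
  save_run_config(config, cfg_file)
  files <- c(files, cfg_file)
  if (length(log_lines)) {
    log_file <- file.path(out_dir, paste0(stem, "_balance.log"))
    writeLines(log_lines, log_file)
    files <- c(files, log_file)
  }
  manifest <- list(
    config = unclass(config),
    config_hash = unname(tools::md5sum(cfg_file)),
    package = "slcmod",
    version = as.character(utils::packageVersion("slcmod")),
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f))))
  )
  manifest_file <- file.path(out_dir, paste0(stem, "_manifest.json"))
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
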