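# Fixtures built in code: a moderate-rate eight-state scheme with the same
# two-loop topology as the presets but rate constants within three orders
# of magnitude, so that the embedded jump chain of the Gillespie sampler
# mixes within a small event budget. All loops satisfy detailed balance at
# the reference concentration. Written/loaded through the YAML config path
# so the loader is exercised on every test run.

toy_state_list <- function() {
  st <- data.frame(
    name = c("To", "ToNaS", "TiNaS", "Ti", "ToM", "ToNaSM", "TiNaSM",
             "TiM"),
    facing = c("outward", "outward", "inward", "inward",
               "outward", "outward", "inward", "inward"),
    substrate_bound = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE,
                        FALSE),
    modulator_bound = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE,
                        TRUE),
    stringsAsFactors = FALSE)
  lapply(seq_len(nrow(st)), function(i) as.list(st[i, ]))
}

toy_rate_list <- function() {
  r <- function(from, to, k, factors = "") {
    list(from = from, to = to, base_constant = k, factors = factors)
  }
  list(
    r("To", "ToNaS", 200, "na_out*s_out"), r("ToNaS", "TiNaS", 30),
    r("TiNaS", "Ti", 40), r("Ti", "To", 2),
    r("To", "Ti", 2), r("Ti", "TiNaS", 200, "na_in*s_in"),
    r("TiNaS", "ToNaS", 15), r("ToNaS", "To", 80),
    r("ToM", "ToNaSM", 200, "na_out*s_out"), r("ToNaSM", "TiNaSM", 30),
    r("TiNaSM", "TiM", 40), r("TiM", "ToM", 20),
    r("ToM", "TiM", 2), r("TiM", "TiNaSM", 200, "na_in*s_in"),
    r("TiNaSM", "ToNaSM", 15), r("ToNaSM", "ToM", 800),
    r("To", "ToM", 5, "modulator"), r("ToM", "To", 1),
    r("ToNaS", "ToNaSM", 5, "modulator"), r("ToNaSM", "ToNaS", 10),
    r("TiNaS", "TiNaSM", 5, "modulator"), r("TiNaSM", "TiNaS", 10),
    r("Ti", "TiM", 5, "modulator"), r("TiM", "Ti", 10)
  )
}

toy_scheme <- function(na_out = 0.5, s_out = 1, na_in = 0.1, s_in = 0.05,
                       modulator = 0.4) {
  cfg <- list(
    modulator_mode = "positive", x_factor = NA, selectivity = NA,
    alpha = NA,
    concentrations = list(na_out = na_out, s_out = s_out, na_in = na_in,
                          s_in = s_in, modulator = modulator),
    states = toy_state_list(), rates = toy_rate_list())
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path, precision = 17)
  on.exit(unlink(path))
  scheme_load(path)
}

# a two-state reversible reaction as a degenerate "scheme", for closed-form
# relaxation checks
two_state_scheme <- function(k_fw = 2, k_bw = 2) {
  cfg <- list(
    modulator_mode = "positive", x_factor = NA, selectivity = NA,
    alpha = NA,
    concentrations = list(na_out = 0, s_out = 0, na_in = 0, s_in = 0,
                          modulator = 0),
    states = list(
      list(name = "R", facing = "outward", substrate_bound = FALSE,
           modulator_bound = FALSE),
      list(name = "P", facing = "inward", substrate_bound = FALSE,
           modulator_bound = FALSE)),
    rates = list(
      list(from = "R", to = "P", base_constant = k_fw, factors = ""),
      list(from = "P", to = "R", base_constant = k_bw, factors = "")))
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path, precision = 17)
  on.exit(unlink(path))
  scheme_load(path)
}
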