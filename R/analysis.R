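# Scan engines over the transport-cycle presets: gain and inhibition
# surfaces, dose-response curves with EC50/IC50 extraction, and the
# composite (occluded-state) reaction machinery with its apparent alpha.

#' Gain in substrate uptake as a function of alpha
#'
#' Steady-state uptake gain of the positive-modulator cycle on a grid of
#' transition-state positions and modulator concentrations.
#'
#' @param selectivity Affinity ratio of the modulator for the OF state
#'   (>= 1).
#' @param conc_list Modulator concentrations, molar.
#' @param alpha_grid Grid of alpha values (default 0 to 1 in steps of
#'   0.05).
#' @param conc A [cycle_concentrations()] for the bias conditions.
#' @param cap Optional translocation cap (see [cap_second_step()]).
#' @return A data.frame of class `gain_scan` with columns `alpha`,
#'   `selectivity`, `conc_M` and `gain`.
#' @examples
#' \donttest{
#' g <- gain_vs_alpha(10, conc_list = c(1e-5, 1))
#' max(g$gain) # ~10 at alpha = 1, saturating modulator
#' }
#' @export
gain_vs_alpha <- function(selectivity, conc_list,
                          alpha_grid = seq(0, 1, by = 0.05),
                          conc = cycle_concentrations(), cap = Inf) {
  stopifnot(selectivity >= 1, length(alpha_grid) >= 1,
            length(conc_list) >= 1)
  builder <- positive_scheme_builder(selectivity, conc, cap)
  grid <- expand.grid(alpha = alpha_grid, conc_M = conc_list,
                      KEEP.OUT.ATTRS = FALSE)
  grid$selectivity <- selectivity
  grid$gain <- mapply(function(a, cm) uptake_gain(builder, a, cm),
                      grid$alpha, grid$conc_M)
  structure(grid[, c("alpha", "selectivity", "conc_M", "gain")],
            class = c("gain_scan", "data.frame"))
}

#' Gain scan with a capped second step
#'
#' Same scan as [gain_vs_alpha()] but with the lumped translocation step
#' capped (default 20 s^-1) so that it becomes rate-limiting once the
#' return step is sufficiently accelerated; the attainable gain is then
#' bounded by the two-slow-step harmonic limit whatever the selectivity.
#'
#' @param cap Translocation cap, s^-1.
#' @param selectivities Vector of modulator selectivities.
#' @param alpha_grid Grid of alpha values.
#' @param conc_m Modulator concentration, molar.
#' @param conc A [cycle_concentrations()].
#' @return A `gain_scan` data.frame over alpha and selectivity.
#' @export
capped_gain_scan <- function(cap = 20, selectivities = c(10, 100, 1000),
                             alpha_grid = seq(0, 1, by = 0.05),
                             conc_m = 1, conc = cycle_concentrations()) {
  stopifnot(cap > 0)
  out <- lapply(selectivities, function(s) {
    g <- gain_vs_alpha(s, conc_m, alpha_grid, conc, cap = cap)
    g
  })
  structure(do.call(rbind, out), class = c("gain_scan", "data.frame"))
}

#' Normalized dose-response curves and EC50 of the allosteric gain
#'
#' For each selectivity, computes the uptake gain over a concentration
#' grid at fixed alpha, normalizes the response to [0, 1]
#' (`(gain - 1) / (gain_max - 1)`), and extracts the EC50 by log-linear
#' interpolation at the half-maximal normalized response. A non-monotone
#' curve yields an `NA` EC50 plus a warning record rather than an error.
#'
#' @param selectivities Vector of modulator selectivities.
#' @param conc_grid Modulator concentrations, molar; should span at least
#'   four decades.
#' @param alpha Transition-state position (default 1).
#' @param conc A [cycle_concentrations()].
#' @return A list of class `dose_response` with `curves` (data.frame:
#'   selectivity, conc_M, gain, normalized) and `ec50` (data.frame:
#'   selectivity, ec50_M, monotone).
#' @export
dose_response <- function(selectivities,
                          conc_grid = 10^seq(-8, 0, length.out = 33),
                          alpha = 1, conc = cycle_concentrations()) {
  stopifnot(length(conc_grid) >= 4,
            diff(range(log10(conc_grid))) >= 4)
  curves <- list()
  ec <- list()
  for (s in selectivities) {
    builder <- positive_scheme_builder(s, conc)
    gain <- vapply(conc_grid, function(cm) uptake_gain(builder, alpha, cm),
                   numeric(1))
    normalized <- (gain - 1) / (max(gain) - 1)
    curves[[length(curves) + 1L]] <- data.frame(
      selectivity = s, conc_M = conc_grid, gain = gain,
      normalized = normalized)
    mono <- !is.unsorted(gain, strictly = FALSE)
    e <- if (mono) interp_half_level(conc_grid, normalized, 0.5) else {
      warning("non-monotone dose-response at selectivity ", s,
              ": EC50 undefined", call. = FALSE)
      NA_real_
    }
    ec[[length(ec) + 1L]] <- data.frame(selectivity = s, ec50_M = e,
                                        monotone = mono)
  }
  structure(list(curves = do.call(rbind, curves),
                 ec50 = do.call(rbind, ec)),
            class = "dose_response")
}

# log-linear interpolation of the concentration at which a normalized,
# increasing response crosses `level`
interp_half_level <- function(conc, resp, level) {
  i <- which(resp >= level)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(conc[1])
  x1 <- log10(conc[i - 1]); x2 <- log10(conc[i])
  y1 <- resp[i - 1]; y2 <- resp[i]
  10^(x1 + (level - y1) / (y2 - y1) * (x2 - x1))
}

#' Gain as a function of modulator selectivity
#'
#' At a fixed, sub-saturating modulator concentration the relation between
#' selectivity and gain is bell-shaped: a moderately selective ligand gains
#' from the faster modulated return step, but an over-selective one no
#' longer occupies the low-affinity (IF) state and loses its effect.
#'
#' @param alpha Transition-state position.
#' @param conc_m Modulator concentration, molar.
#' @param selectivity_grid Grid of selectivities (spanning at least 10 to
#'   1e4 for the bell shape to be visible).
#' @param conc A [cycle_concentrations()].
#' @return data.frame with columns `selectivity`, `alpha`, `conc_M`,
#'   `gain`.
#' @export
gain_vs_selectivity <- function(alpha = 1, conc_m = 1e-5,
                                selectivity_grid = 10^seq(0, 4, by = 0.25),
                                conc = cycle_concentrations()) {
  gain <- vapply(selectivity_grid, function(s) {
    uptake_gain(positive_scheme_builder(s, conc), alpha, conc_m)
  }, numeric(1))
  data.frame(selectivity = selectivity_grid, alpha = alpha,
             conc_M = conc_m, gain = gain)
}

#' Inhibition scan for the negative-modulator cycle
#'
#' Normalized steady-state uptake (1 = no modulator) of the
#' negative-modulator preset on a grid of alpha, selectivity and
#' concentration, with IC50 (log-interpolated on the 1 -> residual
#' normalized inhibition scale) and the residual uptake at the highest
#' concentration per (selectivity, alpha) combination.
#'
#' @param selectivities Vector of modulator selectivities.
#' @param alpha_grid Grid of alpha values.
#' @param conc_grid Modulator concentrations, molar.
#' @param conc A [cycle_concentrations()].
#' @param base_translocation Modulator-free translocation rate, s^-1.
#' @return A list of class `inhibition_scan` with `grid` (data.frame:
#'   alpha, selectivity, conc_M, normalized_uptake) and `summary`
#'   (data.frame: selectivity, alpha, residual_uptake_at_saturation,
#'   ic50_M).
#' @export
inhibition_scan <- function(selectivities = 10,
                            alpha_grid = seq(0, 1, by = 0.05),
                            conc_grid = 10^seq(-6, 0, length.out = 25),
                            conc = cycle_concentrations(),
                            base_translocation = 100) {
  rows <- list()
  summ <- list()
  for (s in selectivities) {
    builder <- negative_scheme_builder(s, conc, base_translocation)
    for (a in alpha_grid) {
      sc <- builder(a)
      base <- steady_state(set_concentrations(sc, modulator = 0))$uptake_rate
      u <- vapply(conc_grid, function(cm) {
        steady_state(set_concentrations(sc, modulator = cm))$uptake_rate /
          base
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        alpha = a, selectivity = s, conc_M = conc_grid,
        normalized_uptake = u)
      resid <- u[length(u)]
      inhib <- (1 - u) / (1 - resid)
      ic50 <- if (resid < 1 - 1e-6 && !is.unsorted(inhib)) {
        interp_half_level(conc_grid, inhib, 0.5)
      } else NA_real_
      summ[[length(summ) + 1L]] <- data.frame(
        selectivity = s, alpha = a,
        residual_uptake_at_saturation = resid, ic50_M = ic50)
    }
  }
  structure(list(grid = do.call(rbind, rows),
                 summary = do.call(rbind, summ)),
            class = "inhibition_scan")
}

#' Composite two-step reaction with a short-lived intermediate
#'
#' A reaction R <-> I <-> P whose intermediate (e.g. the occluded state of
#' a transporter) is too short-lived to resolve experimentally. Each
#' elementary step has its own transition-state position; the ligand may
#' bind all three states with different affinities.
#'
#' @param a,b Forward/backward rate constants of step 1 (R -> I, I -> R),
#'   s^-1.
#' @param c_,d Forward/backward rate constants of step 2 (I -> P, P -> I),
#'   s^-1.
#' @param alpha1,alpha2 Transition-state positions of steps 1 and 2.
#' @param kd_reactant,kd_intermediate,kd_product Ligand K_D per state,
#'   molar.
#' @return An object of class `composite_reaction`; the intermediate
#'   lifetime is `1 / (b + c_)`.
#' @export
composite_reaction <- function(a, b, c_, d, alpha1 = 0.5, alpha2 = 0.5,
                               kd_reactant = 1e-6, kd_intermediate = 5e-6,
                               kd_product = 1e-5) {
  stopifnot(a > 0, b >= 0, c_ > 0, d >= 0,
            kd_reactant > 0, kd_intermediate > 0, kd_product > 0)
  structure(
    list(a = a, b = b, c_ = c_, d = d, alpha1 = alpha1, alpha2 = alpha2,
         kd_reactant = kd_reactant, kd_intermediate = kd_intermediate,
         kd_product = kd_product,
         intermediate_lifetime = 1 / (b + c_),
         K_eq = (a * c_) / (b * d)),
    class = "composite_reaction"
  )
}

#' Build a composite reaction from observable constraints
#'
#' Parameterizes [composite_reaction()] by the quantities a kineticist
#' would state: the intermediate lifetime, the branching ratio
#' `b / (b + c)` of the intermediate, and the observable (quasi-steady-
#' state) composite forward and backward rates.
#'
#' @param lifetime Intermediate lifetime 1/(b + c), s.
#' @param branching Branching ratio b/(b + c) in (0, 1).
#' @param k_fw_composite,k_bw_composite Observable composite rates, s^-1.
#' @inheritParams composite_reaction
#' @return A `composite_reaction`.
#' @export
composite_from_observables <- function(lifetime = 1e-5, branching = 0.5,
                                       k_fw_composite = 100,
                                       k_bw_composite = 100,
                                       alpha1 = 0.5, alpha2 = 0.5,
                                       kd_reactant = 1e-6,
                                       kd_intermediate = 5e-6,
                                       kd_product = 1e-5) {
  stopifnot(lifetime > 0, branching > 0, branching < 1,
            k_fw_composite > 0, k_bw_composite > 0)
  b <- branching / lifetime
  c_ <- (1 - branching) / lifetime
  a <- k_fw_composite * (b + c_) / c_
  d <- k_bw_composite * (b + c_) / b
  composite_reaction(a, b, c_, d, alpha1, alpha2,
                     kd_reactant, kd_intermediate, kd_product)
}

#' Reduce a composite reaction to effective rates
#'
#' Quasi-steady-state elimination of the short-lived intermediate gives the
#' observable composite rates `k_FW = a c / (b + c)` and
#' `k_BW = d b / (b + c)`. The modulated composite is computed the same way
#' from the LFER-transformed elementary rates (step 1 with `alpha1` and the
#' reactant/intermediate K_Ds; step 2 with `alpha2` and the
#' intermediate/product K_Ds). The composite equilibrium ratio shifts by
#' exactly the product/reactant stabilization ratio, independent of the
#' alphas and of the intermediate K_D. The alternative `"relaxation"`
#' method takes the slowest relaxation eigenvalue of the three-state rate
#' matrix and splits it by the composite equilibrium constant.
#'
#' @param cr A [composite_reaction()].
#' @param conc_m Modulator concentration, molar.
#' @param ctx A [thermo_context()].
#' @param method `"qssa"` (default) or `"relaxation"`.
#' @return A list of class `composite_rates` with `k_fw`, `k_bw`
#'   (modulator-free), `k_fw_mod`, `k_bw_mod` (modulated), the elementary
#'   modulated rates, the stabilization factors `s_reactant`,
#'   `s_intermediate`, `s_product`, and `qssa_ok` (FALSE, with a warning,
#'   when the intermediate is not fast compared to the composite rates).
#' @export
composite_reduce <- function(cr, conc_m, ctx = thermo_context(),
                             method = c("qssa", "relaxation")) {
  stopifnot(inherits(cr, "composite_reaction"), conc_m >= 0)
  method <- match.arg(method)
  s_R <- 1 + conc_m / cr$kd_reactant
  s_I <- 1 + conc_m / cr$kd_intermediate
  s_P <- 1 + conc_m / cr$kd_product
  # LFER transform of each elementary step (closed form of lfer_apply)
  a2 <- cr$a * (s_I / s_R)^cr$alpha1
  b2 <- cr$b * (s_I / s_R)^(cr$alpha1 - 1)
  c2 <- cr$c_ * (s_P / s_I)^cr$alpha2
  d2 <- cr$d * (s_P / s_I)^(cr$alpha2 - 1)
  reduce <- switch(method,
    qssa = function(a, b, c_, d) {
      c(k_fw = a * c_ / (b + c_), k_bw = d * b / (b + c_))
    },
    relaxation = function(a, b, c_, d) {
      Q <- matrix(c(-a, a, 0,
                    b, -(b + c_), c_,
                    0, d, -d), 3, 3, byrow = TRUE)
      ev <- sort(abs(Re(eigen(t(Q), only.values = TRUE)$values)))
      lambda <- ev[2] # slowest nonzero relaxation rate
      K <- (a * c_) / (b * d)
      c(k_fw = lambda * K / (1 + K), k_bw = lambda / (1 + K))
    })
  free <- reduce(cr$a, cr$b, cr$c_, cr$d)
  mod <- reduce(a2, b2, c2, d2)
  qssa_ok <- (cr$b + cr$c_) > 10 * max(free) &&
    (b2 + c2) > 10 * max(mod)
  if (method == "qssa" && !qssa_ok) {
    warning("intermediate is not fast compared to the composite rates: ",
            "quasi-steady-state reduction is dubious", call. = FALSE)
  }
  structure(
    list(k_fw = unname(free["k_fw"]), k_bw = unname(free["k_bw"]),
         k_fw_mod = unname(mod["k_fw"]), k_bw_mod = unname(mod["k_bw"]),
         elementary_mod = c(a = a2, b = b2, c_ = c2, d = d2),
         s_reactant = s_R, s_intermediate = s_I, s_product = s_P,
         method = method, qssa_ok = qssa_ok),
    class = "composite_rates"
  )
}

#' Apparent alpha of a composite reaction
#'
#' Treats the composite reaction as if it were elementary: the
#' transition-state shift is read off the modulator-induced change of the
#' observable composite forward rate, the ground-state shifts from the
#' reactant/product stabilization energies, and [extract_alpha()] gives the
#' apparent transition-state position
#' `alpha_app = log(k_FW'/k_FW) / log(s_P / s_R)`. The value derived from
#' the backward-rate change is identical (a consequence of detailed
#' balance), which is exposed for verification via `derivation`.
#'
#' @param cr A [composite_reaction()].
#' @param conc_m Modulator concentration, molar (> 0).
#' @param ctx A [thermo_context()].
#' @param method Reduction method, passed to [composite_reduce()].
#' @param derivation Use the forward- or backward-rate change.
#' @return alpha_app, dimensionless.
#' @export
alpha_app <- function(cr, conc_m, ctx = thermo_context(),
                      method = c("qssa", "relaxation"),
                      derivation = c("forward", "backward")) {
  stopifnot(conc_m > 0)
  derivation <- match.arg(derivation)
  red <- composite_reduce(cr, conc_m, ctx, method)
  if (red$s_product == red$s_reactant) {
    stop("alpha_app undefined: modulator does not discriminate reactant ",
         "from product state", call. = FALSE)
  }
  ddG_R <- -ctx$RT * log(red$s_reactant)
  ddG_P <- -ctx$RT * log(red$s_product)
  ddG_ts <- switch(derivation,
    forward = ddG_R - ctx$RT * log(red$k_fw_mod / red$k_fw),
    backward = ddG_P - ctx$RT * log(red$k_bw_mod / red$k_bw))
  extract_alpha(ddG_ts, ddG_R, ddG_P)
}

#' Write a tidy scan result as CSV plus a JSON summary sidecar
#'
#' @param x A `gain_scan`, `dose_response` or `inhibition_scan` object.
#' @param path CSV output path; the JSON sidecar (EC50/IC50/residual
#'   summaries, when the object carries them) is written next to it with
#'   extension `.json`.
#' @return Character vector of the files written, invisibly.
#' @export
write_scan_csv <- function(x, path) {
  json_path <- sub("\\.csv$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  files <- path
  if (inherits(x, "gain_scan")) {
    write_numeric_csv(as.data.frame(x), path)
  } else if (inherits(x, "dose_response")) {
    write_numeric_csv(x$curves, path)
    jsonlite::write_json(x$ec50, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
    files <- c(files, json_path)
  } else if (inherits(x, "inhibition_scan")) {
    write_numeric_csv(x$grid, path)
    jsonlite::write_json(x$summary, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
    files <- c(files, json_path)
  } else stop("unsupported object", call. = FALSE)
  invisible(files)
}

write_numeric_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 17,
                                                 format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
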