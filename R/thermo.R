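#' Thermodynamic context for rate/energy conversions
#'
#' Bundles the physical constants and the temperature that govern every
#' conversion between unidirectional rate constants and activation free
#' energies via the Eyring equation
#' \deqn{k = \kappa \frac{k_B T}{h} e^{-\Delta G^\ddagger / RT}.}
#'
#' The default temperature is 293.15 K (20 degrees C); the transmission
#' coefficient defaults to 1, i.e. no recrossing of the barrier.
#'
#' @param temperature Absolute temperature in kelvin. Must be positive.
#' @param kappa Transmission coefficient, dimensionless, in (0, 1].
#' @param gas_constant Molar gas constant R in J mol^-1 K^-1.
#' @param boltzmann Boltzmann constant k_B in J K^-1.
#' @param planck Planck constant h in J s.
#'
#' @return An object of class `thermo_context` with fields `temperature`,
#'   `kappa`, `gas_constant`, `boltzmann`, `planck`, plus the derived
#'   `RT` (J mol^-1) and `attempt_frequency` (kappa * k_B T / h, s^-1).
#' @examples
#' ctx <- thermo_context()
#' ctx$attempt_frequency # ~6.1e12 s^-1 at 293.15 K
#' @export
thermo_context <- function(temperature = 293.15, kappa = 1,
                           gas_constant = 8.31446261815324,
                           boltzmann = 1.380649e-23,
                           planck = 6.62607015e-34) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0)
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa <= 0 || kappa > 1) {
    stop("`kappa` must be a single number in (0, 1]", call. = FALSE)
  }
  stopifnot(gas_constant > 0, boltzmann > 0, planck > 0)
  ctx <- list(
    temperature = temperature,
    kappa = kappa,
    gas_constant = gas_constant,
    boltzmann = boltzmann,
    planck = planck,
    RT = gas_constant * temperature,
    attempt_frequency = kappa * boltzmann * temperature / planck
  )
  stopifnot(is.finite(ctx$attempt_frequency), ctx$attempt_frequency > 0)
  class(ctx) <- "thermo_context"
  ctx
}

#' @export
print.thermo_context <- function(x, ...) {
  cat("Thermodynamic context\n")
  cat(sprintf("  T          = %.2f K\n", x$temperature))
  cat(sprintf("  kappa      = %g\n", x$kappa))
  cat(sprintf("  RT         = %.4f kJ/mol\n", x$RT / 1000))
  cat(sprintf("  kB*T/h     = %.4g s^-1\n", x$attempt_frequency / x$kappa))
  invisible(x)
}

#' Reversible elementary reaction
#'
#' A single reversible step reactant <-> product with unidirectional rate
#' constants and a Bronsted-type coefficient `alpha` locating its transition
#' state on the reaction coordinate (0 = reactant-like, 1 = product-like).
#' `alpha` may take any real value on construction; values outside [0, 1]
#' describe barriers that defy the linear free energy relationship and are
#' flagged via `lfer_compliant` rather than rejected.
#'
#' @param k_fw Forward unidirectional rate constant, s^-1. Positive.
#' @param k_bw Backward unidirectional rate constant, s^-1. Positive.
#' @param alpha Position of the transition state on the reaction coordinate.
#' @return An object of class `elementary_reaction` with fields `k_fw`,
#'   `k_bw`, `alpha`, `K_eq` (= k_fw/k_bw) and `lfer_compliant`.
#' @examples
#' elementary_reaction(2, 2, alpha = 0.5)
#' @export
elementary_reaction <- function(k_fw, k_bw, alpha = 0.5) {
  stopifnot(is.numeric(k_fw), is.numeric(k_bw), is.numeric(alpha),
            length(k_fw) == 1L, length(k_bw) == 1L, length(alpha) == 1L,
            is.finite(alpha))
  if (!is.finite(k_fw) || k_fw <= 0 || !is.finite(k_bw) || k_bw <= 0) {
    stop("rate constants must be positive and finite", call. = FALSE)
  }
  K_eq <- k_fw / k_bw
  stopifnot(is.finite(K_eq), K_eq > 0)
  structure(
    list(k_fw = k_fw, k_bw = k_bw, alpha = alpha, K_eq = K_eq,
         lfer_compliant = alpha >= 0 && alpha <= 1),
    class = "elementary_reaction"
  )
}

#' State-selective modulator binding
#'
#' Dissociation constants of an allosteric ligand for the reactant and the
#' product ground state of an elementary reaction, plus its free
#' concentration. The selectivity ratio `kd_reactant / kd_product` — not the
#' absolute affinities — determines how strongly the ligand reshapes the
#' free energy landscape.
#'
#' @param kd_reactant K_D for the reactant state, molar. Positive.
#' @param kd_product K_D for the product state, molar. Positive.
#' @param concentration Free modulator concentration, molar. Non-negative.
#' @return An object of class `modulator_binding`.
#' @examples
#' # the tenfold product-selective micromolar ligand at 1 mM
#' modulator_binding(1e-5, 1e-6, 1e-3)
#' @export
modulator_binding <- function(kd_reactant, kd_product, concentration) {
  stopifnot(is.numeric(kd_reactant), kd_reactant > 0, is.finite(kd_reactant),
            is.numeric(kd_product), kd_product > 0, is.finite(kd_product),
            is.numeric(concentration), concentration >= 0,
            is.finite(concentration))
  structure(
    list(kd_reactant = kd_reactant, kd_product = kd_product,
         concentration = concentration,
         selectivity = kd_reactant / kd_product),
    class = "modulator_binding"
  )
}

#' Convert an activation free energy to a rate constant
#'
#' Eyring equation: `k = kappa * (k_B T / h) * exp(-dG / RT)`. A zero barrier
#' returns the attempt frequency; the rate is strictly decreasing in `dG`.
#'
#' @param dG Activation free energy Delta-G-double-dagger, J mol^-1.
#'   May be vectorised.
#' @param ctx A [thermo_context()].
#' @return Rate constant(s), s^-1.
#' @seealso [rate_to_barrier()] for the exact inverse.
#' @export
barrier_to_rate <- function(dG, ctx = thermo_context()) {
  stopifnot(inherits(ctx, "thermo_context"), is.numeric(dG))
  if (any(!is.finite(dG))) {
    stop("non-finite activation free energy: invalid landscape", call. = FALSE)
  }
  ctx$attempt_frequency * exp(-dG / ctx$RT)
}

#' Convert a rate constant to an activation free energy
#'
#' Exact inverse of [barrier_to_rate()]:
#' `dG = -RT * log(k h / (kappa k_B T))`.
#'
#' @param k Unidirectional rate constant(s), s^-1. Must be positive.
#' @param ctx A [thermo_context()].
#' @return Activation free energy, J mol^-1.
#' @export
rate_to_barrier <- function(k, ctx = thermo_context()) {
  stopifnot(inherits(ctx, "thermo_context"), is.numeric(k))
  if (any(!is.finite(k) | k <= 0)) {
    stop("rate constants must be positive and finite", call. = FALSE)
  }
  -ctx$RT * log(k / ctx$attempt_frequency)
}

#' Activation barriers of an elementary reaction
#'
#' Converts both unidirectional rate constants of a reaction into activation
#' free energies. Their difference equals `-RT log(k_fw / k_bw)`, the
#' standard reaction free energy.
#'
#' @param rxn An [elementary_reaction()].
#' @param ctx A [thermo_context()].
#' @return An object of class `transition_barrier` with fields `dG_forward`
#'   and `dG_backward` (J mol^-1).
#' @export
transition_barrier <- function(rxn, ctx = thermo_context()) {
  stopifnot(inherits(rxn, "elementary_reaction"))
  structure(
    list(dG_forward = rate_to_barrier(rxn$k_fw, ctx),
         dG_backward = rate_to_barrier(rxn$k_bw, ctx)),
    class = "transition_barrier"
  )
}

#' Ground-state stabilization energy on ligand binding
#'
#' Free-energy change of a ground state when a ligand with dissociation
#' constant `kd` is present at concentration `conc`, from the binding
#' polynomial: `ddG = -RT * log(1 + conc / kd)`. Always <= 0; zero without
#' ligand. For two states with K_D ratio rho the difference of their
#' stabilization energies tends to `-RT log(rho)` at saturation.
#'
#' @param kd Dissociation constant, molar. Positive.
#' @param conc Ligand concentration, molar. Non-negative. Vectorised.
#' @param ctx A [thermo_context()].
#' @return Stabilization energy, J mol^-1 (<= 0).
#' @examples
#' stabilization_energy(1e-6, 1e-3) / 1000 # ~ -16.8 kJ/mol
#' @export
stabilization_energy <- function(kd, conc, ctx = thermo_context()) {
  stopifnot(is.numeric(kd), all(kd > 0), is.numeric(conc), all(conc >= 0),
            inherits(ctx, "thermo_context"))
  -ctx$RT * log1p(conc / kd)
}

#' Apply the linear free energy relationship to a modulated reaction
#'
#' Given an elementary reaction and a state-selective ligand, computes the
#' ligand-induced ground-state shifts `ddG_R` and `ddG_P` (from the binding
#' polynomial), places the transition-state shift by LFER,
#' \deqn{\Delta\Delta G^\ddagger =
#'   \alpha\,\Delta\Delta G_P + (1-\alpha)\,\Delta\Delta G_R,}
#' and returns the modulated rate constants
#' `k_fw_new = k_fw * exp(-(ddG_ts - ddG_R)/RT)` and
#' `k_bw_new = k_bw * exp(-(ddG_ts - ddG_P)/RT)`.
#'
#' The equilibrium-constant shift `(k_fw_new/k_bw_new) / (k_fw/k_bw)` equals
#' `exp(-(ddG_P - ddG_R)/RT)` for every `alpha`: the modulated rate pair
#' always satisfies detailed balance around the binding loop.
#'
#' @param rxn An [elementary_reaction()]; its `alpha` is used unless
#'   overridden.
#' @param binding A [modulator_binding()].
#' @param ctx A [thermo_context()].
#' @param alpha Optional override of the reaction's alpha.
#' @return An object of class `lfer_shift` with fields `ddG_reactant`,
#'   `ddG_product`, `ddG_ts` (J mol^-1), `k_fw_new`, `k_bw_new` (s^-1),
#'   `alpha` and `lfer_compliant`.
#' @examples
#' rxn <- elementary_reaction(2, 2, alpha = 0)
#' b <- modulator_binding(1e-5, 1e-6, 1e-3)
#' lfer_apply(rxn, b) # backward slows from 2 to ~0.2 per second
#' @export
lfer_apply <- function(rxn, binding, ctx = thermo_context(),
                       alpha = rxn$alpha) {
  stopifnot(inherits(rxn, "elementary_reaction"),
            inherits(binding, "modulator_binding"),
            inherits(ctx, "thermo_context"),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  ddG_R <- stabilization_energy(binding$kd_reactant, binding$concentration, ctx)
  ddG_P <- stabilization_energy(binding$kd_product, binding$concentration, ctx)
  ddG_ts <- alpha * ddG_P + (1 - alpha) * ddG_R
  structure(
    list(ddG_reactant = ddG_R, ddG_product = ddG_P, ddG_ts = ddG_ts,
         k_fw_new = rxn$k_fw * exp(-(ddG_ts - ddG_R) / ctx$RT),
         k_bw_new = rxn$k_bw * exp(-(ddG_ts - ddG_P) / ctx$RT),
         alpha = alpha, lfer_compliant = alpha >= 0 && alpha <= 1),
    class = "lfer_shift"
  )
}

#' @export
print.lfer_shift <- function(x, ...) {
  cat("LFER shift (alpha =", format(x$alpha), ")\n")
  cat(sprintf("  ddG_R  = %+.4f kJ/mol\n", x$ddG_reactant / 1000))
  cat(sprintf("  ddG_P  = %+.4f kJ/mol\n", x$ddG_product / 1000))
  cat(sprintf("  ddG_ts = %+.4f kJ/mol\n", x$ddG_ts / 1000))
  cat(sprintf("  k_fw -> %.6g s^-1, k_bw -> %.6g s^-1\n",
              x$k_fw_new, x$k_bw_new))
  if (!x$lfer_compliant) cat("  (alpha outside [0,1]: defies LFER)\n")
  invisible(x)
}

#' Extract alpha from ground- and transition-state shifts
#'
#' Inverts the linear free energy relationship:
#' `alpha = (ddG_ts - ddG_reactant) / (ddG_product - ddG_reactant)`.
#' Values outside [0, 1] are returned as-is (they identify landscapes that
#' defy LFER); a degenerate perturbation with equal ground-state shifts
#' leaves alpha undefined and is an error.
#'
#' @param ddG_ts Transition-state shift, J mol^-1.
#' @param ddG_reactant Reactant ground-state shift, J mol^-1.
#' @param ddG_product Product ground-state shift, J mol^-1.
#' @return alpha, dimensionless.
#' @export
extract_alpha <- function(ddG_ts, ddG_reactant, ddG_product) {
  stopifnot(is.numeric(ddG_ts), is.numeric(ddG_reactant),
            is.numeric(ddG_product))
  if (any(ddG_product == ddG_reactant)) {
    stop("alpha is undefined: reactant and product shifts are equal ",
         "(degenerate perturbation)", call. = FALSE)
  }
  (ddG_ts - ddG_reactant) / (ddG_product - ddG_reactant)
}

#' Enumerate detailed-balance-consistent rate pairs over alpha
#'
#' For a fixed reaction and ligand, every alpha defines a unique modulated
#' rate pair whose ratio is pinned by detailed balance; sweeping alpha traces
#' the one-parameter family of free energy landscapes compatible with the
#' binding thermodynamics. Rows with alpha outside [0, 1] satisfy detailed
#' balance but defy LFER and are flagged.
#'
#' @param rxn An [elementary_reaction()].
#' @param binding A [modulator_binding()].
#' @param alpha_grid Non-empty numeric vector of alpha values.
#' @param ctx A [thermo_context()].
#' @return A data.frame with columns `alpha`, `k_fw`, `k_bw`, `ddG_R`,
#'   `ddG_P`, `ddG_ts`, `lfer_compliant`; one row per grid point.
#' @export
enumerate_balanced_pairs <- function(rxn, binding, alpha_grid,
                                     ctx = thermo_context()) {
  stopifnot(is.numeric(alpha_grid), length(alpha_grid) >= 1L,
            all(is.finite(alpha_grid)))
  rows <- lapply(alpha_grid, function(a) {
    sh <- lfer_apply(rxn, binding, ctx, alpha = a)
    data.frame(alpha = a, k_fw = sh$k_fw_new, k_bw = sh$k_bw_new,
               ddG_R = sh$ddG_reactant, ddG_P = sh$ddG_product,
               ddG_ts = sh$ddG_ts, lfer_compliant = sh$lfer_compliant)
  })
  do.call(rbind, rows)
}

#' Write a landscape/rate table to TSV
#'
#' @param pairs A data.frame from [enumerate_balanced_pairs()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_landscape_tsv <- function(pairs, path) {
  stopifnot(is.data.frame(pairs))
  out <- pairs
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 17,
                                                   format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
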