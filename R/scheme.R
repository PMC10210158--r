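#' Bias concentrations for the transport cycle
#'
#' Ion, substrate and modulator concentrations that multiply the lumped
#' binding constants of the cycle. The defaults bias the cycle into the
#' forward (clockwise) direction with an inwardly directed Na+ gradient:
#' 150 mM Na+ outside, 1 mM substrate outside, nothing inside.
#'
#' @param na_out,s_out Extracellular Na+ and substrate concentration, molar.
#' @param na_in,s_in Intracellular Na+ and substrate concentration, molar.
#' @param modulator Allosteric modulator concentration, molar.
#' @return An object of class `cycle_concentrations` (a named list).
#' @export
cycle_concentrations <- function(na_out = 0.15, s_out = 1e-3,
                                 na_in = 0, s_in = 0, modulator = 0) {
  vals <- list(na_out = na_out, s_out = s_out, na_in = na_in, s_in = s_in,
               modulator = modulator)
  ok <- vapply(vals, function(x) is.numeric(x) && length(x) == 1L &&
                 is.finite(x) && x >= 0, logical(1))
  if (!all(ok)) stop("all concentrations must be finite and >= 0",
                     call. = FALSE)
  structure(vals, class = "cycle_concentrations")
}

# The eight states of the two-loop cycle, indexed 1..8 as in the k_ij naming
# convention: 1=To, 2=ToNaS, 3=TiNaS, 4=Ti (front, modulator-free loop);
# 5=ToM, 6=ToNaSM, 7=TiNaSM, 8=TiM (rear, modulator-bound loop).
cycle_states <- function() {
  data.frame(
    name = c("To", "ToNaS", "TiNaS", "Ti", "ToM", "ToNaSM", "TiNaSM", "TiM"),
    facing = c("outward", "outward", "inward", "inward",
               "outward", "outward", "inward", "inward"),
    substrate_bound = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
    modulator_bound = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

new_scheme <- function(states, rates, concentrations, modulator_mode,
                       x_factor = NA_real_, selectivity = NA_real_,
                       alpha = NA_real_) {
  stopifnot(!anyDuplicated(states$name),
            all(rates$from %in% states$name),
            all(rates$to %in% states$name),
            all(rates$base_constant >= 0))
  structure(
    list(states = states, rates = rates, concentrations = concentrations,
         modulator_mode = modulator_mode, x_factor = x_factor,
         selectivity = selectivity, alpha = alpha),
    class = "transport_scheme"
  )
}

rate_row <- function(from, to, constant, factors = "") {
  data.frame(from = from, to = to, base_constant = constant,
             factors = factors, stringsAsFactors = FALSE)
}

#' Effective first-order rates of a scheme
#'
#' Each directed rate is its base constant multiplied by the named
#' concentration factors (e.g. `"na_out*s_out"` or `"modulator"`), yielding
#' an effective first-order rate in s^-1. A rate is zero only when one of
#' its concentration factors is zero.
#'
#' @param scheme A `transport_scheme`.
#' @param concentrations Optional [cycle_concentrations()] overriding the
#'   scheme's own (used e.g. to evaluate detailed balance at a common
#'   reference concentration).
#' @return Numeric vector of effective rates, one per row of `scheme$rates`.
#' @export
effective_rates <- function(scheme, concentrations = scheme$concentrations) {
  stopifnot(inherits(scheme, "transport_scheme"))
  conc <- unclass(concentrations)
  vapply(seq_len(nrow(scheme$rates)), function(i) {
    f <- scheme$rates$factors[i]
    k <- scheme$rates$base_constant[i]
    if (nzchar(f)) {
      for (nm in strsplit(f, "*", fixed = TRUE)[[1]]) {
        if (is.null(conc[[nm]])) {
          stop("unknown concentration factor: ", nm, call. = FALSE)
        }
        k <- k * conc[[nm]]
      }
    }
    k
  }, numeric(1))
}

#' Rate (generator) matrix of a scheme
#'
#' Returns the n-by-n matrix Q with `Q[i, j]` the effective rate of the
#' transition i -> j and diagonal entries minus the row sums, so that the
#' occupancy ODE reads `dp/dt = t(Q) %*% p`.
#'
#' @inheritParams effective_rates
#' @return A square numeric matrix with state names as dimnames.
#' @export
rate_matrix <- function(scheme, concentrations = scheme$concentrations) {
  n <- nrow(scheme$states)
  Q <- matrix(0, n, n, dimnames = list(scheme$states$name,
                                       scheme$states$name))
  k <- effective_rates(scheme, concentrations)
  idx <- cbind(match(scheme$rates$from, scheme$states$name),
               match(scheme$rates$to, scheme$states$name))
  Q[idx] <- k
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' Query one effective rate
#'
#' @param scheme A `transport_scheme`.
#' @param from,to State names of the directed transition.
#' @return The effective rate in s^-1 (length-one numeric).
#' @export
rate_constant <- function(scheme, from, to) {
  i <- which(scheme$rates$from == from & scheme$rates$to == to)
  if (length(i) != 1L) stop("no unique rate ", from, " -> ", to,
                            call. = FALSE)
  effective_rates(scheme)[i]
}

#' Replace concentrations of a scheme
#'
#' Returns a copy of the scheme with updated bias/modulator concentrations;
#' the rate constants themselves are untouched.
#'
#' @param scheme A `transport_scheme`.
#' @param ... Named concentrations to change, e.g. `modulator = 1e-3`.
#' @return The modified scheme.
#' @export
set_concentrations <- function(scheme, ...) {
  stopifnot(inherits(scheme, "transport_scheme"))
  upd <- list(...)
  conc <- unclass(scheme$concentrations)
  bad <- setdiff(names(upd), names(conc))
  if (length(bad)) stop("unknown concentration(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  conc[names(upd)] <- upd
  scheme$concentrations <- do.call(cycle_concentrations, conc)
  scheme
}

#' Map alpha to the rate-adjustment factor X of the positive preset
#'
#' The rear-loop return step of the positive-modulator preset carries rates
#' `k_85 = 20 X` and `k_58 = 2 X`. For the tenfold OF-selective modulator,
#' `X = 10^(alpha - 1)` places the transition state of the return step at
#' position `alpha`: applying [extract_alpha()] to the modulator-bound
#' versus modulator-free return-step rates recovers `alpha`.
#'
#' @param alpha Position of the transition state, any real number.
#' @return X, dimensionless (positive).
#' @seealso [x_to_alpha()] for the inverse map.
#' @export
alpha_to_x <- function(alpha) {
  stopifnot(is.numeric(alpha), all(is.finite(alpha)))
  10^(alpha - 1)
}

#' @rdname alpha_to_x
#' @param x_factor X, must be positive.
#' @export
x_to_alpha <- function(x_factor) {
  stopifnot(is.numeric(x_factor), all(is.finite(x_factor)),
            all(x_factor > 0))
  1 + log10(x_factor)
}

#' Build the positive-allosteric-modulator transport cycle
#'
#' Constructs the eight-state two-loop scheme in which the modulator binds
#' the substrate-free outward-facing state (To) with high affinity (K_D
#' 1 uM) and all other states with low affinity (K_D `selectivity` uM):
#' a more selective ligand binds the low-affinity states more weakly, so
#' higher concentrations are needed to keep it bound through the whole
#' cycle. The modulator-free return step Ti -> To runs at 2 s^-1; in the
#' modulator-bound loop the return step TiM -> ToM is accelerated according
#' to the LFER position encoded by `x_factor`: with `alpha = 1 + log10(X)`
#' the forward rate is `2 * selectivity^alpha` and the backward rate
#' `2 * selectivity^(alpha - 1)` (for the default tenfold selectivity these
#' are exactly `20 X` and `2 X`). All loops satisfy detailed balance for
#' every positive `x_factor`.
#'
#' @param x_factor Positive rate-adjustment factor X; `X = 1` makes the
#'   modulator-bound return step tenfold faster (alpha = 1).
#' @param conc A [cycle_concentrations()]; the default biases the cycle
#'   forward (0.15 M Na+ and 1 mM substrate outside, nothing inside).
#' @param selectivity Affinity ratio of the modulator for the To state over
#'   the other states (>= 1).
#' @return A `transport_scheme` with `modulator_mode = "positive"`.
#' @examples
#' sc <- build_positive_scheme(x_factor = 1)
#' rate_constant(sc, "TiM", "ToM") # 20 s^-1
#' @export
build_positive_scheme <- function(x_factor = 1,
                                  conc = cycle_concentrations(),
                                  selectivity = 10) {
  stopifnot(is.numeric(x_factor), length(x_factor) == 1L,
            is.finite(x_factor))
  if (x_factor <= 0) stop("`x_factor` must be positive", call. = FALSE)
  stopifnot(selectivity >= 1, inherits(conc, "cycle_concentrations"))
  alpha <- x_to_alpha(x_factor)
  k85 <- 2 * selectivity^alpha
  k58 <- 2 * selectivity^(alpha - 1)
  rates <- rbind(
    # front loop, clockwise then counter-clockwise
    rate_row("To", "ToNaS", 1e16, "na_out*s_out"),
    rate_row("ToNaS", "TiNaS", 1e6),
    rate_row("TiNaS", "Ti", 1e12),
    rate_row("Ti", "To", 2),
    rate_row("To", "Ti", 2),
    rate_row("Ti", "TiNaS", 1e16, "na_in*s_in"),
    rate_row("TiNaS", "ToNaS", 1e6),
    rate_row("ToNaS", "To", 1e12),
    # rear (modulator-bound) loop
    rate_row("ToM", "ToNaSM", 1e16, "na_out*s_out"),
    rate_row("ToNaSM", "TiNaSM", 1e6),
    rate_row("TiNaSM", "TiM", 1e12),
    rate_row("TiM", "ToM", k85),
    rate_row("ToM", "TiM", k58),
    rate_row("TiM", "TiNaSM", 1e16, "na_in*s_in"),
    rate_row("TiNaSM", "ToNaSM", 1e6),
    rate_row("ToNaSM", "ToM", 1e12 * selectivity),
    # modulator binding: K_D 1 uM at To, `selectivity` uM elsewhere
    rate_row("To", "ToM", 1e6, "modulator"),
    rate_row("ToM", "To", 1),
    rate_row("ToNaS", "ToNaSM", 1e6, "modulator"),
    rate_row("ToNaSM", "ToNaS", selectivity),
    rate_row("TiNaS", "TiNaSM", 1e6, "modulator"),
    rate_row("TiNaSM", "TiNaS", selectivity),
    rate_row("Ti", "TiM", 1e6, "modulator"),
    rate_row("TiM", "Ti", selectivity)
  )
  new_scheme(cycle_states(), rates, conc, "positive",
             x_factor = x_factor, selectivity = selectivity, alpha = alpha)
}

#' Build the negative-allosteric-modulator transport cycle
#'
#' Constructs the eight-state scheme in which the modulator binds the
#' substrate-bound outward-facing state (ToNaS) with high affinity (K_D
#' 1 uM) and all other states with K_D `selectivity` uM. The
#' substrate translocation step ToNaS -> TiNaS runs at `base_translocation`
#' (default 100 s^-1); in the modulator-bound loop its forward rate is
#' `base * selectivity^(-alpha)` and its backward rate
#' `base * selectivity^(1 - alpha)`, the LFER transform of the reactant-
#' stabilizing ligand at saturation. The rate-limiting return step (2 s^-1)
#' is unmodified. Binding-edge constants complete every loop to detailed
#' balance; construction is verified and a violation is an internal error.
#'
#' @param selectivity Affinity ratio for the ToNaS state over the others
#'   (>= 1).
#' @param alpha Position of the translocation transition state in [0, 1].
#' @param conc A [cycle_concentrations()].
#' @param base_translocation Modulator-free translocation rate, s^-1.
#' @return A `transport_scheme` with `modulator_mode = "negative"`.
#' @examples
#' sc <- build_negative_scheme(selectivity = 10, alpha = 1)
#' rate_constant(sc, "ToNaSM", "TiNaSM") # 100 -> 10 s^-1
#' @export
build_negative_scheme <- function(selectivity = 10, alpha = 1,
                                  conc = cycle_concentrations(),
                                  base_translocation = 100) {
  stopifnot(selectivity >= 1, alpha >= 0, alpha <= 1,
            base_translocation > 0,
            inherits(conc, "cycle_concentrations"))
  b <- base_translocation
  kf_mod <- b * selectivity^(-alpha)
  kb_mod <- b * selectivity^(1 - alpha)
  rates <- rbind(
    rate_row("To", "ToNaS", 1e16, "na_out*s_out"),
    rate_row("ToNaS", "TiNaS", b),
    rate_row("TiNaS", "Ti", 1e12),
    rate_row("Ti", "To", 2),
    rate_row("To", "Ti", 2),
    rate_row("Ti", "TiNaS", 1e16, "na_in*s_in"),
    rate_row("TiNaS", "ToNaS", b),
    rate_row("ToNaS", "To", 1e12),
    rate_row("ToM", "ToNaSM", 1e16, "na_out*s_out"),
    rate_row("ToNaSM", "TiNaSM", kf_mod),
    rate_row("TiNaSM", "TiM", 1e12),
    rate_row("TiM", "ToM", 2),
    rate_row("ToM", "TiM", 2),
    rate_row("TiM", "TiNaSM", 1e16, "na_in*s_in"),
    rate_row("TiNaSM", "ToNaSM", kb_mod),
    rate_row("ToNaSM", "ToM", 1e12 / selectivity),
    # modulator binding: K_D 1 uM at ToNaS, `selectivity` uM elsewhere
    rate_row("To", "ToM", 1e6, "modulator"),
    rate_row("ToM", "To", selectivity),
    rate_row("ToNaS", "ToNaSM", 1e6, "modulator"),
    rate_row("ToNaSM", "ToNaS", 1),
    rate_row("TiNaS", "TiNaSM", 1e6, "modulator"),
    rate_row("TiNaSM", "TiNaS", selectivity),
    rate_row("Ti", "TiM", 1e6, "modulator"),
    rate_row("TiM", "Ti", selectivity)
  )
  sc <- new_scheme(cycle_states(), rates, conc, "negative",
                   selectivity = selectivity, alpha = alpha)
  rep <- check_detailed_balance(sc)
  if (!rep$pass) {
    stop("internal error: constructed negative scheme violates detailed ",
         "balance", call. = FALSE)
  }
  sc
}

#' Check microscopic reversibility of a reaction network
#'
#' Verifies that every directed rate has a reverse partner and that around
#' each loop of a cycle basis the product of clockwise effective rates
#' equals the product of counter-clockwise rates. Concentration factors are
#' evaluated at a common reference (1 M each) so that only the thermodynamic
#' consistency of the rate constants is tested; detailed balance on a cycle
#' basis implies it on every cycle of the network.
#'
#' @param scheme A `transport_scheme`.
#' @param tol Relative tolerance on each loop's forward/backward product
#'   ratio.
#' @return An object of class `balance_report`: a list with `loops` (a
#'   data.frame of per-loop products and ratios) and `pass`.
#' @export
check_detailed_balance <- function(scheme, tol = 1e-6) {
  stopifnot(inherits(scheme, "transport_scheme"))
  r <- scheme$rates
  key <- paste(r$from, r$to, sep = "->")
  rev_key <- paste(r$to, r$from, sep = "->")
  orphan <- setdiff(key, rev_key)
  if (length(orphan)) {
    stop("directed rate(s) without reverse partner: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  ref <- do.call(cycle_concentrations,
                 as.list(setNames(rep(1, 5),
                                  names(unclass(scheme$concentrations)))))
  k_ref <- setNames(effective_rates(scheme, ref), key)

  # undirected edge list (each reversible pair once)
  und <- unique(t(apply(cbind(r$from, r$to), 1, sort)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = und[, 1], to = und[, 2]),
    directed = FALSE, vertices = scheme$states$name)
  tr <- igraph::mst(g)
  tr_ends <- igraph::as_edgelist(tr)
  tr_key <- apply(tr_ends, 1, function(e) paste(sort(e), collapse = "|"))
  loops <- list()
  for (i in seq_len(nrow(und))) {
    e_key <- paste(sort(und[i, ]), collapse = "|")
    if (e_key %in% tr_key) next
    path <- igraph::shortest_paths(tr, from = und[i, 2], to = und[i, 1],
                                   output = "vpath")$vpath[[1]]
    cyc <- c(und[i, 1], names(path)) # closed walk back to und[i, 1]
    fw <- prod(k_ref[paste(cyc[-length(cyc)], cyc[-1], sep = "->")])
    bw <- prod(k_ref[paste(cyc[-1], cyc[-length(cyc)], sep = "->")])
    loops[[length(loops) + 1L]] <- data.frame(
      loop = paste(cyc, collapse = "-"),
      forward_product = fw, backward_product = bw,
      ratio = fw / bw, stringsAsFactors = FALSE)
  }
  loops <- if (length(loops)) do.call(rbind, loops) else
    data.frame(loop = character(), forward_product = numeric(),
               backward_product = numeric(), ratio = numeric())
  loops$pass <- abs(loops$ratio - 1) <= tol
  structure(list(loops = loops, pass = all(loops$pass), tol = tol),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Detailed-balance report (", nrow(x$loops), " basis loops, tol ",
      format(x$tol), ")\n", sep = "")
  if (nrow(x$loops)) {
    df <- x$loops
    df$ratio <- signif(df$ratio, 10)
    print(df[, c("loop", "ratio", "pass")], row.names = FALSE)
  }
  cat(if (x$pass) "PASS: microscopic reversibility holds\n" else
    "FAIL: at least one loop violates detailed balance\n")
  invisible(x)
}

#' Cap the second rate-limiting step of the cycle
#'
#' Slows the lumped (co)-substrate loading step To -> ToNaS (and its
#' modulator-bound counterpart ToM -> ToNaSM) to an effective rate of
#' `cap` s^-1, so that once the return step is accelerated beyond `cap`
#' this second reaction becomes rate-limiting. Forward and backward base
#' constants of each affected edge are scaled by the same factor, which
#' preserves every equilibrium constant and hence detailed balance; the
#' modulator is assumed not to touch this reaction, so both loops receive
#' the identical cap. `cap = Inf` leaves the scheme unchanged.
#'
#' @param scheme A `transport_scheme` from [build_positive_scheme()].
#' @param cap New effective loading rate at the scheme's current bias
#'   concentrations, s^-1 (default 20).
#' @return The modified scheme.
#' @export
cap_second_step <- function(scheme, cap = 20) {
  stopifnot(inherits(scheme, "transport_scheme"), is.numeric(cap),
            length(cap) == 1L, cap > 0)
  if (!is.finite(cap)) return(scheme)
  k_eff <- effective_rates(scheme)
  for (pair in list(c("To", "ToNaS"), c("ToM", "ToNaSM"))) {
    i_fw <- which(scheme$rates$from == pair[1] & scheme$rates$to == pair[2])
    i_bw <- which(scheme$rates$from == pair[2] & scheme$rates$to == pair[1])
    f <- cap / k_eff[i_fw]
    scheme$rates$base_constant[i_fw] <- scheme$rates$base_constant[i_fw] * f
    scheme$rates$base_constant[i_bw] <- scheme$rates$base_constant[i_bw] * f
  }
  scheme
}

#' @export
print.transport_scheme <- function(x, ...) {
  cat("Transport-cycle scheme (", x$modulator_mode, " modulator mode)\n",
      sep = "")
  cat("  states:", paste(x$states$name, collapse = ", "), "\n")
  cat("  directed rates:", nrow(x$rates), "\n")
  if (!is.na(x$selectivity)) cat("  selectivity:", x$selectivity, "\n")
  if (!is.na(x$x_factor)) cat("  X factor:", x$x_factor, "\n")
  if (!is.na(x$alpha)) cat("  alpha:", x$alpha, "\n")
  conc <- unclass(x$concentrations)
  cat("  concentrations (M):",
      paste(sprintf("%s=%g", names(conc), unlist(conc)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Save / load a scheme as a YAML configuration
#'
#' Serializes states, rates (from, to, constant, factors), concentrations
#' and scalar metadata to a structured text file. Numeric fields are written
#' with 17 significant digits so that load -> save -> load is bit-stable.
#'
#' @param scheme A `transport_scheme`.
#' @param path File path.
#' @return `scheme_save` returns the path invisibly; `scheme_load` returns
#'   the reconstructed `transport_scheme`.
#' @export
scheme_save <- function(scheme, path) {
  stopifnot(inherits(scheme, "transport_scheme"))
  obj <- list(
    modulator_mode = scheme$modulator_mode,
    x_factor = scheme$x_factor,
    selectivity = scheme$selectivity,
    alpha = scheme$alpha,
    concentrations = unclass(scheme$concentrations),
    states = lapply(seq_len(nrow(scheme$states)), function(i)
      as.list(scheme$states[i, ])),
    rates = lapply(seq_len(nrow(scheme$rates)), function(i)
      as.list(scheme$rates[i, ]))
  )
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname scheme_save
#' @export
scheme_load <- function(path) {
  obj <- yaml::read_yaml(path)
  states <- do.call(rbind, lapply(obj$states, function(s)
    data.frame(name = s$name, facing = s$facing,
               substrate_bound = s$substrate_bound,
               modulator_bound = s$modulator_bound,
               stringsAsFactors = FALSE)))
  rates <- do.call(rbind, lapply(obj$rates, function(r)
    rate_row(r$from, r$to, r$base_constant,
             if (is.null(r$factors) || !nzchar(r$factors)) "" else
               r$factors)))
  conc <- do.call(cycle_concentrations, obj$concentrations)
  new_scheme(states, rates, conc, obj$modulator_mode,
             x_factor = if (is.null(obj$x_factor)) NA_real_ else
               obj$x_factor,
             selectivity = if (is.null(obj$selectivity)) NA_real_ else
               obj$selectivity,
             alpha = if (is.null(obj$alpha)) NA_real_ else obj$alpha)
}
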