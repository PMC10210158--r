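#' Time derivative of the state occupancies
#'
#' Right-hand side of the occupancy ODE system: for each state,
#' `dp_i/dt = sum_j k_ji p_j - p_i sum_j k_ij`. The derivatives sum to zero
#' (probability conservation) up to floating rounding.
#'
#' @param scheme A `transport_scheme`.
#' @param occupancy Numeric vector of state occupancies, same length and
#'   order as `scheme$states`.
#' @return Numeric vector of d(occupancy)/dt, per second.
#' @export
ode_rhs <- function(scheme, occupancy) {
  stopifnot(inherits(scheme, "transport_scheme"))
  n <- nrow(scheme$states)
  if (length(occupancy) != n) {
    stop("occupancy has length ", length(occupancy), ", expected ", n,
         call. = FALSE)
  }
  drop(occupancy %*% rate_matrix(scheme))
}

#' Integrate the occupancy ODE system
#'
#' Stiff time integration of `dp/dt = t(Q) p` with `deSolve::ode`
#' (lsoda, analytic constant Jacobian). The rate constants of the preset
#' schemes span about 13 orders of magnitude, so a stiff method is
#' mandatory.
#'
#' @param scheme A `transport_scheme`.
#' @param p0 Initial occupancy vector (must lie in [0,1] and sum to 1
#'   within 1e-8). Defaults to all probability in the first state.
#' @param t_end Final time, s (> 0).
#' @param n_points Number of output time points (including t = 0).
#' @param rtol,atol Relative/absolute solver tolerances.
#' @return An object of class `cycle_trajectory`: a list with `time`
#'   (seconds) and `occupancy` (matrix, one column per state).
#' @export
integrate_scheme <- function(scheme, p0 = NULL, t_end, n_points = 201,
                             rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(scheme, "transport_scheme"), t_end > 0)
  n <- nrow(scheme$states)
  if (is.null(p0)) p0 <- c(1, rep(0, n - 1))
  stopifnot(length(p0) == n, all(p0 >= 0), all(p0 <= 1))
  if (abs(sum(p0) - 1) > 1e-8) {
    stop("initial occupancies must sum to 1", call. = FALSE)
  }
  Q <- rate_matrix(scheme)
  Qt <- t(Q)
  times <- seq(0, t_end, length.out = n_points)
  sol <- deSolve::ode(
    y = stats::setNames(p0, scheme$states$name), times = times,
    func = function(t, y, parms) list(drop(Qt %*% y)),
    parms = NULL, jacfunc = function(t, y, parms) Qt, jactype = "fullusr",
    method = "lsoda", rtol = rtol, atol = atol
  )
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE solver failed (istate ", attr(sol, "istate")[1], ")",
         call. = FALSE)
  }
  occ <- unclass(sol)[, -1, drop = FALSE]
  if (any(occ < -1e-6) || any(occ > 1 + 1e-6)) {
    stop("integration drifted outside [0, 1]: occupancies not reliable",
         call. = FALSE)
  }
  structure(list(time = as.numeric(sol[, 1]), occupancy = occ),
            class = "cycle_trajectory")
}

#' Trajectory as a data.frame
#'
#' @param x A `cycle_trajectory`.
#' @param ... Unused.
#' @return data.frame with a `time` column plus one column per state.
#' @export
as.data.frame.cycle_trajectory <- function(x, ...) {
  data.frame(time = x$time, x$occupancy, check.names = FALSE)
}

# The stationary distribution is unique iff exactly one closed communicating
# class exists at the given concentrations; with several, any convex mixture
# is stationary and the answer would depend on the elimination order.
assert_unique_recurrent_class <- function(Q) {
  A <- Q
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  closed <- rep(TRUE, comp$no)
  idx <- which(A > 0, arr.ind = TRUE)
  closed_edges <- memb[idx[, 1]] != memb[idx[, 2]]
  closed[unique(memb[idx[closed_edges, 1]])] <- FALSE
  if (sum(closed) > 1L) {
    classes <- vapply(which(closed), function(cl)
      paste(rownames(Q)[memb == cl], collapse = ","), character(1))
    stop("stationary distribution ambiguous: multiple closed ",
         "communicating classes {", paste(classes, collapse = "} {"),
         "}", call. = FALSE)
  }
  which(memb == which(closed))
}

# Stationary distribution of a CTMC generator by GTH (Grassmann-Taksar-
# Heyman) state elimination. Subtraction-free, hence entrywise accurate even
# when rates span many orders of magnitude (plain null-space solves lose
# ~cond(Q) * eps of relative accuracy here). States with no route back in
# (transient at the given concentrations) receive exactly zero mass; a state
# with no outgoing route to the remaining states makes the stationary
# distribution ambiguous and is an error.
gth_stationary <- function(Q) {
  n <- nrow(Q)
  A <- Q
  diag(A) <- 0
  if (n == 1L) return(1)
  for (k in n:2) {
    below <- seq_len(k - 1L)
    s <- sum(A[k, below])
    if (s <= 0) {
      stop("stationary distribution ambiguous: state '",
           rownames(Q)[k], "' cannot reach the reference component ",
           "(disconnected rate graph at these concentrations)",
           call. = FALSE)
    }
    A[below, below] <- A[below, below] + A[below, k] %o% (A[k, below] / s)
  }
  p <- numeric(n)
  p[1] <- 1
  for (k in 2:n) {
    below <- seq_len(k - 1L)
    p[k] <- sum(p[below] * A[below, k]) / sum(A[k, below])
  }
  p / sum(p)
}

#' Steady state of the transport cycle
#'
#' Computes the stationary occupancy distribution of the scheme's rate
#' matrix by subtraction-free GTH elimination, then per-edge net
#' probability fluxes and the substrate-uptake velocity. Uptake is the sum
#' of the net flux through the front and the rear loop, measured across the
#' substrate-translocation cut (ToNaS -> TiNaS and ToNaSM -> TiNaSM for the
#' eight-state presets); by flux continuity any parallel cut gives the same
#' total.
#'
#' @param scheme A `transport_scheme`.
#' @param front_edge,rear_edge Length-2 character vectors naming the
#'   directed edges across which the front- and rear-loop fluxes are
#'   measured.
#' @return An object of class `steady_state_result`: list with
#'   `occupancies` (named vector), `edge_flux` (data.frame from, to,
#'   forward, backward, net), `front_loop_flux`, `rear_loop_flux`,
#'   `uptake_rate` (substrate molecules per transporter per second) and
#'   `cut` (the edges used).
#' @export
steady_state <- function(scheme,
                         front_edge = c("ToNaS", "TiNaS"),
                         rear_edge = c("ToNaSM", "TiNaSM")) {
  stopifnot(inherits(scheme, "transport_scheme"))
  Q <- rate_matrix(scheme)
  # GTH back-substitutes from state 1, so the recurrent class goes first
  recurrent <- assert_unique_recurrent_class(Q)
  perm <- c(recurrent, setdiff(seq_len(nrow(Q)), recurrent))
  p <- numeric(nrow(Q))
  p[perm] <- gth_stationary(Q[perm, perm, drop = FALSE])
  names(p) <- scheme$states$name
  r <- scheme$rates
  k <- effective_rates(scheme)
  key <- paste(r$from, r$to, sep = "->")
  i_rev <- match(paste(r$to, r$from, sep = "->"), key)
  fwd <- p[r$from] * k
  bwd <- p[r$to] * k[i_rev]
  # one row per reversible pair, oriented as listed first
  i_from <- match(r$from, names(p))
  i_to <- match(r$to, names(p))
  first <- !duplicated(paste(pmin(i_from, i_to), pmax(i_from, i_to)))
  edge_flux <- data.frame(from = r$from, to = r$to,
                          forward = as.numeric(fwd),
                          backward = as.numeric(bwd),
                          net = as.numeric(fwd - bwd),
                          stringsAsFactors = FALSE)[first, ]
  net_of <- function(edge) {
    i <- which(edge_flux$from == edge[1] & edge_flux$to == edge[2])
    j <- which(edge_flux$from == edge[2] & edge_flux$to == edge[1])
    if (length(i) == 1L) edge_flux$net[i]
    else if (length(j) == 1L) -edge_flux$net[j]
    else stop("cut edge ", edge[1], "->", edge[2], " not in scheme",
              call. = FALSE)
  }
  f_front <- net_of(front_edge)
  f_rear <- net_of(rear_edge)
  structure(
    list(occupancies = p, edge_flux = edge_flux,
         front_loop_flux = f_front, rear_loop_flux = f_rear,
         uptake_rate = f_front + f_rear,
         cut = list(front = front_edge, rear = rear_edge)),
    class = "steady_state_result"
  )
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat("Steady state of the transport cycle\n")
  occ <- signif(x$occupancies, 6)
  cat("  occupancies:\n")
  for (nm in names(occ)) cat(sprintf("    %-7s %g\n", nm, occ[[nm]]))
  cat(sprintf("  front-loop flux: %g s^-1\n", x$front_loop_flux))
  cat(sprintf("  rear-loop flux:  %g s^-1\n", x$rear_loop_flux))
  cat(sprintf("  uptake rate:     %g s^-1 (cut: %s->%s + %s->%s)\n",
              x$uptake_rate, x$cut$front[1], x$cut$front[2],
              x$cut$rear[1], x$cut$rear[2]))
  invisible(x)
}

#' Modulator-induced gain in substrate uptake
#'
#' Ratio of the steady-state uptake velocity with the modulator at
#' `conc_m` to the velocity of the otherwise identical modulator-free
#' scheme.
#'
#' @param scheme_builder Function of one argument `alpha` returning a
#'   `transport_scheme` (e.g. [positive_scheme_builder()]); its modulator
#'   concentration is overridden.
#' @param alpha Position of the transition state of the modulated step.
#' @param conc_m Modulator concentration, molar (>= 0).
#' @return Fold change in uptake velocity (dimensionless).
#' @examples
#' uptake_gain(positive_scheme_builder(10), alpha = 1, conc_m = 1) # ~10
#' @export
uptake_gain <- function(scheme_builder, alpha, conc_m) {
  stopifnot(is.function(scheme_builder), is.numeric(alpha),
            is.numeric(conc_m), conc_m >= 0)
  sc <- scheme_builder(alpha)
  base <- steady_state(set_concentrations(sc, modulator = 0))$uptake_rate
  if (base <= 0) {
    stop("baseline uptake flux is zero: the cycle is not biased",
         call. = FALSE)
  }
  mod <- steady_state(set_concentrations(sc, modulator = conc_m))$uptake_rate
  mod / base
}

#' Builder closures for the preset schemes
#'
#' Convenience factories returning a function `alpha -> transport_scheme`
#' suitable for [uptake_gain()] and the scan engines.
#'
#' @param selectivity Affinity ratio of the modulator for its high-affinity
#'   state.
#' @param conc A [cycle_concentrations()].
#' @param cap Optional translocation cap passed to [cap_second_step()]
#'   (positive preset only).
#' @return A function of `alpha`.
#' @export
positive_scheme_builder <- function(selectivity = 10,
                                    conc = cycle_concentrations(),
                                    cap = Inf) {
  force(selectivity); force(conc); force(cap)
  function(alpha) {
    sc <- build_positive_scheme(alpha_to_x(alpha), conc, selectivity)
    cap_second_step(sc, cap)
  }
}

#' @rdname positive_scheme_builder
#' @param base_translocation Modulator-free translocation rate, s^-1.
#' @export
negative_scheme_builder <- function(selectivity = 10,
                                    conc = cycle_concentrations(),
                                    base_translocation = 100) {
  force(selectivity); force(conc); force(base_translocation)
  function(alpha) {
    build_negative_scheme(selectivity, alpha, conc, base_translocation)
  }
}

#' Stochastic-jump estimate of the stationary occupancies
#'
#' Simulates the embedded jump chain of the scheme's continuous-time Markov
#' chain (Gillespie algorithm) and estimates state occupancies from
#' accumulated exponential dwell times. Used as an independent stochastic
#' cross-check of the deterministic steady state; standard errors are
#' estimated regeneratively from returns to the most-occupied state.
#'
#' @param scheme A `transport_scheme`.
#' @param n_events Number of jump events.
#' @param seed Integer seed for reproducibility.
#' @param init Starting state index (default 1).
#' @return A list with `occupancy` (named vector of time fractions),
#'   `se` (regenerative standard errors), `n_events` and `n_cycles`
#'   (completed regeneration cycles).
#' @export
gillespie_occupancy <- function(scheme, n_events = 2e5, seed = 20230505,
                                init = 1L) {
  stopifnot(inherits(scheme, "transport_scheme"), n_events >= 100)
  Q <- rate_matrix(scheme)
  n <- nrow(Q)
  exit <- -diag(Q)
  P <- Q
  diag(P) <- 0
  P <- P / ifelse(exit > 0, exit, 1)
  cum <- t(apply(P, 1, cumsum))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  u_jump <- stats::runif(n_events)
  u_dwell <- stats::runif(n_events)
  state <- integer(n_events + 1L)
  state[1] <- init
  dwell <- numeric(n_events)
  for (i in seq_len(n_events)) {
    s <- state[i]
    if (exit[s] <= 0) stop("absorbing state reached: '",
                           rownames(Q)[s], "'", call. = FALSE)
    dwell[i] <- -log(u_dwell[i]) / exit[s]
    state[i + 1L] <- findInterval(u_jump[i], cum[s, ]) + 1L
  }
  state <- state[seq_len(n_events)]
  tt <- vapply(seq_len(n), function(s) sum(dwell[state == s]), numeric(1))
  occ <- tt / sum(tt)
  names(occ) <- rownames(Q)
  # regenerative SE: split at returns to the modal state
  ref <- which.max(occ)
  starts <- which(state == ref)
  n_cyc <- length(starts) - 1L
  se <- rep(NA_real_, n)
  if (n_cyc >= 30) {
    cyc_id <- findInterval(seq_len(n_events), starts)
    keep <- cyc_id >= 1L & cyc_id <= n_cyc
    tot <- tapply(dwell[keep], cyc_id[keep], sum)
    for (s in seq_len(n)) {
      num <- tapply(dwell[keep] * (state[keep] == s), cyc_id[keep], sum)
      m_num <- mean(num); m_tot <- mean(tot)
      ratio <- m_num / m_tot
      v <- stats::var(num - ratio * tot) / n_cyc / m_tot^2
      se[s] <- sqrt(pmax(v, 0))
    }
  }
  names(se) <- rownames(Q)
  list(occupancy = occ, se = se, n_events = n_events, n_cycles = n_cyc)
}

#' Export a steady state or trajectory as CSV
#'
#' @param x A `steady_state_result` or `cycle_trajectory`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cycle_csv <- function(x, path) {
  if (inherits(x, "cycle_trajectory")) {
    df <- as.data.frame(x)
  } else if (inherits(x, "steady_state_result")) {
    df <- data.frame(state = names(x$occupancies),
                     occupancy = as.numeric(x$occupancies))
    df$front_loop_flux <- x$front_loop_flux
    df$rear_loop_flux <- x$rear_loop_flux
    df$uptake_rate <- x$uptake_rate
  } else stop("unsupported object", call. = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 17,
                                                 format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
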