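test_that("gain surface: unity at alpha 0, monotone to ~selectivity at saturation", {
  g <- gain_vs_alpha(10, conc_list = c(1e-5, 1),
                     alpha_grid = seq(0, 1, by = 0.25))
  expect_true(all(g$gain > 0))
  expect_true(all(abs(g$gain[g$alpha == 0] - 1) < 1e-3))
  expect_equal(max(g$gain), 10, tolerance = 0.02)
  # monotone non-decreasing in alpha at saturating concentration
  sat <- g[g$conc_M == 1, ]
  expect_true(all(diff(sat$gain[order(sat$alpha)]) > -1e-9))
  # non-selective modulator: flat unity surface
  g1 <- gain_vs_alpha(1, conc_list = c(1e-4, 1),
                      alpha_grid = c(0, 0.5, 1))
  expect_true(all(abs(g1$gain - 1) < 1e-3))
})

test_that("EC50 shifts right as the modulator becomes more selective", {
  dr <- dose_response(c(10, 100, 1000),
                      conc_grid = 10^seq(-8, 0, length.out = 33),
                      alpha = 1)
  ec <- dr$ec50
  expect_true(all(ec$monotone))
  expect_lt(ec$ec50_M[ec$selectivity == 10],
            ec$ec50_M[ec$selectivity == 100])
  expect_lt(ec$ec50_M[ec$selectivity == 100],
            ec$ec50_M[ec$selectivity == 1000])
  # normalized response saturates at 1
  top <- tapply(dr$curves$normalized, dr$curves$selectivity, max)
  expect_true(all(abs(top - 1) < 1e-9))
  expect_true(all(dr$curves$normalized >= -1e-9 &
                    dr$curves$normalized <= 1 + 1e-9))
})

test_that("over-selective modulators lose potency at low concentration", {
  # at 10 uM and alpha = 0.5, selectivity 10 beats selectivity 10000
  g_lo <- uptake_gain(positive_scheme_builder(10), 0.5, 1e-5)
  g_hi <- uptake_gain(positive_scheme_builder(10000), 0.5, 1e-5)
  expect_gt(g_lo, g_hi)
  expect_gt(g_lo, 1.5)
  expect_lt(g_hi, 1.5)

  # bell-shaped selectivity-gain relation at alpha = 1, 10 uM
  gs <- gain_vs_selectivity(1, 1e-5,
                            selectivity_grid = 10^seq(0, 4, by = 0.25))
  i_max <- which.max(gs$gain)
  expect_gt(i_max, 1)
  expect_lt(i_max, nrow(gs))
  expect_equal(gs$gain[gs$selectivity == 1], 1, tolerance = 1e-3)
  # saturating concentration instead: gain tracks the selectivity
  gs_sat <- gain_vs_selectivity(1, 1,
                                selectivity_grid = c(10, 100))
  expect_equal(gs_sat$gain, c(10, 100), tolerance = 0.05)
})

test_that("capping the second step flattens the attainable gain", {
  sels <- c(10, 100, 1000)
  capped <- vapply(sels, function(s)
    uptake_gain(positive_scheme_builder(s, cap = 20), 1, 1), numeric(1))
  uncapped <- vapply(sels, function(s)
    uptake_gain(positive_scheme_builder(s), 1, 1), numeric(1))
  # 100-fold more selectivity buys less than 2.2-fold extra gain ...
  expect_lt(max(capped) / min(capped), 2.2)
  # ... instead of the ~43-fold spread without the cap
  expect_gt(max(uncapped) / min(uncapped), 20)
  # the modulated velocity can never exceed the capped step itself
  for (s in sels) {
    sc <- cap_second_step(build_positive_scheme(1, selectivity = s), 20)
    v_base <- steady_state(set_concentrations(sc, modulator = 0))$uptake_rate
    g <- uptake_gain(positive_scheme_builder(s, cap = 20), 1, 1)
    expect_lte(g * v_base, 20 + 1e-9)
  }
  # cap -> Inf recovers the uncapped scan exactly
  g_inf <- uptake_gain(positive_scheme_builder(10, cap = Inf), 1, 1)
  expect_equal(g_inf, uncapped[1], tolerance = 1e-12)
  # scan wrapper covers the full grid; at alpha = 0 only the slowed
  # backward return leak acts, leaving the gain near (not exactly) 1
  cg <- capped_gain_scan(20, sels, alpha_grid = c(0, 1), conc_m = 1)
  expect_equal(nrow(cg), 6)
  expect_true(all(abs(cg$gain[cg$alpha == 0] - 1) < 0.15))
})

test_that("negative modulators inhibit partially, with modest IC50 shifts", {
  inh <- inhibition_scan(c(10, 100, 1000), alpha_grid = 1,
                         conc_grid = 10^seq(-7, 0, length.out = 15))
  s <- inh$summary
  # residual uptake at saturation stays positive at every selectivity,
  # and shrinks as the modulator becomes more selective
  expect_true(all(s$residual_uptake_at_saturation > 0))
  resid <- s$residual_uptake_at_saturation[order(s$selectivity)]
  expect_true(all(diff(resid) < 0))
  # selectivity 10: uptake reduced only modestly (slowed translocation at
  # 10 s^-1 still beats the 2 s^-1 return step)
  expect_gt(s$residual_uptake_at_saturation[s$selectivity == 10], 0.7)
  # IC50 shifts modestly to the right with selectivity
  ic <- s$ic50_M[order(s$selectivity)]
  expect_true(all(diff(ic) > 0))
  expect_lt(ic[3] / ic[1], 100)
  # normalized uptake: 1 at zero concentration, non-increasing in dose
  for (sel in c(10, 1000)) {
    cur <- inh$grid[inh$grid$selectivity == sel, ]
    expect_true(all(diff(cur$normalized_uptake[order(cur$conc_M)]) <
                      1e-9))
    expect_true(all(cur$normalized_uptake > 0 &
                      cur$normalized_uptake <= 1 + 1e-9))
  }
  nb <- negative_scheme_builder(10)
  expect_equal(uptake_gain(nb, 1, 0), 1, tolerance = 1e-12)
})

test_that("quasi-steady-state reduction matches the relaxation spectrum", {
  # 10 us intermediate, composite rates ~100 s^-1: the two reductions
  # agree to better than 1%
  cr <- composite_from_observables(lifetime = 1e-5, branching = 0.5,
                                   k_fw_composite = 100,
                                   k_bw_composite = 100)
  expect_equal(cr$intermediate_lifetime, 1e-5, tolerance = 1e-9)
  q <- composite_reduce(cr, conc_m = 1e-3)
  r <- composite_reduce(cr, conc_m = 1e-3, method = "relaxation")
  expect_equal(q$k_fw, 100, tolerance = 1e-9)
  expect_equal(q$k_bw, 100, tolerance = 1e-9)
  expect_equal(q$k_fw_mod, r$k_fw_mod, tolerance = 0.01)
  expect_equal(q$k_bw_mod, r$k_bw_mod, tolerance = 0.01)
  expect_true(q$qssa_ok)

  # fully committed intermediate: composite forward rate is just `a`
  cr0 <- composite_reaction(a = 50, b = 0, c_ = 1e5, d = 20)
  expect_equal(composite_reduce(cr0, 0)$k_fw, 50, tolerance = 1e-12)

  # a slow intermediate triggers the approximation warning
  cr_slow <- composite_reaction(a = 100, b = 5, c_ = 5, d = 100)
  expect_warning(composite_reduce(cr_slow, 1e-3), "dubious")
})

test_that("composite equilibrium shifts by the ground-state ratio only", {
  set.seed(99)
  for (i in 1:50) {
    cr <- composite_reaction(
      a = 10^stats::runif(1, 1, 4), b = 10^stats::runif(1, 4, 6),
      c_ = 10^stats::runif(1, 4, 6), d = 10^stats::runif(1, 1, 4),
      alpha1 = stats::runif(1), alpha2 = stats::runif(1),
      kd_reactant = 10^stats::runif(1, -7, -5),
      kd_intermediate = 10^stats::runif(1, -7, -5),
      kd_product = 10^stats::runif(1, -7, -5))
    cm <- 10^stats::runif(1, -5, -2)
    red <- suppressWarnings(composite_reduce(cr, cm))
    shift <- (red$k_fw_mod / red$k_bw_mod) / (red$k_fw / red$k_bw)
    expect_equal(shift, red$s_product / red$s_reactant, tolerance = 1e-9)
  }
})

test_that("apparent alpha is derivation-invariant and bracketed", {
  # forward- and backward-derived alpha_app agree for random composites
  set.seed(123)
  for (i in 1:1000) {
    cr <- composite_reaction(
      a = 10^stats::runif(1, 1, 3), b = 10^stats::runif(1, 4, 6),
      c_ = 10^stats::runif(1, 4, 6), d = 10^stats::runif(1, 1, 3),
      alpha1 = stats::runif(1), alpha2 = stats::runif(1),
      kd_reactant = 1e-6, kd_intermediate = 10^stats::runif(1, -7, -4),
      kd_product = 1e-5)
    a_f <- suppressWarnings(alpha_app(cr, 1e-3))
    a_b <- suppressWarnings(alpha_app(cr, 1e-3, derivation = "backward"))
    expect_equal(a_f, a_b, tolerance = 1e-9)
  }

  # a degenerate composite (intermediate indistinguishable from the
  # product, exit much faster than re-entry) collapses to alpha1
  cr1 <- composite_reaction(a = 100, b = 10, c_ = 1e6, d = 1e-3,
                            alpha1 = 0.3, alpha2 = 0.8,
                            kd_reactant = 1e-6, kd_intermediate = 1e-5,
                            kd_product = 1e-5)
  expect_equal(alpha_app(cr1, 1e-3), 0.3, tolerance = 1e-3)

  # the default occluded-state scenario lies strictly inside the envelope
  # swept by the intermediate branching ratio
  envelope <- vapply(seq(0.02, 0.98, by = 0.04), function(beta) {
    alpha_app(composite_from_observables(branching = beta), 1e-3)
  }, numeric(1))
  a_mid <- alpha_app(composite_from_observables(branching = 0.5), 1e-3)
  expect_gt(a_mid, min(envelope) - 1e-12)
  expect_lt(a_mid, max(envelope) + 1e-12)
  # the envelope is a proper interval (the branching ratio matters)
  expect_gt(max(envelope) - min(envelope), 0.1)
})

test_that("scan export writes parseable tables and summaries", {
  g <- gain_vs_alpha(10, conc_list = 1, alpha_grid = c(0, 1))
  f <- tempfile(fileext = ".csv")
  write_scan_csv(g, f)
  back <- utils::read.csv(f)
  expect_equal(back$gain, g$gain, tolerance = 1e-15)
  unlink(f)

  inh <- inhibition_scan(10, alpha_grid = 1, conc_grid = c(1e-6, 1e-3, 1))
  f2 <- tempfile(fileext = ".csv")
  files <- write_scan_csv(inh, f2)
  expect_length(files, 2)
  summ <- jsonlite::read_json(files[2], simplifyVector = TRUE)
  expect_equal(summ$residual_uptake_at_saturation,
               inh$summary$residual_uptake_at_saturation,
               tolerance = 1e-12)
  unlink(files)
})
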