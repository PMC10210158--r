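ctx <- thermo_context() # 293.15 K, kappa = 1

test_that("Eyring conversions: attempt frequency, tenfold rule, inverses", {
  # zero barrier returns the universal attempt frequency kB*T/h
  expect_equal(barrier_to_rate(0, ctx), 6.108e12, tolerance = 1e-3)
  expect_equal(rate_to_barrier(ctx$attempt_frequency, ctx), 0,
               tolerance = 1e-9)
  # lowering the barrier by RT*ln(10) multiplies the rate by exactly 10
  dG <- 5e4
  expect_equal(barrier_to_rate(dG - ctx$RT * log(10), ctx) /
                 barrier_to_rate(dG, ctx), 10, tolerance = 1e-12)
  # a tenfold rate pair differs by RT*ln(10) ~ 5.6 kJ/mol in barrier height
  expect_equal(rate_to_barrier(0.2, ctx) - rate_to_barrier(2, ctx),
               ctx$RT * log(10), tolerance = 1e-12)
  expect_equal((rate_to_barrier(10, ctx) - rate_to_barrier(100, ctx)) /
                 1000, 5.6, tolerance = 0.01)
  # round trips over 21 decades of rate
  for (k in 10^seq(-6, 15, by = 1)) {
    expect_equal(barrier_to_rate(rate_to_barrier(k, ctx), ctx), k,
                 tolerance = 1e-10)
  }
  expect_equal(barrier_to_rate(rate_to_barrier(2, ctx), ctx), 2,
               tolerance = 1e-12)
})

test_that("invalid thermodynamic inputs are rejected", {
  expect_error(thermo_context(temperature = -1))
  expect_error(thermo_context(kappa = 0))
  expect_error(thermo_context(kappa = 1.5))
  expect_error(rate_to_barrier(0, ctx), "positive")
  expect_error(rate_to_barrier(-2, ctx), "positive")
  expect_error(barrier_to_rate(NaN, ctx), "landscape")
  expect_error(elementary_reaction(0, 2))
  expect_error(modulator_binding(0, 1e-6, 1e-3))
  expect_error(modulator_binding(1e-6, 1e-6, -1))
})

test_that("ground-state stabilization follows the binding polynomial", {
  expect_identical(stabilization_energy(1e-6, 0, ctx), 0)
  # 1 uM KD at 1 mM ligand: -RT*ln(1001) ~ -16.8 kJ/mol
  expect_equal(stabilization_energy(1e-6, 1e-3, ctx),
               -ctx$RT * log(1001), tolerance = 1e-12)
  expect_equal(stabilization_energy(1e-6, 1e-3, ctx) / 1000, -16.84,
               tolerance = 1e-3)
  expect_true(all(stabilization_energy(1e-6, 10^seq(-9, 0), ctx) <= 0))
  # the gap between a 10 uM and a 1 uM site at 1 mM is ~5.6 kJ/mol ...
  gap <- abs(stabilization_energy(1e-6, 1e-3, ctx) -
               stabilization_energy(1e-5, 1e-3, ctx))
  expect_equal(gap / 1000, 5.6, tolerance = 0.01)
  # ... and tends to exactly RT*ln(rho) at saturation
  gap_sat <- abs(stabilization_energy(1e-6, 10, ctx) -
                   stabilization_energy(1e-5, 10, ctx))
  expect_equal(gap_sat, ctx$RT * log(10), tolerance = 1e-4)
})

test_that("LFER transform reproduces the limiting-alpha rate changes", {
  rxn <- elementary_reaction(2, 2)
  b <- modulator_binding(kd_reactant = 1e-5, kd_product = 1e-6,
                         concentration = 1e-3)
  s_ratio <- (1 + 1e-3 / 1e-6) / (1 + 1e-3 / 1e-5) # s_P / s_R

  # non-selective ligand leaves both rates untouched at any alpha
  b_eq <- modulator_binding(1e-6, 1e-6, 1e-3)
  for (a in c(-1, 0, 0.5, 1, 2)) {
    sh <- lfer_apply(rxn, b_eq, ctx, alpha = a)
    expect_equal(sh$k_fw_new, 2, tolerance = 1e-12)
    expect_equal(sh$k_bw_new, 2, tolerance = 1e-12)
  }

  # alpha = 0: forward untouched, backward drops from 2 to ~0.2
  sh0 <- lfer_apply(rxn, b, ctx, alpha = 0)
  expect_equal(sh0$k_fw_new, 2, tolerance = 1e-12)
  expect_equal(sh0$k_bw_new, 2 / s_ratio, tolerance = 1e-12)
  expect_equal(sh0$k_bw_new, 0.2, tolerance = 0.01)

  # alpha = 1: forward increases ~tenfold, backward untouched
  sh1 <- lfer_apply(rxn, b, ctx, alpha = 1)
  expect_equal(sh1$k_fw_new, 2 * s_ratio, tolerance = 1e-12)
  expect_equal(sh1$k_bw_new, 2, tolerance = 1e-12)

  # alpha = 0.5: forward multiplied by sqrt(s_P/s_R) ~ 3.15
  sh5 <- lfer_apply(rxn, b, ctx, alpha = 0.5)
  expect_equal(sh5$k_fw_new / 2, sqrt(s_ratio), tolerance = 1e-12)
  expect_equal(sh5$k_fw_new / 2, 3.148, tolerance = 1e-3)

  # LFER placement invariant of the returned shift
  for (a in c(0, 0.3, 1, 2)) {
    sh <- lfer_apply(rxn, b, ctx, alpha = a)
    expect_equal(sh$ddG_ts,
                 a * sh$ddG_product + (1 - a) * sh$ddG_reactant,
                 tolerance = 1e-12)
  }
})

test_that("equilibrium shift is alpha-independent and affinity-ratio-scaled", {
  rxn <- elementary_reaction(3, 0.7)
  set.seed(42)
  for (i in 1:25) {
    kd_R <- 10^stats::runif(1, -8, -4)
    rho <- 10^stats::runif(1, -2, 2)
    conc <- 10^stats::runif(1, -7, -1)
    bind <- modulator_binding(kd_R, kd_R / rho, conc)
    ratios <- vapply(seq(-1, 2, by = 0.25), function(a) {
      sh <- lfer_apply(rxn, bind, ctx, alpha = a)
      sh$k_fw_new / sh$k_bw_new
    }, numeric(1))
    expect_equal(max(ratios) / min(ratios), 1, tolerance = 1e-9)
    # and it equals the thermodynamically required value
    expect_equal(ratios[1] / (rxn$k_fw / rxn$k_bw),
                 (1 + conc / (kd_R / rho)) / (1 + conc / kd_R),
                 tolerance = 1e-9)
  }

  # micromolar and nanomolar ligands with the same conc/K_D act identically
  rxn22 <- elementary_reaction(2, 2)
  lo <- lfer_apply(rxn22, modulator_binding(1e-5, 1e-6, 1e-3), ctx,
                   alpha = 0.5)
  hi <- lfer_apply(rxn22, modulator_binding(1e-8, 1e-9, 1e-6), ctx,
                   alpha = 0.5)
  expect_equal(lo$k_fw_new, hi$k_fw_new, tolerance = 1e-12)
  expect_equal(lo$k_bw_new, hi$k_bw_new, tolerance = 1e-12)

  # forward rate strictly increasing in alpha when the product state is
  # stabilized more than the reactant state
  b <- modulator_binding(1e-5, 1e-6, 1e-3)
  kf <- vapply(seq(0, 1, by = 0.1), function(a)
    lfer_apply(rxn22, b, ctx, alpha = a)$k_fw_new, numeric(1))
  expect_true(all(diff(kf) > 0))
})

test_that("alpha extraction inverts the LFER transform", {
  expect_equal(extract_alpha(-5, -5, -20), 0)
  expect_equal(extract_alpha(-20, -5, -20), 1)
  expect_error(extract_alpha(-3, -5, -5), "undefined")

  rxn <- elementary_reaction(2, 2)
  b <- modulator_binding(1e-5, 1e-6, 1e-3)
  for (a_star in c(-1, 0, 0.27, 0.5, 1, 2)) {
    sh <- lfer_apply(rxn, b, ctx, alpha = a_star)
    expect_equal(extract_alpha(sh$ddG_ts, sh$ddG_reactant, sh$ddG_product),
                 a_star, tolerance = 1e-9)
    expect_identical(sh$lfer_compliant, a_star >= 0 && a_star <= 1)
  }

  # recovery from the rate changes alone, over random draws
  set.seed(7)
  for (i in 1:1000) {
    a_star <- stats::runif(1, -1, 2)
    kd_R <- 10^stats::runif(1, -8, -4)
    kd_P <- 10^stats::runif(1, -8, -4)
    conc <- 10^stats::runif(1, -6, -1)
    if (abs(log(kd_R / kd_P)) < 1e-3) next # near-degenerate perturbation
    bind <- modulator_binding(kd_R, kd_P, conc)
    sh <- lfer_apply(rxn, bind, ctx, alpha = a_star)
    ddG_R <- stabilization_energy(kd_R, conc, ctx)
    ddG_P <- stabilization_energy(kd_P, conc, ctx)
    ddG_ts <- ddG_R - ctx$RT * log(sh$k_fw_new / rxn$k_fw)
    expect_equal(extract_alpha(ddG_ts, ddG_R, ddG_P), a_star,
                 tolerance = 1e-8)
  }
})

test_that("balanced-pair enumeration traces the detailed-balance continuum", {
  rxn <- elementary_reaction(2, 2)
  b <- modulator_binding(1e-5, 1e-6, 1e-3)
  grid <- seq(-1, 2, by = 0.05)
  tab <- enumerate_balanced_pairs(rxn, b, grid, ctx)
  expect_equal(nrow(tab), length(grid))

  # every row shares the detailed-balance-pinned rate ratio
  ratio <- tab$k_fw / tab$k_bw
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-9)

  # consistency with lfer_apply at alpha = 0.5
  sh <- lfer_apply(rxn, b, ctx, alpha = 0.5)
  i <- which.min(abs(tab$alpha - 0.5))
  expect_equal(tab$k_fw[i], sh$k_fw_new, tolerance = 1e-12)
  expect_equal(tab$k_bw[i], sh$k_bw_new, tolerance = 1e-12)

  # the (8, 0.8) pair lies on the continuum (at alpha = log 4 / log ~10)
  s_ratio <- (1 + 1e3) / (1 + 1e2)
  a8 <- log(8 / 2) / log(s_ratio)
  sh8 <- lfer_apply(rxn, b, ctx, alpha = a8)
  expect_equal(sh8$k_fw_new, 8, tolerance = 1e-12)
  expect_equal(sh8$k_bw_new, 0.8, tolerance = 0.01)
  expect_true(sh8$lfer_compliant)

  # rows outside [0, 1] are flagged, not dropped
  expect_identical(tab$lfer_compliant, grid >= 0 & grid <= 1)

  # TSV export round-trips numerically at 17 digits
  path <- tempfile(fileext = ".tsv")
  write_landscape_tsv(tab, path)
  back <- utils::read.delim(path)
  expect_equal(back$k_fw, tab$k_fw, tolerance = 1e-15)
  unlink(path)
})
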