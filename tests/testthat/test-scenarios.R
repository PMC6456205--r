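test_that("scenarios are pure parameter transformations", {
  p <- default_normal_eye()
  p_snapshot <- unclass(p)
  sc <- scenario_supine(p)
  p2 <- apply_scenario(p, sc)
  expect_equal(p2$p_back, 3)
  expect_equal(p2$p_CSF, 9)
  expect_identical(unclass(p), p_snapshot)   # original untouched
  # identity scenario reproduces the baseline exactly
  ident <- scenario("identity", list(p_back = 0, p_CSF = 3))
  expect_equal(unclass(apply_scenario(p, ident)), p_snapshot)
})

test_that("the nocturnal scenario applies the three reported modifications", {
  sc <- scenario_nocturnal_nau(default_normal_eye())
  expect_equal(sc$overrides$production_rate, 0.65 * 0.94 * 6.14,
               tolerance = 1e-12)
  expect_equal(sc$overrides$c_ap_SL, 0.325)
  expect_equal(sc$overrides$alpha, 0.10)
  scs <- scenario_nocturnal_nau(default_normal_eye(), supine = TRUE)
  expect_equal(scs$overrides$p_back, 3)
  expect_equal(scs$overrides$p_CSF, 9)
})

test_that("the tamponade coverage map is monotone and hits the measured points", {
  m <- tamponade_map()
  expect_true(all(diff(m$coverage_pct) > 0))
  expect_equal(tamponade_coverage(c(45, 60, 75, 90)), c(20, 30, 45, 68))
  expect_equal(tamponade_coverage(0), 0)
  expect_equal(tamponade_coverage(100), 100)
  expect_error(tamponade_coverage(120), "\\[0, 100\\]")
  # inverse map round-trips on the interior
  expect_equal(tamponade_fill(tamponade_coverage(c(30, 50, 80))),
               c(30, 50, 80), tolerance = 1e-9)
  # 0 % fill leaves the parameters at baseline
  sc0 <- scenario_tamponade(default_normal_eye(), 0)
  expect_equal(sc0$overrides$c_pre_SL, 0.5)
})

test_that("production calibration converges and is a fixed point at the target", {
  p <- calibrated_params()
  expect_equal(iop(solve_eye(p, normal_mesh())), 15, tolerance = 0.01 / 15)
  # calibrating to the current IOP leaves production unchanged
  p2 <- calibrate_production(p, iop(solve_eye(p, normal_mesh())),
                             normal_mesh())
  expect_equal(p2$production_rate, p$production_rate, tolerance = 1e-9)
  # the lower daytime operating point of the aqueous-flow study
  p3 <- calibrate_production(p, 13.9, normal_mesh())
  expect_equal(p3$production_rate, 5.78, tolerance = 0.02)
})

test_that("scenario runs reproduce the reported IOPs", {
  base <- calibrated_params()
  expect_equal(iop(solve_scenario(scenario_nau_daytime(base), base)), 13.9,
               tolerance = 0.3 / 13.9)
  expect_equal(iop(solve_scenario("nocturnal_upright", base)), 13.0,
               tolerance = 0.3 / 13)
  expect_equal(iop(solve_scenario("nocturnal_supine", base)), 16.0,
               tolerance = 0.4 / 16)
  expect_equal(iop(solve_scenario("ntg1", base)), 21.0, tolerance = 0.4 / 21)
  expect_equal(iop(solve_scenario("schwartz_matsuo_0.148", base)), 32.9,
               tolerance = 0.10)
  expect_equal(iop(solve_scenario("tamponade_45", base)) - 15, 2.0,
               tolerance = 0.25)
})

test_that("scenario TLPGs reproduce the reported posture/nocturnal values", {
  tlpg_of <- function(s) compute_tlpg(extract_axial_profile(s))$tlpg
  expect_equal(tlpg_of(cached("sol_supine", solve_scenario("supine"))),
               14.7, tolerance = 0.10)
  expect_equal(tlpg_of(cached("sol_noct_up", solve_scenario("nocturnal_upright"))),
               16.6, tolerance = 0.10)
  expect_equal(tlpg_of(cached("sol_noct_sup", solve_scenario("nocturnal_supine"))),
               11.3, tolerance = 0.10)
  expect_equal(tlpg_of(cached("sol_ntg2", solve_scenario("ntg2"))),
               46.1, tolerance = 0.10)
  # supine LC drop 17.3 - 11.7 = 5.6 mmHg
  rep <- compute_tlpg(extract_axial_profile(cached("sol_supine", NULL)))
  expect_equal(rep$p_upstream - rep$p_downstream, 5.6, tolerance = 0.10)
})

test_that("the Schwartz-Matsuo variants bracket the observed cohort IOP", {
  base <- calibrated_params()
  sc <- scenario_schwartz_matsuo(base, 0.5)
  expect_equal(iop(solve_scenario(sc, base)), 15, tolerance = 0.3 / 15)
  boosted <- scenario_schwartz_matsuo(base, 0.148, production_boost = 0.045)
  expect_gt(iop(solve_scenario(boosted, base)), 33)
  expect_error(scenario_schwartz_matsuo(base, 0.6), "c_ap_value")
})

test_that("the inverse tamponade fit recovers the cohort conductivities", {
  base <- calibrated_params()
  fit16 <- cached("jonas16",
                  scenario_jonas_tamponade_inverse(base, normal_mesh(), 16))
  expect_equal(fit16$baseline_iop, 13, tolerance = 0.3 / 13)
  expect_equal(fit16$c_pre_SL, 0.33, tolerance = 0.10)
  fit21 <- scenario_jonas_tamponade_inverse(base, normal_mesh(), 21)
  expect_equal(fit21$c_pre_SL, 0.19, tolerance = 0.10)
  expect_gt(fit21$fill_pct, fit16$fill_pct)
  # target at the baseline returns the unreduced conductivity
  fit0 <- scenario_jonas_tamponade_inverse(base, normal_mesh(),
                                           fit16$baseline_iop)
  expect_equal(fit0$c_pre_SL, 0.5)
  expect_error(scenario_jonas_tamponade_inverse(base, normal_mesh(), 10),
               "below the baseline")
})

test_that("IOP sensitivities match the reported one-at-a-time table", {
  tb <- cached("sens", sensitivity_scan(calibrated_params(), normal_mesh()))
  g <- function(nm) tb$pct_change_iop[tb$parameter == nm]
  expect_equal(g("production_rate"), 13.3, tolerance = 0.10)
  expect_equal(g("c_total_SL"), -10.3, tolerance = 0.10)
  expect_equal(g("alpha"), 8.1, tolerance = 0.10)
  expect_equal(g("p_T"), 4.6, tolerance = 0.10)
  expect_equal(g("p_back"), 10, tolerance = 0.10)
  # optic nerve parameters barely move the IOP
  expect_lt(abs(g("p_CSF")), 0.5)
  expect_lt(abs(g("k_ONLC")), 0.5)
})

test_that("the outflow-split scan matches the reported IOP table", {
  tb <- cached("split", outflow_split_scan(calibrated_params(),
                                           mesh = normal_mesh()))
  g <- function(f) tb$iop_mmHg[abs(tb$anterior_fraction - f) < 1e-9]
  expect_equal(g(0.35), 15.41, tolerance = 0.01)
  expect_equal(g(0.5), 15.0, tolerance = 0.01)
  expect_equal(g(0.65), 14.70, tolerance = 0.01)
  # IOP is monotone decreasing in the anterior fraction (and so in both
  # surface conductivities at fixed total)
  expect_true(all(diff(tb$iop_mmHg) < 0))
})

test_that("sequentially introduced resistances reproduce the build-up record", {
  tb <- cached("seq", sequential_resistance_study(calibrated_params(),
                                                  normal_mesh()))
  d <- function(step) tb$delta_iop_mmHg[tb$step == step]
  expect_equal(tb$iop_mmHg[tb$step == "uniform"], 15, tolerance = 0.02 / 15)
  expect_equal(d("retina_5e-12"), 0.006, tolerance = 0.5)
  expect_equal(d("vitreous_8.4e-11"), 0.05, tolerance = 0.5)
  expect_equal(d("vitreous_1e-11_variant"), 0.41, tolerance = 0.25)
})

test_that("pial conductivity calibration matches its anchor and limits", {
  m <- coarse_mesh()
  p <- default_normal_eye()
  pf <- cached("pial", calibrate_pial_conductivity(p, m, target_pressure = 4))
  expect_equal(pf$h_ON, 1.5e-11, tolerance = 0.3)
  # published value -> retrolaminar pressure ~3.5 mmHg at zero CSF pressure
  p0 <- update_params(p, p_CSF = 0)
  expect_equal(nerve_pressure(solve_eye(p0, m)), 3.5, tolerance = 0.5 / 3.5)
  # Robin limits: huge h clamps the nerve to CSF pressure, tiny h lets it
  # rise towards the supply pressure
  np <- function(h) nerve_pressure(solve_eye(update_params(p0, h_ON = h), m))
  expect_equal(np(1e-6), 0, tolerance = 0.1)
  expect_gt(np(1e-15), np(1.5e-11))
  expect_gt(np(1e-15), 10)
})

test_that("ONH conductivity validation keeps the laminar share in range", {
  v <- calibrate_onh_conductivities(default_normal_eye(), mesh = coarse_mesh(),
                                    validate = TRUE)
  expect_gte(v$laminar_fraction, 0.80)
  expect_lte(v$laminar_fraction, 0.88)
})
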