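synthetic_profile <- function(z, p, lc_a, lc_p) {
  prof <- tibble::tibble(z_m = z, z_mm = z * 1e3, p_mmHg = p)
  attr(prof, "lc_anterior_z") <- lc_a
  attr(prof, "lc_posterior_z") <- lc_p
  attr(prof, "axis_z") <- z
  attr(prof, "axis_p") <- p
  class(prof) <- c("axial_profile", class(prof))
  prof
}

test_that("TLPG arithmetic is exact on synthetic profiles", {
  # linear drop of 7.6 mmHg across 0.38 mm -> exactly 20 mmHg/mm
  z <- seq(-1e-3, 1e-3, length.out = 201)  # kinks at +/-0.19 mm on-grid
  p <- 10 - 7.6 * (pmin(pmax(z, -0.19e-3), 0.19e-3) + 0.19e-3) / 0.38e-3
  prof <- synthetic_profile(z, p, lc_a = -0.19e-3, lc_p = 0.19e-3)
  # markers: anterior face is the high-pressure (larger z in the eye) side;
  # here use the constructed geometry directly
  prof2 <- synthetic_profile(z, rev(p), lc_a = 0.19e-3, lc_p = -0.19e-3)
  rep2 <- compute_tlpg(prof2)
  expect_equal(rep2$tlpg, 20.0, tolerance = 1e-9)
  expect_equal(rep2$p_upstream - rep2$p_downstream, 7.6, tolerance = 1e-9)
})

test_that("a flat profile yields zero gradient and degenerate markers error", {
  z <- seq(-1e-3, 1e-3, length.out = 60)
  prof <- synthetic_profile(z, rep(12, 60), lc_a = 0.2e-3, lc_p = -0.2e-3)
  expect_equal(compute_tlpg(prof)$tlpg, 0)
  expect_error(compute_tlpg(prof, lc_thickness_mm = 0), "degenerate")
})

test_that("the normal-eye axial profile matches the reported pressures", {
  s <- calibrated_solution()
  prof <- extract_axial_profile(s)
  expect_error(extract_axial_profile(s, n_samples = 10), "n_samples")
  # monotone non-increasing from vitreous to nerve (z ascending)
  expect_true(all(diff(prof$p_mmHg) >= -1e-3))
  rep <- compute_tlpg(prof)
  expect_equal(rep$p_upstream, 14.0, tolerance = 0.5 / 14)    # LC anterior face
  expect_equal(rep$p_downstream, 6.5, tolerance = 0.5 / 6.5)  # LC posterior face
  expect_equal(rep$tlpg, 19.7, tolerance = 0.10)
  expect_equal(rep$laminar_fraction, 0.82, tolerance = 0.10)
  expect_equal(nerve_pressure(s), 5.7, tolerance = 0.5 / 5.7) # mid-nerve
  # the steepest axial segment lies within the lamina cribrosa
  grad <- abs(diff(prof$p_mmHg) / diff(prof$z_mm))
  zmid <- (prof$z_m[-1] + prof$z_m[-nrow(prof)]) / 2
  imax <- which.max(grad)
  expect_true(zmid[imax] <= attr(prof, "lc_anterior_z") &&
              zmid[imax] >= attr(prof, "lc_posterior_z"))
})

test_that("the flow partition reproduces the reported outflow split", {
  part <- flow_partition(calibrated_solution())
  expect_equal(sum(part$fraction), 1, tolerance = 2e-3)
  expect_equal(part$fraction[part$route == "anterior"], 0.515,
               tolerance = 0.10)
  expect_equal(part$fraction[part$route == "onh"], 0.0042, tolerance = 0.10)
})

test_that("removing the RPE route sends all flow anterior and through the ONH", {
  p <- update_params(calibrated_params(), c_pre_SL = 0)
  part <- flow_partition(solve_eye(p, normal_mesh()))
  a <- part$fraction[part$route == "anterior"] +
       part$fraction[part$route == "onh"]
  expect_equal(a, 1, tolerance = 2e-3)
})

test_that("lamina cribrosa velocities match the reported magnitudes", {
  vel <- lc_velocities(calibrated_solution(), porosity = 0.70)
  vc <- vel$v_darcy_um_s[vel$location == "centreline"]
  vp <- vel$v_darcy_um_s[vel$location == "periphery"]
  expect_equal(vc, 0.209, tolerance = 0.10)
  expect_equal(vp, 0.216, tolerance = 0.10)
  expect_equal(vel$v_true_um_s[vel$location == "centreline"], 0.30,
               tolerance = 0.10)
  # porosity 1 collapses true velocity onto the Darcy velocity
  v1 <- lc_velocities(calibrated_solution(), porosity = 1 - 1e-12)
  expect_equal(v1$v_true_um_s, v1$v_darcy_um_s, tolerance = 1e-9)
})

test_that("factors of safety follow their defining ratios", {
  sf <- safety_factors(19.7, 0.30)
  expect_equal(sf$fos_gradient, 1.52, tolerance = 0.005)
  expect_equal(sf$fos_dynein, 2.0, tolerance = 1e-9)
  # dynein stall condition: fluid at the mean retrograde transport speed
  st <- safety_factors(19.7, 0.6)
  expect_equal(st$v_dynein_mean_um_s, 0)
  expect_equal(st$fos_dynein, 1)
  # non-positive inputs are flagged, not numeric errors
  rev <- safety_factors(-5, -0.1)
  expect_true(is.na(rev$fos_gradient))
  expect_match(attr(rev, "note"), "not at risk")
  expect_equal(dynein_drag(2e-8, 0.3e-6), 6e-15)
})

test_that("the two safety factors co-vary within a factor of two", {
  for (s in list(calibrated_solution(),
                 cached("sol_ntg1", solve_scenario("ntg1")))) {
    summ <- summarise_solution(s)
    expect_gt(summ$fos_gradient / summ$fos_dynein, 0.5)
    expect_lt(summ$fos_gradient / summ$fos_dynein, 2)
  }
})
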