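# The integrated outflow law F(p) = (C/alpha)(exp(-alpha pT) -
# exp(-alpha (p - pback))) is the antiderivative of the instantaneous
# facility C exp(-alpha (x - pback)) between the no-flow pressure and p, so
# numerical quadrature of the facility is an independent oracle for it.

quad_outflow <- function(p, c_SL, alpha, p_T, p_back = 0) {
  stats::integrate(function(x) c_SL * exp(-alpha * (x - p_back)),
                   lower = p_T + p_back, upper = p, rel.tol = 1e-12)$value
}

test_that("pathway outflow matches quadrature of the instantaneous facility", {
  cases <- expand.grid(p = c(5, 13.9, 19, 30), c_SL = c(0.12, 0.5, 1.0),
                       alpha = c(0.05, 0.075, 0.10), p_back = c(0, 3))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    spec <- pathway_spec(cs$c_SL, cs$alpha, p_T = 3, p_back = cs$p_back)
    expect_equal(pathway_outflow(cs$p, spec, quiet = TRUE),
                 quad_outflow(cs$p, cs$c_SL, cs$alpha, 3, cs$p_back),
                 tolerance = 1e-9)
  }
})

test_that("anterior outflow reproduces the reported operating points", {
  anterior <- pathway_spec(0.5, 0.075, 3, 0)
  expect_equal(pathway_outflow(13.9, anterior), 2.97, tolerance = 0.005)
  expect_equal(pathway_outflow(3, anterior), 0)        # no-flow pressure
  # direct closed-form evaluation, frozen: 5 (e^-0.3 - e^-1.9)
  expect_equal(pathway_outflow(19, pathway_spec(0.5, 0.10, 3, 0)),
               2.956248, tolerance = 1e-6)
})

test_that("tonographic facility matches the reported day/night values", {
  expect_equal(tonographic_facility(19, pathway_spec(0.5, 0.075, 3, 0)),
               0.233, tolerance = 0.005)
  expect_equal(tonographic_facility(19, pathway_spec(0.5, 0.10, 3, 0)),
               0.185, tolerance = 0.005)
  # limit p -> pT+: facility -> C exp(-alpha pT) = 0.399 for the normal
  # anterior pathway (L'Hopital on the closed form)
  expect_equal(tonographic_facility(3 + 1e-7, pathway_spec(0.5, 0.075, 3, 0)),
               0.5 * exp(-0.075 * 3), tolerance = 1e-6)
  expect_error(tonographic_facility(3, pathway_spec(0.5, 0.075, 3, 0)),
               "no-flow")
})

test_that("solve_iop agrees with an independent bisection oracle", {
  pw <- list(pathway_spec(0.6, 0.075, 3, 0),
             pathway_spec(0.4, 0.10, 3, 1))
  for (q in c(0.5, 3, 6, 9)) {
    oracle <- bisect(function(p)
      pathway_outflow(p, pw[[1]], quiet = TRUE) +
      pathway_outflow(p, pw[[2]], quiet = TRUE) - q, lo = 4, hi = 200)
    expect_equal(solve_iop(q, pw), oracle, tolerance = 1e-8)
  }
})

test_that("the initial single-pathway model predicts 15 mmHg at 6.32 uL/min", {
  expect_equal(solve_iop(6.32, pathway_spec(1.0, 0.075, 3, 0)), 15.0,
               tolerance = 0.005)
  expect_equal(solve_production(15, pathway_spec(1.0, 0.075, 3, 0)), 6.32,
               tolerance = 0.005)
})

test_that("zero production settles at the no-flow pressure", {
  expect_equal(solve_iop(0, pathway_spec(0.5, 0.075, 3, 2)), 5)
  expect_equal(solve_production(3, pathway_spec(0.5, 0.075, 3, 0)), 0)
})

test_that("production above the saturation outflow is rejected", {
  # saturation (C/alpha) exp(-alpha pT) = 10.65 uL/min for the normal eye pair
  pw <- list(pathway_spec(0.5, 0.075, 3, 0), pathway_spec(0.5, 0.075, 3, 0))
  expect_error(solve_iop(11, pw), "unsustainable")
})

test_that("a series resistance on the RPE route raises the solved IOP", {
  # mirrors the 90%-fill tamponade balance: c_ap 0.5 direct, c_pre 0.16 with
  # a 0.407 mmHg/(uL/min) series drop
  pw <- list(pathway_spec(0.5, 0.075, 3, 0),
             pathway_spec(0.16, 0.075, 3, 0, series_resistance = 0.407))
  oracle <- bisect(function(p)
    pathway_outflow(p, pw[[1]], quiet = TRUE) +
    pathway_outflow(p, pw[[2]], quiet = TRUE) - 6.14, lo = 3, hi = 200)
  io <- solve_iop(6.14, pw)
  expect_equal(io, oracle, tolerance = 1e-8)
  # frozen oracle value; the full model's 90%-fill case sits ~1 mmHg lower
  # because its optic-nerve-head leak grows with IOP
  expect_equal(io, 30.75, tolerance = 0.01)
})

test_that("solve_iop and solve_production are mutual inverses", {
  pw <- lumped_pathways(default_normal_eye())
  for (p0 in c(8, 15, 25)) {
    expect_equal(solve_iop(solve_production(p0, pw), pw), p0,
                 tolerance = 1e-8)
  }
})

test_that("outflow is strictly increasing and concave in pressure", {
  spec <- pathway_spec(0.5, 0.075, 3, 0)
  p <- seq(4, 60, by = 0.5)
  f <- pathway_outflow(p, spec, quiet = TRUE)
  expect_true(all(diff(f) > 0))
  expect_true(all(diff(diff(f)) < 0))
})

test_that("lumped IOP is monotone in production, conductivity and alpha", {
  base <- function(...) {
    p <- update_params(default_normal_eye(), ...)
    solve_iop(p$production_rate, lumped_pathways(p))
  }
  expect_true(base() < base(production_rate = 7))
  expect_true(base() > base(c_ap_SL = 0.6))
  expect_true(base() > base(c_pre_SL = 0.6))
  expect_true(base() < base(alpha = 0.09))
})

test_that("backpressure shifts the lumped IOP one-to-one", {
  p0 <- default_normal_eye()
  p3 <- update_params(p0, p_back = 3)
  # the linear ONH route is referenced to p_CSF, which moves with posture,
  # so the pure two-pathway surrogate shows the exact 1:1 shift
  i0 <- solve_iop(6.14, lumped_pathways(p0, onh_facility = NULL))
  i3 <- solve_iop(6.14, lumped_pathways(p3, onh_facility = NULL))
  expect_equal(i3 - i0, 3, tolerance = 1e-8)
})

test_that("backflow below the no-flow pressure is flagged", {
  expect_warning(pathway_outflow(2, pathway_spec(0.5, 0.075, 3, 0)),
                 "backflow")
})
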