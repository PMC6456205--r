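test_that("the solver reproduces the log-radial annulus solution to 0.1 %", {
  an <- make_fixture("annulus", n = 12)
  k <- 1e-13
  s <- solve_darcy(an, c(shell = k),
                   list(inner_face = bc_pressure(20), outer_face = bc_pressure(5),
                        end_faces = bc_impermeable()))
  r <- an$nodes[, 1]
  p_exact <- 20 + (5 - 20) * log(r / 5e-3) / log(2)
  expect_lt(max(abs(Pa_to_mmHg(s$pressure_Pa) - p_exact)) / 15, 1e-3)
  # radial Darcy speed v(r) = k dp/dr = k DP / (ln(r2/r1) r) at the centroid
  v <- darcy_velocity_field(s)
  v_exact <- k * mmHg_to_Pa(15) / (log(2) * v$r)
  expect_lt(max(abs(v$speed - v_exact) / v_exact), 5e-3)
  expect_true(all(abs(v$vz) < 1e-3 * v$speed + 1e-15))
  # net through-flux matches the closed form 2 pi k H DP / ln(r2/r1)
  q_exact <- m3s_to_ulmin(2 * pi * k * 4e-3 * mmHg_to_Pa(15) / log(2))
  expect_equal(boundary_flux(s, "outer_face"), q_exact, tolerance = 1e-3)
  expect_equal(boundary_flux(s, "inner_face"), -q_exact, tolerance = 1e-3)
})

test_that("the solver reproduces the 1/rho spherical-shell solution to 0.1 %", {
  sh <- make_fixture("sphere_shell", n = 20)
  s <- solve_darcy(sh, c(shell = 1e-13),
                   list(inner_face = bc_pressure(20), outer_face = bc_pressure(5),
                        end_faces = bc_impermeable(),
                        symmetry_axis = bc_impermeable()))
  rho <- sqrt(rowSums(sh$nodes^2))
  p_exact <- 20 + (5 - 20) * (1 / 5e-3 - 1 / rho) / (1 / 5e-3 - 1 / 10e-3)
  expect_lt(max(abs(Pa_to_mmHg(s$pressure_Pa) - p_exact)) / 15, 1e-3)
})

test_that("zero production with outflow conditions everywhere gives p = pT + pback", {
  m <- coarse_mesh()
  p <- normal_params()
  bcs <- boundary_conditions(update_params(p, p_back = 1), Q = 0)
  bcs$pia_interface <- bc_outflow(0.1, p$alpha, p$p_T, p_back = 1)
  s <- solve_darcy(m, material_field(p), bcs, control = list(tol_Pa = 1e-5))
  expect_equal(range(Pa_to_mmHg(s$pressure_Pa)), c(4, 4), tolerance = 1e-7)
  # a uniform pressure field implies zero Darcy velocity (to round-off,
  # even through the enormous chamber conductivity)
  s_uniform <- s
  s_uniform$pressure_Pa[] <- mmHg_to_Pa(4)
  expect_lt(max(darcy_velocity_field(s_uniform)$speed), 1e-9)
})

test_that("the normal eye solves to the clinical operating point", {
  s <- normal_solution()
  expect_true(s$converged)
  expect_equal(iop(s), 15.0, tolerance = 0.3 / 15)
  expect_lt(mass_balance_error(s), 1e-3)
  # mid-vitreous Darcy speeds are of order 0.1 um/s
  v <- darcy_velocity_field(s)
  mid <- v$region == "vitreous" & abs(v$z) < 4e-3 & v$r < 6e-3
  expect_gt(stats::median(v$speed[mid]), 1e-8)
  expect_lt(stats::median(v$speed[mid]), 1e-6)
})

test_that("with linear Robin conditions the solver equals a hand-assembled system", {
  an <- make_fixture("annulus", n = 3)
  k <- 2e-13
  h_in <- 3e-9; h_out <- 1e-9
  p_in <- mmHg_to_Pa(18); p_out <- mmHg_to_Pa(4)
  s <- solve_darcy(an, c(shell = k),
                   list(inner_face = bc_robin(h_in, 18),
                        outer_face = bc_robin(h_out, 4),
                        end_faces = bc_impermeable()))
  # independent dense assembly of the identical linear system
  nn <- nrow(an$nodes)
  A <- matrix(0, nn, nn); b <- numeric(nn)
  for (e in seq_len(nrow(an$triangles))) {
    idx <- an$triangles[e, ]
    P <- an$nodes[idx, ]
    twoA <- (P[2, 1] - P[1, 1]) * (P[3, 2] - P[1, 2]) -
            (P[3, 1] - P[1, 1]) * (P[2, 2] - P[1, 2])
    bb <- c(P[2, 2] - P[3, 2], P[3, 2] - P[1, 2], P[1, 2] - P[2, 2]) / twoA
    cc <- c(P[3, 1] - P[2, 1], P[1, 1] - P[3, 1], P[2, 1] - P[1, 1]) / twoA
    w <- 2 * pi * mean(P[, 1]) * (twoA / 2) * k
    A[idx, idx] <- A[idx, idx] + w * (outer(bb, bb) + outer(cc, cc))
  }
  robin_edge <- function(idx, h, pref) {
    P <- an$nodes[idx, ]
    L <- sqrt(sum((P[2, ] - P[1, ])^2)); ra <- P[1, 1]; rb <- P[2, 1]
    M <- 2 * pi * L / 12 * matrix(c(3 * ra + rb, ra + rb, ra + rb,
                                    ra + 3 * rb), 2, 2)
    bv <- 2 * pi * L / 6 * c(2 * ra + rb, ra + 2 * rb)
    A[idx, idx] <<- A[idx, idx] + h * M
    b[idx] <<- b[idx] + h * pref * bv
  }
  for (i in which(an$boundary_label == "inner_face")) {
    robin_edge(an$boundary_edges[i, ], h_in, p_in)
  }
  for (i in which(an$boundary_label == "outer_face")) {
    robin_edge(an$boundary_edges[i, ], h_out, p_out)
  }
  p_ref <- solve(A, b)
  expect_equal(s$pressure_Pa, p_ref, tolerance = 1e-10)
})

test_that("degenerate boundary-condition sets raise explicit errors", {
  an <- make_fixture("annulus", n = 4)
  expect_error(solve_darcy(an, c(shell = 1e-13),
                           list(inner_face = bc_impermeable(),
                                outer_face = bc_impermeable(),
                                end_faces = bc_impermeable())),
               "singular")
  expect_error(solve_darcy(an, c(shell = 1e-13),
                           list(inner_face = bc_pressure(10))),
               "no boundary condition")
  expect_error(solve_darcy(an, c(wrong = 1e-13),
                           list(inner_face = bc_pressure(10),
                                outer_face = bc_pressure(5),
                                end_faces = bc_impermeable())),
               "no conductivity")
  s <- solve_darcy(an, c(shell = 1e-13),
                   list(inner_face = bc_pressure(10), outer_face = bc_pressure(5),
                        end_faces = bc_impermeable()))
  expect_error(boundary_flux(s, "nope"), "unknown boundary")
})
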