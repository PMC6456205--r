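# Clinical scenarios and calibration procedures, encoded as pure parameter
# transformations plus drivers that run the full model.

#' Solve the full eye model for a parameter set
#'
#' Convenience driver: builds (or reuses) the mesh and solves the Darcy
#' problem with the standard boundary-condition set.
#'
#' @param params An [eye_params()] object.
#' @param mesh An `axisym_mesh` (built with [generate_mesh()] if omitted).
#' @param Q Production override (uL/min).
#' @param bcs Boundary-condition override (a named `flow_bc` list).
#' @param control Solver control list (see [solve_darcy()]).
#' @return A `flow_solution`.
#' @export
solve_eye <- function(params, mesh = NULL, Q = NULL, bcs = NULL,
                      control = list()) {
  mesh <- mesh %||% generate_mesh(eye_geometry())
  solve_darcy(mesh, material_field(params),
              bcs %||% boundary_conditions(params, Q = Q), control = control)
}

#' Scenario objects
#'
#' A scenario is a named, documented set of parameter overrides; applying and
#' then reverting a scenario leaves the original parameters untouched (the
#' transformation is pure).
#'
#' @param name Scenario name.
#' @param overrides Named list of parameter overrides.
#' @param doc One-line description of the clinical situation.
#' @return A `scenario` object.
#' @export
scenario <- function(name, overrides, doc = "") {
  structure(list(name = name, overrides = overrides, doc = doc),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", x$name, "\n  ", x$doc, "\n", sep = "")
  for (nm in names(x$overrides)) {
    cat(sprintf("  %s = %s\n", nm, format(x$overrides[[nm]])))
  }
  invisible(x)
}

#' Apply a scenario to a parameter set
#'
#' @param params An [eye_params()] object.
#' @param sc A [scenario()].
#' @return A new `eye_params` object.
#' @export
apply_scenario <- function(params, sc) {
  stopifnot(inherits(sc, "scenario"))
  do.call(update_params, c(list(params), sc$overrides))
}

#' Daytime supine posture
#'
#' Rising venous pressure adds a 3 mmHg all-round backpressure and the
#' subarachnoid CSF pressure rises to about 9 mmHg; everything else is
#' unchanged.
#'
#' @param params Baseline parameters (used only for documentation).
#' @return A [scenario()].
#' @export
scenario_supine <- function(params = default_normal_eye()) {
  scenario("supine_daytime", list(p_back = 3, p_CSF = 9),
           "daytime supine posture: backpressure 3 mmHg, CSF 9 mmHg")
}

#' Nocturnal eye (aqueous-flow study conditions)
#'
#' Daytime baseline first lowers production 6 % (IOP 13.9 mmHg); night-time
#' then reduces production to 65 % of the daytime rate, reduces the
#' anterior-pathway surface conductivity from 0.5 to 0.325 and raises alpha
#' from 0.075 to 0.10. With `supine = TRUE` the nocturnal posture overrides
#' (backpressure 3, CSF 9 mmHg) are added.
#'
#' @param params Baseline parameters.
#' @param supine Apply the supine posture on top of the nocturnal changes.
#' @return A [scenario()].
#' @export
scenario_nocturnal_nau <- function(params = default_normal_eye(),
                                   supine = FALSE) {
  q_day <- 0.94 * params$production_rate
  over <- list(production_rate = 0.65 * q_day, c_ap_SL = 0.325, alpha = 0.10)
  if (supine) over <- c(over, list(p_back = 3, p_CSF = 9))
  scenario(if (supine) "nocturnal_supine" else "nocturnal_upright", over,
           "nocturnal eye: production 65% of the 5.78 uL/min daytime rate, c_ap 0.325, alpha 0.10")
}

#' Daytime baseline of the nocturnal study (production -6 %)
#' @param params Baseline parameters.
#' @return A [scenario()].
#' @export
scenario_nau_daytime <- function(params = default_normal_eye()) {
  scenario("nau_daytime", list(production_rate = 0.94 * params$production_rate),
           "daytime baseline of the aqueous-flow study: IOP 13.9 mmHg")
}

#' Normal-tension glaucoma scenarios
#'
#' Variant 1: alpha raised from 0.075 to 0.10 (raising IOP to about 21 mmHg)
#' with subarachnoid CSF pressure -4 mmHg. Variant 2 (aged adult): CSF
#' pressure -7 mmHg.
#'
#' @param params Baseline parameters.
#' @param variant 1 or 2.
#' @return A [scenario()].
#' @export
scenario_ntg <- function(params = default_normal_eye(), variant = 1L) {
  stopifnot(variant %in% c(1L, 2L))
  scenario(paste0("ntg", variant),
           list(alpha = 0.10, p_CSF = if (variant == 1L) -4 else -7),
           "normal-tension glaucoma: reduced outflow facility, negative CSF pressure")
}

#' Silicone-oil fill fraction to retinal surface coverage
#'
#' Piecewise-linear map through the measured shape of a silicone-oil bubble
#' in the vitreous cavity: fill fractions 45/60/75/90 % cover 20/30/45/68 %
#' of the retinal surface, extended linearly to (0, 0) and (100, 100).
#'
#' @return A tibble with `fill_pct`, `coverage_pct`.
#' @export
tamponade_map <- function() {
  tibble::tibble(fill_pct = c(0, 45, 60, 75, 90, 100),
                 coverage_pct = c(0, 20, 30, 45, 68, 100))
}

#' @rdname tamponade_map
#' @param fill_pct Fill fraction (%, in \[0, 100\]).
#' @export
tamponade_coverage <- function(fill_pct) {
  if (any(fill_pct < 0 | fill_pct > 100)) {
    stop("fill fraction must lie in [0, 100] %", call. = FALSE)
  }
  m <- tamponade_map()
  stats::approx(m$fill_pct, m$coverage_pct, xout = fill_pct)$y
}

#' @rdname tamponade_map
#' @param coverage_pct Retinal coverage (%, in \[0, 100\]).
#' @export
tamponade_fill <- function(coverage_pct) {
  m <- tamponade_map()
  stats::approx(m$coverage_pct, m$fill_pct, xout = coverage_pct)$y
}

#' Silicone-oil tamponade scenario
#'
#' The oil is assumed to block RPE outflow wherever it covers the retina, so
#' the RPE surface conductivity is scaled by (1 - coverage); production is
#' unchanged.
#'
#' @param params Baseline parameters.
#' @param fill_fraction Vitreous volume filling fraction (%).
#' @return A [scenario()].
#' @export
scenario_tamponade <- function(params = default_normal_eye(), fill_fraction) {
  cov <- tamponade_coverage(fill_fraction)
  scenario(sprintf("tamponade_%g", fill_fraction),
           list(c_pre_SL = params$c_pre_SL * (1 - cov / 100)),
           sprintf("silicone-oil tamponade, %g%% fill (%g%% retinal coverage)",
                   fill_fraction, cov))
}

#' Schwartz-Matsuo syndrome scenario
#'
#' Photoreceptor outer segments clog the anterior outflow pathways: the
#' anterior surface conductivity is reduced (e.g. from 0.5 to 0.148 or 0.12),
#' production unchanged. `production_boost` optionally raises production
#' (e.g. 0.045 for the variant whose baseline IOP is 16 mmHg).
#'
#' @param params Baseline parameters.
#' @param c_ap_value Reduced anterior surface conductivity (uL/min/mmHg).
#' @param production_boost Fractional production increase (default 0).
#' @return A [scenario()].
#' @export
scenario_schwartz_matsuo <- function(params = default_normal_eye(),
                                     c_ap_value, production_boost = 0) {
  stopifnot(c_ap_value > 0, c_ap_value <= params$c_ap_SL)
  over <- list(c_ap_SL = c_ap_value)
  if (production_boost != 0) {
    over$production_rate <- params$production_rate * (1 + production_boost)
  }
  scenario("schwartz_matsuo", over,
           "Schwartz-Matsuo syndrome: clogged anterior outflow pathways")
}

## ---- calibrations ---------------------------------------------------------

#' Calibrate aqueous production to a target IOP
#'
#' Secant iteration on the production rate using full model solves until the
#' anterior-chamber probe pressure matches the target within `tol_mmHg`.
#'
#' @param params An [eye_params()] object.
#' @param target_iop Target IOP (mmHg).
#' @param mesh An `axisym_mesh`.
#' @param tol_mmHg Convergence tolerance (mmHg).
#' @param max_solves Maximum number of model solves.
#' @return `params` with the fitted `production_rate`; the fitted solution is
#'   attached as attribute `solution`.
#' @export
calibrate_production <- function(params, target_iop, mesh = NULL,
                                 tol_mmHg = 0.01, max_solves = 50L) {
  mesh <- mesh %||% generate_mesh(eye_geometry())
  f <- function(q) iop(solve_eye(params, mesh, Q = q)) - target_iop
  q0 <- params$production_rate
  e0 <- f(q0)
  if (abs(e0) < tol_mmHg) {
    params$production_rate <- q0
    return(params)
  }
  q1 <- q0 * if (e0 > 0) 0.9 else 1.1
  e1 <- f(q1)
  n <- 2L
  while (abs(e1) >= tol_mmHg) {
    if (n >= max_solves) {
      stop("production calibration did not converge in ", max_solves,
           " solves", call. = FALSE)
    }
    q2 <- q1 - e1 * (q1 - q0) / (e1 - e0)
    q2 <- max(q2, 1e-3)
    q0 <- q1; e0 <- e1; q1 <- q2; e1 <- f(q2)
    n <- n + 1L
  }
  params$production_rate <- q1
  sol <- solve_eye(params, mesh)
  attr(params, "solution") <- sol
  params
}

# layer-drop fractions of the axial profile under a fixed nerve-surface
# pressure (penalty Robin), used by the ONH conductivity calibration
onh_profile_measure <- function(params, mesh, nerve_surface_pressure) {
  bcs <- boundary_conditions(params)
  bcs$pia_interface <- bc_pressure(nerve_surface_pressure)
  sol <- solve_darcy(mesh, material_field(params), bcs)
  prof <- extract_axial_profile(sol)
  d <- mesh$derived
  p_disc <- axis_pressure_at(prof, d$z_disc)
  p_lca <- axis_pressure_at(prof, d$z_lc_a)
  p_lcp <- axis_pressure_at(prof, d$z_lc_p)
  p_rl <- axis_pressure_at(prof, d$z_rl)
  tot <- p_disc - nerve_surface_pressure
  list(prelaminar_fraction = (p_disc - p_lca) / tot,
       laminar_fraction = (p_lca - p_lcp) / tot,
       retrolaminar_fraction = (p_lcp - p_rl) / tot,
       solution = sol)
}

#' Calibrate the optic nerve head conductivities
#'
#' Fits (`k_ONPL`, `k_ONLC`, `k_ONRL`) — with `k_ON` held at its anchor value
#' — so that the axial pressure profile through the optic nerve head matches
#' target layer-drop fractions, after temporarily fixing the nerve-surface
#' pressure (default 5 mmHg, the depth-profile measurement condition).
#' Derivative-free Nelder-Mead search in log-space, bounded to
#' \[1e-15, 1e-10\] m^2/Pa-s.
#'
#' With `validate = TRUE` no fit is run: the function solves the standard
#' model and returns its laminar fraction for checking against the expected
#' 0.80-0.88 range.
#'
#' @param params An [eye_params()] object.
#' @param profile_targets List with `prelaminar_fraction`, `laminar_fraction`,
#'   `retrolaminar_fraction` (shares of the disc-to-nerve-surface drop).
#' @param mesh An `axisym_mesh`.
#' @param nerve_surface_pressure Temporary fixed nerve-surface pressure (mmHg).
#' @param validate Run validation instead of fitting.
#' @param maxit Nelder-Mead iteration budget.
#' @return Fitted `params` (attribute `fit` holds optim diagnostics), or for
#'   `validate = TRUE` a list with `laminar_fraction` and the solution.
#' @export
calibrate_onh_conductivities <- function(params,
                                         profile_targets = list(
                                           prelaminar_fraction = 0.10,
                                           laminar_fraction = 0.85,
                                           retrolaminar_fraction = 0.05),
                                         mesh = NULL,
                                         nerve_surface_pressure = 5,
                                         validate = FALSE,
                                         maxit = 120L) {
  mesh <- mesh %||% generate_mesh(eye_geometry())
  if (validate) {
    sol <- solve_eye(params, mesh)
    rep <- compute_tlpg(extract_axial_profile(sol))
    return(list(laminar_fraction = rep$laminar_fraction, tlpg = rep$tlpg,
                solution = sol))
  }
  tg <- unlist(profile_targets[c("prelaminar_fraction", "laminar_fraction",
                                 "retrolaminar_fraction")])
  obj <- function(logk) {
    if (any(logk < log10(1e-15)) || any(logk > log10(1e-10))) return(1e6)
    pk <- update_params(params, k_ONPL = 10^logk[1], k_ONLC = 10^logk[2],
                        k_ONRL = 10^logk[3])
    m <- onh_profile_measure(pk, mesh, nerve_surface_pressure)
    sum((unlist(m[names(tg)]) - tg)^2)
  }
  x0 <- log10(c(params$k_ONPL, params$k_ONLC, params$k_ONRL))
  if (obj(x0) < 1e-8) return(params)   # targets already satisfied
  fit <- stats::optim(x0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8))
  if (any(fit$par < log10(1e-15)) || any(fit$par > log10(1e-10))) {
    stop("ONH conductivity search left bounds [1e-15, 1e-10]", call. = FALSE)
  }
  out <- update_params(params, k_ONPL = 10^fit$par[1], k_ONLC = 10^fit$par[2],
                       k_ONRL = 10^fit$par[3])
  attr(out, "fit") <- fit
  out
}

#' Calibrate the pial interface conductivity
#'
#' Root-finds `h_ON` so that the optic nerve pressure (4 mm behind the lamina
#' cribrosa) matches a target — about 4 mmHg when the subarachnoid CSF
#' pressure is temporarily set to zero.
#'
#' @param params An [eye_params()] object.
#' @param mesh An `axisym_mesh`.
#' @param target_pressure Target nerve pressure (mmHg) at `p_CSF = 0`.
#' @return `params` with the fitted `h_ON`.
#' @export
calibrate_pial_conductivity <- function(params, mesh = NULL,
                                        target_pressure = 4.0) {
  mesh <- mesh %||% generate_mesh(eye_geometry())
  p0 <- update_params(params, p_CSF = 0)
  f <- function(log_h) {
    pk <- update_params(p0, h_ON = 10^log_h)
    nerve_pressure(solve_eye(pk, mesh)) - target_pressure
  }
  lo <- -13; hi <- -9
  if (f(lo) * f(hi) > 0) stop("pial conductivity root not bracketed", call. = FALSE)
  r <- stats::uniroot(f, lower = lo, upper = hi, tol = 1e-4)
  update_params(params, h_ON = 10^r$root)
}

#' Inverse tamponade fit (silicone-oil cohort analysis)
#'
#' Production is first reduced 11.5 % so the baseline IOP is 13 mmHg; the RPE
#' surface conductivity is then root-found so the model predicts the target
#' IOP (16 mmHg for the median 3 mmHg elevation). The fitted conductivity is
#' mapped back through the tamponade coverage map to a fill fraction.
#'
#' @param params Baseline parameters.
#' @param mesh An `axisym_mesh`.
#' @param target_iop Target elevated IOP (mmHg).
#' @return List: `c_pre_SL`, `coverage_pct`, `fill_pct`, `baseline_iop`.
#' @export
scenario_jonas_tamponade_inverse <- function(params = default_normal_eye(),
                                             mesh = NULL, target_iop = 16) {
  mesh <- mesh %||% generate_mesh(eye_geometry())
  pj <- update_params(params,
                      production_rate = params$production_rate * (1 - 0.115))
  base_iop <- iop(solve_eye(pj, mesh))
  if (abs(target_iop - base_iop) < 0.05) {
    return(list(c_pre_SL = params$c_pre_SL, coverage_pct = 0, fill_pct = 0,
                baseline_iop = base_iop))
  }
  if (target_iop < base_iop) {
    stop("target IOP ", target_iop, " is below the baseline ",
         signif(base_iop, 4), " mmHg", call. = FALSE)
  }
  f <- function(cpre) {
    iop(solve_eye(update_params(pj, c_pre_SL = cpre), mesh)) - target_iop
  }
  r <- stats::uniroot(f, lower = 0.02, upper = pj$c_pre_SL, tol = 1e-4)
  cov <- 100 * (1 - r$root / params$c_pre_SL)
  list(c_pre_SL = r$root, coverage_pct = cov, fill_pct = tamponade_fill(cov),
       baseline_iop = base_iop)
}

## ---- scans ----------------------------------------------------------------

#' One-at-a-time sensitivity of IOP to the model parameters
#'
#' Each parameter is perturbed by `fractional_step` (+10 % by default); the
#' backpressure row, whose baseline is 0, is stepped by
#' `fractional_step * 15` mmHg (a 10 % step on a 15 mmHg scale).
#'
#' @param params An [eye_params()] object.
#' @param mesh An `axisym_mesh`.
#' @param fractional_step Fractional perturbation.
#' @return A tibble: parameter, baseline and perturbed IOP, `pct_change_iop`,
#'   `sensitivity` (% change in IOP per % change in parameter).
#' @export
sensitivity_scan <- function(params, mesh = NULL, fractional_step = 0.10) {
  mesh <- mesh %||% generate_mesh(eye_geometry())
  base <- iop(solve_eye(params, mesh))
  perturb <- list(
    production_rate = function(p) update_params(
      p, production_rate = p$production_rate * (1 + fractional_step)),
    c_total_SL = function(p) update_params(
      p, c_pre_SL = p$c_pre_SL * (1 + fractional_step),
      c_ap_SL = p$c_ap_SL * (1 + fractional_step),
      c_total_SL = p$c_total_SL * (1 + fractional_step)),
    alpha = function(p) update_params(p, alpha = p$alpha * (1 + fractional_step)),
    p_T = function(p) update_params(p, p_T = p$p_T * (1 + fractional_step)),
    p_back = function(p) update_params(p, p_back = p$p_back + fractional_step * 15),
    p_CSF = function(p) update_params(p, p_CSF = p$p_CSF * (1 + fractional_step)),
    k_ONLC = function(p) update_params(p, k_ONLC = p$k_ONLC * (1 + fractional_step))
  )
  rows <- lapply(names(perturb), function(nm) {
    io <- iop(solve_eye(perturb[[nm]](params), mesh))
    pct <- 100 * (io - base) / base
    tibble::tibble(parameter = nm, iop_base = base, iop_perturbed = io,
                   pct_change_iop = pct,
                   sensitivity = pct / (100 * fractional_step))
  })
  do.call(rbind, rows)
}

#' IOP as a function of the anterior/RPE outflow split
#'
#' Holds the total surface conductivity fixed and sweeps the anterior
#' fraction.
#'
#' @param params An [eye_params()] object.
#' @param anterior_fractions Vector of anterior fractions in (0, 1).
#' @param mesh An `axisym_mesh`.
#' @return A tibble: anterior_fraction, c_ap_SL, c_pre_SL, iop_mmHg.
#' @export
outflow_split_scan <- function(params,
                               anterior_fractions = c(0.35, 0.4, 0.45, 0.5,
                                                      0.55, 0.6, 0.65),
                               mesh = NULL) {
  stopifnot(all(anterior_fractions > 0 & anterior_fractions < 1))
  mesh <- mesh %||% generate_mesh(eye_geometry())
  ct <- params$c_total_SL
  rows <- lapply(anterior_fractions, function(f) {
    pk <- update_params(params, c_ap_SL = f * ct, c_pre_SL = (1 - f) * ct,
                        c_total_SL = ct)
    tibble::tibble(anterior_fraction = f, c_ap_SL = f * ct,
                   c_pre_SL = (1 - f) * ct,
                   iop_mmHg = iop(solve_eye(pk, mesh)))
  })
  do.call(rbind, rows)
}

#' Sequential introduction of tissue flow resistances
#'
#' Rebuilds the model construction sequence: starting from the
#' uniform-conductivity eye (the 0D-equivalent model, production 6.32
#' uL/min, no optic nerve head leakage), tissue resistances are introduced
#' one at a time and the IOP response recorded: retinal conductivity, then
#' vitreous conductivity, then the optic nerve head tissues with the pial
#' leak.
#'
#' @param params Final parameter set (supplies the Table-style values).
#' @param mesh An `axisym_mesh`.
#' @param k_ret_initial Initial (upper-bound) retinal conductivity used in
#'   the first introduction step.
#' @param k_vit_variant Alternative vitreous conductivity explored as a
#'   variant step.
#' @return A tibble: step, description, iop_mmHg, delta_iop_mmHg (vs the
#'   previous cumulative step; the variant row is relative to the retina
#'   step).
#' @export
sequential_resistance_study <- function(params, mesh = NULL,
                                        k_ret_initial = 5e-12,
                                        k_vit_variant = 1.0e-11) {
  mesh <- mesh %||% generate_mesh(eye_geometry())
  q0 <- 6.32
  uniform <- material_field(NULL,
    anterior_chamber = params$k_ac, posterior_chamber = params$k_ac,
    vitreous = params$k_ac, retina = params$k_ac,
    onh_prelaminar = params$k_ac, onh_lamina_cribrosa = params$k_ac,
    onh_retrolaminar = params$k_ac, optic_nerve = params$k_ac)
  bcs0 <- boundary_conditions(params, Q = q0)
  bcs0$pia_interface <- bc_impermeable()   # ONH leakage introduced last
  run <- function(mat, bcs) iop(solve_darcy(mesh, mat, bcs))
  i1 <- run(uniform, bcs0)
  m2 <- uniform; m2["retina"] <- k_ret_initial
  i2 <- run(m2, bcs0)
  m3 <- m2; m3["vitreous"] <- params$k_vit
  i3 <- run(m3, bcs0)
  m3b <- m2; m3b["vitreous"] <- k_vit_variant
  i3b <- run(m3b, bcs0)
  m4 <- material_field(params)
  m4["retina"] <- k_ret_initial   # retina still at the initial estimate
  i4 <- run(m4, boundary_conditions(params, Q = q0))
  m5 <- material_field(params)
  i5 <- run(m5, boundary_conditions(params, Q = q0))
  tibble::tibble(
    step = c("uniform", "retina_5e-12", "vitreous_8.4e-11",
             "vitreous_1e-11_variant", "onh_and_pia", "retina_5e-14_final"),
    description = c(
      "uniform conductivity, no ONH leakage (0D-equivalent)",
      sprintf("retina k = %.1e", k_ret_initial),
      sprintf("vitreous k = %.1e", params$k_vit),
      sprintf("variant: vitreous k = %.1e", k_vit_variant),
      "ONH tissue conductivities + pial leakage",
      sprintf("final retina k = %.1e", params$k_ret)),
    iop_mmHg = c(i1, i2, i3, i3b, i4, i5),
    delta_iop_mmHg = c(NA, i2 - i1, i3 - i2, i3b - i2, i4 - i3, i5 - i4)
  )
}
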