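# Steady axisymmetric Darcy solver.
#
# Weak form of  div(v_d) = 0,  v_d = -k grad p  on the (r,z) half-section,
# with all integrals weighted by 2 pi r (surface of revolution). Linear (P1)
# triangles; the gradient is element-wise constant so the stiffness integral
# 2 pi k A rbar (grad phi_i . grad phi_j) is exact with the centroid radius.
#
# Outflow surfaces carry the pressure-dependent exponential Robin condition
#   v_dn(p) = (C^SL / (A alpha)) (exp(-alpha p_T) - exp(-alpha (p - p_back)))
# (pressures in the exponent in mmHg in the reporting convention; converted
# to SI here), the pia mater carries v_dn = h_ON (p - p_CSF), and the ciliary
# body a prescribed uniform influx. The exponential condition is linearized
# about the previous boundary pressure (Picard with tangent slope) and
# iterated to |dp|_max < 0.01 Pa.

#' Boundary condition constructors
#'
#' `bc_outflow` is the pressure-dependent exponential outflow law,
#' `bc_robin` a linear Robin (leakage) law `v = h (p - p_ref)`, `bc_inflow` a
#' prescribed total influx distributed uniformly over the boundary,
#' `bc_pressure` an (approximate) fixed-pressure condition implemented as a
#' high-conductance Robin penalty, and `bc_impermeable` zero normal flux.
#'
#' @param c_SL Surface hydraulic conductivity (uL/min/mmHg).
#' @param alpha Outflow decay constant (1/mmHg).
#' @param p_T,p_back No-flow pressure and backpressure (mmHg).
#' @param h Interface conductivity (m/Pa-s).
#' @param p_ref,p Reference / imposed pressure (mmHg).
#' @param Q Total inflow (uL/min).
#' @param penalty Penalty conductance for `bc_pressure` (m/Pa-s).
#' @return A `flow_bc` object.
#' @export
bc_outflow <- function(c_SL, alpha, p_T, p_back = 0) {
  structure(list(type = "outflow", c_SL = c_SL, alpha = alpha,
                 p_T = p_T, p_back = p_back), class = "flow_bc")
}

#' @rdname bc_outflow
#' @export
bc_robin <- function(h, p_ref) {
  structure(list(type = "robin", h = h, p_ref = p_ref), class = "flow_bc")
}

#' @rdname bc_outflow
#' @export
bc_inflow <- function(Q) {
  stopifnot(Q >= 0)
  structure(list(type = "inflow", Q = Q), class = "flow_bc")
}

#' @rdname bc_outflow
#' @export
bc_pressure <- function(p, penalty = 1e-2) {
  structure(list(type = "robin", h = penalty, p_ref = p), class = "flow_bc")
}

#' @rdname bc_outflow
#' @export
bc_impermeable <- function() {
  structure(list(type = "impermeable"), class = "flow_bc")
}

#' Per-region hydraulic conductivity map
#'
#' @param params An [eye_params()] object, or `NULL` when `...` supplies the
#'   map directly.
#' @param ... Named overrides `region = k` (m^2/Pa-s).
#' @return Named numeric vector, one conductivity per region label.
#' @export
material_field <- function(params = NULL, ...) {
  k <- if (!is.null(params)) {
    c(anterior_chamber = params$k_ac, posterior_chamber = params$k_ac,
      vitreous = params$k_vit, retina = params$k_ret,
      onh_prelaminar = params$k_ONPL, onh_lamina_cribrosa = params$k_ONLC,
      onh_retrolaminar = params$k_ONRL, optic_nerve = params$k_ON)
  } else c()
  over <- unlist(list(...))
  k[names(over)] <- over
  if (any(k <= 0)) stop("all hydraulic conductivities must be positive",
                        call. = FALSE)
  k
}

#' Standard boundary-condition set from a parameter set
#'
#' Anterior outflow and RPE surfaces get the exponential outflow law with the
#' anterior-pathway and RPE surface conductivities, the pia mater the linear
#' leakage law towards `p_CSF`, the ciliary band the production influx; the
#' symmetry axis, distal nerve face and all remaining walls are impermeable.
#'
#' @param params An [eye_params()] object.
#' @param Q Production rate override (uL/min); defaults to
#'   `params$production_rate`.
#' @return Named list of `flow_bc`, one per boundary label.
#' @export
boundary_conditions <- function(params, Q = NULL) {
  list(
    ciliary_inflow = bc_inflow(Q %||% params$production_rate),
    anterior_outflow = bc_outflow(params$c_ap_SL, params$alpha,
                                  params$p_T, params$p_back),
    rpe_outflow = bc_outflow(params$c_pre_SL, params$alpha,
                             params$p_T, params$p_back),
    pia_interface = bc_robin(params$h_ON, params$p_CSF),
    distal_nerve_face = bc_impermeable(),
    symmetry_axis = bc_impermeable(),
    impermeable = bc_impermeable()
  )
}

# Edge line-integral matrices with weight 2 pi r, r linear on the edge.
#   mass:  M[i,j] = int phi_i phi_j 2 pi r ds   (2x2 per edge, exact)
#   load:  b[i]   = int phi_i 2 pi r ds
edge_integrals <- function(nodes, edges) {
  n1 <- nodes[edges[, 1], , drop = FALSE]
  n2 <- nodes[edges[, 2], , drop = FALSE]
  L <- sqrt(rowSums((n2 - n1)^2))
  ra <- n1[, 1]; rb <- n2[, 1]
  list(
    L = L, ra = ra, rb = rb,
    m11 = 2 * pi * L * (3 * ra + rb) / 12,
    m12 = 2 * pi * L * (ra + rb) / 12,
    m22 = 2 * pi * L * (ra + 3 * rb) / 12,
    b1 = 2 * pi * L * (2 * ra + rb) / 6,
    b2 = 2 * pi * L * (ra + 2 * rb) / 6
  )
}

#' Solve the axisymmetric Darcy problem
#'
#' Assembles the axisymmetric weak form and solves it with Picard iteration
#' on the exponential outflow boundary term (tangent linearization about the
#' previous boundary pressure). Convergence when the largest nodal pressure
#' update is below `tol_Pa`. The converged solution satisfies global mass
#' balance to well under 0.1 % of the inflow.
#'
#' @param mesh An `axisym_mesh`.
#' @param materials Named conductivity vector from [material_field()].
#' @param bcs Named list of `flow_bc` from [boundary_conditions()]; every
#'   boundary label in the mesh must have a condition.
#' @param control List: `tol_Pa` (default 0.01), `max_iter` (200),
#'   `relax` (1; halved on oscillation), `p_init_mmHg` (15).
#' @return A `flow_solution`: nodal pressures (Pa), per-boundary volumetric
#'   fluxes (uL/min, outflow positive), iteration diagnostics.
#' @export
solve_darcy <- function(mesh, materials, bcs, control = list()) {
  ctl <- utils::modifyList(list(tol_Pa = 0.01, max_iter = 200L, relax = 1,
                                p_init_mmHg = 15), control)
  labs <- unique(mesh$boundary_label)
  missing_bc <- setdiff(labs, names(bcs))
  if (length(missing_bc)) {
    stop("no boundary condition for label(s): ",
         paste(missing_bc, collapse = ", "), call. = FALSE)
  }
  missing_k <- setdiff(unique(mesh$region), names(materials))
  if (length(missing_k)) {
    stop("no conductivity for region(s): ",
         paste(missing_k, collapse = ", "), call. = FALSE)
  }
  nn <- nrow(mesh$nodes)

  ## interior stiffness (fixed across Picard iterations)
  tr <- mesh$triangles
  p1 <- mesh$nodes[tr[, 1], , drop = FALSE]
  p2 <- mesh$nodes[tr[, 2], , drop = FALSE]
  p3 <- mesh$nodes[tr[, 3], , drop = FALSE]
  two_a <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
           (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  area <- two_a / 2
  rbar <- (p1[, 1] + p2[, 1] + p3[, 1]) / 3
  ke <- unname(materials[mesh$region])
  b1 <- (p2[, 2] - p3[, 2]) / two_a; c1 <- (p3[, 1] - p2[, 1]) / two_a
  b2 <- (p3[, 2] - p1[, 2]) / two_a; c2 <- (p1[, 1] - p3[, 1]) / two_a
  b3 <- (p1[, 2] - p2[, 2]) / two_a; c3 <- (p2[, 1] - p1[, 1]) / two_a
  w <- 2 * pi * rbar * area * ke
  bb <- cbind(b1, b2, b3); cc <- cbind(c1, c2, c3)
  ii <- jj <- xx <- vector("list", 9L)
  n <- 0L
  for (a in 1:3) for (b in 1:3) {
    n <- n + 1L
    ii[[n]] <- tr[, a]; jj[[n]] <- tr[, b]
    xx[[n]] <- w * (bb[, a] * bb[, b] + cc[, a] * cc[, b])
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nn, nn))

  ## boundary pieces per label
  by_lab <- split(seq_along(mesh$boundary_label), mesh$boundary_label)
  einfo <- lapply(by_lab, function(idx)
    edge_integrals(mesh$nodes, mesh$boundary_edges[idx, , drop = FALSE]))
  eidx <- lapply(by_lab, function(idx) mesh$boundary_edges[idx, , drop = FALSE])
  areas <- vapply(names(by_lab), function(l) {
    e <- einfo[[l]]; sum(2 * pi * (e$ra + e$rb) / 2 * e$L)
  }, numeric(1))

  any_robin <- any(vapply(names(by_lab), function(l)
    bcs[[l]]$type %in% c("robin", "outflow"), logical(1)))
  if (!any_robin) {
    stop("singular system: no Robin or outflow condition on any boundary",
         call. = FALSE)
  }

  # SI forms of the outflow law per label
  law <- lapply(names(by_lab), function(l) {
    bc <- bcs[[l]]
    if (bc$type == "outflow") {
      a_si <- alpha_to_si(bc$alpha)
      c_si <- csl_to_si(bc$c_SL)
      A <- areas[[l]]
      list(
        type = "outflow",
        v = function(p_Pa) (c_si / (A * a_si)) *
          (exp(-a_si * mmHg_to_Pa(bc$p_T)) -
           exp(-a_si * (p_Pa - mmHg_to_Pa(bc$p_back)))),
        dv = function(p_Pa) (c_si / A) *
          exp(-a_si * (p_Pa - mmHg_to_Pa(bc$p_back)))
      )
    } else if (bc$type == "robin") {
      list(type = "robin", h = bc$h, p_ref = mmHg_to_Pa(bc$p_ref))
    } else if (bc$type == "inflow") {
      list(type = "inflow", q = ulmin_to_m3s(bc$Q) / areas[[l]])
    } else list(type = "impermeable")
  })
  names(law) <- names(by_lab)

  p <- rep(mmHg_to_Pa(ctl$p_init_mmHg), nn)
  relax <- ctl$relax
  resid_hist <- numeric(0)
  converged <- FALSE
  d_prev <- Inf
  for (it in seq_len(ctl$max_iter)) {
    Ai <- K
    rhs <- numeric(nn)
    for (l in names(by_lab)) {
      lw <- law[[l]]; e <- einfo[[l]]; ed <- eidx[[l]]
      if (lw$type == "impermeable") next
      if (lw$type == "inflow") {
        rhs[ed[, 1]] <- rhs[ed[, 1]] + lw$q * e$b1
        rhs[ed[, 2]] <- rhs[ed[, 2]] + lw$q * e$b2
        next
      }
      if (lw$type == "robin") {
        gam1 <- gam2 <- rep(lw$h, length(e$L))
        f1 <- lw$h * lw$p_ref * e$b1
        f2 <- lw$h * lw$p_ref * e$b2
      } else {
        pm <- (p[ed[, 1]] + p[ed[, 2]]) / 2
        gam <- lw$dv(pm)
        gam1 <- gam2 <- gam
        # v(p) ~ v(pm) + gam (p - pm): RHS gets gam*pm - v(pm)
        f0 <- gam * pm - lw$v(pm)
        f1 <- f0 * e$b1
        f2 <- f0 * e$b2
      }
      Ai <- Ai + Matrix::sparseMatrix(
        i = c(ed[, 1], ed[, 1], ed[, 2], ed[, 2]),
        j = c(ed[, 1], ed[, 2], ed[, 1], ed[, 2]),
        x = c(gam1 * e$m11, gam1 * e$m12, gam2 * e$m12, gam2 * e$m22),
        dims = c(nn, nn))
      rhs[ed[, 1]] <- rhs[ed[, 1]] + f1
      rhs[ed[, 2]] <- rhs[ed[, 2]] + f2
    }
    p_new <- as.numeric(Matrix::solve(Ai, rhs))
    dmax <- max(abs(p_new - p))
    resid_hist <- c(resid_hist, dmax)
    if (dmax > d_prev * 1.5 && relax > 0.25) relax <- relax / 2  # oscillation
    d_prev <- dmax
    p <- p + relax * (p_new - p)
    if (dmax < ctl$tol_Pa) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("Picard iteration did not converge in ", ctl$max_iter,
         " iterations; residual history (Pa): ",
         paste(signif(utils::tail(resid_hist, 8), 4), collapse = ", "),
         call. = FALSE)
  }

  ## per-boundary volumetric fluxes from the converged boundary laws
  flux <- vapply(names(by_lab), function(l) {
    lw <- law[[l]]; e <- einfo[[l]]; ed <- eidx[[l]]
    if (lw$type == "impermeable") return(0)
    if (lw$type == "inflow") return(-sum(lw$q * (e$b1 + e$b2)))
    pm <- (p[ed[, 1]] + p[ed[, 2]]) / 2
    vm <- if (lw$type == "robin") lw$h * (pm - lw$p_ref) else lw$v(pm)
    # edge-linear v from nodal pressures, integrated with the load weights
    va <- if (lw$type == "robin") lw$h * (p[ed[, 1]] - lw$p_ref) else lw$v(p[ed[, 1]])
    vb <- if (lw$type == "robin") lw$h * (p[ed[, 2]] - lw$p_ref) else lw$v(p[ed[, 2]])
    sum(va * e$b1 + vb * e$b2)
  }, numeric(1))

  structure(list(
    pressure_Pa = p,
    mesh = mesh,
    materials = materials,
    bcs = bcs,
    boundary_flux_m3s = flux,
    iterations = length(resid_hist),
    residual_history_Pa = resid_hist,
    converged = converged,
    relax_final = relax
  ), class = "flow_solution")
}

#' Volumetric flux through a labeled boundary
#'
#' Revolved surface integral of the normal Darcy flux, evaluated through the
#' converged boundary law (consistent flux). Outflow positive; the inflow
#' boundary reports a negative value.
#'
#' @param solution A `flow_solution`.
#' @param boundary_label Boundary label.
#' @return Flux in uL/min.
#' @export
boundary_flux <- function(solution, boundary_label) {
  fx <- solution$boundary_flux_m3s
  if (!boundary_label %in% names(fx)) {
    stop("unknown boundary label '", boundary_label, "'", call. = FALSE)
  }
  m3s_to_ulmin(fx[[boundary_label]])
}

#' Element-wise Darcy velocity field
#'
#' `v_d = -k grad p`, constant per linear element.
#'
#' @param solution A `flow_solution`.
#' @param materials Optional conductivity override (defaults to the solve's).
#' @return A tibble: element id, centroid (r, z), region, `vr`, `vz`,
#'   `speed` (m/s).
#' @export
darcy_velocity_field <- function(solution, materials = NULL) {
  mesh <- solution$mesh
  materials <- materials %||% solution$materials
  tr <- mesh$triangles
  p1 <- mesh$nodes[tr[, 1], , drop = FALSE]
  p2 <- mesh$nodes[tr[, 2], , drop = FALSE]
  p3 <- mesh$nodes[tr[, 3], , drop = FALSE]
  two_a <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
           (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  u <- solution$pressure_Pa
  dpdr <- (u[tr[, 1]] * (p2[, 2] - p3[, 2]) +
           u[tr[, 2]] * (p3[, 2] - p1[, 2]) +
           u[tr[, 3]] * (p1[, 2] - p2[, 2])) / two_a
  dpdz <- (u[tr[, 1]] * (p3[, 1] - p2[, 1]) +
           u[tr[, 2]] * (p1[, 1] - p3[, 1]) +
           u[tr[, 3]] * (p2[, 1] - p1[, 1])) / two_a
  ke <- unname(materials[mesh$region])
  vr <- -ke * dpdr
  vz <- -ke * dpdz
  tibble::tibble(
    element = seq_len(nrow(tr)),
    r = (p1[, 1] + p2[, 1] + p3[, 1]) / 3,
    z = (p1[, 2] + p2[, 2] + p3[, 2]) / 3,
    region = mesh$region,
    vr = vr, vz = vz, speed = sqrt(vr^2 + vz^2)
  )
}

#' Anterior-chamber pressure (IOP) of a solution
#'
#' Pressure at a fixed probe point in the mid anterior chamber, where IOP is
#' measured clinically.
#'
#' @param solution A `flow_solution`.
#' @return IOP in mmHg.
#' @export
iop <- function(solution) {
  mesh <- solution$mesh
  d <- mesh$derived
  if (is.null(d) || is.null(d$z_ac_bot)) return(NA_real_)
  probe <- c(0.3 * d$r_chamber, (d$z_ac_bot + d$z_ac_top) / 2)
  i <- which.min((mesh$nodes[, 1] - probe[1])^2 + (mesh$nodes[, 2] - probe[2])^2)
  Pa_to_mmHg(solution$pressure_Pa[i])
}

#' Global mass-balance error of a solution
#'
#' @param solution A `flow_solution`.
#' @return Net boundary flux imbalance as a fraction of the inflow.
#' @export
mass_balance_error <- function(solution) {
  fx <- solution$boundary_flux_m3s
  inflow <- -sum(fx[fx < 0])
  if (inflow == 0) return(abs(sum(fx)))
  abs(sum(fx)) / inflow
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("<flow_solution> ", length(x$pressure_Pa), " nodes, ",
      x$iterations, " Picard iterations\n", sep = "")
  if (!is.na(iop(x))) {
    cat(sprintf("  IOP %.2f mmHg; mass balance error %.2e\n",
                iop(x), mass_balance_error(x)))
  }
  fx <- m3s_to_ulmin(x$boundary_flux_m3s)
  for (l in names(fx)) {
    if (abs(fx[[l]]) > 1e-12) cat(sprintf("  %-18s %+.4f uL/min\n", l, fx[[l]]))
  }
  invisible(x)
}

#' Tidy per-boundary fluxes of a solution
#'
#' @param x A `flow_solution`.
#' @param ... Unused.
#' @return A tibble: boundary, flux_ulmin.
#' @export
tidy.flow_solution <- function(x, ...) {
  fx <- m3s_to_ulmin(x$boundary_flux_m3s)
  tibble::tibble(boundary = names(fx), flux_ulmin = unname(fx))
}

#' One-row summary of a solution
#'
#' @param x A `flow_solution`.
#' @param ... Unused.
#' @return A tibble with IOP, iteration count and mass-balance error.
#' @export
glance.flow_solution <- function(x, ...) {
  tibble::tibble(iop_mmHg = iop(x), iterations = x$iterations,
                 mass_balance_error = mass_balance_error(x),
                 converged = x$converged)
}

#' Plot the pressure field
#'
#' @param object A `flow_solution`.
#' @param ... Unused.
#' @return A ggplot object (nodal pressure in mmHg).
#' @exportS3Method ggplot2::autoplot
autoplot.flow_solution <- function(object, ...) {
  mesh <- object$mesh
  tr <- mesh$triangles
  df <- data.frame(
    id = rep(seq_len(nrow(tr)), each = 3L),
    r = as.vector(t(matrix(mesh$nodes[t(tr), 1], nrow = 3L))) * 1e3,
    z = as.vector(t(matrix(mesh$nodes[t(tr), 2], nrow = 3L))) * 1e3,
    p = Pa_to_mmHg(as.vector(t(matrix(object$pressure_Pa[t(tr)], nrow = 3L))))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$r, .data$z, group = .data$id,
                                   fill = .data$p)) +
    ggplot2::geom_polygon() +
    ggplot2::scale_fill_viridis_c(name = "p (mmHg)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "r (mm)", y = "z (mm)")
}
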