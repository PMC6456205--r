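# Headline quantities derived from a flow solution: axial pressure profile,
# translaminar pressure gradient (TLPG), flow partition, lamina cribrosa
# velocities and the two axonal-transport factors of safety.

#' Pressure profile along the symmetry axis
#'
#' Interpolates the nodal pressure along r = 0 from the distal nerve face to
#' the top of the vitreous, with markers at the anterior and posterior faces
#' of the lamina cribrosa.
#'
#' @param solution A `flow_solution` on an eye mesh.
#' @param n_samples Number of samples (>= 50).
#' @return An `axial_profile`: tibble with `z_m`, `z_mm`, `p_mmHg`, and
#'   attributes `lc_anterior_z`, `lc_posterior_z` (m).
#' @export
extract_axial_profile <- function(solution, n_samples = 200L) {
  stopifnot(n_samples >= 50L)
  mesh <- solution$mesh
  d <- mesh$derived
  if (is.null(d)) stop("axial profile requires an eye mesh", call. = FALSE)
  on_axis <- abs(mesh$nodes[, 1]) < 1e-12
  if (!any(on_axis)) stop("symmetry axis not present in mesh", call. = FALSE)
  z <- mesh$nodes[on_axis, 2]
  p <- Pa_to_mmHg(solution$pressure_Pa[on_axis])
  o <- order(z)
  z <- z[o]; p <- p[o]
  keep <- z <= solution$mesh$geometry$vitreous_top_z + 1e-12
  z <- z[keep]; p <- p[keep]
  zs <- seq(min(z), max(z), length.out = n_samples)
  ps <- stats::approx(z, p, xout = zs, ties = mean)$y
  prof <- tibble::tibble(z_m = zs, z_mm = zs * 1e3, p_mmHg = ps)
  attr(prof, "lc_anterior_z") <- d$z_lc_a
  attr(prof, "lc_posterior_z") <- d$z_lc_p
  attr(prof, "z_disc") <- d$z_disc
  attr(prof, "axis_z") <- z
  attr(prof, "axis_p") <- p
  class(prof) <- c("axial_profile", class(prof))
  prof
}

axis_pressure_at <- function(profile, z) {
  stats::approx(attr(profile, "axis_z"), attr(profile, "axis_p"),
                xout = z, ties = mean, rule = 2)$y
}

#' Pressure in the optic nerve at a given depth behind the lamina cribrosa
#'
#' @param solution A `flow_solution` on an eye mesh.
#' @param distance_behind_lc Distance (m) behind the posterior lamina
#'   cribrosa face; default 4 mm, the customary mid-nerve reporting point.
#' @return Pressure in mmHg.
#' @export
nerve_pressure <- function(solution, distance_behind_lc = 4e-3) {
  prof <- extract_axial_profile(solution)
  axis_pressure_at(prof, solution$mesh$derived$z_lc_p - distance_behind_lc)
}

#' Translaminar pressure gradient report
#'
#' The TLPG is the centreline pressure drop across the lamina cribrosa
#' divided by its thickness. The laminar fraction is that drop as a share of
#' the total vitreous-to-nerve drop, with the vitreous pressure taken at the
#' globe centre and the nerve pressure 4 mm behind the lamina.
#'
#' @param profile An [extract_axial_profile()] result.
#' @param lc_thickness_mm Lamina cribrosa thickness in millimetres; defaults
#'   to the marker separation.
#' @return A `tlpg_report` list: `p_upstream`, `p_downstream` (mmHg),
#'   `lc_thickness_mm`, `tlpg` (mmHg/mm), `laminar_fraction`, `p_vitreous`,
#'   `p_nerve`.
#' @export
compute_tlpg <- function(profile, lc_thickness_mm = NULL) {
  za <- attr(profile, "lc_anterior_z")
  zp <- attr(profile, "lc_posterior_z")
  if (is.null(za) || is.null(zp)) stop("profile lacks LC markers", call. = FALSE)
  th <- lc_thickness_mm %||% ((za - zp) * 1e3)
  if (th <= 0) stop("degenerate lamina cribrosa markers", call. = FALSE)
  p_up <- axis_pressure_at(profile, za)
  p_dn <- axis_pressure_at(profile, zp)
  p_vit <- axis_pressure_at(profile, 0)
  p_nerve <- axis_pressure_at(profile, zp - 4e-3)
  total <- p_vit - p_nerve
  structure(list(
    p_upstream = p_up, p_downstream = p_dn,
    lc_thickness_mm = th,
    tlpg = (p_up - p_dn) / th,
    laminar_fraction = if (abs(total) > 1e-12) (p_up - p_dn) / total else NA_real_,
    p_vitreous = p_vit, p_nerve = p_nerve
  ), class = "tlpg_report")
}

#' @export
print.tlpg_report <- function(x, ...) {
  cat(sprintf("<tlpg_report> LC drop %.2f - %.2f = %.2f mmHg over %.2f mm\n",
              x$p_upstream, x$p_downstream, x$p_upstream - x$p_downstream,
              x$lc_thickness_mm))
  cat(sprintf("  TLPG %.1f mmHg/mm; laminar fraction %.2f\n",
              x$tlpg, x$laminar_fraction))
  invisible(x)
}

#' Partition of aqueous production over the outflow routes
#'
#' @param solution A `flow_solution` on an eye mesh.
#' @return A tibble with `route` (anterior, rpe, onh), `flow_ulmin` and
#'   `fraction` of production; fractions sum to 1 within the mass-balance
#'   tolerance.
#' @export
flow_partition <- function(solution) {
  fx <- m3s_to_ulmin(solution$boundary_flux_m3s)
  q <- -sum(fx[fx < 0])
  anterior <- sum(fx[names(fx) == "anterior_outflow"])
  rpe <- sum(fx[names(fx) == "rpe_outflow"])
  onh <- sum(fx[names(fx) %in% c("pia_interface", "distal_nerve_face")])
  tibble::tibble(
    route = c("anterior", "rpe", "onh"),
    flow_ulmin = c(anterior, rpe, onh),
    fraction = c(anterior, rpe, onh) / q
  )
}

#' Darcy and true fluid velocities in the lamina cribrosa
#'
#' Maximum Darcy velocity magnitude over the lamina cribrosa sampled on the
#' centreline (elements touching the axis) and at the periphery (95 % of the
#' disc radius); the true (interstitial) velocity is the Darcy velocity
#' divided by the porosity of the axon bundles.
#'
#' @param solution A `flow_solution` on an eye mesh.
#' @param porosity Fluid porosity in (0, 1); 0.70 for the lamina cribrosa.
#' @return A tibble with `location` (centreline, periphery),
#'   `v_darcy_um_s`, `v_true_um_s`.
#' @export
lc_velocities <- function(solution, porosity = 0.70) {
  stopifnot(porosity > 0, porosity < 1)
  v <- darcy_velocity_field(solution)
  mesh <- solution$mesh
  r_disc <- mesh$derived$r_disc
  lc <- v[v$region == "onh_lamina_cribrosa", ]
  tr <- mesh$triangles[v$region == "onh_lamina_cribrosa", , drop = FALSE]
  rmin <- pmin(mesh$nodes[tr[, 1], 1], mesh$nodes[tr[, 2], 1],
               mesh$nodes[tr[, 3], 1])
  centre <- max(lc$speed[rmin < 1e-12])
  band <- abs(lc$r - 0.95 * r_disc)
  periph <- max(lc$speed[band <= sort(band)[max(4L, nrow(lc) %/% 20L)]])
  tibble::tibble(
    location = c("centreline", "periphery"),
    v_darcy_um_s = c(centre, periph) * 1e6,
    v_true_um_s = c(centre, periph) * 1e6 / porosity
  )
}

#' Axonal-transport factors of safety
#'
#' Two independent safety factors against glaucomatous interruption of
#' axonal transport: a threshold pressure gradient (30 mmHg/mm, acute
#' axoplasmic-flow interruption in peripheral nerve) divided by the predicted
#' TLPG, and the mean retrograde fast-transport speed (0.6 um/s) divided by
#' the true fluid velocity in the lamina cribrosa. The mean dynein velocity
#' relative to the cell membrane is the transport speed minus the true fluid
#' velocity; it reaches zero (stall) when the fluid moves at 0.6 um/s.
#'
#' @param tlpg_report A [compute_tlpg()] result (or a TLPG value in mmHg/mm).
#' @param velocities A [lc_velocities()] result (or a true centreline
#'   velocity in um/s).
#' @param gradient_threshold Threshold TLPG (mmHg/mm).
#' @param stall_velocity Mean retrograde transport speed (um/s).
#' @return A `safety_report` tibble: TLPG, true velocity, both factors of
#'   safety, mean dynein velocity, and an `at_risk` flag.
#' @export
safety_factors <- function(tlpg_report, velocities,
                           gradient_threshold = 30, stall_velocity = 0.6) {
  tlpg <- if (inherits(tlpg_report, "tlpg_report")) tlpg_report$tlpg
          else as.numeric(tlpg_report)
  v_true <- if (is.data.frame(velocities)) {
    velocities$v_true_um_s[velocities$location == "centreline"]
  } else as.numeric(velocities)
  fos_grad <- if (tlpg > 0) gradient_threshold / tlpg else NA_real_
  fos_dyn <- if (v_true > 0) stall_velocity / v_true else NA_real_
  out <- tibble::tibble(
    tlpg_mmHg_per_mm = tlpg,
    v_true_um_s = v_true,
    fos_gradient = fos_grad,
    fos_dynein = fos_dyn,
    v_dynein_mean_um_s = stall_velocity - v_true,
    at_risk = !is.na(fos_grad) & (fos_grad <= 1 | fos_dyn <= 1)
  )
  if (tlpg <= 0 || v_true <= 0) {
    attr(out, "note") <- "non-positive gradient/velocity: not at risk (reverse flow)"
  }
  class(out) <- c("safety_report", class(out))
  out
}

#' Drag force on a transported cargo
#'
#' `F_D = f * v_r`: friction factor times the velocity of the cargo relative
#' to the surrounding fluid (not relative to the axonal membrane).
#'
#' @param f Friction factor (N s/m).
#' @param v_r Relative velocity (m/s).
#' @return Drag force (N).
#' @export
dynein_drag <- function(f, v_r) f * v_r

#' Plot an axial pressure profile
#'
#' @param object An `axial_profile`.
#' @param ... Unused.
#' @return A ggplot object with the lamina cribrosa faces marked.
#' @exportS3Method ggplot2::autoplot
autoplot.axial_profile <- function(object, ...) {
  za <- attr(object, "lc_anterior_z") * 1e3
  zp <- attr(object, "lc_posterior_z") * 1e3
  ggplot2::ggplot(object, ggplot2::aes(.data$z_mm, .data$p_mmHg)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(za, zp), linetype = "dashed") +
    ggplot2::labs(x = "z (mm, posterior to anterior)", y = "pressure (mmHg)")
}
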