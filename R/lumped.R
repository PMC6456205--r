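# Lumped (0D) pressure-dependent outflow model. Integrating the exponential
# outflow boundary condition over a surface at uniform pressure p gives
#   F(p) = (C^SL / alpha) * (exp(-alpha p_T) - exp(-alpha (p - p_back)))
# in uL/min with pressures in mmHg. This closed form is both a standalone
# calculator and the independent oracle for the anterior-chamber IOP of the
# full finite-element model.

#' Describe one pressure-dependent outflow pathway
#'
#' @param c_SL Surface hydraulic conductivity (uL/min/mmHg); non-negative.
#' @param alpha Outflow decay constant (1/mmHg).
#' @param p_T No-flow pressure (mmHg).
#' @param p_back Backpressure (mmHg).
#' @param series_resistance Optional series resistance upstream of the outflow
#'   surface (retina + vitreous in series with the RPE route). Either a
#'   non-negative scalar (mmHg per uL/min, linear) or a function mapping
#'   pathway flow (uL/min) to a pressure drop (mmHg) with
#'   `series_resistance(0) == 0`, monotone non-decreasing.
#' @param name Pathway label used in messages.
#' @return A `pathway_spec` object.
#' @export
pathway_spec <- function(c_SL, alpha = 0.075, p_T = 3, p_back = 0,
                         series_resistance = NULL, name = "pathway") {
  stopifnot(is.numeric(c_SL), length(c_SL) == 1L, c_SL >= 0, alpha > 0)
  if (is.numeric(series_resistance)) {
    stopifnot(length(series_resistance) == 1L, series_resistance >= 0)
    rs <- series_resistance
    series_resistance <- function(f) rs * f
    attr(series_resistance, "scalar") <- rs
  }
  if (!is.null(series_resistance) &&
      abs(series_resistance(0)) > 1e-12) {
    stop("series_resistance(0) must be 0 for pathway '", name, "'", call. = FALSE)
  }
  structure(list(c_SL = c_SL, alpha = alpha, p_T = p_T, p_back = p_back,
                 series_resistance = series_resistance, name = name),
            class = "pathway_spec")
}

# closed form, no series drop
outflow_closed_form <- function(p, c_SL, alpha, p_T, p_back) {
  (c_SL / alpha) * (exp(-alpha * p_T) - exp(-alpha * (p - p_back)))
}

#' Linear leakage pathway
#'
#' A small pressure-proportional outflow route, `F = facility (p - p_ref)`,
#' used for the optic-nerve-head leak towards the CSF in the lumped surrogate
#' of the full model.
#'
#' @param facility Facility (uL/min/mmHg).
#' @param p_ref Reference (CSF) pressure (mmHg).
#' @param name Pathway label.
#' @return A `pathway_spec` of type "linear".
#' @export
pathway_linear <- function(facility, p_ref, name = "linear") {
  stopifnot(facility >= 0)
  structure(list(type = "linear", facility = facility, p_ref = p_ref,
                 c_SL = 0, series_resistance = NULL, name = name),
            class = "pathway_spec")
}

#' Outflow through one pathway at a given driving pressure
#'
#' Evaluates the integrated exponential outflow law. When the pathway carries
#' a series resistance the effective surface pressure `p_eff = p - drop(F)` is
#' solved self-consistently by damped fixed-point iteration. Flows below the
#' no-flow pressure (`p < p_T + p_back`) are mathematically negative
#' (backflow) and are flagged with a warning.
#'
#' @param p Pressure upstream of the pathway (mmHg), scalar or vector.
#' @param spec A [pathway_spec()].
#' @param quiet Suppress the backflow warning.
#' @return Flow in uL/min (same length as `p`).
#' @examples
#' anterior <- pathway_spec(c_SL = 0.5)
#' pathway_outflow(13.9, anterior)  # ~2.97 uL/min
#' @export
pathway_outflow <- function(p, spec, quiet = FALSE) {
  stopifnot(inherits(spec, "pathway_spec"))
  f <- vapply(p, function(pi) pathway_outflow_1(pi, spec), numeric(1))
  if (!quiet && any(f < 0)) {
    warning("backflow (negative outflow) below the no-flow pressure on '",
            spec$name, "'", call. = FALSE)
  }
  f
}

pathway_outflow_1 <- function(p, spec) {
  if (identical(spec$type, "linear")) {
    return(spec$facility * (p - spec$p_ref))
  }
  g <- function(pe) outflow_closed_form(pe, spec$c_SL, spec$alpha,
                                        spec$p_T, spec$p_back)
  if (is.null(spec$series_resistance)) return(g(p))
  # fixed point F = g(p - s(F)); s monotone non-decreasing, g increasing
  f <- g(p)
  for (i in seq_len(200L)) {
    f_new <- g(p - spec$series_resistance(max(f, 0)))
    if (abs(f_new - f) < 1e-12) return(f_new)
    f <- 0.5 * f + 0.5 * f_new
  }
  stop("series-resistance fixed point did not converge for pathway '",
       spec$name, "'", call. = FALSE)
}

#' Mean (tonographic) outflow facility of a pathway
#'
#' `pathway_outflow(p) / (p - p_T - p_back)`: the secant facility between the
#' operating point and the no-flow pressure, the quantity tonography reports.
#'
#' @inheritParams pathway_outflow
#' @return Facility in uL/min/mmHg.
#' @examples
#' tonographic_facility(19, pathway_spec(c_SL = 0.5, alpha = 0.075)) # ~0.233
#' tonographic_facility(19, pathway_spec(c_SL = 0.5, alpha = 0.10))  # ~0.185
#' @export
tonographic_facility <- function(p, spec) {
  stopifnot(inherits(spec, "pathway_spec"))
  dp <- p - spec$p_T - spec$p_back
  if (any(dp <= 1e-9)) {
    stop("facility undefined at or below the no-flow pressure p_T + p_back",
         call. = FALSE)
  }
  pathway_outflow(p, spec, quiet = TRUE) / dp
}

total_outflow <- function(p, pathways) {
  Reduce(`+`, lapply(pathways, function(s) pathway_outflow(p, s, quiet = TRUE)))
}

#' Solve the lumped model for IOP
#'
#' Finds the pressure at which total outflow over all pathways balances the
#' aqueous production rate, by bracketed root finding on
#' `[p_T + p_back, 200]` mmHg. The exponential law saturates at
#' `(c_SL/alpha) exp(-alpha p_T)` per pathway; a production rate above the
#' total saturation flow is rejected as unsustainable.
#'
#' @param q Aqueous production rate (uL/min), non-negative.
#' @param pathways A list of [pathway_spec()] objects (a single spec is
#'   accepted).
#' @return IOP in mmHg; residual below 1e-10 uL/min.
#' @examples
#' solve_iop(6.32, pathway_spec(c_SL = 1.0))  # ~15 mmHg
#' @export
solve_iop <- function(q, pathways) {
  if (inherits(pathways, "pathway_spec")) pathways <- list(pathways)
  stopifnot(q >= 0, length(pathways) >= 1L)
  expo <- !vapply(pathways, function(s) identical(s$type, "linear"), logical(1))
  p_floor <- if (any(expo)) {
    max(vapply(pathways[expo], function(s) s$p_T + s$p_back, numeric(1)))
  } else min(vapply(pathways, function(s) s$p_ref, numeric(1)))
  if (q == 0 && all(expo)) return(p_floor)
  f_sup <- if (all(expo)) {
    sum(vapply(pathways, function(s)
      (s$c_SL / s$alpha) * exp(-s$alpha * s$p_T), numeric(1)))
  } else Inf
  if (q >= f_sup) {
    stop("unsustainable production: ", format(q),
         " uL/min exceeds the saturation outflow ", format(f_sup), " uL/min",
         call. = FALSE)
  }
  lo <- min(p_floor, -50)
  if (all(expo)) lo <- p_floor
  hi <- 200
  if (total_outflow(hi, pathways) < q) {
    stop("root not bracketed below 200 mmHg", call. = FALSE)
  }
  stats::uniroot(function(p) total_outflow(p, pathways) - q,
                 lower = lo, upper = hi, tol = 1e-12)$root
}

#' Production rate consistent with a target IOP
#'
#' The inverse of [solve_iop()]: total outflow evaluated at `p_target`.
#'
#' @param p_target Target IOP (mmHg), above the no-flow pressure.
#' @inheritParams solve_iop
#' @return Production rate in uL/min.
#' @export
solve_production <- function(p_target, pathways) {
  if (inherits(pathways, "pathway_spec")) pathways <- list(pathways)
  total_outflow(p_target, pathways)
}

#' Two-pathway lumped surrogate of the full eye model
#'
#' Builds the anterior + RPE pathway pair from a parameter set, with the RPE
#' route carrying a linear series resistance representing the retina and
#' vitreous. The default resistance is calibrated from the full model's
#' trans-retinal + vitreous pressure drop (~1.2 mmHg at ~2.95 uL/min).
#'
#' @param params An [eye_params()] object.
#' @param rpe_series RPE series resistance, mmHg per uL/min.
#' @param onh_facility Linear facility of the optic-nerve-head leak towards
#'   the CSF (uL/min/mmHg): the series conductance of the prelaminar, laminar,
#'   retrolaminar and pial resistances of the full model. `NULL` omits the
#'   route (pure two-pathway surrogate).
#' @return A named list of [pathway_spec()] objects.
#' @export
lumped_pathways <- function(params, rpe_series = 0.407,
                            onh_facility = 0.00212) {
  pw <- list(
    anterior = pathway_spec(params$c_ap_SL, params$alpha, params$p_T,
                            params$p_back, name = "anterior"),
    rpe = pathway_spec(params$c_pre_SL, params$alpha, params$p_T,
                       params$p_back, series_resistance = rpe_series,
                       name = "rpe")
  )
  if (!is.null(onh_facility)) {
    pw$onh <- pathway_linear(onh_facility, params$p_CSF, name = "onh")
  }
  pw
}
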