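# Model parameter set: production rate, outflow-surface coefficients,
# tissue hydraulic conductivities, pial interface conductivity, porosity.

#' Construct a model parameter set
#'
#' Holds every physical parameter of the eye outflow model with its customary
#' reporting unit. Pressures are mmHg, the production rate is uL/min, surface
#' hydraulic conductivities are uL/min/mmHg, tissue hydraulic conductivities
#' are m^2/Pa-s and the pial interface conductivity is m/Pa-s. Internally the
#' solvers convert everything to SI.
#'
#' @param production_rate Aqueous production rate (uL/min).
#' @param c_total_SL Total surface hydraulic conductivity over all outflow
#'   surfaces (uL/min/mmHg). Must equal `c_pre_SL + c_ap_SL`.
#' @param c_pre_SL Surface hydraulic conductivity of the retinal pigment
#'   epithelium outflow route (uL/min/mmHg).
#' @param c_ap_SL Surface hydraulic conductivity of the lumped anterior
#'   pathways (conventional + uveoscleral + pseudofacility) (uL/min/mmHg).
#' @param alpha Exponential decay constant of outflow facility with pressure
#'   (1/mmHg).
#' @param p_T No-flow intraocular pressure (mmHg).
#' @param p_back All-round venous backpressure (mmHg).
#' @param p_CSF Cerebrospinal fluid pressure in the subarachnoid space around
#'   the optic nerve (mmHg); its floor is set by orbital pressure.
#' @param k_ac,k_vit,k_ret,k_ON,k_ONRL,k_ONLC,k_ONPL Hydraulic conductivities
#'   (m^2/Pa-s) of the anterior/posterior chambers, vitreous, retina, optic
#'   nerve, retrolaminar tissue, lamina cribrosa and prelaminar tissue.
#' @param h_ON Hydraulic conductivity of the pia mater and adjacent tissues at
#'   the optic nerve surface (m/Pa-s).
#' @param porosity_LC Fluid porosity of the lamina cribrosa axon bundles
#'   (dimensionless, in (0, 1)).
#' @return An object of class `eye_params` (a named list).
#' @seealso [default_normal_eye()], [validate_params()]
#' @export
eye_params <- function(production_rate = 6.14,
                       c_total_SL = 1.0,
                       c_pre_SL = 0.5,
                       c_ap_SL = 0.5,
                       alpha = 0.075,
                       p_T = 3,
                       p_back = 0,
                       p_CSF = 3,
                       k_ac = 1.0e-5,
                       k_vit = 8.4e-11,
                       k_ret = 5.0e-14,
                       k_ON = 1.6e-11,
                       k_ONRL = 9.1e-13,
                       k_ONLC = 7.7e-14,
                       k_ONPL = 8.3e-13,
                       h_ON = 1.5e-11,
                       porosity_LC = 0.70) {
  p <- list(
    production_rate = production_rate,
    c_total_SL = c_total_SL, c_pre_SL = c_pre_SL, c_ap_SL = c_ap_SL,
    alpha = alpha, p_T = p_T, p_back = p_back, p_CSF = p_CSF,
    k_ac = k_ac, k_vit = k_vit, k_ret = k_ret, k_ON = k_ON,
    k_ONRL = k_ONRL, k_ONLC = k_ONLC, k_ONPL = k_ONPL,
    h_ON = h_ON, porosity_LC = porosity_LC
  )
  class(p) <- "eye_params"
  validate_params(p)
}

#' Reference parameter set for the normal upright human eye
#'
#' The calibrated base-case parameter set: production 6.14 uL/min, total
#' surface conductivity 1.0 split evenly between anterior pathways and the
#' retinal pigment epithelium, alpha 0.075/mmHg, no-flow pressure 3 mmHg,
#' zero backpressure and a 3 mmHg CSF floor pressure.
#'
#' @return An `eye_params` object.
#' @examples
#' p <- default_normal_eye()
#' p$k_ONLC  # 7.7e-14 m^2/Pa-s
#' @export
default_normal_eye <- function() eye_params()

#' Validate a parameter set
#'
#' Checks positivity of all conductivities and `alpha`, non-negative `p_T`,
#' porosity in (0, 1), and consistency `c_pre_SL + c_ap_SL == c_total_SL`
#' (to 1e-12 relative).
#'
#' @param p An `eye_params` object (or plain named list with the same fields).
#' @return `p`, invisibly classed as `eye_params`, or an error.
#' @export
validate_params <- function(p) {
  ks <- c("k_ac", "k_vit", "k_ret", "k_ON", "k_ONRL", "k_ONLC", "k_ONPL", "h_ON")
  for (f in ks) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !(p[[f]] > 0)) {
      stop("parameter '", f, "' must be a positive scalar", call. = FALSE)
    }
  }
  if (!(p$alpha > 0)) stop("'alpha' must be positive", call. = FALSE)
  if (p$p_T < 0) stop("'p_T' must be non-negative", call. = FALSE)
  if (p$c_pre_SL < 0 || p$c_ap_SL < 0) {
    stop("surface hydraulic conductivities must be non-negative", call. = FALSE)
  }
  if (!(p$porosity_LC > 0 && p$porosity_LC < 1)) {
    stop("'porosity_LC' must lie in (0, 1)", call. = FALSE)
  }
  tot <- p$c_pre_SL + p$c_ap_SL
  if (abs(tot - p$c_total_SL) > 1e-12 * max(1, abs(p$c_total_SL))) {
    stop("c_pre_SL + c_ap_SL must equal c_total_SL (got ",
         format(tot), " vs ", format(p$c_total_SL), ")", call. = FALSE)
  }
  class(p) <- "eye_params"
  invisible(p)
}

#' Modify parameters, keeping the split consistency invariant
#'
#' Convenience wrapper used by the scenario layer: applies named overrides and
#' re-derives `c_total_SL` when only one of the split conductivities changes.
#'
#' @param p An `eye_params` object.
#' @param ... Named overrides of any parameter field.
#' @return A new validated `eye_params` object.
#' @export
update_params <- function(p, ...) {
  over <- list(...)
  if (length(over) == 0L) return(p)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  # keep the total in step unless the caller set it explicitly
  if (any(c("c_pre_SL", "c_ap_SL") %in% names(over)) &&
      !("c_total_SL" %in% names(over))) {
    p$c_total_SL <- p$c_pre_SL + p$c_ap_SL
  }
  validate_params(p)
  p
}

#' @export
print.eye_params <- function(x, ...) {
  cat("<eye_params>\n")
  print(as_tibble_params(x))
  invisible(x)
}

param_units <- c(
  production_rate = "uL/min",
  c_total_SL = "uL/min/mmHg", c_pre_SL = "uL/min/mmHg", c_ap_SL = "uL/min/mmHg",
  alpha = "1/mmHg", p_T = "mmHg", p_back = "mmHg", p_CSF = "mmHg",
  k_ac = "m^2/Pa-s", k_vit = "m^2/Pa-s", k_ret = "m^2/Pa-s", k_ON = "m^2/Pa-s",
  k_ONRL = "m^2/Pa-s", k_ONLC = "m^2/Pa-s", k_ONPL = "m^2/Pa-s",
  h_ON = "m/Pa-s", porosity_LC = "-"
)

#' Parameter set as a tibble
#'
#' @param p An `eye_params` object.
#' @return A tibble with columns `parameter`, `value`, `units`.
#' @export
as_tibble_params <- function(p) {
  tibble::tibble(
    parameter = names(param_units),
    value = vapply(names(param_units), function(f) p[[f]], numeric(1)),
    units = unname(param_units)
  )
}

#' Read/write a parameter set as YAML
#'
#' The file holds a `parameters` block (snake_case keys as in the model
#' parameter table) and a `units` metadata block.
#'
#' @param p An `eye_params` object.
#' @param path File path.
#' @return `write_params` returns `path` invisibly; `read_params` returns an
#'   `eye_params` object.
#' @export
write_params <- function(p, path) {
  yaml::write_yaml(list(parameters = unclass(p),
                        units = as.list(param_units)), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  y <- yaml::read_yaml(path)
  vals <- y$parameters %||% y
  do.call(eye_params, vals[intersect(names(vals), names(param_units))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
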