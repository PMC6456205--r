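# Axisymmetric eye geometry. The eye is a sphere of internal diameter 23.6 mm
# with the optic nerve on the symmetry axis (shifted there from its off-centre
# anatomical position). Coordinates are (r, z) in metres, z increasing from
# the optic nerve (posterior) to the cornea (anterior), globe centre at the
# origin. The anterior segment (posterior/anterior chambers, lens, iris) is
# represented by simple cylindrical blocks: the chambers carry a very large
# hydraulic conductivity so their exact shape does not influence the flow.

#' Construct the eye geometry configuration
#'
#' All lengths in metres. Defaults reconstruct an average adult eye from the
#' dimensions the model is built on: 23.6 mm internal diameter, 1.6 mm optic
#' disc, 3.2 mm optic nerve, 0.38 mm lamina cribrosa, ~6 mm of modeled nerve.
#' Layer thicknesses not fixed by those dimensions (retina, prelaminar,
#' retrolaminar, chamber depths) are configuration, not code, and are
#' documented in the methods vignette.
#'
#' @param internal_diameter Internal diameter of the globe (outer model
#'   boundary, the retinal pigment epithelium level).
#' @param retina_thickness Retinal shell thickness.
#' @param disc_diameter Optic disc (scleral canal) diameter.
#' @param nerve_diameter Myelinated optic nerve diameter.
#' @param nerve_length Length of optic nerve proper included distal to the
#'   retrolaminar segment.
#' @param prelaminar_thickness,lc_thickness,retrolaminar_thickness Axial
#'   thicknesses of the optic nerve head layers.
#' @param ora_serrata_z Axial position (z) of the retinal margin (ora
#'   serrata) on the inner sphere.
#' @param vitreous_top_z Axial position of the anterior hyaloid plane bounding
#'   the vitreous.
#' @param lens_gap Thickness of the impermeable lens slab separating the
#'   posterior chamber from the vitreous.
#' @param posterior_chamber_depth,anterior_chamber_depth Chamber depths.
#' @param iris_gap Thickness of the impermeable iris slab separating the
#'   chambers.
#' @param lens_radius Lens radius: the posterior chamber communicates with the
#'   vitreous only outside this radius.
#' @param pupil_radius Pupil radius: the chambers communicate only inside
#'   this radius.
#' @param limbal_band_width Axial width of the limbal (anterior outflow)
#'   annulus on the anterior chamber wall.
#' @param ciliary_torus_minor_radius Nominal minor radius of the ciliary-body
#'   torus; the inflow is applied as a uniform band on the posterior chamber
#'   wall whose exact extent does not materially influence the results.
#' @return An object of class `eye_geometry`.
#' @export
eye_geometry <- function(internal_diameter = 23.6e-3,
                         retina_thickness = 0.16e-3,
                         disc_diameter = 1.6e-3,
                         nerve_diameter = 3.2e-3,
                         nerve_length = 6.0e-3,
                         prelaminar_thickness = 0.3e-3,
                         lc_thickness = 0.38e-3,
                         retrolaminar_thickness = 0.5e-3,
                         ora_serrata_z = 3.4e-3,
                         vitreous_top_z = 6.0e-3,
                         lens_gap = 1.0e-3,
                         posterior_chamber_depth = 1.4e-3,
                         iris_gap = 0.5e-3,
                         anterior_chamber_depth = 3.0e-3,
                         lens_radius = 4.5e-3,
                         pupil_radius = 1.5e-3,
                         limbal_band_width = 1.2e-3,
                         ciliary_torus_minor_radius = 0.5e-3) {
  g <- as.list(environment())
  class(g) <- "eye_geometry"
  validate_geometry(g)
  g
}

#' Validate an eye geometry configuration
#'
#' @param g An `eye_geometry` object or compatible named list.
#' @return `g` invisibly, or an error naming the offending field.
#' @export
validate_geometry <- function(g) {
  pos <- c("internal_diameter", "retina_thickness", "disc_diameter",
           "nerve_diameter", "nerve_length", "prelaminar_thickness",
           "lc_thickness", "retrolaminar_thickness", "lens_gap",
           "posterior_chamber_depth", "iris_gap", "anterior_chamber_depth",
           "lens_radius", "pupil_radius", "limbal_band_width")
  for (f in pos) {
    if (!is.numeric(g[[f]]) || length(g[[f]]) != 1L || !(g[[f]] > 0)) {
      stop("geometry field '", f, "' must be a positive scalar", call. = FALSE)
    }
  }
  if (g$disc_diameter >= g$nerve_diameter) {
    stop("disc_diameter must be smaller than nerve_diameter", call. = FALSE)
  }
  Ri <- g$internal_diameter / 2 - g$retina_thickness
  if (abs(g$ora_serrata_z) >= Ri) {
    stop("ora_serrata_z must lie inside the inner sphere", call. = FALSE)
  }
  if (abs(g$vitreous_top_z) >= Ri) {
    stop("vitreous_top_z must lie inside the inner sphere", call. = FALSE)
  }
  d <- derived_geometry(g)
  if (!(g$ora_serrata_z > -d$Ri && g$ora_serrata_z < g$vitreous_top_z)) {
    stop("ora_serrata_z must lie between the posterior pole and vitreous_top_z",
         call. = FALSE)
  }
  if (g$vitreous_top_z >= d$Ri) {
    stop("vitreous_top_z must be below the top of the inner sphere", call. = FALSE)
  }
  if (g$pupil_radius >= g$lens_radius) {
    stop("pupil_radius must be smaller than lens_radius", call. = FALSE)
  }
  if (g$lens_radius >= d$r_vit_top) {
    stop("lens_radius must be smaller than the vitreous top-plane radius",
         call. = FALSE)
  }
  if (g$limbal_band_width >= g$anterior_chamber_depth) {
    stop("limbal_band_width must be smaller than anterior_chamber_depth",
         call. = FALSE)
  }
  invisible(g)
}

# All derived coordinates used by the mesher and classifiers.
derived_geometry <- function(g) {
  R  <- g$internal_diameter / 2
  Ri <- R - g$retina_thickness
  r_disc  <- g$disc_diameter / 2
  r_nerve <- g$nerve_diameter / 2
  theta_d   <- asin(r_disc / Ri)
  theta_ora <- acos(-g$ora_serrata_z / Ri)  # polar angle from posterior pole
  z1 <- g$vitreous_top_z
  theta_z1 <- acos(-z1 / Ri)
  z_disc <- -Ri * cos(theta_d)              # flat disc face
  list(
    R = R, Ri = Ri, r_disc = r_disc, r_nerve = r_nerve,
    theta_d = theta_d, theta_ora = theta_ora, theta_z1 = theta_z1,
    z_disc = z_disc,
    z_lc_a = z_disc - g$prelaminar_thickness,
    z_lc_p = z_disc - g$prelaminar_thickness - g$lc_thickness,
    z_rl   = z_disc - g$prelaminar_thickness - g$lc_thickness -
             g$retrolaminar_thickness,
    z_nerve_end = z_disc - g$prelaminar_thickness - g$lc_thickness -
                  g$retrolaminar_thickness - g$nerve_length,
    r_vit_top = sqrt(Ri^2 - z1^2),
    r_chamber = sqrt(R^2 - z1^2),
    z_pc_bot = z1 + g$lens_gap,
    z_pc_top = z1 + g$lens_gap + g$posterior_chamber_depth,
    z_ac_bot = z1 + g$lens_gap + g$posterior_chamber_depth + g$iris_gap,
    z_ac_top = z1 + g$lens_gap + g$posterior_chamber_depth + g$iris_gap +
               g$anterior_chamber_depth
  )
}

#' Labeled subdomain description of the eye half-section
#'
#' Expands a geometry configuration into the labeled planar subdomains the
#' mesher triangulates, with exact half-section areas (used by the tiling
#' check) and headline surface areas.
#'
#' @param g An [eye_geometry()] object.
#' @return A list with elements `regions` (tibble: region, area_m2),
#'   `sphere_surface_area` (full globe, 4 pi R^2), `retina_outer_area`
#'   (revolved RPE outflow surface), and `derived` (internal coordinates).
#' @export
build_geometry <- function(g) {
  validate_geometry(g)
  d <- derived_geometry(g)
  # exact (r,z) planar areas per region
  a_pl <- d$r_disc * g$prelaminar_thickness
  a_lc <- d$r_disc * g$lc_thickness
  a_rl <- (d$r_disc + d$r_nerve) / 2 * g$retrolaminar_thickness
  a_nv <- d$r_nerve * g$nerve_length
  a_ret <- (d$theta_ora - d$theta_d) * (d$R^2 - d$Ri^2) / 2
  # vitreous: polar sector area about the globe centre (see derivation in the
  # methods vignette): flat disc cap + spherical sector + top-plane cap
  a_vit <- d$Ri^2 * (cos(d$theta_d) * sin(d$theta_d) +
                     d$theta_z1 - d$theta_d) / 2 +
           g$vitreous_top_z * d$r_vit_top / 2
  a_pc <- d$r_chamber * g$posterior_chamber_depth +
          (d$r_vit_top - g$lens_radius) * g$lens_gap
  a_ac <- d$r_chamber * g$anterior_chamber_depth +
          g$pupil_radius * g$iris_gap
  regions <- tibble::tibble(
    region = c("anterior_chamber", "posterior_chamber", "vitreous", "retina",
               "onh_prelaminar", "onh_lamina_cribrosa", "onh_retrolaminar",
               "optic_nerve"),
    area_m2 = c(a_ac, a_pc, a_vit, a_ret, a_pl, a_lc, a_rl, a_nv)
  )
  list(
    regions = regions,
    sphere_surface_area = 4 * pi * d$R^2,
    retina_outer_area = 2 * pi * d$R^2 * (cos(d$theta_d) - cos(d$theta_ora)),
    derived = d,
    config = g
  )
}

#' @export
print.eye_geometry <- function(x, ...) {
  d <- derived_geometry(x)
  cat("<eye_geometry>\n")
  cat(sprintf("  globe internal radius   %.2f mm\n", 1e3 * d$R))
  cat(sprintf("  optic disc radius       %.2f mm\n", 1e3 * d$r_disc))
  cat(sprintf("  nerve radius / length   %.2f / %.2f mm\n",
              1e3 * d$r_nerve, 1e3 * x$nerve_length))
  cat(sprintf("  ONH layers (PL/LC/RL)   %.2f / %.2f / %.2f mm\n",
              1e3 * x$prelaminar_thickness, 1e3 * x$lc_thickness,
              1e3 * x$retrolaminar_thickness))
  invisible(x)
}
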