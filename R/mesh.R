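# Structured multi-block triangulation of the eye half-section.
#
# Each region is meshed as a mapped quadrilateral grid split into triangles;
# coordinates on shared interfaces are produced from the *same* numeric
# vectors in both adjacent blocks, so nodes coincide bit-exactly and a merge
# by exact coordinate key yields a conforming mesh. The vitreous is meshed in
# polar fashion about the globe centre (it is star-shaped with respect to
# it), with its boundary ring anchored to canonical interface points.

# n+1 points from a to b, interval widths in geometric progression with
# last/first ratio `ratio` (ratio > 1: fine near a).
seq_graded <- function(a, b, n, ratio = 1) {
  if (n == 1L || ratio == 1) return(seq(a, b, length.out = n + 1L))
  w <- ratio^((seq_len(n) - 1) / (n - 1))
  a + (b - a) * c(0, cumsum(w)) / sum(w)
}

# Triangulate an nu x nv structured node grid (index matrix) into 2(nu-1)(nv-1)
# triangles; returns an integer matrix of local node indices.
grid_tris <- function(nu, nv) {
  idx <- matrix(seq_len(nu * nv), nrow = nu)
  i <- rep(seq_len(nu - 1L), nv - 1L)
  j <- rep(seq_len(nv - 1L), each = nu - 1L)
  a <- idx[cbind(i, j)]
  b <- idx[cbind(i + 1L, j)]
  c_ <- idx[cbind(i + 1L, j + 1L)]
  d <- idx[cbind(i, j + 1L)]
  rbind(cbind(a, b, c_), cbind(a, c_, d))
}

# A rectangular-ish block from explicit per-row radial coordinates.
# r_rows: list (length nv) of numeric vectors (length nu) of r per row,
# z_rows: numeric vector length nv. Returns list(coords, tris).
block_from_rows <- function(r_rows, z_rows) {
  nv <- length(z_rows)
  nu <- length(r_rows[[1]])
  coords <- do.call(rbind, lapply(seq_len(nv), function(j) {
    cbind(r_rows[[j]], rep(z_rows[j], nu))
  }))
  # grid index: node (i,j) at (j-1)*nu + i -> arrange as nu x nv
  tris <- {
    idx <- matrix(seq_len(nu * nv), nrow = nu)
    i <- rep(seq_len(nu - 1L), nv - 1L)
    j <- rep(seq_len(nv - 1L), each = nu - 1L)
    a <- idx[cbind(i, j)]; b <- idx[cbind(i + 1L, j)]
    cc <- idx[cbind(i + 1L, j + 1L)]; d <- idx[cbind(i, j + 1L)]
    rbind(cbind(a, b, cc), cbind(a, cc, d))
  }
  list(coords = coords, tris = tris)
}

rect_block <- function(r_vec, z_vec) {
  block_from_rows(rep(list(r_vec), length(z_vec)), z_vec)
}

#' Generate the axisymmetric finite-element mesh of the eye
#'
#' Conforming triangulation (linear P1 elements) of the eye half-section with
#' region labels per tissue and labeled boundary segments. The optic nerve
#' head layers are locally refined (at least 4 elements across the lamina
#' cribrosa at any resolution).
#'
#' @param geometry An [eye_geometry()] object.
#' @param h Target edge length (m) away from the optic nerve head. The
#'   default yields roughly 6,000 elements.
#' @return An object of class `axisym_mesh`: list with `nodes` (n x 2 matrix,
#'   metres), `triangles` (m x 3), `region` (character, per triangle),
#'   `boundary_edges` (b x 2), `boundary_label` (character, per edge),
#'   `geometry`, `derived`.
#' @export
generate_mesh <- function(geometry, h = 1.7e-4) {
  stopifnot(h > 0)
  validate_geometry(geometry)
  g <- geometry
  d <- derived_geometry(g)
  f <- 3e-4 / h

  nr      <- max(6L, round(8 * f))    # intervals across disc radius
  nz_pl   <- max(3L, round(4 * f))
  nz_lc   <- max(4L, round(5 * f))    # >= 4 across the lamina cribrosa
  nz_rl   <- max(3L, round(4 * f))
  nz_nv   <- max(8L, round(14 * f))
  n_ret   <- max(14L, round(30 * f))  # retina angular intervals
  n_lay   <- max(2L, round(3 * f))    # retina radial layers
  n_pp    <- max(3L, round(5 * f))    # pars plana angular intervals
  n_s     <- max(7L, round(11 * f))   # vitreous radial levels
  nz_pc   <- max(2L, round(2 * f))
  nz_ac   <- max(3L, round(3 * f))
  h_ch    <- 3 * h                    # chamber lateral spacing

  ## ---- canonical shared coordinate vectors -------------------------------
  col_r   <- seq(0, d$r_disc, length.out = nr + 1L)
  nerve_r <- col_r / d$r_disc * d$r_nerve

  master_r <- c(
    seq(0, g$pupil_radius, length.out = max(2L, ceiling(g$pupil_radius / h_ch)) + 1L),
    seq(g$pupil_radius, g$lens_radius,
        length.out = max(2L, ceiling((g$lens_radius - g$pupil_radius) / h_ch)) + 1L)[-1],
    seq(g$lens_radius, d$r_vit_top,
        length.out = max(3L, ceiling((d$r_vit_top - g$lens_radius) / h_ch)) + 1L)[-1],
    seq(d$r_vit_top, d$r_chamber, length.out = 2L)[-1]
  )

  z1 <- g$vitreous_top_z
  # vitreous boundary ring, theta from 0 (posterior pole) to pi (top centre)
  th_ret <- seq_graded(d$theta_d, d$theta_ora, n_ret, ratio = 6)
  th_pp  <- seq(d$theta_ora, d$theta_z1, length.out = n_pp + 1L)
  ret_pts <- cbind(d$Ri * sin(th_ret), -d$Ri * cos(th_ret))
  ret_pts[1, ] <- c(d$r_disc, d$z_disc)          # canonical disc corner
  pp_pts <- cbind(d$Ri * sin(th_pp), -d$Ri * cos(th_pp))
  pp_pts[1, ] <- ret_pts[nrow(ret_pts), ]        # canonical ora corner
  pp_pts[nrow(pp_pts), ] <- c(d$r_vit_top, z1)   # canonical top corner
  top_r <- rev(master_r[master_r < d$r_vit_top - 1e-12])
  top_pts <- cbind(top_r, rep(z1, length(top_r)))
  ring <- rbind(
    cbind(col_r, rep(d$z_disc, nr + 1L)),        # disc face (incl corner)
    ret_pts[-1, , drop = FALSE],
    pp_pts[-1, , drop = FALSE],
    top_pts
  )

  blocks <- list()
  add <- function(b, region) {
    b$region <- region
    blocks[[length(blocks) + 1L]] <<- b
  }

  ## ---- optic nerve column ------------------------------------------------
  add(rect_block(col_r, seq(d$z_lc_a, d$z_disc, length.out = nz_pl + 1L)),
      "onh_prelaminar")
  add(rect_block(col_r, seq(d$z_lc_p, d$z_lc_a, length.out = nz_lc + 1L)),
      "onh_lamina_cribrosa")
  # retrolaminar expansion cone: rows interpolate nerve_r (bottom) -> col_r (top)
  z_cone <- seq(d$z_rl, d$z_lc_p, length.out = nz_rl + 1L)
  t_cone <- (z_cone - d$z_rl) / (d$z_lc_p - d$z_rl)
  add(block_from_rows(lapply(t_cone, function(t) (1 - t) * nerve_r + t * col_r),
                      z_cone), "onh_retrolaminar")
  z_nv <- rev(d$z_rl - seq_graded(0, g$nerve_length, nz_nv, ratio = 4))
  add(rect_block(nerve_r, z_nv), "optic_nerve")

  ## ---- vitreous (polar about globe centre) -------------------------------
  u <- seq(0, 1, length.out = n_s + 1L)
  s_lev <- 1 - (1 - u)^1.7                       # crowd levels near the wall
  nring <- nrow(ring)
  vit_coords <- rbind(
    c(0, 0),                                     # centre node (fan apex)
    do.call(rbind, lapply(s_lev[-1], function(s)
      if (s == 1) ring else ring * s))
  )
  n_in <- n_s                                    # interior+boundary levels
  lev_idx <- function(i) 2L + (i - 1L) * nring   # first node of level i (1 = apex)
  vit_tris <- list()
  for (jj in seq_len(nring - 1L)) {              # centre fan
    vit_tris[[length(vit_tris) + 1L]] <-
      c(1L, lev_idx(1L) + jj - 1L, lev_idx(1L) + jj)
  }
  for (i in seq_len(n_in - 1L)) {
    for (jj in seq_len(nring - 1L)) {
      a <- lev_idx(i) + jj - 1L; b <- a + 1L
      cc <- lev_idx(i + 1L) + jj; dd <- cc - 1L
      vit_tris[[length(vit_tris) + 1L]] <- c(a, b, cc)
      vit_tris[[length(vit_tris) + 1L]] <- c(a, cc, dd)
    }
  }
  add(list(coords = vit_coords, tris = do.call(rbind, vit_tris)), "vitreous")

  ## ---- retina shell ------------------------------------------------------
  ret_ring <- rbind(ret_pts[1, , drop = FALSE], ret_pts[-1, , drop = FALSE])
  t_lay <- seq(0, g$retina_thickness, length.out = n_lay + 1L)
  ret_coords <- do.call(rbind, lapply(t_lay, function(t)
    if (t == 0) ret_ring else ret_ring * ((d$Ri + t) / d$Ri)))
  nrr <- nrow(ret_ring)
  ret_tris <- list()
  for (k in seq_len(n_lay)) {
    for (jj in seq_len(nrr - 1L)) {
      a <- (k - 1L) * nrr + jj; b <- a + 1L
      cc <- k * nrr + jj + 1L; dd <- cc - 1L
      ret_tris[[length(ret_tris) + 1L]] <- c(a, b, cc)
      ret_tris[[length(ret_tris) + 1L]] <- c(a, cc, dd)
    }
  }
  add(list(coords = ret_coords, tris = do.call(rbind, ret_tris)), "retina")

  ## ---- chambers and connectors ------------------------------------------
  ring_r <- master_r[master_r >= g$lens_radius - 1e-12 &
                     master_r <= d$r_vit_top + 1e-12]
  add(rect_block(ring_r, seq(z1, d$z_pc_bot, length.out = 3L)),
      "posterior_chamber")
  add(rect_block(master_r, seq(d$z_pc_bot, d$z_pc_top, length.out = nz_pc + 1L)),
      "posterior_chamber")
  pup_r <- master_r[master_r <= g$pupil_radius + 1e-12]
  add(rect_block(pup_r, seq(d$z_pc_top, d$z_ac_bot, length.out = 3L)),
      "anterior_chamber")
  add(rect_block(master_r, seq(d$z_ac_bot, d$z_ac_top, length.out = nz_ac + 1L)),
      "anterior_chamber")

  ## ---- merge blocks ------------------------------------------------------
  all_coords <- do.call(rbind, lapply(blocks, `[[`, "coords"))
  offs <- cumsum(c(0L, vapply(blocks, function(b) nrow(b$coords), integer(1))))
  all_tris <- do.call(rbind, lapply(seq_along(blocks), function(i)
    blocks[[i]]$tris + offs[i]))
  region <- unlist(lapply(blocks, function(b) rep(b$region, nrow(b$tris))))

  key <- paste(sprintf("%.17g", all_coords[, 1]),
               sprintf("%.17g", all_coords[, 2]))
  uid <- match(key, key[!duplicated(key)])
  nodes <- all_coords[!duplicated(key), , drop = FALSE]
  tris <- matrix(uid[all_tris], ncol = 3L)

  # orient counter-clockwise (positive area)
  p1 <- nodes[tris[, 1], , drop = FALSE]
  p2 <- nodes[tris[, 2], , drop = FALSE]
  p3 <- nodes[tris[, 3], , drop = FALSE]
  a2 <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
        (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  flip <- a2 < 0
  tris[flip, 2:3] <- tris[flip, 3:2]
  if (any(abs(a2) < 1e-16)) stop("degenerate (zero-area) triangle produced")

  mesh <- structure(list(nodes = nodes, triangles = tris, region = region,
                         geometry = g, derived = d, h = h),
                    class = "axisym_mesh")
  bd <- extract_boundary(mesh)
  mesh$boundary_edges <- bd$edges
  mesh$boundary_label <- classify_boundary(mesh, bd)
  mesh
}

# boundary edges (those owned by exactly one triangle) + owning region
extract_boundary <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  own <- rep(seq_len(nrow(tr)), 3L)
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(ekey)
  if (any(cnt > 2)) stop("non-manifold edge in mesh")
  is_bd <- cnt[ekey] == 1L
  list(edges = e[is_bd, , drop = FALSE],
       owner_region = mesh$region[own[is_bd]])
}

classify_boundary <- function(mesh, bd, tol = 1e-7) {
  g <- mesh$geometry; d <- mesh$derived
  n1 <- mesh$nodes[bd$edges[, 1], , drop = FALSE]
  n2 <- mesh$nodes[bd$edges[, 2], , drop = FALSE]
  reg <- bd$owner_region
  lab <- rep("impermeable", nrow(bd$edges))

  on_axis <- abs(n1[, 1]) < tol & abs(n2[, 1]) < tol
  lab[on_axis] <- "symmetry_axis"

  rad1 <- sqrt(rowSums(n1^2)); rad2 <- sqrt(rowSums(n2^2))
  lab[reg == "retina" & abs(rad1 - d$R) < tol & abs(rad2 - d$R) < tol] <-
    "rpe_outflow"

  on_wall <- abs(n1[, 1] - d$r_chamber) < tol & abs(n2[, 1] - d$r_chamber) < tol
  lab[reg == "posterior_chamber" & on_wall] <- "ciliary_inflow"
  zmax <- pmax(n1[, 2], n2[, 2])
  lab[reg == "anterior_chamber" & on_wall &
      zmax <= d$z_ac_bot + g$limbal_band_width + tol] <- "anterior_outflow"

  nerve_side <- abs(n1[, 1] - d$r_nerve) < tol & abs(n2[, 1] - d$r_nerve) < tol &
    n1[, 2] <= d$z_rl + tol & n2[, 2] <= d$z_rl + tol
  lab[reg %in% c("optic_nerve", "onh_retrolaminar") & nerve_side] <-
    "pia_interface"
  # retrolaminar expansion cone flank
  cone_dist <- function(p) {
    a <- c(d$r_nerve, d$z_rl); b <- c(d$r_disc, d$z_lc_p)
    ab <- b - a
    t <- pmin(1, pmax(0, ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) /
                           sum(ab^2)))
    sqrt((p[, 1] - (a[1] + t * ab[1]))^2 + (p[, 2] - (a[2] + t * ab[2]))^2)
  }
  on_cone <- cone_dist(n1) < tol & cone_dist(n2) < tol
  lab[reg == "onh_retrolaminar" & on_cone] <- "pia_interface"

  on_distal <- abs(n1[, 2] - d$z_nerve_end) < tol & abs(n2[, 2] - d$z_nerve_end) < tol
  lab[reg == "optic_nerve" & on_distal] <- "distal_nerve_face"
  lab
}

#' Triangle areas of an axisymmetric mesh (planar, m^2)
#' @param mesh An `axisym_mesh`.
#' @return Numeric vector of (r,z)-plane triangle areas.
#' @export
mesh_areas <- function(mesh) {
  p1 <- mesh$nodes[mesh$triangles[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$triangles[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$triangles[, 3], , drop = FALSE]
  0.5 * abs((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
            (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
}

#' Revolved surface area of a labeled boundary
#'
#' Area of the surface of revolution generated by the labeled boundary
#' segment (Pappus: sum of 2 pi r_mid L over its edges).
#'
#' @param mesh An `axisym_mesh`.
#' @param boundary_label Boundary label present in the mesh.
#' @return Area in m^2.
#' @export
revolved_surface_area <- function(mesh, boundary_label) {
  sel <- mesh$boundary_label == boundary_label
  if (!any(sel) && !(boundary_label %in% mesh$boundary_label)) {
    stop("unknown boundary label '", boundary_label, "'", call. = FALSE)
  }
  e <- mesh$boundary_edges[sel, , drop = FALSE]
  n1 <- mesh$nodes[e[, 1], , drop = FALSE]
  n2 <- mesh$nodes[e[, 2], , drop = FALSE]
  len <- sqrt(rowSums((n2 - n1)^2))
  rmid <- (n1[, 1] + n2[, 1]) / 2
  sum(2 * pi * rmid * len)
}

#' @export
print.axisym_mesh <- function(x, ...) {
  cat("<axisym_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$triangles),
      " triangles\n", sep = "")
  cat("  regions: ", paste(sort(unique(x$region)), collapse = ", "), "\n")
  cat("  boundaries: ", paste(sort(unique(x$boundary_label)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Mesh summary as a tibble (per-region element counts and areas)
#' @param mesh An `axisym_mesh`.
#' @return A tibble with region, element count and planar area.
#' @export
mesh_summary <- function(mesh) {
  ar <- mesh_areas(mesh)
  regs <- sort(unique(mesh$region))
  tibble::tibble(
    region = regs,
    n_elements = vapply(regs, function(r) sum(mesh$region == r), integer(1),
                        USE.NAMES = FALSE),
    area_m2 = vapply(regs, function(r) sum(ar[mesh$region == r]), numeric(1),
                     USE.NAMES = FALSE)
  )
}

#' Plot a mesh
#'
#' @param object An `axisym_mesh`.
#' @param ... Unused.
#' @return A ggplot object (triangles coloured by region).
#' @exportS3Method ggplot2::autoplot
autoplot.axisym_mesh <- function(object, ...) {
  tr <- object$triangles
  df <- data.frame(
    id = rep(seq_len(nrow(tr)), each = 3L),
    r = as.vector(t(matrix(object$nodes[t(tr), 1], nrow = 3L))) * 1e3,
    z = as.vector(t(matrix(object$nodes[t(tr), 2], nrow = 3L))) * 1e3,
    region = rep(object$region, each = 3L)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$r, .data$z, group = .data$id,
                                   fill = .data$region)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.05) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "r (mm)", y = "z (mm)", fill = "region")
}
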