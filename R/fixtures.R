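# Deterministic test fixtures with known analytic Darcy solutions.

#' Generate a small deterministic fixture mesh
#'
#' * `annulus`: cylindrical annulus `r in [r1, r2]`, height `H`; with fixed
#'   pressures on the inner/outer faces the solution is the log-radial
#'   profile `p(r) = p1 + (p2 - p1) log(r/r1) / log(r2/r1)`.
#' * `sphere_shell`: spherical shell `rho in [R1, R2]` (full half-section,
#'   polar angle 0..pi); with fixed face pressures the solution is
#'   `p(rho) = A + B/rho`.
#' * `coarse_eye`: the default eye geometry meshed coarsely (under 2,500
#'   elements), for fast smoke tests.
#'
#' Boundary labels are `inner_face` / `outer_face` / `end_faces` (+
#' `symmetry_axis` where the axis is part of the domain) for the analytic
#' fixtures; the coarse eye carries the standard eye labels.
#'
#' @param kind One of `"annulus"`, `"sphere_shell"`, `"coarse_eye"`.
#' @param n Resolution (intervals across the thickness).
#' @param r1,r2 Inner/outer radius (m).
#' @param H Annulus height (m).
#' @return An `axisym_mesh`.
#' @export
make_fixture <- function(kind = c("annulus", "sphere_shell", "coarse_eye"),
                         n = 12L, r1 = 5e-3, r2 = 10e-3, H = 4e-3) {
  kind <- match.arg(kind)
  if (kind == "coarse_eye") {
    return(generate_mesh(eye_geometry(), h = 4.5e-4))
  }
  if (kind == "annulus") {
    nz <- max(4L, round(n / 2))
    b <- rect_block(seq(r1, r2, length.out = 3L * n + 1L),
                    seq(0, H, length.out = nz + 1L))
    mesh <- structure(list(nodes = b$coords, triangles = b$tris,
                           region = rep("shell", nrow(b$tris)),
                           geometry = NULL, derived = NULL, h = (r2 - r1) / n),
                      class = "axisym_mesh")
    mesh <- orient_mesh(mesh)
    bd <- extract_boundary(mesh)
    n1 <- mesh$nodes[bd$edges[, 1], , drop = FALSE]
    n2 <- mesh$nodes[bd$edges[, 2], , drop = FALSE]
    tol <- 1e-9
    lab <- rep("end_faces", nrow(bd$edges))
    lab[abs(n1[, 1] - r1) < tol & abs(n2[, 1] - r1) < tol] <- "inner_face"
    lab[abs(n1[, 1] - r2) < tol & abs(n2[, 1] - r2) < tol] <- "outer_face"
    mesh$boundary_edges <- bd$edges
    mesh$boundary_label <- lab
    return(mesh)
  }
  # spherical shell: polar grid theta 0..pi, rho R1..R2
  th <- seq(0, pi, length.out = 6L * n + 1L)
  rho <- seq(r1, r2, length.out = n + 1L)
  coords <- do.call(rbind, lapply(rho, function(rr)
    cbind(rr * sin(th), -rr * cos(th))))
  nth <- length(th)
  tris <- list()
  for (i in seq_len(length(rho) - 1L)) {
    for (j in seq_len(nth - 1L)) {
      a <- (i - 1L) * nth + j; b <- a + 1L
      cc <- i * nth + j + 1L; dd <- cc - 1L
      tris[[length(tris) + 1L]] <- c(a, b, cc)
      tris[[length(tris) + 1L]] <- c(a, cc, dd)
    }
  }
  mesh <- structure(list(nodes = coords, triangles = do.call(rbind, tris),
                         region = rep("shell", 2L * (length(rho) - 1L) * (nth - 1L)),
                         geometry = NULL, derived = NULL, h = (r2 - r1) / n),
                    class = "axisym_mesh")
  mesh <- orient_mesh(mesh)
  bd <- extract_boundary(mesh)
  n1 <- mesh$nodes[bd$edges[, 1], , drop = FALSE]
  n2 <- mesh$nodes[bd$edges[, 2], , drop = FALSE]
  tol <- 1e-9
  rad1 <- sqrt(rowSums(n1^2)); rad2 <- sqrt(rowSums(n2^2))
  lab <- rep("end_faces", nrow(bd$edges))
  lab[abs(n1[, 1]) < tol & abs(n2[, 1]) < tol] <- "symmetry_axis"
  lab[abs(rad1 - r1) < tol & abs(rad2 - r1) < tol] <- "inner_face"
  lab[abs(rad1 - r2) < tol & abs(rad2 - r2) < tol] <- "outer_face"
  mesh$boundary_edges <- bd$edges
  mesh$boundary_label <- lab
  mesh
}

orient_mesh <- function(mesh) {
  tr <- mesh$triangles
  p1 <- mesh$nodes[tr[, 1], , drop = FALSE]
  p2 <- mesh$nodes[tr[, 2], , drop = FALSE]
  p3 <- mesh$nodes[tr[, 3], , drop = FALSE]
  a2 <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
        (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  tr[a2 < 0, 2:3] <- tr[a2 < 0, 3:2]
  mesh$triangles <- tr
  mesh
}
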