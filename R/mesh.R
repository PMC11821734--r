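#' Ring geometry
#'
#' Idealized circular arterial ring (perfect cylinder segment).
#'
#' @param outer_diameter Outer diameter, m.
#' @param thickness Mural thickness, m (0 < thickness < outer radius).
#' @param height Axial ring height, m.
#' @param region Optional region label.
#' @return An object of class \code{ring_geometry}.
#' @export
ring_geometry <- function(outer_diameter, thickness, height,
                          region = "custom") {
  stopifnot(outer_diameter > 0, height > 0, thickness > 0,
            thickness < outer_diameter / 2)
  structure(list(outer_diameter = outer_diameter, thickness = thickness,
                 height = height, region = region),
            class = "ring_geometry")
}

#' Reference porcine ring geometry
#'
#' @param region One of \code{"ascending"}, \code{"arch"},
#'   \code{"descending"}.
#' @return A [ring_geometry()] in SI units (m).
#' @export
porcine_ring_geometry <- function(region) {
  region <- match_region(region)
  g <- porcine_reference_data()$geometry
  g <- g[g$region == region, ]
  ring_geometry(g$outer_diameter_mm * 1e-3, g$thickness_mm * 1e-3,
                g$height_mm * 1e-3, region)
}

#' Build a quarter-ring mesh of 20-node hexahedra
#'
#' Meshes one quarter of a radially cut ring: half the circumference (the
#' other half is recovered by mirror symmetry across plane A) and half the
#' height (symmetry across plane B at mid-height). The ring axis is z, the
#' cross-section lies in x-y; the symmetry face (plane A) is at the positive
#' x-axis (theta = 0), the traction-free cut face at theta = pi, and plane B
#' at z = 0. Mid-edge nodes are placed on the exact cylindrical surfaces, so
#' elements are curved.
#'
#' @param geom A [ring_geometry()].
#' @param resolution Integer vector \code{c(nr, nc, nz)}: elements through
#'   the wall, along the (half) circumference, and along the (half) height.
#'   Default \code{c(8, 20, 8)}.
#' @return An object of class \code{quarter_ring_mesh} with nodes (N x 3, m),
#'   20-node connectivity (E x 20), per-element radial/circumferential/axial
#'   indices, and the node sets planeA, planeB, cut_face, inner_surface,
#'   outer_surface, fixed_node plus the two inner mid-height nodes used for
#'   opening-angle measurement.
#' @export
build_quarter_ring <- function(geom, resolution = c(8L, 20L, 8L)) {
  stopifnot(inherits(geom, "ring_geometry"))
  res <- as.integer(resolution)
  stopifnot(length(res) == 3L, all(res >= 1L))
  nr <- res[1]; nc <- res[2]; nz <- res[3]

  Ro <- geom$outer_diameter / 2
  Ri <- Ro - geom$thickness
  hz <- geom$height / 2

  ni <- 2L * nr + 1L; nj <- 2L * nc + 1L; nk <- 2L * nz + 1L
  # serendipity grid: keep points with at most one odd index
  grid_id <- array(NA_integer_, dim = c(ni, nj, nk))
  coords <- matrix(0, ni * nj * nk, 3L)
  keep_i <- integer(0); keep_j <- integer(0); keep_k <- integer(0)
  n_node <- 0L
  for (k in seq_len(nk)) for (j in seq_len(nj)) for (i in seq_len(ni)) {
    odd <- ((i - 1L) %% 2L) + ((j - 1L) %% 2L) + ((k - 1L) %% 2L)
    if (odd <= 1L) {
      n_node <- n_node + 1L
      grid_id[i, j, k] <- n_node
      keep_i[n_node] <- i; keep_j[n_node] <- j; keep_k[n_node] <- k
    }
  }
  r <- Ri + (keep_i - 1L) / (ni - 1L) * (Ro - Ri)
  th <- (keep_j - 1L) / (nj - 1L) * pi
  z <- (keep_k - 1L) / (nk - 1L) * hz
  nodes <- cbind(x = r * cos(th), y = r * sin(th), z = z)

  # local ordering: corners, bottom edges, top edges, vertical edges
  loc <- rbind(
    c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0),
    c(0, 0, 2), c(2, 0, 2), c(2, 2, 2), c(0, 2, 2),
    c(1, 0, 0), c(2, 1, 0), c(1, 2, 0), c(0, 1, 0),
    c(1, 0, 2), c(2, 1, 2), c(1, 2, 2), c(0, 1, 2),
    c(0, 0, 1), c(2, 0, 1), c(2, 2, 1), c(0, 2, 1))
  nel <- nr * nc * nz
  conn <- matrix(0L, nel, 20L)
  elem_radial <- integer(nel); elem_circ <- integer(nel)
  elem_axial <- integer(nel)
  e <- 0L
  for (ez in seq_len(nz)) for (ec in seq_len(nc)) for (er in seq_len(nr)) {
    e <- e + 1L
    i0 <- 2L * (er - 1L); j0 <- 2L * (ec - 1L); k0 <- 2L * (ez - 1L)
    conn[e, ] <- grid_id[cbind(i0 + loc[, 1] + 1L, j0 + loc[, 2] + 1L,
                               k0 + loc[, 3] + 1L)]
    elem_radial[e] <- er; elem_circ[e] <- ec; elem_axial[e] <- ez
  }
  if (anyNA(conn)) stop("internal error: connectivity references a removed node")

  planeA <- grid_id[, 1L, ]; planeA <- sort(planeA[!is.na(planeA)])
  cut_face <- grid_id[, nj, ]; cut_face <- sort(cut_face[!is.na(cut_face)])
  planeB <- grid_id[, , 1L]; planeB <- sort(planeB[!is.na(planeB)])
  inner <- grid_id[1L, , ]; inner <- sort(inner[!is.na(inner)])
  outer <- grid_id[ni, , ]; outer <- sort(outer[!is.na(outer)])

  structure(list(
    nodes = nodes, conn = conn,
    elem_radial = elem_radial, elem_circ = elem_circ,
    elem_axial = elem_axial,
    resolution = c(nr = nr, nc = nc, nz = nz),
    geometry = geom,
    sets = list(planeA = planeA, planeB = planeB, cut_face = cut_face,
                inner_surface = inner, outer_surface = outer,
                fixed_node = grid_id[1L, 1L, 1L],
                angle_node_symm = grid_id[1L, 1L, 1L],
                angle_node_cut = grid_id[1L, nj, 1L])),
    class = "quarter_ring_mesh")
}

#' Reference volume of each element
#'
#' @param mesh A [build_quarter_ring()] mesh.
#' @return Numeric vector of element volumes, m^3.
#' @export
mesh_element_volumes <- function(mesh) {
  as.numeric(.hex20_volumes(mesh$nodes, mesh$conn))
}

#' Symmetry and support constraints for the quarter-ring model
#'
#' Plane A nodes are fixed in y (mirror symmetry of the cut ring), plane B
#' nodes in z (mid-height symmetry), and the single designated node lying in
#' both planes is fixed in all directions (removing the remaining x
#' translation). The cut face carries no constraint and is traction-free.
#'
#' @param mesh A [build_quarter_ring()] mesh.
#' @return A list with \code{fixed_dofs} (sorted indices into the stacked
#'   (x1,y1,z1,x2,...) displacement vector) and a bookkeeping table
#'   \code{constraints}.
#' @export
apply_boundary_conditions <- function(mesh) {
  s <- mesh$sets
  if (is.na(s$fixed_node)) stop("mesh has no fixed node")
  dof <- function(node, comp) 3L * (node - 1L) + comp
  fixed <- c(dof(s$planeA, 2L),      # y on plane A
             dof(s$planeB, 3L),      # z on plane B
             dof(s$fixed_node, 1L))  # x on the doubly constrained node
  constraints <- data.frame(
    set = c(rep("planeA_y", length(s$planeA)),
            rep("planeB_z", length(s$planeB)), "fixed_node_x"),
    node = c(s$planeA, s$planeB, s$fixed_node),
    comp = c(rep(2L, length(s$planeA)), rep(3L, length(s$planeB)), 1L))
  if (any(s$cut_face %in% constraints$node[constraints$set == "planeA_y"]))
    stop("cut face must remain unconstrained")
  list(fixed_dofs = sort(unique(fixed)), constraints = constraints)
}

#' Assign material and FCD fields to mesh elements
#'
#' Maps the 8 mural FCD domains onto element radial indices (domain 1 =
#' innermost) and tags the innermost \code{n_media_elements} (out of 8
#' notional through-thickness slots) as intima-media, the rest as
#' adventitia. Works for refined radial resolutions by assigning each
#' element the domain/layer containing its radial center.
#'
#' @param mesh A [build_quarter_ring()] mesh.
#' @param fcd An [fcd_domain_profile()] (signed values; magnitudes are used
#'   for swelling).
#' @param materials Either a single [holmes_mow_material()] (one-layer wall)
#'   or \code{list(media = ..., adventitia = ...)}.
#' @param n_media_elements Number of innermost through-thickness slots (of
#'   \code{fcd$n_domains}) occupied by the intima-media; ignored for a
#'   one-layer wall.
#' @return A list of per-element vectors \code{mu}, \code{beta}, \code{lam},
#'   \code{c0F} (magnitude, mEq/L = mol/m^3) and \code{layer}
#'   (\code{"media"}/\code{"adventitia"}).
#' @export
assign_fields <- function(mesh, fcd, materials, n_media_elements = NULL) {
  stopifnot(inherits(fcd, "fcd_domain_profile"))
  nd <- fcd$n_domains
  nr <- mesh$resolution[["nr"]]
  frac <- (mesh$elem_radial - 0.5) / nr          # radial center in (0,1)
  domain <- pmin(nd, floor(frac * nd) + 1L)
  c0F <- abs(fcd$c0F)[domain]

  one_layer <- inherits(materials, "holmes_mow_material")
  if (one_layer) {
    layer <- rep("media", length(domain))
    mat_of <- function(lay) materials
  } else {
    stopifnot(is.list(materials),
              inherits(materials$media, "holmes_mow_material"),
              inherits(materials$adventitia, "holmes_mow_material"))
    if (is.null(n_media_elements) || n_media_elements < 1 ||
        n_media_elements > nd)
      stop("n_media_elements must be in 1..n_domains for a two-layer wall")
    layer <- ifelse(frac <= n_media_elements / nd, "media", "adventitia")
    mat_of <- function(lay) materials[[lay]]
  }
  mu <- vapply(layer, function(l) mat_of(l)$mu_vol, numeric(1))
  beta <- vapply(layer, function(l) mat_of(l)$beta, numeric(1))
  lam <- vapply(layer, function(l) mat_of(l)$lam, numeric(1))
  list(mu = unname(mu), beta = unname(beta), lam = unname(lam),
       c0F = c0F, layer = unname(layer), domain = domain)
}
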