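# Cell geometry: membrane ring + interior lamellipodial network.
#
# The cell is a simple counterclockwise polygon of membrane nodes enclosing a
# cloud of interior nodes; the lamellipodial network is the Delaunay
# triangulation of all nodes clipped to the (possibly concave) membrane
# polygon.  Each (triangle, corner) carries a reference angle captured when
# the corner first appeared; the angular strain relative to it drives the
# FLNa-FilGAP mechanosensing pathway.

#' Build the initial disk-shaped cell mesh
#'
#' Membrane nodes are placed equally spaced on a circle of the given
#' diameter; interior nodes start from a deterministic sunflower (Fibonacci
#' disk) layout and are settled into the zero-rest-length spring equilibrium
#' of the lamellipodial network (three rounds of retriangulation +
#' relaxation), so a fresh mesh carries zero angular strain and zero interior
#' net force.  A seed-derived jitter of 1e-9 um breaks Delaunay co-circular
#' ties deterministically.
#'
#' @param diameter cell diameter (um).  Default 10 um.
#' @param n_membrane number of membrane (peripheral) nodes, >= 8.
#' @param n_interior number of interior (lamellipodial) nodes, >= 1.
#' @param seed integer seed controlling the tie-breaking jitter.
#' @return an object of class `cell_mesh` with fields `membrane`
#'   (n_membrane x 2, counterclockwise), `interior` (n_interior x 2),
#'   `triangles` (canonical vertex triples over all nodes, membrane nodes
#'   first), `ref_angles` (per triangle corner, rad) and `rest_spacing`
#'   (initial membrane spacing, um).
#' @examples
#' m <- build_disk_mesh(diameter = 10, n_membrane = 45, n_interior = 421)
#' nrow(m$membrane) + nrow(m$interior)  # 466 nodes
#' @export
build_disk_mesh <- function(diameter = 10, n_membrane = 45L,
                            n_interior = 421L, seed = 1L) {
  stopifnot(diameter > 0, n_membrane >= 8, n_interior >= 1)
  r <- diameter / 2
  th <- 2 * pi * (seq_len(n_membrane) - 1) / n_membrane
  membrane <- cbind(r * cos(th), r * sin(th))   # counterclockwise
  spacing <- 2 * r * sin(pi / n_membrane)

  # sunflower layout, kept one membrane spacing off the rim
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(n_interior)
  rad <- (r - spacing) * sqrt((k - 0.5) / n_interior)
  ang <- k * golden
  interior <- cbind(rad * cos(ang), rad * sin(ang))

  for (attempt in 0:4) {
    jseed <- derive_seed(seed, attempt)
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    set.seed(jseed)
    jit <- matrix(runif(2 * n_interior, -1, 1), ncol = 2) * 1e-9
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    mesh <- list(membrane = membrane, interior = interior + jit,
                 n_membrane = n_membrane, n_interior = n_interior,
                 diameter = diameter, seed = seed, rest_spacing = spacing)
    class(mesh) <- "cell_mesh"
    ok <- tryCatch({
      for (i in 1:3) {
        mesh <- retriangulate(mesh, carry_reference = FALSE)
        mesh <- relax_interior(mesh)
      }
      mesh <- retriangulate(mesh, carry_reference = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (ok) {
      validate_mesh(mesh)
      return(mesh)
    }
  }
  stop("degenerate triangulation after 5 jitter attempts")
}

all_positions <- function(mesh) rbind(mesh$membrane, mesh$interior)

validate_mesh <- function(mesh) {
  g <- compute_geometry(mesh)   # errors on non-simple / clockwise polygon
  inside <- points_in_polygon_cpp(mesh$interior[, 1], mesh$interior[, 2],
                                  mesh$membrane[, 1], mesh$membrane[, 2])
  if (!all(inside))
    stop("integrity error: ", sum(!inside), " interior node(s) outside the membrane polygon")
  angsum <- rowSums(g$corner_angles)
  if (max(abs(angsum - pi)) > 1e-9)
    stop("integrity error: triangle corner angles do not sum to pi")
  invisible(mesh)
}

#' Geometric quantities of the current cell shape
#'
#' Outward unit normals per membrane node (bisector of the two incident edge
#' normals), segment arc lengths, node-centred arc lengths (the 1D
#' finite-difference metric), perimeter, enclosed area (shoelace), polygon
#' centroid and the current triangle corner angles.
#'
#' @param mesh a `cell_mesh`.
#' @return a list with `normals`, `seg_lengths` (edge i joins node i to
#'   i + 1), `node_lengths`, `perimeter`, `area`, `centroid`,
#'   `corner_angles`.
#' @export
compute_geometry <- function(mesh) {
  v <- mesh$membrane
  n <- nrow(v)
  if (!polygon_is_simple_cpp(v[, 1], v[, 2]))
    stop("integrity error: membrane polygon self-intersects")
  nxt <- c(2:n, 1)
  dx <- v[nxt, 1] - v[, 1]
  dy <- v[nxt, 2] - v[, 2]
  seg <- sqrt(dx^2 + dy^2)
  if (any(seg < 1e-12)) stop("integrity error: zero-length membrane edge")
  area2 <- sum(v[, 1] * v[nxt, 2] - v[nxt, 1] * v[, 2])
  if (area2 <= 0)
    stop("integrity error: membrane polygon is not counterclockwise")
  area <- area2 / 2
  cx <- sum((v[, 1] + v[nxt, 1]) * (v[, 1] * v[nxt, 2] - v[nxt, 1] * v[, 2])) / (6 * area)
  cy <- sum((v[, 2] + v[nxt, 2]) * (v[, 1] * v[nxt, 2] - v[nxt, 1] * v[, 2])) / (6 * area)
  # outward edge normal of a CCW polygon is (dy, -dx)/len
  enx <- dy / seg
  eny <- -dx / seg
  prv <- c(n, 1:(n - 1))
  nx <- enx[prv] + enx
  ny <- eny[prv] + eny
  nl <- sqrt(nx^2 + ny^2)
  nl[nl < 1e-12] <- 1
  normals <- cbind(nx / nl, ny / nl)
  node_lengths <- (seg[prv] + seg) / 2
  angles <- if (!is.null(mesh$triangles))
    tri_angles_cpp(mesh$triangles, all_positions(mesh)) else NULL
  list(normals = normals, seg_lengths = seg, node_lengths = node_lengths,
       perimeter = sum(seg), area = area, centroid = c(cx, cy),
       corner_angles = angles)
}

#' Recompute the Delaunay triangulation of the deformed cell
#'
#' Replaces the triangle set by the Delaunay triangulation of all nodes,
#' clipped to the membrane polygon by a centroid-in-polygon test.  Corners
#' whose vertex triple persists keep their reference angles; newly created
#' corners are born strain-free (reference = current angle).
#'
#' @param mesh a `cell_mesh`.
#' @param carry_reference carry over reference angles of persisting corners
#'   (default `TRUE`); `FALSE` resets all references to the current angles.
#' @return the mesh with updated `triangles`, `tri_keys_v`, `ref_angles`, and
#'   an attribute-free record of which rows are new in `new_rows`.
#' @export
retriangulate <- function(mesh, carry_reference = TRUE) {
  pos <- all_positions(mesh)
  n <- nrow(pos)
  tm <- interp::tri.mesh(pos[, 1], pos[, 2])
  tri <- interp::triangles(tm)[, 1:3, drop = FALSE]
  tri <- tri_canonical(tri)
  # clip concave parts: keep triangles whose centroid lies inside the membrane
  cx <- (pos[tri[, 1], 1] + pos[tri[, 2], 1] + pos[tri[, 3], 1]) / 3
  cy <- (pos[tri[, 1], 2] + pos[tri[, 2], 2] + pos[tri[, 3], 2]) / 3
  keep <- points_in_polygon_cpp(cx, cy, mesh$membrane[, 1], mesh$membrane[, 2])
  tri <- tri[keep, , drop = FALSE]
  keys <- tri_keys(tri, n)
  ang <- tri_angles_cpp(tri, pos)
  ref <- ang
  new_rows <- rep(TRUE, nrow(tri))
  if (carry_reference && !is.null(mesh$tri_keys_v)) {
    idx <- match(keys, mesh$tri_keys_v)
    hit <- !is.na(idx)
    ref[hit, ] <- mesh$ref_angles[idx[hit], , drop = FALSE]
    new_rows <- !hit
  }
  mesh$triangles <- tri
  mesh$tri_keys_v <- keys
  mesh$ref_angles <- ref
  mesh$new_rows <- new_rows
  mesh
}

#' Angular strain per triangle corner
#'
#' Signed difference between the current corner angle and the reference angle
#' captured when the corner was created.  The three signed strains of any
#' triangle sum to zero (the corner angles always sum to pi).
#'
#' @param mesh a `cell_mesh` with reference angles.
#' @return a matrix (triangles x 3) of strains in rad.
#' @export
angle_strain <- function(mesh) {
  tri_angles_cpp(mesh$triangles, all_positions(mesh)) - mesh$ref_angles
}

# Pull any interior node that escaped the (concave) membrane polygon back
# inside by contracting it toward the polygon centroid.  Escapes are rare --
# the harmonic relaxation keeps nodes in the convex hull of their
# neighbours, which can poke outside only near strong concavities.
confine_interior <- function(mesh) {
  inside <- points_in_polygon_cpp(mesh$interior[, 1], mesh$interior[, 2],
                                  mesh$membrane[, 1], mesh$membrane[, 2])
  if (all(inside)) return(mesh)
  ctr <- colMeans(mesh$membrane)
  for (i in which(!inside)) {
    p <- mesh$interior[i, ]
    for (it in 1:30) {
      p <- ctr + 0.85 * (p - ctr)
      if (points_in_polygon_cpp(p[1], p[2], mesh$membrane[, 1],
                                mesh$membrane[, 2])[1]) break
    }
    mesh$interior[i, ] <- p
  }
  mesh
}

#' @export
print.cell_mesh <- function(x, ...) {
  cat(sprintf("<cell_mesh> %d membrane + %d interior nodes, %d triangles, diameter %g um\n",
              x$n_membrane, x$n_interior,
              if (is.null(x$triangles)) 0L else nrow(x$triangles), x$diameter))
  invisible(x)
}

#' Serialize a mesh snapshot to JSON
#'
#' @param mesh a `cell_mesh`.
#' @param path output file; when `NULL` the JSON string is returned.
#' @export
mesh_to_json <- function(mesh, path = NULL) {
  obj <- list(membrane = unname(mesh$membrane), interior = unname(mesh$interior),
              triangles = unname(mesh$triangles),
              ref_angles = unname(mesh$ref_angles), diameter = mesh$diameter)
  js <- jsonlite::toJSON(obj, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
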