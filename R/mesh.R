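# Triangulated surface container and geometric validation.
#
# A surface is stored as a vertex matrix (cm) plus a face index matrix and a
# layer tag ("lumen" or "outer_wall"). Loaded meshes are repaired (degenerate
# faces dropped, orientation made consistent with positive enclosed volume)
# and must be watertight: every undirected edge shared by exactly two faces.

LAYERS <- c("lumen", "outer_wall")

#' Construct a triangulated surface mesh
#'
#' @param vertices Numeric matrix, one row per vertex, columns x, y, z (cm).
#' @param faces Integer matrix, one row per triangle, 1-based vertex indices.
#' @param layer `"lumen"` or `"outer_wall"`.
#' @param validate Check watertightness/orientation (default `TRUE`); repairs
#'   orientation and drops zero-area faces before checking.
#' @return An object of class `aaa_mesh`.
#' @export
aaa_mesh <- function(vertices, faces, layer = "outer_wall", validate = TRUE) {
  layer <- match.arg(layer, LAYERS)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop_validation("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop_validation("faces must have 3 columns")
  if (nrow(vertices) < 4L) stop_validation("a closed surface needs >= 4 vertices, got %d", nrow(vertices))
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop_validation("face indices out of range")
  m <- structure(list(vertices = vertices, faces = faces, layer = layer),
                 class = "aaa_mesh")
  if (validate) m <- validate_mesh(repair_mesh(m))
  m
}

#' @export
print.aaa_mesh <- function(x, ...) {
  cat(sprintf("<aaa_mesh> %s: %d vertices, %d faces, signed volume %.4f cm^3\n",
              x$layer, nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

#' Signed enclosed volume of a closed triangulated surface
#'
#' Divergence-theorem sum of signed tetrahedron volumes about the origin;
#' positive for consistently outward-oriented surfaces.
#'
#' @param mesh An `aaa_mesh`.
#' @return Signed volume in cm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' @noRd
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @noRd
bbox_diag <- function(mesh) {
  r <- apply(mesh$vertices, 2, range)
  sqrt(sum((r[2, ] - r[1, ])^2))
}

# undirected edge keys per face, as a 3F x 2 matrix of sorted index pairs
#' @noRd
mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

# numeric edge key (exact below 2^53): fast hashing without string paste
#' @noRd
edge_key <- function(e, n_vert) e[, 1] * (n_vert + 1) + e[, 2]

#' Count boundary (open) edges of a mesh
#'
#' An edge is open when it belongs to exactly one face. Zero for a
#' watertight surface.
#'
#' @param mesh An `aaa_mesh`.
#' @return Integer count of open edges.
#' @export
open_edge_count <- function(mesh) {
  key <- edge_key(mesh_edges(mesh$faces), nrow(mesh$vertices))
  cnt <- tabulate(match(key, unique(key)))
  sum(cnt == 1L)
}

# Drop zero-area faces, merge duplicated vertices, and make the face
# orientation globally consistent with positive signed volume.
#' @noRd
repair_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  # merge exactly coincident vertices (STL stores a triangle soup)
  key <- paste(v[, 1], v[, 2], v[, 3])
  first <- match(key, key)
  keep <- which(first == seq_along(first))
  remap <- match(first, keep)
  v <- v[keep, , drop = FALSE]
  f <- matrix(remap[f], ncol = 3L)
  # drop degenerate faces (repeated vertex or zero area)
  m <- structure(list(vertices = v, faces = f, layer = mesh$layer), class = "aaa_mesh")
  bad <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  ar <- face_areas(m)
  keepf <- !bad & ar > 1e-14 * max(ar, 1e-300)
  f <- f[keepf, , drop = FALSE]
  m$faces <- f
  m <- orient_mesh(m)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2), drop = FALSE]
  m
}

# Flip faces (breadth-first over the face adjacency graph) until every shared
# edge is traversed once in each direction.
#' @noRd
orient_mesh <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  if (nf == 0L) return(mesh)
  # fast path: already consistent when no directed edge repeats
  nv <- nrow(mesh$vertices)
  de <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  if (!anyDuplicated(edge_key(de, nv))) return(mesh)
  eu <- mesh_edges(f)
  key <- edge_key(eu, nv)
  face_of <- rep(seq_len(nf), 3L)
  # adjacency: faces sharing each undirected edge
  sp <- split(seq_along(key), key)
  adj <- vector("list", nf)
  for (idx in sp) {
    fs <- face_of[idx]
    if (length(fs) == 2L) {
      adj[[fs[1]]] <- c(adj[[fs[1]]], fs[2])
      adj[[fs[2]]] <- c(adj[[fs[2]]], fs[1])
    }
  }
  directed_edges <- function(tri) rbind(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)])
  visited <- rep(FALSE, nf)
  flipped <- rep(FALSE, nf)
  for (root in seq_len(nf)) {
    if (visited[root]) next
    visited[root] <- TRUE
    queue <- root
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      de_cur <- directed_edges(if (flipped[cur]) f[cur, c(1, 3, 2)] else f[cur, ])
      for (nb in adj[[cur]]) {
        if (visited[nb]) next
        visited[nb] <- TRUE
        de_nb <- directed_edges(f[nb, ])
        # consistent orientation: the shared edge runs in opposite directions
        same_dir <- any(apply(de_cur, 1, function(e)
          any(de_nb[, 1] == e[1] & de_nb[, 2] == e[2])))
        flipped[nb] <- xor(same_dir, flipped[cur])
        queue <- c(queue, nb)
      }
    }
  }
  if (any(flipped)) f[flipped, ] <- f[flipped, c(1, 3, 2), drop = FALSE]
  mesh$faces <- f
  mesh
}

#' Validate a surface mesh
#'
#' Checks the closed-surface invariants: at least 4 vertices, watertight
#' (every edge shared by exactly 2 faces) and strictly positive signed
#' volume.
#'
#' @param mesh An `aaa_mesh`.
#' @return The mesh, invisibly classed, on success; otherwise a validation
#'   error naming the number of open edges.
#' @export
validate_mesh <- function(mesh) {
  if (nrow(mesh$vertices) < 4L)
    stop_validation("mesh has %d vertices; a closed surface needs >= 4", nrow(mesh$vertices))
  key <- edge_key(mesh_edges(mesh$faces), nrow(mesh$vertices))
  cnt <- tabulate(match(key, unique(key)))
  if (any(cnt == 1L))
    stop_validation("mesh is not watertight: %d open edges", sum(cnt == 1L))
  if (any(cnt > 2L))
    stop_validation("non-manifold mesh: %d edges shared by > 2 faces", sum(cnt > 2L))
  if (mesh_volume(mesh) <= 0)
    stop_validation("mesh has non-positive signed volume after orientation repair")
  mesh
}

#' @noRd
mesh_z_range <- function(mesh) range(mesh$vertices[, 3])
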