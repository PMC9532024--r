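# Triangulated unit sphere by recursive subdivision of an icosahedron,
# and its dual polyhedral graph. The dual of the triangulation is the
# hexagonal-ish mesh used as the synthetic pial surface: one dual node per
# triangle, one dual edge per pair of edge-adjacent triangles, so every
# dual node has degree 3.

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(vertices = v, faces = f)
}

subdivide_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  midpoint_id <- new.env(parent = emptyenv())
  verts <- v
  get_mid <- function(a, b) {
    key <- edge_key(a, b)
    id <- midpoint_id[[key]]
    if (is.null(id)) {
      m <- (verts[a, ] + verts[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      id <- nrow(verts)
      midpoint_id[[key]] <- id
    }
    id
  }
  new_faces <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
    ab <- get_mid(a, b); bc <- get_mid(b, cc); ca <- get_mid(cc, a)
    new_faces[4 * i - 3, ] <- c(a, ab, ca)
    new_faces[4 * i - 2, ] <- c(b, bc, ab)
    new_faces[4 * i - 1, ] <- c(cc, ca, bc)
    new_faces[4 * i, ] <- c(ab, bc, ca)
  }
  list(vertices = verts, faces = new_faces)
}

#' Triangulated sphere surface
#'
#' Recursively subdivided icosahedron projected onto the unit sphere;
#' `20 * 4^resolution` triangles.
#'
#' @param resolution non-negative integer refinement level.
#' @return List with `vertices` (n x 3 matrix) and `faces` (m x 3 integer
#'   matrix of vertex indices).
#' @keywords internal
icosphere <- function(resolution) {
  stopifnot(resolution >= 0)
  mesh <- icosahedron()
  for (i in seq_len(resolution)) mesh <- subdivide_mesh(mesh)
  mesh
}

# Dual of a closed triangulation: a node per face (at the projected face
# centroid), an edge per shared triangle edge. Returns list(positions m x 3
# on the unit sphere, edges k x 2 of face indices).
dual_mesh <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  cent <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  cent <- cent / sqrt(rowSums(cent^2))
  # every undirected triangle edge appears in exactly two faces
  edges_long <- rbind(
    cbind(f[, 1], f[, 2], seq_len(nrow(f))),
    cbind(f[, 2], f[, 3], seq_len(nrow(f))),
    cbind(f[, 3], f[, 1], seq_len(nrow(f)))
  )
  key <- paste(pmin(edges_long[, 1], edges_long[, 2]),
               pmax(edges_long[, 1], edges_long[, 2]))
  ord <- order(key)
  key <- key[ord]
  face_of <- edges_long[ord, 3]
  stopifnot(all(key[c(TRUE, FALSE)] == key[c(FALSE, TRUE)]))
  dual_edges <- cbind(face_of[c(TRUE, FALSE)], face_of[c(FALSE, TRUE)])
  list(positions = cent, edges = dual_edges)
}
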