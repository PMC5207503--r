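#' Triangle mesh with stable face identifiers
#'
#' The package represents a body "skin" as a triangle mesh: a matrix of 3D
#' vertices (in decimeters, the canonical length unit of the package) and a
#' matrix of vertex-index triples. Every triangle carries a stable integer
#' identifier (`face_ids`), which is what decouples the view-area ground
#' truth from any reconstruction step: a ray cast reports *which* triangles
#' were seen, and their areas are then looked up on the original mesh.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z), in dm.
#' @param faces integer matrix with 3 columns of 1-based vertex indices.
#' @param face_ids integer vector of unique triangle identifiers; defaults to
#'   `0:(nrow(faces) - 1)` in face order.
#' @return An object of class `"mesh3t"`: a list with elements `vertices`,
#'   `faces`, `face_ids`.
#' @examples
#' m <- mesh3t(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
#' mesh_area(m)$wbsa # 0.5
#' @export
mesh3t <- function(vertices, faces, face_ids = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) == 0L) stop("empty mesh: no faces")
  if (anyNA(vertices) || anyNA(faces)) stop("NA in mesh data")
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("face indices out of vertex range")
  }
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3])) {
    stop("faces must have 3 distinct vertex indices")
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (is.null(face_ids)) face_ids <- seq_len(nrow(faces)) - 1L
  face_ids <- as.integer(face_ids)
  if (length(face_ids) != nrow(faces)) stop("one face_id per face required")
  if (anyDuplicated(face_ids)) stop("face_ids must be unique")
  structure(list(vertices = vertices, faces = faces, face_ids = face_ids),
            class = "mesh3t")
}

#' @export
print.mesh3t <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("mesh3t: %d vertices, %d triangles\n", nrow(x$vertices),
              nrow(x$faces)))
  cat(sprintf("  bbox (dm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  cat(sprintf("  total area: %.3f dm^2\n", mesh_area(x)$wbsa))
  invisible(x)
}

#' Area of a triangle from two edge vectors
#'
#' Computes `A = |u x v| / 2`, half the magnitude of the cross product of the
#' two edge vectors — the basic primitive behind every area in the package.
#' Degenerate (collinear) edges give area 0.
#'
#' @param u,v numeric 3-vectors: two edges of the triangle sharing a vertex.
#' @return Triangle area (dm^2 when edges are in dm).
#' @export
triangle_area <- function(u, v) {
  stopifnot(length(u) == 3L, length(v) == 3L)
  cx <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  sqrt(sum(cx^2)) / 2
}

# vectorised per-face areas, in face order
face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  sqrt(rowSums(cx^2)) / 2
}

#' Total surface area of a mesh
#'
#' The whole body surface area (WBSA) of a body mesh is simply the sum of
#' all its triangle areas.
#'
#' @param mesh a [mesh3t()] object.
#' @return A list with `wbsa` (total area, dm^2) and `per_face_area`, a named
#'   numeric vector keyed by `face_id`.
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "mesh3t"))
  a <- face_areas(mesh)
  names(a) <- as.character(mesh$face_ids)
  list(wbsa = sum(a), per_face_area = a)
}

#' Flat midpoint subdivision
#'
#' Splits every triangle into four by its edge midpoints, `levels` times.
#' The subdivision is flat (no smoothing), so total area is conserved
#' exactly up to floating-point accumulation; its purpose is to shrink the
#' overestimation that full-triangle visibility counting incurs on partially
#' visible triangles. New faces get fresh sequential ids; the originating
#' id of each new face is recorded in `attr(, "parent_ids")`.
#'
#' @param mesh a [mesh3t()] object.
#' @param levels integer >= 0; number of 1-to-4 rounds.
#' @return A [mesh3t()] with `4^levels` times the faces.
#' @export
subdivide <- function(mesh, levels = 1L) {
  stopifnot(inherits(mesh, "mesh3t"))
  if (length(levels) != 1L || is.na(levels) || levels < 0) {
    stop("levels must be a non-negative integer")
  }
  levels <- as.integer(levels)
  parent <- mesh$face_ids
  if (levels == 0L) {
    out <- mesh
    attr(out, "parent_ids") <- parent
    return(out)
  }
  v <- mesh$vertices
  f <- mesh$faces
  for (l in seq_len(levels)) {
    # unique undirected edges and their midpoint vertex
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    key <- paste(e[, 1], e[, 2])
    uk <- !duplicated(key)
    eu <- e[uk, , drop = FALSE]
    mid_idx <- nrow(v) + match(key, key[uk])
    v <- rbind(v, (v[eu[, 1], , drop = FALSE] + v[eu[, 2], , drop = FALSE]) / 2)
    nf <- nrow(f)
    m12 <- mid_idx[seq_len(nf)]
    m23 <- mid_idx[nf + seq_len(nf)]
    m13 <- mid_idx[2L * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m13),
               cbind(m12, f[, 2], m23),
               cbind(m13, m23, f[, 3]),
               cbind(m12, m23, m13))
    parent <- rep(parent, 4L)
  }
  out <- mesh3t(v, f)
  attr(out, "parent_ids") <- parent
  out
}

#' Isotropic mesh scaling
#'
#' @param mesh a [mesh3t()] object.
#' @param s positive scale factor; areas scale by `s^2`.
#' @return The scaled mesh (face ids preserved).
#' @export
scale_mesh <- function(mesh, s) {
  stopifnot(inherits(mesh, "mesh3t"), s > 0)
  mesh$vertices <- mesh$vertices * s
  mesh
}

#' Read a Wavefront OBJ mesh
#'
#' Parses `v` and `f` records. Quads are split into two triangles by a fan at
#' the first vertex: `(v1, v2, v3)` and `(v1, v3, v4)`. Triangle ids are
#' assigned in file order (quads contribute two consecutive ids), and
#' `f` entries of the form `i/..` or `i//..` are accepted (texture/normal
#' references are ignored).
#'
#' @param path path to an OBJ file.
#' @return A [mesh3t()] object.
#' @export
read_obj <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  tag <- vapply(toks, function(t) if (length(t)) t[[1]] else "", "")
  vi <- which(tag == "v")
  fi <- which(tag == "f")
  if (length(fi) == 0L) stop("empty mesh: no 'f' records in ", path)
  vert <- matrix(NA_real_, length(vi), 3)
  for (k in seq_along(vi)) {
    t <- toks[[vi[k]]]
    if (length(t) < 4L) stop("malformed vertex record at line ", vi[k])
    vert[k, ] <- as.numeric(t[2:4])
  }
  tris <- vector("list", length(fi))
  for (k in seq_along(fi)) {
    t <- toks[[fi[k]]]
    idx <- suppressWarnings(
      as.integer(vapply(t[-1], function(s) strsplit(s, "/")[[1]][1], "")))
    if (length(idx) < 3L || length(idx) > 4L || anyNA(idx)) {
      stop("malformed face record at line ", fi[k])
    }
    tris[[k]] <- if (length(idx) == 3L) {
      rbind(idx)
    } else {
      rbind(idx[c(1, 2, 3)], idx[c(1, 3, 4)])
    }
  }
  mesh3t(vert, do.call(rbind, tris))
}

#' Write a mesh as Wavefront OBJ
#'
#' Triangles only; face ids are implicit in the file order, so a
#' `write_obj()` / [read_obj()] round trip preserves vertices, faces and ids.
#'
#' @param mesh a [mesh3t()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "mesh3t"))
  o <- order(mesh$face_ids)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[o, 1], mesh$faces[o, 2],
                     mesh$faces[o, 3]), con)
  invisible(path)
}

#' Write per-face areas as CSV
#'
#' @param mesh a [mesh3t()] object.
#' @param path output path for a `face_id,area_dm2` table.
#' @return `path`, invisibly.
#' @export
write_face_areas <- function(mesh, path) {
  ar <- mesh_area(mesh)
  utils::write.csv(
    data.frame(face_id = mesh$face_ids, area_dm2 = unname(ar$per_face_area)),
    path, row.names = FALSE)
  invisible(path)
}

#' Icosphere test mesh
#'
#' Unit-construction sphere: an icosahedron whose faces are midpoint-split
#' `level` times with vertices re-projected to the sphere. Used as the
#' analytic test body (surface area `4 pi R^2`; the spherical-cap formula
#' gives its visible area from any distance).
#'
#' @param radius sphere radius (dm).
#' @param level subdivision level; faces number `20 * 4^level`.
#' @param center sphere centre (3-vector, dm).
#' @return A [mesh3t()] object.
#' @export
icosphere <- function(radius = 1, level = 3L, center = c(0, 0, 0)) {
  stopifnot(radius > 0, level >= 0)
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
    c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  m <- mesh3t(v / sqrt(1 + p^2), f)
  for (l in seq_len(level)) {
    m <- subdivide(m, 1L)
    m$vertices <- m$vertices / sqrt(rowSums(m$vertices^2))
  }
  m$vertices <- m$vertices * radius
  m$vertices <- sweep(m$vertices, 2, center, "+")
  mesh3t(m$vertices, m$faces)
}
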