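#' Blastomere surface meshes
#'
#' A `blastomere_mesh` is one closed triangle surface per cell of a
#' cleavage-stage embryo: a vertex matrix (rows are 3D points, nominally in
#' micrometres, units arbitrary but consistent within an embryo) and a face
#' matrix of 1-based vertex-index triples. Surfaces are expected to be
#' watertight (every edge shared by exactly two faces) with positive enclosed
#' volume; faces are oriented so the divergence-theorem volume is positive
#' (the constructor flips orientation if needed).
#'
#' @param vertices Numeric matrix with 3 columns (x, y, z), at least 4 rows.
#' @param faces Integer matrix with 3 columns of 1-based vertex indices.
#' @param cell_id Short string label for the cell.
#' @param validate Check closedness and positive volume (default `TRUE`).
#' @return An object of class `blastomere_mesh` with elements `cell_id`,
#'   `vertices`, `faces`.
#' @export
blastomere_mesh <- function(vertices, faces, cell_id = "cell", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) {
    abort("`vertices` must have 3 columns", "invalid_mesh")
  }
  if (ncol(faces) != 3L) {
    abort("`faces` must have 3 columns (triangles only)", "invalid_mesh")
  }
  if (nrow(vertices) < 4L) {
    abort("a closed surface needs at least 4 vertices", "invalid_mesh")
  }
  if (anyNA(vertices) || anyNA(faces)) {
    abort("mesh contains missing values", "invalid_mesh")
  }
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    abort("face indices out of range", "invalid_mesh")
  }
  m <- structure(
    list(cell_id = as.character(cell_id)[1], vertices = vertices, faces = faces),
    class = "blastomere_mesh"
  )
  # orient outward: signed volume must be positive
  v <- mesh_volume(m, signed = TRUE)
  if (v < 0) {
    m$faces <- m$faces[, c(1L, 3L, 2L), drop = FALSE]
    v <- -v
  }
  if (validate) validate_mesh(m)
  m
}

#' @export
print.blastomere_mesh <- function(x, ...) {
  cat(sprintf("<blastomere_mesh '%s': %d vertices, %d faces, volume %.4g>\n",
              x$cell_id, nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

#' Validate a blastomere mesh
#'
#' Checks watertightness (every undirected edge shared by exactly two faces)
#' and strictly positive enclosed volume. Self-intersection is not checked:
#' pathological inputs are a rejection concern for upstream reconstruction,
#' not something this package repairs.
#'
#' @param mesh A `blastomere_mesh`.
#' @return The mesh, invisibly; signals an `invalid_mesh` condition otherwise.
#' @export
validate_mesh <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2, drop = FALSE], f[, 2:3, drop = FALSE], f[, c(3L, 1L), drop = FALSE])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt != 2L)) {
    abort(sprintf("mesh '%s' is not closed: %d edge(s) not shared by exactly 2 faces",
                  mesh$cell_id, sum(cnt != 2L)), "invalid_mesh")
  }
  v <- mesh_volume(mesh, signed = TRUE)
  if (!is.finite(v) || abs(v) < 1e-12) {
    abort(sprintf("mesh '%s' has (near-)zero enclosed volume", mesh$cell_id),
          "invalid_mesh")
  }
  invisible(mesh)
}

#' Enclosed volume of a closed triangle mesh
#'
#' Divergence-theorem volume: the sum of signed tetrahedra spanned by each
#' face and the origin, \eqn{V = \sum_f \det(v_1, v_2, v_3) / 6}.
#'
#' @param mesh A `blastomere_mesh`.
#' @param signed Return the signed value (negative for inward orientation).
#' @return Scalar volume.
#' @export
mesh_volume <- function(mesh, signed = FALSE) {
  V <- mesh$vertices
  f <- mesh$faces
  a <- V[f[, 1], , drop = FALSE]
  b <- V[f[, 2], , drop = FALSE]
  c_ <- V[f[, 3], , drop = FALSE]
  # scalar triple product a . (b x c), row-wise
  cx <- b[, 2] * c_[, 3] - b[, 3] * c_[, 2]
  cy <- b[, 3] * c_[, 1] - b[, 1] * c_[, 3]
  cz <- b[, 1] * c_[, 2] - b[, 2] * c_[, 1]
  v <- sum(a[, 1] * cx + a[, 2] * cy + a[, 3] * cz) / 6
  if (signed) v else abs(v)
}

#' Volume centroid of a closed triangle mesh
#'
#' Centroid of the enclosed solid by signed-tetrahedron decomposition, not the
#' vertex average, so vertex density does not bias it. Each face contributes a
#' tetrahedron with the origin whose centroid is `(v1+v2+v3)/4`, weighted by
#' its signed volume.
#'
#' @param mesh A `blastomere_mesh`.
#' @return Length-3 numeric vector.
#' @export
mesh_centroid <- function(mesh) {
  V <- mesh$vertices
  f <- mesh$faces
  a <- V[f[, 1], , drop = FALSE]
  b <- V[f[, 2], , drop = FALSE]
  c_ <- V[f[, 3], , drop = FALSE]
  cx <- b[, 2] * c_[, 3] - b[, 3] * c_[, 2]
  cy <- b[, 3] * c_[, 1] - b[, 1] * c_[, 3]
  cz <- b[, 1] * c_[, 2] - b[, 2] * c_[, 1]
  w <- (a[, 1] * cx + a[, 2] * cy + a[, 3] * cz) / 6 # signed tet volumes
  vol <- sum(w)
  if (abs(vol) < 1e-12) {
    abort(sprintf("mesh '%s' has (near-)zero enclosed volume", mesh$cell_id),
          "invalid_mesh")
  }
  colSums(w * (a + b + c_) / 4) / vol
}

#' Scale a mesh about its volume centroid
#'
#' Displaces every vertex radially from the mesh's volume centroid by
#' `factor`, leaving the centroid and topology unchanged and multiplying the
#' enclosed volume by `factor^3`. This is the operation used to detect cell
#' contacts: each blastomere is inflated by a small factor (1.05 by default
#' downstream) and overlap of the inflated surfaces is read as contact.
#'
#' @param mesh A `blastomere_mesh`.
#' @param factor Positive scale factor.
#' @return The scaled `blastomere_mesh`.
#' @export
scale_mesh <- function(mesh, factor) {
  if (!is_scalar_num(factor) || factor <= 0) {
    abort("`factor` must be a single positive number", "invalid_parameter")
  }
  ctr <- mesh_centroid(mesh) # errors on degenerate mesh
  out <- mesh
  out$vertices <- sweep(sweep(mesh$vertices, 2, ctr) * factor, 2, ctr, "+")
  out
}

# icospheres --------------------------------------------------------------

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere: the standard watertight
#' sphere tessellation. Subdivision level `s` gives `20 * 4^s` faces; level 2
#' (320 faces) approximates a sphere to under 2% maximum radial deficiency
#' (see [icosphere_tolerance()]), comfortably inside the 5% contact-scaling
#' margin used downstream.
#'
#' @param radius Sphere radius.
#' @param center Length-3 numeric center.
#' @param subdivisions Non-negative integer refinement level (default 2).
#' @param cell_id Label for the resulting mesh.
#' @return A `blastomere_mesh`.
#' @export
icosphere <- function(radius = 1, center = c(0, 0, 0), subdivisions = 2,
                      cell_id = "cell") {
  check_positive_scalar(radius, "radius")
  if (!is.numeric(center) || length(center) != 3L) {
    abort("`center` must be a length-3 numeric vector", "invalid_parameter")
  }
  s <- as.integer(subdivisions)
  if (is.na(s) || s < 0L || s > 5L) {
    abort("`subdivisions` must be an integer in [0, 5]", "invalid_parameter")
  }
  t <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1)
  )
  V <- V / sqrt(rowSums(V^2))
  F0 <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (i in seq_len(s)) {
    res <- subdivide_tris(V, F0)
    V <- res$V / sqrt(rowSums(res$V^2))
    F0 <- res$F
  }
  V <- sweep(V * radius, 2, center, "+")
  blastomere_mesh(V, F0, cell_id = cell_id, validate = FALSE)
}

# One 4:1 loop subdivision step with midpoint de-duplication.
subdivide_tris <- function(V, F0) {
  nv <- nrow(V)
  midkey <- function(i, j) pmin(i, j) * (nv + 1) + pmax(i, j)
  e <- rbind(F0[, 1:2], F0[, 2:3], F0[, c(3, 1)])
  keys <- midkey(e[, 1], e[, 2])
  ukeys <- unique(keys)
  idx <- match(keys, ukeys) + nv
  ue <- e[!duplicated(keys), , drop = FALSE]
  mids <- (V[ue[, 1], , drop = FALSE] + V[ue[, 2], , drop = FALSE]) / 2
  nf <- nrow(F0)
  m12 <- idx[seq_len(nf)]
  m23 <- idx[nf + seq_len(nf)]
  m31 <- idx[2 * nf + seq_len(nf)]
  Fnew <- rbind(
    cbind(F0[, 1], m12, m31),
    cbind(F0[, 2], m23, m12),
    cbind(F0[, 3], m31, m23),
    cbind(m12, m23, m31)
  )
  list(V = rbind(V, mids), F = Fnew)
}

#' Radial deficiency of an icosphere tessellation
#'
#' The maximum fraction by which the faceted surface falls inside the true
#' sphere (1 minus the inradius of the faceting, relative to the sphere
#' radius). Used to define the near-tangency tolerance band within which a
#' mesh-based overlap test may legitimately disagree with the analytic
#' sphere criterion.
#'
#' @param subdivisions Icosphere refinement level.
#' @return Scalar in (0, 1).
#' @export
icosphere_tolerance <- function(subdivisions = 2) {
  m <- icosphere(1, c(0, 0, 0), subdivisions)
  f <- m$faces
  V <- m$vertices
  ctr <- (V[f[, 1], , drop = FALSE] + V[f[, 2], , drop = FALSE] +
            V[f[, 3], , drop = FALSE]) / 3
  1 - min(sqrt(rowSums(ctr^2)))
}

# embryos ------------------------------------------------------------------

#' Construct an embryo from blastomere meshes
#'
#' @param blastomeres List of `blastomere_mesh` objects, one per cell.
#' @param embryo_id String identifier.
#' @param metadata Optional outcome record (see [outcome_record()]).
#' @return An object of class `embryo` with `stage` equal to the number of
#'   blastomeres. Cell ids must be unique within the embryo.
#' @export
embryo <- function(blastomeres, embryo_id = "embryo", metadata = NULL) {
  if (!is.list(blastomeres) || length(blastomeres) < 1L ||
      !all(vapply(blastomeres, inherits, logical(1), "blastomere_mesh"))) {
    abort("`blastomeres` must be a non-empty list of blastomere_mesh objects",
          "invalid_parameter")
  }
  ids <- vapply(blastomeres, function(m) m$cell_id, character(1))
  if (anyDuplicated(ids)) {
    abort("cell_ids must be unique within an embryo", "invalid_parameter")
  }
  structure(
    list(embryo_id = as.character(embryo_id)[1],
         stage = length(blastomeres),
         blastomeres = blastomeres,
         metadata = metadata),
    class = "embryo"
  )
}

#' @export
print.embryo <- function(x, ...) {
  cat(sprintf("<embryo '%s': %d blastomeres [%s]>\n", x$embryo_id, x$stage,
              paste(vapply(x$blastomeres, `[[`, character(1), "cell_id"),
                    collapse = ", ")))
  invisible(x)
}

#' Apply a rigid transform to an embryo
#'
#' Rotates and translates every blastomere identically. Contact networks are
#' invariant under this operation: an embryo re-oriented under the microscope
#' has the same contact structure.
#'
#' @param emb An `embryo`.
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation Length-3 numeric vector.
#' @return The transformed `embryo`.
#' @export
transform_embryo <- function(emb, rotation = diag(3), translation = c(0, 0, 0)) {
  R <- as.matrix(rotation)
  if (!all(dim(R) == c(3L, 3L)) || abs(det(R) - 1) > 1e-6 ||
      max(abs(crossprod(R) - diag(3))) > 1e-6) {
    abort("`rotation` must be a proper 3x3 rotation matrix", "invalid_parameter")
  }
  emb$blastomeres <- lapply(emb$blastomeres, function(m) {
    m$vertices <- sweep(m$vertices %*% t(R), 2, translation, "+")
    m
  })
  emb
}

#' Random rotation matrix
#'
#' Uniform (Haar) random rotation via QR decomposition of a Gaussian matrix.
#'
#' @param seed Optional integer seed.
#' @return 3x3 rotation matrix with determinant +1.
#' @export
random_rotation <- function(seed = NULL) {
  with_seed(seed, {
    qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
    Q <- qr.Q(qr_)
    d <- sign(diag(qr.R(qr_)))
    Q <- Q %*% diag(d)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  })
}
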