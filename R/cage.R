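# 3D capsid cage meshes: the four Archimedean lattice tilings laid on the
# icosahedron via the Caspar-Klug construction, with a polyhedron-to-sphere
# sphericity parameter.  The planar tiling is generated on the (h,k) facet
# triangle, folded over the 20 faces, and the tiling polygons are derived
# from the welded geodesic triangulation:
#   hexagonal          = dual (one face per lattice point),
#   trihexagonal       = rectification (vertices at edge midpoints),
#   rhombitrihexagonal = cantellation (corner hexagons + edge squares),
#   snub hexagonal     = snub (twisted corner hexagons + triangle pairs).
# Hexagons centred on the twelve 5-fold vertices collapse to pentagons.

.newell_normal <- function(pts) {
  m <- nrow(pts)
  n <- c(0, 0, 0)
  for (i in seq_len(m)) {
    a <- pts[i, ]; b <- pts[i %% m + 1L, ]
    n <- n + c((a[2] - b[2]) * (a[3] + b[3]),
               (a[3] - b[3]) * (a[1] + b[1]),
               (a[1] - b[1]) * (a[2] + b[2]))
  }
  n
}

.orient_outward <- function(verts, faces) {
  lapply(faces, function(fc) {
    pts <- verts[fc, , drop = FALSE]
    if (sum(.newell_normal(pts) * colMeans(pts)) < 0) rev(fc) else fc
  })
}

.gon_type <- function(n) {
  switch(as.character(n), "3" = "triangle", "4" = "square",
         "5" = "pentagon", "6" = "hexagon", paste0(n, "-gon"))
}

.apply_sphericity <- function(flat, f, R) {
  r <- sqrt(rowSums(flat^2))
  flat * ((1 - f) + f * R / r)
}

.new_cage_mesh <- function(flat, faces, types, arch, sphericity, radius,
                           is_dual = FALSE) {
  faces <- .orient_outward(flat, faces)
  structure(list(
    vertices = .apply_sphericity(flat * radius, sphericity, radius),
    vertices_flat = flat * radius,
    faces = faces, face_type = types,
    architecture = arch, sphericity = sphericity, radius = radius,
    is_dual = is_dual
  ), class = "cage_mesh")
}

#' Build a 3D icosahedral capsid cage mesh
#'
#' Lays the planar protein lattice of a capsid architecture over the twenty
#' faces of an icosahedron (the Caspar-Klug construction), welds coincident
#' vertices, and collapses the hexagons centred on the twelve 5-fold axes to
#' pentagons. The result is a closed polygonal mesh whose vertex radii
#' interpolate linearly between the flat-faceted polyhedron (`sphericity = 0`)
#' and the circumscribing sphere of radius `radius` (`sphericity = 1`).
#'
#' @param arch A [generalized_t()] architecture (any of the four lattices).
#' @param sphericity Sphere factor in `[0, 1]`.
#' @param radius Circumscribing sphere radius (dimensionless by default;
#'   use nm for physical models). Must be positive.
#' @return A `"cage_mesh"`: list with `vertices` (n x 3), `faces` (list of
#'   vertex index cycles), `face_type` (`"pentagon"`, `"hexagon"`,
#'   `"triangle"`, `"square"`), plus the architecture and build parameters.
#' @examples
#' m <- build_cage(generalized_t(1, 0, "hexagonal"))  # pentagonal dodecahedron
#' face_census(m)
#' @export
build_cage <- function(arch, sphericity = 0, radius = 1) {
  stopifnot(inherits(arch, "capsid_architecture"))
  if (!is.numeric(sphericity) || length(sphericity) != 1L ||
      is.na(sphericity) || sphericity < 0 || sphericity > 1) {
    stop("sphericity must be a single value in [0, 1]")
  }
  if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) ||
      radius <= 0) {
    stop("radius must be a single positive value")
  }
  geo <- .geodesic(arch$h, arch$k)
  topo <- .tri_topology(geo$F)
  built <- switch(arch$tiling$label,
    hexagonal          = .cage_dual_hex(geo, topo),
    trihexagonal       = .cage_rectified(geo, topo),
    rhombitrihexagonal = .cage_cantellated(geo, topo),
    snub_hexagonal     = .cage_snub(geo, topo, arch$tiling$chirality)
  )
  .new_cage_mesh(built$V, built$faces, built$types, arch, sphericity, radius)
}

# hexagonal lattice cage: dual of the geodesic triangulation
.cage_dual_hex <- function(geo, topo) {
  cent <- t(vapply(seq_len(nrow(geo$F)), function(i)
    colMeans(geo$V[geo$F[i, ], , drop = FALSE]), numeric(3)))
  faces <- lapply(seq_len(topo$nV), function(u) topo$vcycle[[u]]$tris)
  types <- vapply(faces, function(fc) .gon_type(length(fc)), character(1))
  list(V = cent, faces = faces, types = types)
}

# trihexagonal cage: vertices at triangulation edge midpoints
.cage_rectified <- function(geo, topo) {
  E <- topo$edges
  mid <- (geo$V[E[, 1], , drop = FALSE] + geo$V[E[, 2], , drop = FALSE]) / 2
  ekey <- paste(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2]), sep = "-")
  eidx <- stats::setNames(seq_len(nrow(E)), ekey)
  faces <- vector("list", nrow(geo$F) + topo$nV)
  n <- 0L
  for (i in seq_len(nrow(geo$F))) {
    vs <- geo$F[i, ]
    n <- n + 1L
    faces[[n]] <- unname(eidx[paste(pmin(vs, vs[c(2, 3, 1)]),
                                    pmax(vs, vs[c(2, 3, 1)]), sep = "-")])
  }
  for (u in seq_len(topo$nV)) {
    nb <- topo$vcycle[[u]]$nbrs
    n <- n + 1L
    faces[[n]] <- unname(eidx[paste(pmin(u, nb), pmax(u, nb), sep = "-")])
  }
  faces <- faces[seq_len(n)]
  types <- vapply(faces, function(fc) .gon_type(length(fc)), character(1))
  # vertex polygons of a 6-valent vertex are hexagons, 5-valent pentagons;
  # per-face triangles are triangles: .gon_type covers all of these
  list(V = mid, faces = faces, types = types)
}

# corner-vertex helper shared by cantellation and snub: one cage vertex per
# (triangulation vertex u, incident triangle t), placed at distance s from u
# towards the centroid of t (optionally twisted about the vertex normal)
.corner_vertices <- function(geo, topo, s, cos_th = 1, sin_th = 0) {
  cent <- t(vapply(seq_len(nrow(geo$F)), function(i)
    colMeans(geo$V[geo$F[i, ], , drop = FALSE]), numeric(3)))
  idx <- new.env(hash = TRUE, parent = emptyenv())
  V <- matrix(0, sum(lengths(lapply(topo$vcycle, `[[`, "tris"))), 3)
  n <- 0L
  for (u in seq_len(topo$nV)) {
    nu <- .unit(geo$V[u, ])
    for (ti in topo$vcycle[[u]]$tris) {
      d <- .unit(cent[ti, ] - geo$V[u, ])
      dd <- d * cos_th + .cross3(nu, d) * sin_th
      n <- n + 1L
      V[n, ] <- geo$V[u, ] + s * dd
      idx[[paste(u, ti, sep = ":")]] <- n
    }
  }
  list(V = V[seq_len(n), , drop = FALSE], idx = idx)
}

.edge_tris <- function(topo) {
  # for each undirected edge, the two adjacent triangles
  E <- topo$edges
  t1 <- integer(nrow(E)); t2 <- integer(nrow(E))
  for (i in seq_len(nrow(E))) {
    a <- E[i, 1]; b <- E[i, 2]
    t1[i] <- topo$dmap[[paste0(a, ">", b)]]
    t2[i] <- topo$dmap[[paste0(b, ">", a)]]
  }
  cbind(t1, t2)
}

# rhombitrihexagonal cage: hexagon (pentagon) at each lattice point, square
# on each lattice edge, triangle at each triangulation face.  Planar edge
# length s = a / (1 + sqrt(3)) for lattice spacing a.
.cage_cantellated <- function(geo, topo) {
  s <- geo$edge_len / (1 + sqrt(3))
  cv <- .corner_vertices(geo, topo, s)
  at <- function(u, t) cv$idx[[paste(u, t, sep = ":")]]
  faces <- list(); types <- character(0)
  for (u in seq_len(topo$nV)) {
    tris <- topo$vcycle[[u]]$tris
    faces[[length(faces) + 1L]] <- vapply(tris, function(t) at(u, t), integer(1))
    types <- c(types, .gon_type(length(tris)))
  }
  for (i in seq_len(nrow(geo$F))) {
    vs <- geo$F[i, ]
    faces[[length(faces) + 1L]] <- vapply(vs, function(u) at(u, i), integer(1))
    types <- c(types, "triangle")
  }
  et <- .edge_tris(topo)
  for (i in seq_len(nrow(topo$edges))) {
    u <- topo$edges[i, 1]; w <- topo$edges[i, 2]
    faces[[length(faces) + 1L]] <-
      c(at(u, et[i, 1]), at(u, et[i, 2]), at(w, et[i, 2]), at(w, et[i, 1]))
    types <- c(types, "square")
  }
  list(V = cv$V, faces = faces, types = types)
}

# snub hexagonal cage: twisted hexagons at lattice points, one triangle per
# triangulation face, two per edge.  The planar snub tiling fixes the corner
# distance s = a/sqrt(7) and twist angle sin(theta) = 1/(2*sqrt(7)); the
# sign of the twist sets the handedness.
.cage_snub <- function(geo, topo, chirality = "laevo") {
  s <- geo$edge_len / sqrt(7)
  sin_th <- (if (identical(chirality, "dextro")) 1 else -1) / (2 * sqrt(7))
  cos_th <- sqrt(1 - sin_th^2)
  cv <- .corner_vertices(geo, topo, s, cos_th, sin_th)
  at <- function(u, t) cv$idx[[paste(u, t, sep = ":")]]
  faces <- list(); types <- character(0)
  for (u in seq_len(topo$nV)) {
    tris <- topo$vcycle[[u]]$tris
    faces[[length(faces) + 1L]] <- vapply(tris, function(t) at(u, t), integer(1))
    types <- c(types, .gon_type(length(tris)))
  }
  for (i in seq_len(nrow(geo$F))) {
    vs <- geo$F[i, ]
    faces[[length(faces) + 1L]] <- vapply(vs, function(u) at(u, i), integer(1))
    types <- c(types, "triangle")
  }
  et <- .edge_tris(topo)
  V <- cv$V
  for (i in seq_len(nrow(topo$edges))) {
    u <- topo$edges[i, 1]; w <- topo$edges[i, 2]
    A <- at(u, et[i, 1]); B <- at(u, et[i, 2])
    C <- at(w, et[i, 2]); D <- at(w, et[i, 1])
    # split the edge quad along its shorter diagonal (the snub diagonal has
    # the tiling edge length; the other one is longer)
    dAC <- sum((V[A, ] - V[C, ])^2)
    dBD <- sum((V[B, ] - V[D, ])^2)
    if (dAC <= dBD) {
      faces[[length(faces) + 1L]] <- c(A, B, C)
      faces[[length(faces) + 1L]] <- c(A, C, D)
    } else {
      faces[[length(faces) + 1L]] <- c(A, B, D)
      faces[[length(faces) + 1L]] <- c(B, C, D)
    }
    types <- c(types, "triangle", "triangle")
  }
  list(V = cv$V, faces = faces, types = types)
}

#' Count cage faces by type
#'
#' @param mesh A [build_cage()] mesh.
#' @return Named integer vector with counts for `pentagon`, `hexagon`,
#'   `triangle`, `square` (plus any other polygon class present). Every
#'   primal cage has exactly 12 pentagons, one per 5-fold axis.
#' @examples
#' face_census(build_cage(generalized_t(1, 1, "hexagonal")))  # 12 + 20
#' @export
face_census <- function(mesh) {
  stopifnot(inherits(mesh, "cage_mesh"))
  base <- c(pentagon = 0L, hexagon = 0L, triangle = 0L, square = 0L)
  tab <- table(mesh$face_type)
  for (nm in names(tab)) base[nm] <- as.integer(tab[[nm]])
  base[!is.na(base)]
}

#' Edges of a cage mesh
#'
#' @param mesh A `"cage_mesh"`.
#' @return Two-column integer matrix of undirected edges (each once).
#' @export
mesh_edges <- function(mesh) {
  stopifnot(inherits(mesh, "cage_mesh"))
  E <- do.call(rbind, lapply(mesh$faces, function(fc) {
    m <- length(fc)
    cbind(fc, fc[c(2:m, 1)])
  }))
  unique(cbind(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2])))
}

#' Euler characteristic V - E + F of a cage mesh
#'
#' @param mesh A `"cage_mesh"`.
#' @return Integer; 2 for any closed genus-0 cage.
#' @export
mesh_euler <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + length(mesh$faces)
}

#' Is the mesh a closed, consistently oriented surface?
#'
#' Checks that every directed edge appears exactly once across the faces
#' (hence every undirected edge is shared by exactly two faces, traversed in
#' opposite directions).
#'
#' @param mesh A `"cage_mesh"`.
#' @return `TRUE` or `FALSE`.
#' @export
mesh_is_closed <- function(mesh) {
  dir <- do.call(rbind, lapply(mesh$faces, function(fc) {
    m <- length(fc)
    cbind(fc, fc[c(2:m, 1)])
  }))
  keys <- paste(dir[, 1], dir[, 2], sep = ">")
  rkeys <- paste(dir[, 2], dir[, 1], sep = ">")
  !anyDuplicated(keys) && all(rkeys %in% keys)
}

#' Dual cage mesh
#'
#' Builds the dual of a cage: one vertex per primal face (at its centroid,
#' projected according to the mesh sphericity) and one face per primal
#' vertex. The duals of the four Archimedean lattice cages carry the
#' associated Laves lattices.
#'
#' @param mesh A primal `"cage_mesh"`.
#' @return A `"cage_mesh"` with `is_dual = TRUE`.
#' @examples
#' d <- dual_mesh(build_cage(generalized_t(1, 0, "hexagonal")))
#' face_census(d)  # icosahedron: 20 triangles
#' @export
dual_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "cage_mesh"))
  flat <- mesh$vertices_flat
  cent <- t(vapply(mesh$faces, function(fc)
    colMeans(flat[fc, , drop = FALSE]), numeric(3)))
  # directed edge (a,b) -> owning face
  dmap <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(mesh$faces)) {
    fc <- mesh$faces[[i]]
    m <- length(fc)
    for (e in seq_len(m)) {
      dmap[[paste0(fc[e], ">", fc[e %% m + 1L])]] <- i
    }
  }
  pred_in <- function(face_id, u) {
    fc <- mesh$faces[[face_id]]
    pos <- match(u, fc)
    fc[(pos - 2L) %% length(fc) + 1L]
  }
  nV <- nrow(flat)
  faces <- vector("list", nV)
  for (u in seq_len(nV)) {
    f0 <- NULL
    for (i in seq_along(mesh$faces)) {
      if (u %in% mesh$faces[[i]]) { f0 <- i; break }
    }
    cyc <- integer(0)
    fi <- f0
    repeat {
      cyc <- c(cyc, fi)
      fi <- dmap[[paste0(u, ">", pred_in(fi, u))]]
      if (fi == f0) break
      if (length(cyc) > 32L) stop("dual walk failed; mesh not closed?")
    }
    faces[[u]] <- cyc
  }
  types <- vapply(faces, function(fc) .gon_type(length(fc)), character(1))
  faces <- .orient_outward(cent, faces)
  structure(list(
    vertices = .apply_sphericity(cent, mesh$sphericity, mesh$radius),
    vertices_flat = cent,
    faces = faces, face_type = types,
    architecture = mesh$architecture,
    sphericity = mesh$sphericity, radius = mesh$radius,
    is_dual = !mesh$is_dual
  ), class = "cage_mesh")
}

#' @export
print.cage_mesh <- function(x, ...) {
  cen <- face_census(x)
  arch <- x$architecture
  cat(sprintf("Capsid cage mesh: (h,k) = (%d,%d) %s%s, T = %.4g\n",
              arch$h, arch$k, arch$tiling$label,
              if (x$is_dual) " (dual)" else "", arch$t))
  cat(sprintf("  V = %d, E = %d, F = %d (Euler %d); sphericity %.2f, radius %g\n",
              nrow(x$vertices), nrow(mesh_edges(x)), length(x$faces),
              mesh_euler(x), x$sphericity, x$radius))
  cat("  faces:", paste(sprintf("%s %d", names(cen)[cen > 0], cen[cen > 0]),
                        collapse = ", "), "\n")
  invisible(x)
}
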