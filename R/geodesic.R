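# Internal geometry: icosahedron, Caspar-Klug lattice claiming, folding of the
# planar lattice onto the icosahedron surface, and surface topology helpers.
# Everything downstream (the four lattice cages, duals) is derived from the
# welded (h,k) geodesic triangulation built here.

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.unit <- function(v) v / sqrt(sum(v * v))

# Icosahedron in standard orientation: two opposite vertices on the z-axis,
# circumradius 1, faces oriented counter-clockwise seen from outside.
.icosahedron <- function() {
  z <- 1 / sqrt(5)
  r <- 2 / sqrt(5)
  upper <- t(vapply(0:4, function(i)
    c(r * cos(2 * pi * i / 5), r * sin(2 * pi * i / 5), z), numeric(3)))
  lower <- t(vapply(0:4, function(i)
    c(r * cos(2 * pi * (i + 0.5) / 5), r * sin(2 * pi * (i + 0.5) / 5), -z),
    numeric(3)))
  V <- rbind(c(0, 0, 1), upper, lower, c(0, 0, -1))
  F <- matrix(0L, 20, 3)
  row <- 1L
  for (i in 0:4) {
    u <- 2L + i; u2 <- 2L + (i + 1L) %% 5L
    l <- 7L + i; l2 <- 7L + (i + 1L) %% 5L
    F[row, ] <- c(1L, u, u2); row <- row + 1L
    F[row, ] <- c(u, l, u2); row <- row + 1L
    F[row, ] <- c(u2, l, l2); row <- row + 1L
    F[row, ] <- c(12L, l2, l); row <- row + 1L
  }
  for (i in seq_len(nrow(F))) {
    tri <- V[F[i, ], , drop = FALSE]
    n <- .cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    if (sum(n * colMeans(tri)) < 0) F[i, ] <- F[i, c(1L, 3L, 2L)]
  }
  list(V = V, F = F)
}

.face_normal <- function(ico, f) {
  tri <- ico$V[ico$F[f, ], , drop = FALSE]
  .unit(.cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ]))
}

# Unit lattice triangles claimed by the Caspar-Klug triangle with corners
# (0,0), (h,k), (-k,h+k) in axial lattice coordinates.  Exact integer
# arithmetic; centroids on a CK edge are tie-broken by an antisymmetric rule
# on the corner distances so that, under the edge gluing between adjacent
# facets, every physical triangle is claimed exactly once.
.claim_triangles <- function(h, k) {
  PA <- rbind(c(0L, 0L), c(h, k), c(-k, h + k))
  PB <- PA[c(2L, 3L, 1L), ]
  det2 <- function(u, v) u[1] * v[2] - u[2] * v[1]
  tris <- vector("list", 4L * (h + k + 4L)^2)
  n_claimed <- 0L
  for (i in (-k - 2L):(h + 2L)) {
    for (j in (-2L):(h + k + 2L)) {
      for (tt in 1:2) {
        tri <- if (tt == 1L) rbind(c(i, j), c(i + 1L, j), c(i, j + 1L))
        else rbind(c(i + 1L, j), c(i + 1L, j + 1L), c(i, j + 1L))
        q <- colSums(tri)  # 3 x centroid, integer
        s <- vapply(1:3, function(e)
          det2(PB[e, ] - PA[e, ], q - 3L * PA[e, ]), numeric(1))
        claim <- if (any(s < 0)) {
          FALSE
        } else if (all(s > 0)) {
          TRUE
        } else {
          e <- which(s == 0)
          if (length(e) != 1L) stop("degenerate lattice triangle at a corner")
          v <- vapply(1:3, function(cn)
            det2(PB[e, ] - PA[e, ], tri[cn, ] - PA[e, ]), numeric(1))
          if (max(v) > -min(v)) TRUE
          else if (max(v) < -min(v)) FALSE
          else {
            cz <- which(v == 0)
            v[cz %% 3L + 1L] > 0  # claim iff the CCW-successor lies inside
          }
        }
        if (claim) {
          n_claimed <- n_claimed + 1L
          tris[[n_claimed]] <- tri
        }
      }
    }
  }
  tris[seq_len(n_claimed)]
}

.lat2xy <- function(p) c(p[1] + p[2] / 2, p[2] * sqrt(3) / 2)

.rodrigues <- function(v, ax, cth, sth) {
  v * cth + .cross3(ax, v) * sth + ax * sum(ax * v) * (1 - cth)
}

# Fold a point mapped by the affine chart of facet f back onto the
# icosahedron surface: while the point lies beyond an edge of its current
# facet, rotate it about that edge onto the neighbouring facet's plane.
.fold_point <- function(p3, f, ico, edge_faces) {
  for (iter in 1:6) {
    W <- ico$V[ico$F[f, ], , drop = FALSE]
    M <- cbind(W[2, ] - W[1, ], W[3, ] - W[1, ])
    ab <- solve(crossprod(M), crossprod(M, p3 - W[1, ]))
    bc <- c(1 - sum(ab), ab)
    if (min(bc) >= -1e-9) return(p3)
    j <- which.min(bc)  # fold across the edge opposite the violated corner
    idx <- ico$F[f, setdiff(1:3, j)]
    e1 <- ico$V[idx[1], ]; e2 <- ico$V[idx[2], ]
    g <- setdiff(edge_faces[[paste(sort(idx), collapse = "-")]], f)
    nf <- .face_normal(ico, f); ng <- .face_normal(ico, g)
    ax <- .unit(e2 - e1)
    cth <- sum(nf * ng)
    sth <- sum(.cross3(nf, ng) * ax)
    p3 <- e1 + .rodrigues(p3 - e1, ax, cth, sth)
    f <- g
  }
  stop("point folding did not converge; unsupported lattice geometry")
}

# Welded geodesic triangulation of the icosahedron for lattice steps (h,k).
# Returns vertices on the flat icosahedron surface (circumradius 1), the
# triangle index matrix (CCW from outside), and bookkeeping: V = 10*T0 + 2,
# E = 30*T0, F = 20*T0.
.geodesic <- function(h, k) {
  t0 <- t0_number(h, k)
  ico <- .icosahedron()
  edge_faces <- .edge_face_map(ico$F)
  tris2d <- .claim_triangles(h, k)
  if (length(tris2d) != t0) {
    stop(sprintf("lattice claiming produced %d triangles, expected T0 = %d",
                 length(tris2d), t0))
  }
  Q1 <- .lat2xy(c(h, k)); Q2 <- .lat2xy(c(-k, h + k))
  A2 <- cbind(Q1, Q2)
  edge_len <- sqrt(sum((ico$V[ico$F[1, 1], ] - ico$V[ico$F[1, 2], ])^2))
  tol2 <- (1e-6 * edge_len)^2
  P <- matrix(0, nrow = 10L * t0 + 2L, ncol = 3)
  nP <- 0L
  Ft <- matrix(0L, nrow = 20L * t0, ncol = 3)
  nF <- 0L
  weld <- function(p) {
    if (nP > 0L) {
      d2 <- colSums((t(P[seq_len(nP), , drop = FALSE]) - p)^2)
      hit <- which(d2 < tol2)
      if (length(hit)) return(hit[1L])
    }
    nP <<- nP + 1L
    if (nP > nrow(P)) P <<- rbind(P, matrix(0, 64L, 3))
    P[nP, ] <<- p
    nP
  }
  for (f in 1:20) {
    W <- ico$V[ico$F[f, ], , drop = FALSE]
    for (tr in tris2d) {
      id3 <- integer(3)
      for (cn in 1:3) {
        q <- .lat2xy(tr[cn, ])
        ab <- solve(A2, q)
        p3 <- W[1, ] + ab[1] * (W[2, ] - W[1, ]) + ab[2] * (W[3, ] - W[1, ])
        id3[cn] <- weld(.fold_point(p3, f, ico, edge_faces))
      }
      nF <- nF + 1L
      Ft[nF, ] <- id3
    }
  }
  if (nP != 10L * t0 + 2L) {
    stop(sprintf("welding produced %d vertices, expected %d", nP, 10L * t0 + 2L))
  }
  list(V = P[seq_len(nP), , drop = FALSE], F = Ft,
       t0 = t0, edge_len = edge_len / sqrt(t0))
}

.edge_face_map <- function(F) {
  m <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(F))) {
    vs <- F[i, ]
    for (e in 1:length(vs)) {
      a <- vs[e]; b <- vs[e %% length(vs) + 1L]
      key <- paste(sort(c(a, b)), collapse = "-")
      m[[key]] <- c(if (!is.null(m[[key]])) m[[key]], i)
    }
  }
  as.list(m)
}

# Topology of a welded triangulation: directed-edge lookup, undirected edges,
# and the cyclic order of triangles/neighbours around every vertex.
.tri_topology <- function(Ft) {
  nF <- nrow(Ft)
  dir_key <- function(a, b) paste0(a, ">", b)
  dmap <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nF)) {
    for (e in 1:3) {
      a <- Ft[i, e]; b <- Ft[i, e %% 3L + 1L]
      k <- dir_key(a, b)
      if (!is.null(dmap[[k]])) stop("surface is not closed/orientable")
      dmap[[k]] <- i
    }
  }
  E <- rbind(Ft[, c(1, 2)], Ft[, c(2, 3)], Ft[, c(3, 1)])
  E <- unique(t(apply(E, 1, sort)))
  nV <- max(Ft)
  # cyclic walk: from triangle t around vertex u, the next triangle is the one
  # containing the directed edge (u, predecessor-of-u-in-t)
  vcycle <- vector("list", nV)
  vstart <- integer(nV)
  for (i in seq_len(nF)) for (e in 1:3) vstart[Ft[i, e]] <- i
  for (u in seq_len(nV)) {
    t0i <- vstart[u]
    cyc_t <- integer(0)
    cyc_n <- integer(0)
    ti <- t0i
    repeat {
      vs <- Ft[ti, ]
      pos <- match(u, vs)
      pred <- vs[(pos - 2L) %% 3L + 1L]  # previous vertex in CCW order
      cyc_t <- c(cyc_t, ti)
      cyc_n <- c(cyc_n, pred)
      ti <- dmap[[dir_key(u, pred)]]
      if (ti == t0i) break
      if (length(cyc_t) > 12L) stop("vertex cycle walk failed")
    }
    vcycle[[u]] <- list(tris = cyc_t, nbrs = cyc_n)
  }
  list(edges = E, vcycle = vcycle, dmap = dmap, nV = nV, nF = nF)
}
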