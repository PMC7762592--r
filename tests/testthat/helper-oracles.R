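# Independent oracles used across the suite.

# brute-force classic T-number
oracle_t0 <- function(h, k) h^2 + h * k + k^2

# the set of achievable classic T-numbers up to a bound, by exhaustive scan
oracle_t0_set <- function(hmax, bound) {
  vals <- c()
  for (h in 0:hmax) for (k in 0:hmax) {
    if (h == 0 && k == 0) next
    vals <- c(vals, oracle_t0(h, k))
  }
  sort(unique(vals[vals <= bound]))
}

# area of the rhombitrihexagonal tiling unit cell (1 hexagon + 2 triangles +
# 3 squares, unit edge) over the hexagon area: the lattice area factor
oracle_alpha_rhombi <- function() {
  hex <- 3 * sqrt(3) / 2
  tri <- sqrt(3) / 4
  (hex + 2 * tri + 3 * 1) / hex
}

# exhaustive (h, k, tiling) scan for membership of a T value
oracle_t_member <- function(t, t_max, tol = 1e-3) {
  alphas <- c(1, 4 / 3, 7 / 3, 4 / 3 + 2 * sqrt(3) / 3)
  hits <- list()
  for (h in 0:ceiling(sqrt(t_max))) for (k in 0:h) {
    if (h == 0 && k == 0) next
    for (a in seq_along(alphas)) {
      tt <- alphas[a] * oracle_t0(h, k)
      if (abs(tt - t) < tol) hits[[length(hits) + 1]] <- c(h, k, a)
    }
  }
  hits
}

# midpoint-interval classifier: boundaries between consecutive model means
oracle_assign_midpoints <- function(length_bp, fit, series) {
  series <- sort(series)
  means <- predict_mean(fit, series)
  cuts <- (means[-1] + means[-length(means)]) / 2
  # lengths exactly on a boundary belong to the smaller t
  idx <- findInterval(length_bp / 1000, cuts, left.open = TRUE) + 1L
  series[idx]
}

# polygon planarity: largest distance of a face's vertices from its
# least-squares plane
face_planarity <- function(mesh, face_id) {
  pts <- mesh$vertices[mesh$faces[[face_id]], , drop = FALSE]
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  max(abs(sweep(pts, 2, ctr) %*% sv$v[, 3]))
}

poly_area3d <- function(pts) {
  m <- nrow(pts)
  n <- c(0, 0, 0)
  for (i in seq_len(m)) {
    a <- pts[i, ]; b <- pts[i %% m + 1L, ]
    n <- n + c(a[2] * b[3] - a[3] * b[2],
               a[3] * b[1] - a[1] * b[3],
               a[1] * b[2] - a[2] * b[1])
  }
  sqrt(sum(n^2)) / 2
}

mesh_total_area <- function(mesh) {
  sum(vapply(mesh$faces, function(fc)
    poly_area3d(mesh$vertices[fc, , drop = FALSE]), numeric(1)))
}

mesh_median_edge <- function(mesh) {
  E <- mesh_edges(mesh)
  stats::median(sqrt(rowSums((mesh$vertices[E[, 1], , drop = FALSE] -
                              mesh$vertices[E[, 2], , drop = FALSE])^2)))
}

# rotate a point set by angle about a unit axis through the origin
rotate_pts <- function(P, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  P %*% t(R)
}

# is point set A equal to point set B up to tolerance (as sets)?
same_point_set <- function(A, B, tol = 1e-6) {
  if (nrow(A) != nrow(B)) return(FALSE)
  all(vapply(seq_len(nrow(A)), function(i) {
    min(colSums((t(B) - A[i, ])^2)) < tol^2
  }, logical(1)))
}

printed_genome_fit <- function() from_printed_params(0.37, 1.47, "genome_kbp",
                                                     0.10, 0.09)
printed_diameter_fit <- function() from_printed_params(1.38, 0.52, "diameter_nm",
                                                       0.34, 0.03)
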