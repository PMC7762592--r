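# The T0 = 1 cages of the four lattices are the classical polyhedra
# (dodecahedron, icosidodecahedron, snub dodecahedron,
# rhombicosidodecahedron); higher architectures are checked through face
# censuses, Euler characteristic and closure.

test_that("T0 = 1 cages reproduce the classical polyhedron topologies", {
  cases <- list(
    list("hexagonal", c(pentagon = 12L, hexagon = 0L, triangle = 0L,
                        square = 0L), V = 20L, E = 30L),
    list("trihexagonal", c(pentagon = 12L, hexagon = 0L, triangle = 20L,
                           square = 0L), V = 30L, E = 60L),
    list("snub_hexagonal", c(pentagon = 12L, hexagon = 0L, triangle = 80L,
                             square = 0L), V = 60L, E = 150L),
    list("rhombitrihexagonal", c(pentagon = 12L, hexagon = 0L,
                                 triangle = 20L, square = 30L),
         V = 60L, E = 120L)
  )
  for (cs in cases) {
    m <- build_cage(generalized_t(1, 0, cs[[1]]))
    expect_identical(face_census(m), cs[[2]], info = cs[[1]])
    expect_identical(nrow(m$vertices), cs$V, info = cs[[1]])
    expect_identical(nrow(mesh_edges(m)), cs$E, info = cs[[1]])
    expect_identical(mesh_euler(m), 2L, info = cs[[1]])
    expect_true(mesh_is_closed(m), info = cs[[1]])
  }
})

test_that("hexagonal cages have 10(T-1) hexagons and 12 pentagons", {
  for (hk in list(c(1, 1), c(2, 0), c(2, 1))) {
    m <- build_cage(generalized_t(hk[1], hk[2], "hexagonal"))
    t <- t0_number(hk[1], hk[2])
    cen <- face_census(m)
    expect_identical(unname(cen["pentagon"]), 12L)
    expect_identical(unname(cen["hexagon"]), 10L * (t - 1L))
    expect_identical(length(m$faces), 10L * t + 2L)  # capsomer count
    expect_identical(mesh_euler(m), 2L)
    expect_true(mesh_is_closed(m))
  }
})

test_that("every small architecture builds a closed Euler-2 mesh", {
  # the full T <= 4 set over all four lattices
  tab <- architecture_table(enumerate_architectures(4))
  for (i in seq_len(nrow(tab))) {
    m <- build_cage(generalized_t(tab$h[i], tab$k[i], tab$tiling[i]))
    expect_true(mesh_is_closed(m),
                info = sprintf("%s (%d,%d)", tab$tiling[i], tab$h[i], tab$k[i]))
    expect_identical(mesh_euler(m), 2L)
    expect_identical(unname(face_census(m)["pentagon"]), 12L)
  }
})

test_that("welding leaves no near-duplicate vertices", {
  m <- build_cage(generalized_t(2, 1, "hexagonal"), radius = 1)
  D <- as.matrix(dist(m$vertices))
  diag(D) <- Inf
  expect_gt(min(D), 1e-8)
})

test_that("sphericity interpolates between flat facets and the sphere", {
  arch <- generalized_t(2, 1, "hexagonal")
  m1 <- build_cage(arch, sphericity = 1, radius = 30)
  r <- sqrt(rowSums(m1$vertices^2))
  expect_equal(max(abs(r - 30)) / 30, 0, tolerance = 1e-6)
  m0 <- build_cage(arch, sphericity = 0, radius = 30)
  expect_gt(diff(range(sqrt(rowSums(m0$vertices^2)))), 0.1)
  mh <- build_cage(arch, sphericity = 0.5, radius = 30)
  r0 <- sqrt(rowSums(m0$vertices^2))
  expect_equal(sqrt(rowSums(mh$vertices^2)), (r0 + 30) / 2, tolerance = 1e-9)
  expect_error(build_cage(arch, sphericity = 1.2), "sphericity")
  expect_error(build_cage(arch, radius = -3), "radius")
})

test_that("faces lying within one facet are planar at sphericity 0", {
  m <- build_cage(generalized_t(1, 0, "hexagonal"))
  for (i in seq_along(m$faces)) expect_lt(face_planarity(m, i), 1e-6)
  # T = 3 truncated-icosahedron-like cage: hexagons centred on facets
  m3 <- build_cage(generalized_t(1, 1, "hexagonal"))
  expect_identical(unname(face_census(m3)[c("pentagon", "hexagon")]),
                   c(12L, 20L))
})

test_that("surface-area ratios between lattices approximate the area factors", {
  # compare at equal t0 and equal edge length, away from the coarse-mesh
  # curvature regime
  mh <- build_cage(generalized_t(2, 0, "hexagonal"))
  ah <- mesh_total_area(mh); eh <- mesh_median_edge(mh)
  for (lab in c("trihexagonal", "snub_hexagonal", "rhombitrihexagonal")) {
    m <- build_cage(generalized_t(2, 0, lab))
    ratio <- (mesh_total_area(m) / ah) * (eh / mesh_median_edge(m))^2
    alpha <- tiling_class(lab)$area_factor
    expect_equal(ratio, alpha, tolerance = 0.02, info = lab)
  }
})

test_that("the sphericity-1 vertex set has icosahedral symmetry", {
  m <- build_cage(generalized_t(2, 1, "hexagonal"), sphericity = 1)
  V <- m$vertices
  # generators: 5-fold rotation about the z vertex axis and a 2-fold
  # rotation about an edge-midpoint axis
  expect_true(same_point_set(V, rotate_pts(V, c(0, 0, 1), 2 * pi / 5)))
  ico <- capsidkit:::.icosahedron()
  edge_mid <- (ico$V[ico$F[1, 1], ] + ico$V[ico$F[1, 2], ]) / 2
  expect_true(same_point_set(V, rotate_pts(V, edge_mid, pi)))
})

test_that("snub cages are chiral: laevo and dextro are distinct mirror forms", {
  ml <- build_cage(generalized_t(1, 0, tiling_class("snub_hexagonal", "laevo")))
  md <- build_cage(generalized_t(1, 0, tiling_class("snub_hexagonal", "dextro")))
  expect_identical(face_census(ml), face_census(md))
  expect_false(same_point_set(ml$vertices, md$vertices))
  # mirroring laevo through the xz-plane gives the dextro vertex set
  mirrored <- ml$vertices %*% diag(c(1, -1, 1))
  expect_true(same_point_set(mirrored, md$vertices))
})

test_that("dual meshes swap vertices and faces and stay closed", {
  m <- build_cage(generalized_t(1, 0, "hexagonal"))
  d <- dual_mesh(m)
  expect_identical(nrow(d$vertices), length(m$faces))
  expect_identical(length(d$faces), nrow(m$vertices))
  expect_identical(unname(face_census(d)["triangle"]), 20L)  # icosahedron
  expect_identical(mesh_euler(d), 2L)
  expect_true(mesh_is_closed(d))
  dd <- dual_mesh(d)
  expect_identical(length(dd$faces), length(m$faces))
  # Laves dual of a larger hexagonal cage
  d7 <- dual_mesh(build_cage(generalized_t(2, 1, "hexagonal")))
  expect_identical(mesh_euler(d7), 2L)
  expect_true(mesh_is_closed(d7))
})
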