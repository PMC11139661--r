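test_that("icospheres are closed, well-oriented, and near-spherical", {
  for (s in 0:2) {
    m <- icosphere(1, c(0, 0, 0), s)
    expect_silent(validate_mesh(m))
    expect_equal(nrow(m$faces), 20 * 4^s)
    # volume approaches 4/3 pi from below as the tessellation refines
    expect_lt(mesh_volume(m), 4 * pi / 3)
    expect_gt(mesh_volume(m), (4 * pi / 3) * (1 - 3 * icosphere_tolerance(s)))
  }
  m <- icosphere(2.5, c(1, -2, 3), 2)
  expect_equal(mesh_centroid(m), c(1, -2, 3), tolerance = 1e-9)
  expect_equal(mesh_volume(m), 2.5^3 * mesh_volume(icosphere(1, c(0, 0, 0), 2)),
               tolerance = 1e-9)
})

test_that("scale_mesh: identity, radial displacement, volume ratio, errors", {
  m <- icosphere(1, c(0, 0, 0), 2)
  expect_equal(scale_mesh(m, 1)$vertices, m$vertices, tolerance = 1e-12)

  s <- scale_mesh(m, 1.05)
  expect_equal(sqrt(rowSums(s$vertices^2)),
               rep(1.05, nrow(s$vertices)), tolerance = 1e-9)
  expect_equal(mesh_volume(s) / mesh_volume(m), 1.05^3, tolerance = 1e-9)
  expect_identical(s$faces, m$faces)

  # centroid is preserved, including off-origin
  m2 <- icosphere(1, c(4, 5, 6), 2)
  expect_equal(mesh_centroid(scale_mesh(m2, 1.3)), c(4, 5, 6), tolerance = 1e-9)

  # star-shaped jittered mesh still scales volume by factor^3 exactly
  star <- jittered_star_mesh(seed = 42)
  expect_equal(mesh_volume(scale_mesh(star, 1.05)) / mesh_volume(star),
               1.05^3, tolerance = 1e-9)

  expect_error(scale_mesh(m, 0), class = "blastonet_invalid_parameter")
  expect_error(scale_mesh(m, -2), class = "blastonet_invalid_parameter")
  flat <- blastomere_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
    rbind(c(1, 2, 3), c(2, 4, 3), c(1, 3, 2), c(2, 3, 4)),
    validate = FALSE)
  expect_error(scale_mesh(flat, 1.05), class = "blastonet_invalid_mesh")
})

test_that("mesh validation rejects open and degenerate surfaces", {
  m <- icosphere(1, c(0, 0, 0), 1)
  open_mesh <- m
  open_mesh$faces <- m$faces[-1, , drop = FALSE]
  expect_error(validate_mesh(open_mesh), class = "blastonet_invalid_mesh")
  expect_error(blastomere_mesh(m$vertices[1:3, ], m$faces),
               class = "blastonet_invalid_mesh")
  expect_error(blastomere_mesh(m$vertices, cbind(m$faces[, 1:2], 999L)),
               class = "blastonet_invalid_mesh")
})

test_that("meshes_overlap matches intuition on sphere pairs and is symmetric", {
  a <- icosphere(1, c(0, 0, 0), 2)
  expect_false(meshes_overlap(a, icosphere(1, c(2.2, 0, 0), 2)))
  expect_true(meshes_overlap(a, icosphere(1, c(1.9, 0, 0), 2)))
  # full engulfment: small sphere strictly inside the big one
  expect_true(meshes_overlap(a, icosphere(0.3, c(0.2, 0, 0), 2)))
  expect_true(meshes_overlap(icosphere(0.3, c(0.2, 0, 0), 2), a))

  set.seed(11)
  for (i in 1:10) {
    r1 <- runif(1, 0.5, 1.5); r2 <- runif(1, 0.5, 1.5)
    d <- runif(1, 0.3, 1.3) * (r1 + r2)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    m1 <- icosphere(r1, c(0, 0, 0), 2)
    m2 <- icosphere(r2, d * dir, 2)
    expect_identical(meshes_overlap(m1, m2), meshes_overlap(m2, m1))
  }
})

test_that("random sphere pairs agree with the analytic contact criterion", {
  tol_band <- icosphere_tolerance(2)
  set.seed(7)
  checked <- 0
  for (i in 1:40) {
    r1 <- runif(1, 0.6, 1.4); r2 <- runif(1, 0.6, 1.4)
    d <- runif(1, 0.8, 1.2) * (r1 + r2) / 1.05 # concentrate near the boundary
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    thresh <- 1.05 * (r1 + r2)
    if (abs(d - thresh) < tol_band * thresh) next # tessellation tolerance band
    m1 <- scale_mesh(icosphere(r1, c(0, 0, 0), 2), 1.05)
    m2 <- scale_mesh(icosphere(r2, d * dir, 2), 1.05)
    expect_identical(meshes_overlap(m1, m2), d < thresh)
    checked <- checked + 1
  }
  expect_gte(checked, 25)
})

test_that("contact_network reproduces analytic graphs for canonical layouts", {
  tet <- canonical_sphere_embryo(rbind(c(1, 1, 1), c(1, -1, -1),
                                       c(-1, 1, -1), c(-1, -1, 1)) / sqrt(2))
  net <- contact_network(tet, 1.05)
  expect_equal(net$n_nodes, 4)
  expect_equal(nrow(net$edges), 6) # K4

  sq <- canonical_sphere_embryo(rbind(c(0, 0, 0), c(2, 0, 0),
                                      c(2, 2, 0), c(0, 2, 0)))
  net_sq <- contact_network(sq, 1.05)
  expect_equal(nrow(net_sq$edges), 4) # 4-cycle: diagonals 2*sqrt(2) > 2.1
  expect_equal(sort(network_degrees(net_sq)), rep(2L, 4))

  single <- embryo(list(icosphere(1, c(0, 0, 0), 1, cell_id = "solo")))
  net1 <- contact_network(single)
  expect_equal(net1$n_nodes, 1)
  expect_equal(nrow(net1$edges), 0)
})

test_that("edge sets grow monotonically with the scale factor", {
  e <- generate_arrangement(arrangement_spec("packed_n8", seed = 21,
                                             jitter_sd = 0.05))
  nets <- lapply(c(1.01, 1.05, 1.2), function(f) contact_network(e, f))
  keys <- lapply(nets, function(n) paste(n$edges[, 1], n$edges[, 2]))
  expect_true(all(keys[[1]] %in% keys[[2]]))
  expect_true(all(keys[[2]] %in% keys[[3]]))
})

test_that("contact networks are invariant under rigid motion", {
  e <- generate_arrangement(arrangement_spec("packed_n8", seed = 3,
                                             jitter_sd = 0.03))
  ref <- contact_network(e)
  for (s in 1:3) {
    e2 <- transform_embryo(e, random_rotation(seed = s),
                           translation = c(10 * s, -5, 2))
    expect_identical(contact_network(e2)$edges, ref$edges)
  }
})

test_that("mesh errors propagate from contact_network with the cell id", {
  good <- icosphere(1, c(0, 0, 0), 1, cell_id = "ok")
  bad <- blastomere_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
    rbind(c(1, 2, 3), c(2, 4, 3), c(1, 3, 2), c(2, 3, 4)),
    cell_id = "broken", validate = FALSE)
  emb <- embryo(list(good, bad))
  err <- tryCatch(contact_network(emb), blastonet_invalid_mesh = function(e) e)
  expect_match(conditionMessage(err), "broken")
})
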