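# marching cubes and the 14 shape features

test_that("an isolated voxel meshes to the exact octahedron", {
  mesh <- maskToMesh(single_voxel_mask())
  expect_equal(nrow(meshVertices(mesh)), 6)
  expect_equal(nrow(meshFaces(mesh)), 8)
  av <- meshAreaVolume(mesh)
  # octahedron with apexes 0.5 mm along each axis: V = 4a^3/3, A = 4 sqrt(3) a^2
  expect_equal(unname(av["volume"]), 1 / 6, tolerance = 1e-12)
  expect_equal(unname(av["area"]), sqrt(3), tolerance = 1e-12)
  expect_gt(signed_mesh_volume(mesh), 0)  # outward orientation
  d <- diameterMetrics(mesh)
  expect_equal(unname(d["max_3d_diameter"]), 1, tolerance = 1e-12)
})

test_that("meshing an empty mask errors", {
  expect_error(maskToMesh(BinaryMask(array(FALSE, c(4, 4, 4)))), "empty")
})

test_that("a solid cube meshes closed with Euler characteristic 2", {
  m <- array(FALSE, c(22, 22, 22))
  m[2:21, 2:21, 2:21] <- TRUE
  mesh <- maskToMesh(BinaryMask(m))
  census <- hippasym:::cpp_edge_census(meshFaces(mesh),
                                       nrow(meshVertices(mesh)))
  expect_true(census$closed_oriented)
  euler <- nrow(meshVertices(mesh)) - census$n_edges + nrow(meshFaces(mesh))
  expect_equal(euler, 2)
  # no degenerate faces
  V <- meshVertices(mesh); F <- meshFaces(mesh)
  u <- V[F[, 2], ] - V[F[, 1], ]; w <- V[F[, 3], ] - V[F[, 1], ]
  areas <- sqrt((u[, 2] * w[, 3] - u[, 3] * w[, 2])^2 +
                (u[, 3] * w[, 1] - u[, 1] * w[, 3])^2 +
                (u[, 1] * w[, 2] - u[, 2] * w[, 1])^2) / 2
  expect_gt(min(areas), 0)
})

test_that("smoothed voxelized balls approach the analytic sphere", {
  errs <- sapply(c(5, 10), function(r) {
    f <- computeShapeFeatures(ball_mask(r))
    c(vol = abs(f[["mesh_volume"]] / (4 * pi * r^3 / 3) - 1),
      area = abs(f[["surface_area"]] / (4 * pi * r^2) - 1),
      sph = f[["sphericity"]],
      d3 = abs(f[["max_3d_diameter"]] / (2 * r) - 1))
  })
  expect_lt(max(errs["vol", ]), 0.025)
  expect_lt(max(errs["area", ]), 0.02)
  expect_gt(min(errs["sph", ]), 0.97)
  expect_lt(errs["d3", 2], 0.03)  # r = 10: within 3% of 20 mm
  # raw-mesh volume error shrinks as the ball grows
  raw_err <- sapply(c(5, 10), function(r) {
    av <- meshAreaVolume(maskToMesh(ball_mask(r)))
    abs(av[["volume"]] / (4 * pi * r^3 / 3) - 1)
  })
  expect_lt(raw_err[2], raw_err[1])
})

test_that("features scale dimensionally with voxel spacing", {
  m <- generateHippocampusMask(phantomConfig(seed = 3, fray_amplitude = 0.2,
                                             semi_axes = c(10, 5, 4)))
  f1 <- computeShapeFeatures(m)
  f2 <- computeShapeFeatures(BinaryMask(maskArray(m), spacing = c(2, 2, 2)))
  expect_equal(f2[["surface_area"]], 4 * f1[["surface_area"]],
               tolerance = 1e-10)
  expect_equal(f2[["mesh_volume"]], 8 * f1[["mesh_volume"]],
               tolerance = 1e-10)
  expect_equal(f2[["voxel_volume"]], 8 * f1[["voxel_volume"]],
               tolerance = 1e-12)
  # shrinking by s multiplies S/V by 1/s
  expect_equal(f2[["surface_to_volume_ratio"]],
               f1[["surface_to_volume_ratio"]] / 2, tolerance = 1e-10)
  expect_equal(f2[["max_3d_diameter"]], 2 * f1[["max_3d_diameter"]],
               tolerance = 1e-10)
})

test_that("axis metrics recover continuum ellipsoid moments", {
  ell <- ellipsoid_mask(c(20, 12, 8))
  ax <- axisMetrics(ell)
  expect_equal(unname(ax["elongation"]), 12 / 20, tolerance = 0.02)
  expect_equal(unname(ax["flatness"]), 8 / 20, tolerance = 0.02)
  # lambda1 = a^2/5 for a solid ellipsoid => major = 4 a / sqrt(5)
  expect_equal(unname(ax["major_axis_length"]), 4 * 20 / sqrt(5),
               tolerance = 0.02)
  ball <- ball_mask(8)
  axb <- axisMetrics(ball)
  expect_equal(unname(axb["elongation"]), 1, tolerance = 0.02)
  expect_equal(unname(axb["flatness"]), 1, tolerance = 0.02)
  expect_error(axisMetrics(single_voxel_mask()), "at least 2")
})

test_that("the feature set has exactly the 14 named features", {
  f <- computeShapeFeatures(ellipsoid_mask(c(6, 4, 3)))
  expect_length(f, 14)
  expect_identical(names(f), shapeFeatureNames())
  expect_true(all(f > 0))
  expect_lte(f[["flatness"]], f[["elongation"]])
  expect_lte(f[["elongation"]], 1)
  expect_lte(f[["sphericity"]], 1)
  expect_gte(f[["max_3d_diameter"]],
             max(f[["max_2d_diameter_slice"]], f[["max_2d_diameter_column"]],
                 f[["max_2d_diameter_row"]]))
  # surface-to-volume and sphericity definitions hold exactly
  expect_equal(f[["surface_to_volume_ratio"]],
               f[["surface_area"]] / f[["mesh_volume"]], tolerance = 1e-12)
  expect_equal(abs(f[["mesh_volume"]] / f[["voxel_volume"]] - 1) < 0.1, TRUE)
})

test_that("rigid motions permute only the plane-specific 2D diameters", {
  m <- generateHippocampusMask(phantomConfig(seed = 9, fray_amplitude = 0.15,
                                             semi_axes = c(12, 6, 5)))
  f0 <- computeShapeFeatures(m)
  # axis-aligned flip
  flipped <- BinaryMask(maskArray(m)[rev(seq_len(dim(maskArray(m))[1])), , ],
                        spacing = voxelSpacing(m))
  ff <- computeShapeFeatures(flipped)
  expect_equal(unname(ff), unname(f0), tolerance = 1e-8)
  # 90 degree rotation about z: x and y swap => column/row diameters swap
  rot <- BinaryMask(aperm(maskArray(m), c(2, 1, 3)),
                    spacing = voxelSpacing(m)[c(2, 1, 3)])
  fr <- computeShapeFeatures(rot)
  inv <- setdiff(shapeFeatureNames(),
                 c("max_2d_diameter_column", "max_2d_diameter_row"))
  expect_equal(fr[inv], f0[inv], tolerance = 1e-8)
  expect_equal(fr[["max_2d_diameter_column"]], f0[["max_2d_diameter_row"]],
               tolerance = 1e-8)
  expect_equal(fr[["max_2d_diameter_row"]], f0[["max_2d_diameter_column"]],
               tolerance = 1e-8)
})

test_that("surface indentation at fixed bulk increases the S/V ratio", {
  sv <- sapply(c(0, 0.2, 0.4), function(amp) {
    f <- computeShapeFeatures(generateHippocampusMask(
      phantomConfig(seed = 11, fray_amplitude = amp)))
    f[["surface_to_volume_ratio"]]
  })
  expect_true(all(diff(sv) > 0))
})

test_that("features for both sides of a label volume are keyed by side", {
  sub <- generateLabelledSubject(phantomConfig(seed = 1),
                                 phantomConfig(seed = 2))
  tab <- computeShapeFeaturesBySide(sub$volume)
  expect_equal(nrow(tab), 28)
  expect_setequal(unique(tab$side), c("left", "right"))
  expect_setequal(unique(tab$feature), shapeFeatureNames())
})
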