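test_that("voxelised domain volume matches the mesh volume", {
  sph <- fxSphere(5L)
  ph64 <- voxelizeChamber(sph, 64L)
  # within 2% of the closed-form sphere volume at 64^3
  expect_equal(domainVolume(ph64), sphereVol(), tolerance = 0.02)

  # refinement converges to the mesh volume at first order or better
  V <- enclosedVolume(sph)
  e64 <- abs(domainVolume(ph64) - V) / V
  e128 <- abs(domainVolume(voxelizeChamber(sph, 128L)) - V) / V
  expect_lt(e128, e64 / 1.8)
})

test_that("voxelisation rejects degenerate input", {
  cube <- unitCubeMesh()
  open <- list(vertices = cube$vertices, faces = cube$faces[-1, ])
  expect_error(voxelizeChamber(open, 16L), "not closed")
  empty <- list(vertices = cube$vertices, faces = cube$faces[0, , drop = FALSE])
  expect_error(voxelizeChamber(empty, 16L), "empty")
})

test_that("voxel mask is consistent with point membership", {
  cube <- unitCubeMesh()
  ph <- voxelizeChamber(cube, 16L)
  expect_equal(domainVolume(ph), 1, tolerance = 0.15)
  # all mask voxels lie inside the cube bounds
  idx <- which(ph@mask, arr.ind = TRUE)
  ax <- SiOTamponade:::gridAxes(ph)
  expect_true(all(ax$x[idx[, 1]] > 0 & ax$x[idx[, 1]] < 1))
  expect_true(all(ax$z[idx[, 3]] > 0 & ax$z[idx[, 3]] < 1))
})
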