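test_that("enclosed volume matches closed forms and flips sign with orientation", {
  cube <- unitCubeMesh()
  expect_equal(abs(enclosedVolume(cube)), 1.0, tolerance = 1e-12)

  sph <- fxSphere(5L)
  expect_equal(enclosedVolume(sph), sphereVol(), tolerance = 0.005)

  flipped <- list(vertices = cube$vertices, faces = cube$faces[, c(1, 3, 2)])
  expect_equal(enclosedVolume(flipped), -enclosedVolume(cube))

  open <- list(vertices = cube$vertices, faces = cube$faces[-1, ])
  expect_error(enclosedVolume(open), "not closed")
})

test_that("truncated sphere volume matches the spherical-cap closed form", {
  # subdivision >= 4 keeps the discretisation error below 1%
  for (sub in c(4L, 5L)) {
    m <- fxMesh("emmetropic", sub)
    expect_equal(enclosedVolume(m), sphereVol() - capVol(3),
                 tolerance = 0.01)
    expect_equal(enclosedVolume(fxSphere(sub)), sphereVol(), tolerance = 0.01)
  }
})

test_that("volume and area converge to closed forms at about second order", {
  errs <- vapply(3:5, function(sub) {
    abs(enclosedVolume(fxSphere(sub)) - sphereVol()) / sphereVol()
  }, numeric(1))
  # each refinement halves h: error ratio should be near 4 (allow 2.5-6.5)
  expect_lt(errs[2] / errs[1], 1 / 2.5)
  expect_lt(errs[3] / errs[2], 1 / 2.5)

  areaErrs <- vapply(3:5, function(sub) {
    abs(sum(faceAreas(fxSphere(sub))) - 4 * pi * 144) / (4 * pi * 144)
  }, numeric(1))
  expect_lt(areaErrs[2] / areaErrs[1], 1 / 2.5)
  expect_lt(areaErrs[3] / areaErrs[2], 1 / 2.5)
})

test_that("variants share connectivity and deformations are local", {
  me <- fxMesh("emmetropic"); ms <- fxMesh("staphyloma")
  mc <- fxMesh("staphyloma_cerclage")
  expect_identical(me@faces, ms@faces)
  expect_identical(me@faces, mc@faces)
  expect_identical(me@psi, ms@psi)

  # staphyloma only moves vertices at or beyond the onset angle
  onset <- me@params@staphylomaOnset
  ahead <- me@psi < onset
  expect_equal(ms@vertices[ahead, ], me@vertices[ahead, ])
  expect_false(isTRUE(all.equal(ms@vertices[!ahead, ], me@vertices[!ahead, ])))

  # outward bulge adds volume, band indentation removes it
  expect_gt(enclosedVolume(ms), enclosedVolume(me))
  expect_lt(enclosedVolume(mc), enclosedVolume(ms))
})

test_that("zero-depth deformations leave the mesh unchanged", {
  me <- fxMesh("emmetropic")
  p0 <- eyeGeometryParams(staphylomaDepth = 0, cerclageDepth = 0,
                          meshSubdivision = 4L)
  expect_equal(applyStaphyloma(me, p0)@vertices, me@vertices)
  expect_equal(applyCerclage(me, p0)@vertices, me@vertices)
})

test_that("staphyloma axial construction lengths and cerclage ring radius", {
  ms <- fxMesh("staphyloma")
  # lens plane at z = 9 to displaced posterior pole: 9 + 12 + 3.5
  axial <- (12 - 3) - min(ms@vertices[, 3])
  expect_equal(axial, 24.5, tolerance = 1e-9)

  mc <- fxMesh("staphyloma_cerclage")
  eq <- abs(mc@psi - 90) < 1e-9
  expect_true(any(eq))
  expect_equal(sqrt(rowSums(mc@vertices[eq, , drop = FALSE]^2)),
               rep(10.5, sum(eq)), tolerance = 1e-9)

  # cerclage deeper than the local radius must fail
  deep <- eyeGeometryParams(cerclageDepth = 13, meshSubdivision = 3L)
  expect_error(applyCerclage(fxMesh("emmetropic", 3L), deep), "radius")
})

test_that("meshes are watertight, outward-oriented, and axisymmetric", {
  for (variant in eyeVariants()) {
    m <- fxMesh(variant)
    expect_true(validObject(m))
    expect_gt(min(faceAreas(m)), 0)
  }
  # azimuthal rotation leaves volume and area unchanged
  m <- fxMesh("staphyloma_cerclage")
  th <- 23.456 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- m; rot@vertices <- m@vertices %*% Rz
  expect_equal(enclosedVolume(rot), enclosedVolume(m), tolerance = 1e-10)
  expect_equal(sum(faceAreas(rot)), sum(faceAreas(m)), tolerance = 1e-10)
})

test_that("mesh export round-trips OBJ vertices and faces", {
  m <- fxMesh("emmetropic", 3L)
  f <- tempfile(fileext = ".obj")
  writeMesh(m, f, "obj")
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "v ")), nrow(m@vertices))
  expect_equal(sum(startsWith(lines, "f ")), nrow(m@faces))
  fstl <- tempfile(fileext = ".stl")
  writeMesh(m, fstl, "stl")
  expect_equal(file.size(fstl), 84 + 50 * nrow(m@faces))
})
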