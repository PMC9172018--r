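test_that("macula area matches the spherical-zone closed form", {
  map <- fxMap("emmetropic")
  macula <- sum(map@faceArea[map@region == "macula"])
  expect_equal(macula, 2 * pi * 144 * (1 - cos(20 * pi / 180)),
               tolerance = 0.02)
})

test_that("every face gets exactly one label and areas partition the mesh", {
  for (variant in eyeVariants()) {
    map <- fxMap(variant)
    mesh <- fxMesh(variant)
    expect_false(anyNA(map@region))
    expect_equal(sum(map@faceArea), sum(faceAreas(mesh)), tolerance = 1e-9)
    ra <- regionAreas(map)
    expect_equal(sum(ra$share_pct, na.rm = TRUE), 100, tolerance = 1e-9)
    expect_true(all(is.na(ra$share_pct[ra$region == "lens"])))
  }
})

test_that("hemifields are area-symmetric on the axisymmetric mesh", {
  map <- fxMap("staphyloma_cerclage")
  sup <- sum(map@faceArea[map@hemifield == "superior"])
  inf <- sum(map@faceArea[map@hemifield == "inferior"])
  expect_equal(sup, inf, tolerance = 0.02)
})

test_that("cerclage relabelling is confined to the banded variant", {
  expect_equal(sum(fxMap("emmetropic")@region == "cerclage_band"), 0)
  expect_equal(sum(fxMap("staphyloma")@region == "cerclage_band"), 0)
  mapC <- fxMap("staphyloma_cerclage")
  expect_gt(sum(mapC@region == "cerclage_band"), 0)
  # band faces sit where the indentation exceeds half its maximum:
  # |psi - 90| < (sigma * sqrt(log 2) / R) in arc terms
  mesh <- fxMesh("staphyloma_cerclage")
  psiF <- rowMeans(matrix(mesh@psi[mesh@faces], ncol = 3L))
  halfWidthDeg <- (2 * sqrt(log(2)) / 12) * 180 / pi
  expect_true(all(abs(psiF[mapC@region == "cerclage_band"] - 90) <
                    halfWidthDeg + 1e-9))

  # labels are otherwise deformation-invariant across variants
  mapE <- fxMap("emmetropic"); mapS <- fxMap("staphyloma")
  expect_identical(mapE@region, mapS@region)
  keep <- mapC@region != "cerclage_band"
  expect_identical(as.character(mapE@region[keep]),
                   as.character(mapC@region[keep]))
})

test_that("staphyloma stretches the macula and zero extent removes it", {
  aE <- sum(fxMap("emmetropic")@faceArea[fxMap("emmetropic")@region == "macula"])
  aS <- sum(fxMap("staphyloma")@faceArea[fxMap("staphyloma")@region == "macula"])
  expect_gt(aS, aE)

  p <- eyeGeometryParams(maculaExtent = 0, meshSubdivision = 3L)
  m <- buildEyeSurface(p, "emmetropic")
  expect_equal(sum(labelRegions(m)@region == "macula"), 0)
})
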