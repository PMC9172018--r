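test_that("flat interface on a pure sphere matches spherical-cap algebra", {
  sph <- fxSphere()
  map <- labelRegions(sph)
  st <- posture("standing")

  # mirror symmetry at half fill, any posture
  for (po in postureNames())
    expect_equal(overallContact(solveFlatInterface(sph, map, 0.5,
                                                   posture(po))),
                 50, tolerance = 0.2)

  # 95% fill: unwetted cap fraction x/2 with x^2 (3 - x) = 0.2
  x <- uniroot(function(x) x^2 * (3 - x) - 0.2, c(0.1, 0.5),
               tol = 1e-12)$root
  expect_equal(overallContact(solveFlatInterface(sph, map, 0.95, st)),
               100 * (1 - x / 2), tolerance = 0.5 / 86)

  # full and empty chamber
  r1 <- solveFlatInterface(sph, map, 1, st)
  expect_true(all(contactTable(r1)$contact_pct == 100))
  r0 <- solveFlatInterface(sph, map, 0, st)
  expect_true(all(contactTable(r0)$contact_pct == 0))

  expect_error(solveFlatInterface(sph, map, 1.2, st), "fill")
})

test_that("clipped oil volume honours the fill fraction", {
  mesh <- fxMesh("staphyloma")
  map <- fxMap("staphyloma")
  V <- enclosedVolume(mesh)
  for (fill in c(0.3, 0.8, 0.95)) {
    rep <- solveFlatInterface(mesh, map, fill, posture("tilt45"))
    h <- rep@meta$planeHeight
    u <- -(mesh@vertices %*% posture("tilt45")@gravityDir)[, 1]
    va <- SiOTamponade:::volumeAbovePlane(mesh, u, posture("tilt45")@gravityDir, h)
    expect_equal(va / V, fill, tolerance = 1e-5)
  }
})

test_that("flat contact report is hemifield-symmetric for supine posture", {
  mesh <- fxMesh("emmetropic"); map <- fxMap("emmetropic")
  rep <- solveFlatInterface(mesh, map, 0.85, posture("supine"))
  tab <- contactTable(rep)
  sup <- tab[tab$hemifield == "superior", ]
  inf <- tab[tab$hemifield == "inferior", ]
  m <- merge(sup, inf, by = "region")
  expect_equal(m$contact_pct.x, m$contact_pct.y, tolerance = 0.015)
})
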