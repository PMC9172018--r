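# Equilibrium solver properties. These run at 48^3/64^3; the quantitative
# study conditions are exercised in test-acceptance.R at 96^3.

test_that("zero interfacial tension reduces to the flat-interface oracle", {
  fl0 <- fluidProperties()
  for (variant in eyeVariants()) {
    mesh <- fxMesh(variant); map <- fxMap(variant)
    dom <- fixture(paste0("dom64_", variant),
                   function() voxelizeChamber(mesh, 64L))
    po <- posture("tilt45")
    ph <- minimizeCapillaryEnergy(dom, fl0, 0.85, po, opts = list(sigma = 0))
    rep <- contactFractions(ph, mesh, map, probeDepth = 1)
    flat <- solveFlatInterface(mesh, map, 0.85, po)
    # agreement within the area swept by a 2-voxel band around the contact
    # line, computed from the exact line length region by region
    lineLen <- flat@meta$lineLengthByRegion
    tabV <- contactTable(rep); tabF <- contactTable(flat)
    m <- merge(tabV, tabF, by = c("region", "hemifield"))
    for (i in seq_len(nrow(m))) {
      ll <- lineLen[[as.character(m$region[i])]]
      if (is.na(ll)) ll <- 0
      tolPct <- 100 * 2 * dom@pitch * ll / m$area_mm2.x[i] + 1
      expect_lt(abs(m$contact_pct.x[i] - m$contact_pct.y[i]), tolPct)
    }
  }
})

test_that("oil volume is conserved at every sweep", {
  mesh <- fxMesh("emmetropic"); map <- fxMap("emmetropic")
  dom <- fixture("dom64_emmetropic", function() voxelizeChamber(mesh, 64L))
  ph <- minimizeCapillaryEnergy(dom, fluidProperties(), 0.9,
                                posture("standing"))
  # film accounting: fill fraction of the film-corrected interior
  n <- dim(dom@mask)
  inner <- SiOTamponade:::shiftSum(array(as.numeric(dom@mask), dim = n)) >= 6
  target <- 0.9 * sum(inner & dom@mask) * dom@pitch^3
  expect_true(all(abs(ph@trace$oil_mm3 - target) / target < 1e-3))
  expect_equal(oilVolume(ph), target, tolerance = 1e-3)
})

test_that("a weightless non-wetting oil blob rounds toward a ball", {
  sph <- fxSphere(5L)
  dom <- fixture("dom64_sphere", function() voxelizeChamber(sph, 64L))
  fl <- fluidProperties(gravity = 1e-9)
  ph <- minimizeCapillaryEnergy(dom, fl, 0.2, posture("standing"))
  A <- interfaceArea(ph); V <- oilVolume(ph)
  expect_lt(abs(A^3 / (36 * pi * V^2) - 1), 0.15)
})

test_that("extreme fills give all-or-nothing contact", {
  mesh <- fxMesh("emmetropic"); map <- fxMap("emmetropic")
  dom <- fixture("dom48_emmetropic", function() voxelizeChamber(mesh, 48L))
  fl <- fluidProperties()
  ph1 <- minimizeCapillaryEnergy(dom, fl, 1, posture("standing"))
  rep1 <- contactFractions(ph1, mesh, map)
  expect_true(all(contactTable(rep1)$contact_pct == 100))
  expect_equal(overallContact(rep1), 100)
  ph0 <- minimizeCapillaryEnergy(dom, fl, 0, posture("standing"))
  rep0 <- contactFractions(ph0, mesh, map)
  expect_true(all(contactTable(rep0)$contact_pct == 0))
  expect_error(minimizeCapillaryEnergy(dom, fl, 1.01, posture("standing")))
})

test_that("contact is monotonically non-decreasing in fill", {
  mesh <- fxMesh("staphyloma"); map <- fxMap("staphyloma")
  for (po in postureNames()) {
    prev <- -1
    for (fill in c(0.8, 0.85, 0.9, 0.95, 1)) {
      res <- solveEquilibrium(mesh, map, fill, posture(po), resolution = 48L,
                              coarseInit = FALSE)
      ov <- overallContact(res$report)
      expect_gte(ov, prev - 1.5)   # allow voxel-scale noise
      prev <- ov
    }
  }
})

test_that("supine equilibrium is hemifield-symmetric", {
  mesh <- fxMesh("emmetropic"); map <- fxMap("emmetropic")
  res <- solveEquilibrium(mesh, map, 0.9, posture("supine"),
                          resolution = 64L)
  tab <- contactTable(res$report)
  m <- merge(tab[tab$hemifield == "superior", ],
             tab[tab$hemifield == "inferior", ], by = "region")
  expect_equal(m$contact_pct.x, m$contact_pct.y, tolerance = 0.04)
})

test_that("solver is deterministic", {
  mesh <- fxMesh("emmetropic"); map <- fxMap("emmetropic")
  dom <- fixture("dom48_emmetropic", function() voxelizeChamber(mesh, 48L))
  fl <- fluidProperties()
  ph1 <- minimizeCapillaryEnergy(dom, fl, 0.85, posture("tilt45"))
  ph2 <- minimizeCapillaryEnergy(dom, fl, 0.85, posture("tilt45"))
  expect_identical(ph1@alpha, ph2@alpha)
  expect_identical(ph1@trace, ph2@trace)
})
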