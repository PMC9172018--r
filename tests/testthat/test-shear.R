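# Reduced-order shear model: scaling behaviour and the qualitative regional
# orderings of the 90%-fill standing scenario.

shearFixture <- function(variant) {
  fixture(paste0("shear_", variant), function() {
    mesh <- fxMesh(variant); map <- fxMap(variant)
    res <- solveEquilibrium(mesh, map, 0.9, posture("standing"),
                            resolution = 48L, coarseInit = FALSE)
    list(mesh = mesh, map = map, report = res$report,
         shear = saccadeShear(mesh, map, res$report))
  })
}

test_that("fluid rotation relaxes with the closed-form exponential law", {
  fl <- fluidProperties()
  # constant omega step: Omega(t) = omega (1 - exp(-t / tau))
  traj <- data.frame(t = seq(0, 0.2, by = 1e-3), omega = 300)
  out <- relaxFluidRotation(traj, fl, R = 12, k = 10)
  tau <- 0.012^2 / (10 * (fl@viscositySiO * 1e-3 / fl@densitySiO))
  expect_equal(out$Omega_sio, 300 * (1 - exp(-out$t / tau)), tolerance = 1e-6)

  # SiO relaxes at least 100x faster than aqueous (ratio of nu values)
  nuS <- fl@viscositySiO * 1e-3 / fl@densitySiO
  nuA <- fl@viscosityAqueous * 1e-3 / fl@densityAqueous
  expect_gte(nuS / nuA, 100)
  iS <- which(out$Omega_sio > 0.95 * 300)[1]
  expect_true(is.na(which(out$Omega_aq > 0.95 * 300)[1]) ||
                which(out$Omega_aq > 0.95 * 300)[1] > 100 * iS)

  # no rotation, no lag
  still <- relaxFluidRotation(data.frame(t = seq(0, 0.1, 1e-3), omega = 0),
                              fl, R = 12)
  expect_true(all(still$Omega_sio == 0) && all(still$Omega_aq == 0))
})

test_that("shear field scales with viscosity, arm length, and slip", {
  fx <- shearFixture("emmetropic")
  traj <- fx$shear$traj
  field <- fx$shear$field
  expect_true(all(field$tau >= 0))
  # faces on the rotation axis carry no shear
  ctr <- faceCentroids(fx$mesh)
  rp <- sqrt(ctr[, 1]^2 + ctr[, 3]^2)
  nearAxis <- which(rp < 0.5)
  if (length(nearAxis))
    expect_lt(max(field$tau[nearAxis, ]), 1e-3 * max(field$tau))
  # emmetropic geometry factor is 1 everywhere: tau proportional to r_perp
  # within one phase at fixed time
  sio <- which(field$phase == "sio")
  it <- which.max(traj$omega)
  ratio <- field$tau[sio, it] / rp[sio]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)

  # doubling viscosity at fixed kinematics and Stokes depth doubles tau:
  # double mu and rho together so nu (hence delta and the lag) is unchanged
  fl2 <- fluidProperties(viscosityAqueous = 2, densityAqueous = 2 * 997)
  traj2 <- relaxFluidRotation(saccadeTrajectory(), fl2,
                              R = fx$mesh@params@sphereRadius)
  f2 <- wallShearField(fx$mesh, fx$map, fx$report@faceWetted, traj2, fl2)
  aq <- which(field$phase == "aqueous")
  expect_equal(f2$tau[aq, ], 2 * field$tau[aq, ], tolerance = 1e-9)

  # zero rotation gives an identically zero field
  trajStill <- relaxFluidRotation(
    data.frame(t = seq(0, 0.274, 1e-3), omega = 0), fluidProperties(), R = 12)
  f0 <- wallShearField(fx$mesh, fx$map, fx$report@faceWetted, trajStill,
                       fluidProperties())
  expect_equal(max(f0$tau), 0)
})

test_that("regional aggregates are consistent with their series", {
  fx <- shearFixture("emmetropic")
  sm <- fx$shear$summary
  for (i in seq_len(nrow(sm$aggregate))) {
    row <- sm$aggregate[i, ]
    ser <- sm$series[sm$series$region == row$region &
                       sm$series$hemifield == row$hemifield &
                       sm$series$phase == row$phase, ]
    expect_equal(row$tau_max_Pa, max(ser$tau_Pa[ser$stat == "max"]))
    expect_gte(row$tau_max_Pa, max(ser$tau_Pa[ser$stat == "avg"]) - 1e-12)
    expect_equal(row$tau_mean_Pa, mean(ser$tau_Pa[ser$stat == "avg"]))
  }
})

test_that("geometry shifts shear as in the reference orderings", {
  fxE <- shearFixture("emmetropic")
  fxS <- shearFixture("staphyloma")
  fxC <- shearFixture("staphyloma_cerclage")
  aggOf <- function(fx) {
    a <- fx$shear$summary$aggregate
    a[a$phase == "sio", ]
  }
  aE <- aggOf(fxE); aS <- aggOf(fxS); aC <- aggOf(fxC)
  # regional means pool phases: a region whose wall ends up aqueous-covered
  # is sheltered by the low-viscosity phase itself
  meanTau <- function(fx, region) {
    a <- fx$shear$summary$aggregate
    sel <- a$region == region
    if (!any(sel)) return(NA_real_)
    mean(a$tau_mean_Pa[sel])
  }
  # staphyloma shelters the macula
  expect_lt(meanTau(fxS, "macula"), meanTau(fxE, "macula"))
  # the band indentation hosts the global maximum in the cerclage variant
  expect_equal(aC$region[which.max(aC$tau_max_Pa)], "cerclage_band")
  # and lowers pre-equatorial stress relative to the unbanded staphyloma
  expect_lt(meanTau(fxC, "pre_equatorial"), meanTau(fxS, "pre_equatorial"))
})
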