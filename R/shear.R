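# Reduced-order wall shear stress during a saccade.
#
# The full moving-mesh two-phase solve is replaced by an explicit
# reduced-order surrogate that keeps the scaling drivers of wall shear:
# viscosity of the wetting phase, slip velocity between eye wall and bulk
# fluid (rigid-lag relaxation), moment arm from the rotation axis, a
# Stokes-layer depth that grows as sqrt(nu t), and a local geometry factor
# (sheltered staphyloma pocket, exposed cerclage ridge). Outputs are
# qualitative regional orderings, never absolute magnitudes; every summary
# is labelled "reduced_order".

#' Rigid-lag relaxation of the fluid rotation
#'
#' Solves dOmega/dt = (omega(t) - Omega) / tau_r with Omega(0) = 0 for each
#' phase, where tau_r = R^2 / (k nu) and nu is the kinematic viscosity of
#' the phase. Integrated exactly over each sampling step treating omega as
#' constant at its midpoint value (exponential integrator; exact for a step
#' input).
#'
#' @param traj trajectory from [saccadeTrajectory()] (sampled at <= 1 ms).
#' @param fluids a [FluidProperties-class].
#' @param R chamber radius in mm.
#' @param k calibration constant of the relaxation time (default 10).
#' @return the trajectory with added columns `Omega_sio`, `Omega_aq`
#'   (deg/s).
#' @export
relaxFluidRotation <- function(traj, fluids, R = 12, k = 10) {
  if (nrow(traj) < 2L) stop("trajectory must be sampled")
  dt <- diff(traj$t)
  if (max(dt) > 1e-3 + 1e-12) stop("trajectory must be sampled at <= 1 ms")
  Rm <- R * 1e-3
  nu <- kinematicViscosities(fluids)      # m^2/s, named sio / aq
  relax <- function(nuPhase) {
    tau <- Rm^2 / (k * nuPhase)
    Om <- numeric(nrow(traj))
    for (i in seq_along(dt)) {
      wMid <- (traj$omega[i] + traj$omega[i + 1L]) / 2
      Om[i + 1L] <- wMid + (Om[i] - wMid) * exp(-dt[i] / tau)
    }
    Om
  }
  traj$Omega_sio <- relax(nu[["sio"]])
  traj$Omega_aq <- relax(nu[["aq"]])
  traj
}

kinematicViscosities <- function(fluids) {
  c(sio = fluids@viscositySiO * 1e-3 / fluids@densitySiO,
    aq  = fluids@viscosityAqueous * 1e-3 / fluids@densityAqueous)
}

#' Per-face wall shear stress during the saccade
#'
#' For each face and time,
#' `tau = mu_phase * |omega - Omega_phase| * r_perp / delta * f_geo`,
#' where `r_perp` is the centroid distance from the rotation axis (+y),
#' `delta(t) = min(sqrt(nu max(t, t_min)), R)` is the Stokes-layer depth of
#' the face's wetting phase, and
#' `f_geo = exp(-d_pocket / delta) * (1 + p_ridge / delta)` encodes the
#' sheltering of the staphyloma recess (`d_pocket`, radial displacement
#' beyond the reference sphere) and the exposure of the cerclage ridge
#' (`p_ridge`, indentation into the flow). Faces wetted by SiO at the static
#' equilibrium use the oil properties, the rest the aqueous ones.
#'
#' @param mesh an [EyeMesh-class].
#' @param map the matching [RegionMap-class].
#' @param wetted per-face SiO-wetted indicator (e.g. the `faceWetted` slot
#'   of the 90\%-fill standing [ContactReport-class]).
#' @param traj output of [relaxFluidRotation()].
#' @param fluids a [FluidProperties-class].
#' @param tmin floor of the Stokes-layer time (s).
#' @return list with `tau` (faces x times matrix, Pa), `phase` (per-face
#'   "sio"/"aqueous"), `t` (times).
#' @export
wallShearField <- function(mesh, map, wetted, traj, fluids, tmin = 1e-3) {
  if (!all(c("Omega_sio", "Omega_aq") %in% names(traj)))
    stop("trajectory lacks relaxed fluid rotation; run relaxFluidRotation()")
  ctr <- faceCentroids(mesh)
  rperp <- sqrt(ctr[, 1]^2 + ctr[, 3]^2) * 1e-3       # m, axis is +y
  vr <- sqrt(rowSums(mesh@vertices^2))
  disp <- vr - mesh@restRadius                        # mm, + outward
  dispF <- rowMeans(matrix(disp[mesh@faces], ncol = 3L))
  # outward displacement (staphyloma) is a sheltered recess. Inward
  # displacement splits at half the maximum indent: the band crest
  # protrudes into the relative flow (exposed ridge), while its flanks sit
  # in the groove between crest and sphere and are sheltered like a pocket.
  indent <- pmax(0, -dispF)
  crest <- indent > max(indent) / 2 & indent > 0
  dPocket <- (pmax(0, dispF) + ifelse(crest, 0, indent)) * 1e-3   # m
  pRidge <- ifelse(crest, indent, 0) * 1e-3                       # m

  Rm <- mesh@params@sphereRadius * 1e-3
  nu <- kinematicViscosities(fluids)
  mu <- c(sio = fluids@viscositySiO * 1e-3,
          aq = fluids@viscosityAqueous * 1e-3)        # Pa s
  phase <- ifelse(wetted >= 0.5, "sio", "aqueous")
  key <- ifelse(phase == "sio", "sio", "aq")

  tEff <- pmax(traj$t, tmin)
  deg2rad <- pi / 180
  tau <- matrix(0, nrow(mesh@faces), nrow(traj))
  for (ph in c("sio", "aq")) {
    sel <- key == ph
    if (!any(sel)) next
    delta <- pmin(sqrt(nu[[ph]] * tEff), Rm)          # m
    slip <- abs(traj$omega - traj[[paste0("Omega_", ph)]]) * deg2rad  # rad/s
    base <- outer(mu[[ph]] * rperp[sel], slip / delta)
    fgeo <- exp(-outer(dPocket[sel], 1 / delta)) *
      (1 + outer(pRidge[sel], 1 / delta))
    tau[sel, ] <- base * fgeo
  }
  list(tau = tau, phase = phase, t = traj$t)
}

#' Regional shear summary
#'
#' Instantaneous maximum and area-averaged shear per (region, hemifield,
#' phase) at every sample time, plus the time-aggregated maxima and
#' time-averaged means. Regions with no face wetted by SiO appear only under
#' the aqueous phase.
#'
#' @param field output of [wallShearField()].
#' @param map the [RegionMap-class].
#' @return list with `series` (long data.frame: t, region, hemifield, phase,
#'   stat in max/avg, tau_Pa) and `aggregate` (region, hemifield, phase,
#'   tau_max_Pa, tau_mean_Pa), both labelled `model = "reduced_order"`.
#' @export
shearSummary <- function(field, map) {
  A <- map@faceArea
  groups <- split(seq_along(A),
                  list(region = map@region, hemifield = map@hemifield,
                       phase = factor(field$phase, c("sio", "aqueous"))),
                  drop = TRUE)
  series <- list(); agg <- list()
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    parts <- strsplit(gname, ".", fixed = TRUE)[[1]]
    sub <- field$tau[idx, , drop = FALSE]
    w <- A[idx] / sum(A[idx])
    mx <- apply(sub, 2, max)
    av <- as.numeric(w %*% sub)
    series[[gname]] <- data.frame(
      t = rep(field$t, 2L), region = parts[1], hemifield = parts[2],
      phase = parts[3], stat = rep(c("max", "avg"), each = length(field$t)),
      tau_Pa = c(mx, av), stringsAsFactors = FALSE)
    agg[[gname]] <- data.frame(
      region = parts[1], hemifield = parts[2], phase = parts[3],
      tau_max_Pa = max(mx), tau_mean_Pa = mean(av), stringsAsFactors = FALSE)
  }
  series <- do.call(rbind, c(series, list(make.row.names = FALSE)))
  agg <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  series$model <- "reduced_order"; agg$model <- "reduced_order"
  list(series = series, aggregate = agg)
}

#' End-to-end saccadic shear analysis
#'
#' Orchestrates the shear scenario: saccade trajectory, rigid-lag fluid
#' rotation, per-face shear field using the wetted mask of a static
#' equilibrium report (the reference scenario is a standing patient at 90\%
#' fill), and the regional summary.
#'
#' @param mesh,map geometry and labels.
#' @param report [ContactReport-class] providing the SiO-wetted mask.
#' @param fluids a [FluidProperties-class].
#' @param saccade a [SaccadeParams-class].
#' @param dt sampling step (s).
#' @param k rigid-lag calibration constant.
#' @param tmin Stokes-layer time floor (s).
#' @return list with `summary` (see [shearSummary()]), `field`, `traj`.
#' @export
saccadeShear <- function(mesh, map, report, fluids = fluidProperties(),
                         saccade = fitSaccade(), dt = 1e-3, k = 10,
                         tmin = 1e-3) {
  traj <- relaxFluidRotation(saccadeTrajectory(saccade, dt), fluids,
                             R = mesh@params@sphereRadius, k = k)
  field <- wallShearField(mesh, map, report@faceWetted, traj, fluids, tmin)
  list(summary = shearSummary(field, map), field = field, traj = traj)
}
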