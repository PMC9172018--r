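# Static capillary equilibrium by volume-conserving threshold dynamics.
#
# The equilibrium oil configuration minimises
#   E[alpha] = sigma * Area(oil-aqueous interface)
#            + sigma * cos(theta_w) * Area(oil-wetted wall)
#            - (rho_aq - rho_sio) * g * integral_oil height dV
# under the oil-volume constraint (theta_w is the contact angle measured
# through the aqueous; with the opposite convention the wall term flips to
# -sigma*cos(theta_oil)*A_wet, handled via the ghost value below).
#
# Each sweep convolves the oil indicator with a Gaussian (walls contribute a
# fixed ghost value encoding the contact angle), adds a buoyancy bias
# proportional to height / capillary length^2, and rethresholds at the level
# that conserves the oil volume exactly. The fixed point of this iteration
# satisfies the Young-Laplace balance kappa + height/l_c^2 = const with the
# prescribed wall angle. Fixed iteration order makes the solver fully
# deterministic (no RNG anywhere).
#
# Wall model. The measured static oil-water-retina angle (16.2 deg through
# the aqueous) makes the retina almost completely aqueous-wet: a thin
# aqueous film separates the buoyant oil bubble from the wall wherever the
# bubble is not pressing, and the oil reaches the wall only where it
# squeezes that film out. The default "film" wall mode represents this with
# a one-voxel aqueous shell on the wall, imposed as a soft ranking penalty
# so that at high fills (or strong pressing) the oil can still claim shell
# voxels in order of decreasing pressure; contact is then read just beyond
# the shell. This near-wall treatment mirrors the unresolved
# "few-microns-thick" aqueous layer acknowledged in CFD treatments of tamponades and
# converges to the sharp-interface non-wetting statics as the grid refines.
#
# Pinning. Plain two-phase threshold dynamics freezes ("pins") once the
# per-sweep interface motion falls below one voxel. The solver therefore
# anneals the kernel width over stages (wide kernels move the interface
# fast, narrow kernels sharpen the frozen state); each stage runs until its
# displacement criterion is met, which doubles as the convergence test.

#' Minimise the capillary energy of the oil phase
#'
#' Volume-conserving threshold dynamics on the voxelised chamber. Initialised
#' from the flat-interface configuration unless `init` is given. Iterates
#' until the mean interface displacement over a 10-sweep window drops below
#' `dispTol` voxels, or `maxSweeps` is reached (in which case the best state
#' is returned flagged non-converged, with a warning).
#'
#' @param domain a [PhaseField-class] from [voxelizeChamber()].
#' @param fluids a [FluidProperties-class].
#' @param fill oil fill fraction in [0, 1].
#' @param posture a [Posture-class].
#' @param opts list of solver options: `kernelSd` (Gaussian standard
#'   deviations in voxels for the annealing stages, widest first; default
#'   `c(4, 2.5, 1.5)`), `maxSweeps` (total across stages, default 2000),
#'   `dispTol` (voxels of interface displacement per 10-sweep window,
#'   default 0.25), `wall` ("film" enforces the one-voxel aqueous wetting
#'   shell, the default; "angle" uses the ghost-value contact-angle wall
#'   with no shell; "neutral" imposes 90 degrees; "nonwetting" a ghost-dry
#'   wall), `shellPenalty` (ranking penalty of shell voxels in film mode,
#'   default 0.3), `sigma` (override the interfacial tension, e.g. 0 for
#'   the gravity-only limit).
#' @param init optional initial oil indicator (array matching the domain).
#' @return a [PhaseField-class] carrying the equilibrated `alpha`.
#' @export
minimizeCapillaryEnergy <- function(domain, fluids, fill, posture,
                                    opts = list(), init = NULL) {
  if (!is.numeric(fill) || length(fill) != 1L || fill < 0 || fill > 1)
    stop("fill must be a single number in [0, 1]")
  o <- modifyList(list(kernelSd = c(4, 2.5, 1.5), maxSweeps = 2000L,
                       dispTol = 0.25, window = 10L, wall = "film",
                       shellPenalty = 0.3, sigma = NULL), opts)
  sigma <- if (is.null(o$sigma)) fluids@interfacialTension else o$sigma

  mask <- domain@mask
  n <- dim(mask)
  nDom <- sum(mask)
  u <- heightField(domain, posture@gravityDir)     # mm, + is up
  uDom <- u[mask]

  # Film wall mode: the one-voxel aqueous shell stands for a physically
  # negligible (micron-scale) wetting film, so its voxels must not be
  # charged against the aqueous volume budget: the oil fraction is taken of
  # the film-corrected interior. Shell volume vanishes on refinement, so
  # both accountings agree in the limit.
  filmMode <- identical(o$wall, "film") && sigma > 0
  interior <- if (filmMode)
    shiftSum(array(as.numeric(mask), dim = n))[mask] >= 6
  else rep(TRUE, nDom)
  nOil <- as.integer(round(fill * sum(interior)))

  # flat initial condition: the nOil highest (interior) voxels
  alphaDom <- numeric(nDom)
  alphaDom[interior] <- if (is.null(init)) {
    topKIndicator(uDom[interior], nOil)
  } else {
    a0 <- as.numeric(init[mask])[interior]
    ui <- uDom[interior]
    topKIndicator(a0 + 1e-7 * (ui - min(ui)) / max(1e-12, diff(range(ui))),
                  nOil)
  }

  if (sigma <= 0) {
    # gravity-only limit: the flat ranking IS the minimiser
    ph <- domain
    alpha <- array(0, dim = n); alpha[mask] <- alphaDom
    ph@alpha <- alpha; ph@fill <- fill; ph@posture <- posture@name
    ph@converged <- TRUE; ph@sweeps <- 0L
    ph@trace <- data.frame(sweep = integer(), stage = numeric(),
                           flips = integer(), oil_mm3 = numeric())
    return(ph)
  }

  # wall ghost value: (1 + cos(theta_oil)) / 2 reproduces Young's angle,
  # where theta_oil is measured through the oil; in film mode the wall sits
  # behind the aqueous shell and acts aqueous-like
  thetaOil <- if (fluids@angleThrough == "oil") fluids@contactAngleStatic
              else 180 - fluids@contactAngleStatic
  ghost <- switch(o$wall,
                  film       = 0,
                  angle      = (1 + cos(thetaOil * pi / 180)) / 2,
                  neutral    = 0.5,
                  nonwetting = 0,
                  stop("unknown wall option"))
  shellPen <- if (o$wall == "film") {
    inner <- shiftSum(array(as.numeric(mask), dim = n))[mask] >= 6
    ifelse(inner, 0, o$shellPenalty)
  } else 0

  drho <- fluids@densityAqueous - fluids@densitySiO
  lc2 <- sigma / (drho * fluids@gravity) * 1e6     # capillary length^2, mm^2

  flips <- integer(0); oilTrace <- numeric(0); stageTrace <- numeric(0)
  converged <- FALSE
  sweep <- 0L
  voxPerSweep <- Inf
  stages <- sort(o$kernelSd, decreasing = TRUE)
  for (sVox in stages) {
    sMm <- sVox * domain@pitch
    r <- as.integer(ceiling(3.5 * sVox))
    kern <- stats::dnorm(seq(-r, r), sd = sVox)
    kern <- kern / sum(kern)
    biasCoef <- sMm / (2 * sqrt(2 * pi)) / lc2     # per mm of height
    bias <- (biasCoef * u)[mask] - shellPen

    np <- n + 2L * r
    Apad <- array(ghost, dim = np)
    coreIdx <- maskPadIndex(mask, r)

    stageDone <- FALSE
    stageSweeps <- 0L
    while (sweep < o$maxSweeps && !stageDone) {
      sweep <- sweep + 1L; stageSweeps <- stageSweeps + 1L
      Apad[coreIdx] <- alphaDom
      phi <- convSep3(Apad, kern, n)[mask] + bias
      newDom <- topKIndicator(phi, nOil)
      fl <- sum(newDom != alphaDom)
      flips <- c(flips, fl)
      stageTrace <- c(stageTrace, sVox)
      oilTrace <- c(oilTrace, sum(newDom) * domain@pitch^3)
      alphaDom <- newDom
      if (fl == 0L) stageDone <- TRUE            # pinned: stage fixed point
      else if (stageSweeps %% o$window == 0L) {
        nb <- boundaryVoxelCount(mask, alphaDom)
        # displacement accumulated over the window, in voxel units
        voxPerSweep <- sum(utils::tail(flips, o$window)) / max(1L, nb)
        if (voxPerSweep < o$dispTol) stageDone <- TRUE
      }
    }
    if (!stageDone) break
  }
  converged <- sweep < o$maxSweeps || stageDone
  if (!converged)
    warning(sprintf(
      "threshold dynamics not converged after %d sweeps (%.3f voxel/sweep)",
      sweep, voxPerSweep))

  alpha <- array(0, dim = n); alpha[mask] <- alphaDom
  ph <- domain
  ph@alpha <- alpha; ph@fill <- fill; ph@posture <- posture@name
  ph@converged <- converged; ph@sweeps <- sweep
  ph@trace <- data.frame(sweep = seq_along(flips), stage = stageTrace,
                         flips = flips, oil_mm3 = oilTrace)
  ph
}

# Exact-count indicator of the k largest values, deterministic tie-break by
# index order.
topKIndicator <- function(x, k) {
  m <- length(x)
  out <- numeric(m)
  if (k <= 0L) return(out)
  if (k >= m) return(out + 1)
  q <- m - k + 1L
  thr <- sort(x, partial = q)[q]
  hi <- which(x > thr)
  need <- k - length(hi)
  if (need > 0L) hi <- c(hi, which(x == thr)[seq_len(need)])
  out[hi] <- 1
  out
}

# Separable Gaussian convolution of a padded array; returns the n^3 core.
convSep3 <- function(Apad, kern, n) {
  r <- (length(kern) - 1L) %/% 2L
  A <- Apad
  for (axis in 1:3) {
    d <- dim(A)
    m <- d[1] - 2L * r                       # output length along this axis
    K <- matrix(0, m, d[1])
    for (i in seq_len(m)) K[i, i:(i + 2L * r)] <- kern
    A <- K %*% matrix(A, d[1])
    dim(A) <- c(m, d[2], d[3])
    A <- aperm(A, c(2, 3, 1))
  }
  A
}

# linear indices (into the padded array) of the domain voxels
maskPadIndex <- function(mask, r) {
  n <- dim(mask)
  np <- n + 2L * r
  w <- which(mask) - 1L
  i <- w %% n[1]; rest <- w %/% n[1]
  j <- rest %% n[2]; k <- rest %/% n[2]
  (i + r) + np[1] * ((j + r) + np[2] * (k + r)) + 1L
}

# oil voxels with at least one aqueous 6-neighbour inside the domain
boundaryVoxelCount <- function(mask, alphaDom) {
  a <- array(0, dim = dim(mask)); a[mask] <- alphaDom
  nb <- shiftSum(a)
  full <- shiftSum(array(as.numeric(mask), dim = dim(mask)))
  sum(a[mask] == 1 & (nb[mask] < full[mask]))
}

shiftSum <- function(a) {
  n <- dim(a)
  s <- array(0, dim = n)
  s[-1, , ] <- s[-1, , ] + a[-n[1], , ]
  s[-n[1], , ] <- s[-n[1], , ] + a[-1, , ]
  s[, -1, ] <- s[, -1, ] + a[, -n[2], ]
  s[, -n[2], ] <- s[, -n[2], ] + a[, -1, ]
  s[, , -1] <- s[, , -1] + a[, , -n[3]]
  s[, , -n[3]] <- s[, , -n[3]] + a[, , -1]
  s
}

#' Oil-aqueous interface area of a phase field
#'
#' Integral of the gradient magnitude of the Gaussian-smoothed oil
#' indicator, a standard coarea estimator of the interface area. Used by the
#' property tests (isoperimetric check) and for energy diagnostics.
#'
#' @param phase a [PhaseField-class].
#' @param smoothSd smoothing standard deviation in voxels.
#' @return area in mm^2.
#' @export
interfaceArea <- function(phase, smoothSd = 1.5) {
  n <- dim(phase@alpha)
  r <- as.integer(ceiling(3.5 * smoothSd))
  kern <- stats::dnorm(seq(-r, r), sd = smoothSd)
  kern <- kern / sum(kern)
  np <- n + 2L * r
  # pad with the nearest alpha value so the wall does not register as
  # oil-aqueous interface: replicate edge by clamping is enough here because
  # probing happens inside the domain
  Apad <- array(0, dim = np)
  Apad[(r + 1L):(r + n[1]), (r + 1L):(r + n[2]), (r + 1L):(r + n[3])] <-
    phase@alpha
  sm <- convSep3(Apad, kern, n)
  gx <- array(0, dim = n); gy <- array(0, dim = n); gz <- array(0, dim = n)
  gx[2:(n[1] - 1), , ] <- (sm[3:n[1], , ] - sm[1:(n[1] - 2), , ]) / 2
  gy[, 2:(n[2] - 1), ] <- (sm[, 3:n[2], ] - sm[, 1:(n[2] - 2), ]) / 2
  gz[, , 2:(n[3] - 1)] <- (sm[, , 3:n[3]] - sm[, , 1:(n[3] - 2)]) / 2
  g <- sqrt(gx^2 + gy^2 + gz^2)
  # count only gradient mass near the fluid-fluid interface (inside domain)
  sum(g[phase@mask]) * phase@pitch^2
}

#' Per-region contact fractions from an equilibrated phase field
#'
#' A face counts as SiO-wetted iff the trilinearly interpolated oil fraction
#' at `centroid - depth * outward normal` is at least 0.5 (ties wet). With
#' the film wall model the probe must look past the one-voxel aqueous shell
#' and ask whether the bubble presses against it: the default probe depth is
#' `pitch + probeGap`, where `probeGap` (mm) is the physical gap-collapse
#' threshold -- an aqueous layer thinner than this counts as squeezed out at
#' the wall. Keeping `probeGap` fixed in physical units makes the reported
#' percentages consistent across grid resolutions (a voxel-scaled probe
#' would shrink the detection gap on refinement). For the shell-free wall
#' modes pass `probeDepth = 1` to place the probe immediately inside the
#' wall.
#'
#' @param phase an equilibrated [PhaseField-class].
#' @param mesh the [EyeMesh-class] the field was voxelised from.
#' @param map the matching [RegionMap-class].
#' @param probeDepth probe depth in voxel pitches; overrides `probeGap`.
#' @param probeGap physical gap-collapse threshold in mm (default 0.5).
#' @param meta extra provenance merged into the report.
#' @return a [ContactReport-class].
#' @export
contactFractions <- function(phase, mesh, map, probeDepth = NULL,
                             probeGap = 0.5, meta = list()) {
  depth <- if (!is.null(probeDepth)) probeDepth * phase@pitch
           else phase@pitch + probeGap
  probes <- faceCentroids(mesh) - depth * faceNormals(mesh)
  aext <- fillExterior(phase@alpha, phase@mask, passes = 4L)
  val <- trilinear(aext, phase@origin, phase@pitch, probes)
  wetted <- as.numeric(val >= 0.5)
  meta <- modifyList(list(method = "threshold_dynamics",
                          resolution = dim(phase@alpha)[1],
                          sweeps = phase@sweeps,
                          converged = phase@converged,
                          probe_mm = depth), meta)
  buildContactReport(mesh, map, wetted, phase@fill, phase@posture, meta)
}

# Nearest-inside extension of alpha: exterior voxels take the mean of their
# already-valued 6-neighbours, a few passes outward.
fillExterior <- function(alpha, mask, passes = 4L) {
  a <- alpha
  known <- mask
  for (p in seq_len(passes)) {
    av <- a; av[!known] <- 0
    s <- shiftSum(av)
    cnt <- shiftSum(array(as.numeric(known), dim = dim(mask)))
    newly <- !known & cnt > 0
    if (!any(newly)) break
    a[newly] <- s[newly] / cnt[newly]
    known <- known | newly
  }
  a
}

trilinear <- function(a, origin, pitch, pts) {
  n <- dim(a)
  gx <- (pts[, 1] - origin[1]) / pitch + 1
  gy <- (pts[, 2] - origin[2]) / pitch + 1
  gz <- (pts[, 3] - origin[3]) / pitch + 1
  clamp <- function(v, m) pmin(pmax(v, 1), m - 1e-9)
  gx <- clamp(gx, n[1]); gy <- clamp(gy, n[2]); gz <- clamp(gz, n[3])
  i0 <- pmin(floor(gx), n[1] - 1); j0 <- pmin(floor(gy), n[2] - 1)
  k0 <- pmin(floor(gz), n[3] - 1)
  fx <- gx - i0; fy <- gy - j0; fz <- gz - k0
  at <- function(di, dj, dk) a[cbind(i0 + di, j0 + dj, k0 + dk)]
  v000 <- at(0, 0, 0); v100 <- at(1, 0, 0)
  v010 <- at(0, 1, 0); v110 <- at(1, 1, 0)
  v001 <- at(0, 0, 1); v101 <- at(1, 0, 1)
  v011 <- at(0, 1, 1); v111 <- at(1, 1, 1)
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}

#' One-call equilibrium solve for a (mesh, posture, fill) case
#'
#' Convenience orchestrator: voxelises the chamber, runs the threshold
#' dynamics (optionally warm-started from a half-resolution solve, which
#' cuts the fine-grid sweep count substantially), and reports contact
#' fractions.
#'
#' @param mesh an [EyeMesh-class].
#' @param map the matching [RegionMap-class].
#' @param fill oil fill fraction in [0, 1].
#' @param posture a [Posture-class].
#' @param fluids a [FluidProperties-class].
#' @param resolution fine-grid voxels per axis.
#' @param coarseInit warm start from a half-resolution solve (default TRUE).
#' @param opts solver options, see [minimizeCapillaryEnergy()].
#' @param domains optional precomputed list of domains (`fine`, `coarse`)
#'   to amortise voxelisation across fills/postures.
#' @return list with elements `report` ([ContactReport-class]) and `phase`
#'   ([PhaseField-class]).
#' @export
solveEquilibrium <- function(mesh, map, fill, posture,
                             fluids = fluidProperties(), resolution = 64L,
                             coarseInit = TRUE, opts = list(),
                             domains = NULL) {
  fine <- if (!is.null(domains$fine)) domains$fine
          else voxelizeChamber(mesh, resolution)
  init <- NULL
  if (coarseInit && resolution >= 48L) {
    coarse <- if (!is.null(domains$coarse)) domains$coarse
              else voxelizeChamber(mesh, max(24L, as.integer(resolution / 2)))
    phC <- minimizeCapillaryEnergy(coarse, fluids, fill, posture, opts)
    ax <- gridAxes(fine)
    n <- dim(fine@mask)
    pts <- cbind(rep(ax$x, times = n[2] * n[3]),
                 rep(rep(ax$y, each = n[1]), times = n[3]),
                 rep(ax$z, each = n[1] * n[2]))
    aC <- fillExterior(phC@alpha, phC@mask, passes = 4L)
    init <- array(trilinear(aC, phC@origin, phC@pitch, pts), dim = n)
  }
  phase <- minimizeCapillaryEnergy(fine, fluids, fill, posture, opts,
                                   init = init)
  wallMode <- if (is.null(opts$wall)) "film" else opts$wall
  report <- if (wallMode == "film") contactFractions(phase, mesh, map)
            else contactFractions(phase, mesh, map, probeDepth = 1)
  list(report = report, phase = phase)
}
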