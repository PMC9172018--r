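#' @import methods
#' @importFrom utils modifyList head tail
#' @importFrom stats dnorm aggregate reshape
NULL

#' Parametric vitreous-chamber geometry parameters
#'
#' Holds the dimensions that define the idealised vitreous chamber: a sphere
#' (default diameter 24 mm) truncated anteriorly by a planar lens cap, with
#' optional posterior staphyloma outpouching and an encircling-band
#' (cerclage) equatorial indentation. All lengths are millimetres, all angles
#' degrees. The polar angle psi is measured from the anterior pole (the
#' optical axis is +z, anatomical superior is +y, origin at the centre of the
#' undeformed sphere).
#'
#' @slot sphereRadius radius of the undeformed globe (mm).
#' @slot lensCapHeight height of the spherical cap removed by the planar lens
#'   indentation (mm); 0 gives a full sphere.
#' @slot staphylomaDepth radial displacement of the posterior pole in the
#'   staphyloma variants (mm).
#' @slot staphylomaOnset polar angle (deg from anterior pole) where the
#'   staphyloma outpouching begins.
#' @slot cerclageDepth maximum inward indentation of the encircling band (mm).
#' @slot cerclageWidth meridional full width of the band indentation (mm);
#'   the Gaussian profile uses sigma = width / 2.
#' @slot parsPlanaBoundary polar angle separating pars plana from
#'   pre-equatorial retina (deg).
#' @slot maculaExtent angular radius of the macula about the posterior pole
#'   (deg).
#' @slot meshSubdivision integer refinement level; azimuthal resolution is
#'   3 * 2^meshSubdivision vertices per ring.
#' @export
setClass("EyeGeometryParams",
  representation(
    sphereRadius      = "numeric",
    lensCapHeight     = "numeric",
    staphylomaDepth   = "numeric",
    staphylomaOnset   = "numeric",
    cerclageDepth     = "numeric",
    cerclageWidth     = "numeric",
    parsPlanaBoundary = "numeric",
    maculaExtent      = "numeric",
    meshSubdivision   = "integer"
  )
)

setValidity("EyeGeometryParams", function(object) {
  msgs <- character()
  num1 <- function(x) length(x) == 1L && is.finite(x)
  if (!num1(object@sphereRadius) || object@sphereRadius <= 0)
    msgs <- c(msgs, "sphereRadius must be a single positive number")
  if (!num1(object@lensCapHeight) || object@lensCapHeight < 0)
    msgs <- c(msgs, "lensCapHeight must be >= 0")
  if (num1(object@lensCapHeight) && num1(object@sphereRadius) &&
      object@lensCapHeight >= object@sphereRadius)
    msgs <- c(msgs, "lensCapHeight must be smaller than sphereRadius")
  if (!num1(object@staphylomaDepth) || object@staphylomaDepth < 0)
    msgs <- c(msgs, "staphylomaDepth must be >= 0")
  if (!num1(object@staphylomaOnset) ||
      object@staphylomaOnset <= 90 || object@staphylomaOnset >= 180)
    msgs <- c(msgs, "staphylomaOnset must lie in (90, 180) degrees")
  if (!num1(object@cerclageDepth) || object@cerclageDepth < 0)
    msgs <- c(msgs, "cerclageDepth must be >= 0")
  if (!num1(object@cerclageWidth) || object@cerclageWidth <= 0)
    msgs <- c(msgs, "cerclageWidth must be > 0")
  # the band (equator +/- 3 sigma along the meridian) must stay anterior to
  # the staphyloma onset so the two deformations never overlap
  if (num1(object@cerclageWidth) && num1(object@staphylomaOnset)) {
    halfAngle <- 3 * (object@cerclageWidth / 2) / object@sphereRadius * 180 / pi
    if (90 + halfAngle > object@staphylomaOnset)
      msgs <- c(msgs, "cerclage band overlaps the staphyloma onset angle")
  }
  if (!num1(object@parsPlanaBoundary) ||
      object@parsPlanaBoundary <= 0 || object@parsPlanaBoundary >= 90)
    msgs <- c(msgs, "parsPlanaBoundary must lie in (0, 90) degrees")
  if (!num1(object@maculaExtent) ||
      object@maculaExtent < 0 || object@maculaExtent >= 90)
    msgs <- c(msgs, "maculaExtent must lie in [0, 90) degrees")
  if (length(object@meshSubdivision) != 1L || object@meshSubdivision < 2L)
    msgs <- c(msgs, "meshSubdivision must be an integer >= 2")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn EyeGeometryParams-class constructor with the package defaults
#'   (24 mm globe, 3 mm lens cap, 3.5 mm staphyloma from 140 deg, 1.5 mm x
#'   4 mm band).
#' @param sphereRadius,lensCapHeight,staphylomaDepth,staphylomaOnset,cerclageDepth,cerclageWidth,parsPlanaBoundary,maculaExtent,meshSubdivision see slots.
#' @export
eyeGeometryParams <- function(sphereRadius = 12, lensCapHeight = 3,
                              staphylomaDepth = 3.5, staphylomaOnset = 140,
                              cerclageDepth = 1.5, cerclageWidth = 4,
                              parsPlanaBoundary = 60, maculaExtent = 20,
                              meshSubdivision = 5L) {
  new("EyeGeometryParams",
      sphereRadius = sphereRadius, lensCapHeight = lensCapHeight,
      staphylomaDepth = staphylomaDepth, staphylomaOnset = staphylomaOnset,
      cerclageDepth = cerclageDepth, cerclageWidth = cerclageWidth,
      parsPlanaBoundary = parsPlanaBoundary, maculaExtent = maculaExtent,
      meshSubdivision = as.integer(meshSubdivision))
}

#' Geometry variants
#'
#' The three vitreous-chamber morphologies: emmetropic, myopic with posterior
#' staphyloma, and staphyloma with an encircling scleral band.
#' @export
eyeVariants <- function() c("emmetropic", "staphyloma", "staphyloma_cerclage")

#' Closed triangulated vitreous-chamber wall
#'
#' A watertight, consistently outward-oriented triangle mesh in the eye frame
#' (+z anterior along the optical axis, +y anatomical superior, origin at the
#' undeformed sphere centre). Each vertex carries its polar angle psi on the
#' undeformed sphere (degrees from the anterior pole) and its undeformed
#' radius, recorded before any deformation so that region labels are
#' deformation-invariant. Faces on the planar lens cap are flagged.
#'
#' @slot vertices numeric n x 3 matrix of coordinates (mm).
#' @slot faces integer m x 3 matrix of vertex indices (1-based, outward CCW).
#' @slot psi numeric length-n polar angle on the undeformed sphere (deg).
#' @slot restRadius numeric length-n vertex radius before deformation (mm).
#' @slot isCap logical length-m; TRUE for lens-cap faces.
#' @slot variant character; one of [eyeVariants()].
#' @slot params the [EyeGeometryParams-class] used to build the mesh.
#' @export
setClass("EyeMesh",
  representation(
    vertices   = "matrix",
    faces      = "matrix",
    psi        = "numeric",
    restRadius = "numeric",
    isCap      = "logical",
    variant    = "character",
    params     = "EyeGeometryParams"
  )
)

setValidity("EyeMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3L) return("vertices must be an n x 3 matrix")
  if (ncol(f) != 3L) return("faces must be an m x 3 matrix")
  if (length(object@psi) != nrow(v)) return("psi must have one entry per vertex")
  if (length(object@restRadius) != nrow(v))
    return("restRadius must have one entry per vertex")
  if (length(object@isCap) != nrow(f)) return("isCap must have one entry per face")
  if (!object@variant %in% eyeVariants()) return("unknown variant")
  if (min(f) < 1L || max(f) > nrow(v)) return("face index out of range")
  # watertight: every directed edge must be matched by its reverse exactly once
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  fwd <- paste(e[, 1], e[, 2]); rev <- paste(e[, 2], e[, 1])
  if (any(duplicated(fwd))) return("mesh is not manifold (duplicated directed edge)")
  if (!all(fwd %in% rev)) return("mesh is not watertight (unmatched edge)")
  if (any(faceAreasOf(v, f) <= 0)) return("degenerate face (zero area)")
  if (signedVolumeOf(v, f) <= 0) return("faces are not oriented outward")
  TRUE
})

setMethod("show", "EyeMesh", function(object) {
  cat(sprintf("EyeMesh '%s': %d vertices, %d faces (%d lens-cap)\n",
              object@variant, nrow(object@vertices), nrow(object@faces),
              sum(object@isCap)))
  cat(sprintf("  enclosed volume %.1f mm^3, surface area %.1f mm^2\n",
              enclosedVolume(object), sum(faceAreas(object))))
})

#' Region and hemifield labels for each mesh face
#'
#' Partition of the chamber wall into lens, pars plana, pre-equatorial
#' retina, post-equatorial retina, macula and (in the banded variant) the
#' cerclage indentation, each split into superior and inferior hemifields by
#' the sign of the face-centroid y coordinate.
#'
#' @slot region factor of length m with levels [regionLevels()].
#' @slot hemifield factor of length m with levels superior/inferior.
#' @slot faceArea numeric face areas (mm^2) cached from the labelled mesh.
#' @slot variant character variant of the labelled mesh.
#' @export
setClass("RegionMap",
  representation(
    region    = "factor",
    hemifield = "factor",
    faceArea  = "numeric",
    variant   = "character"
  )
)

setValidity("RegionMap", function(object) {
  if (!identical(levels(object@region), regionLevels()))
    return("region levels mismatch")
  if (anyNA(object@region)) return("unlabeled face")
  if (length(object@hemifield) != length(object@region))
    return("hemifield length mismatch")
  if (length(object@faceArea) != length(object@region))
    return("faceArea length mismatch")
  TRUE
})

setMethod("show", "RegionMap", function(object) {
  cat(sprintf("RegionMap (%s): %d faces\n", object@variant,
              length(object@region)))
  print(tapply(object@faceArea, object@region, sum))
})

#' Region label set
#' @export
regionLevels <- function()
  c("lens", "pars_plana", "pre_equatorial", "post_equatorial", "macula",
    "cerclage_band")

#' Physical properties of the tamponade fluid pair
#'
#' Silicone oil (SiO, 1000 mPa.s polydimethylsiloxane) against aqueous.
#' Densities kg/m^3, viscosities mPa.s, interfacial tension N/m, contact
#' angles degrees, gravity m/s^2. `angleThrough` records through which phase
#' the static oil-water-retina contact angle is measured: `"aqueous"` (the
#' default; the small measured angle means aqueous wets the retina and the
#' oil is effectively non-wetting) or `"oil"` (the opposite reading, oil
#' wetting).
#'
#' @slot densitySiO,densityAqueous kg/m^3.
#' @slot viscositySiO,viscosityAqueous dynamic viscosity, mPa.s.
#' @slot interfacialTension N/m.
#' @slot contactAngleStatic,contactAngleAdvancing,contactAngleReceding deg.
#' @slot gravity m/s^2.
#' @slot angleThrough "aqueous" or "oil".
#' @export
setClass("FluidProperties",
  representation(
    densitySiO           = "numeric",
    densityAqueous       = "numeric",
    viscositySiO         = "numeric",
    viscosityAqueous     = "numeric",
    interfacialTension   = "numeric",
    contactAngleStatic   = "numeric",
    contactAngleAdvancing = "numeric",
    contactAngleReceding = "numeric",
    gravity              = "numeric",
    angleThrough         = "character"
  )
)

setValidity("FluidProperties", function(object) {
  msgs <- character()
  if (object@densitySiO >= object@densityAqueous)
    msgs <- c(msgs, "SiO must be buoyant (densitySiO < densityAqueous)")
  if (!(object@contactAngleReceding <= object@contactAngleStatic &&
        object@contactAngleStatic <= object@contactAngleAdvancing))
    msgs <- c(msgs, "contact angles must satisfy receding <= static <= advancing")
  if (object@interfacialTension < 0) msgs <- c(msgs, "interfacialTension < 0")
  if (!object@angleThrough %in% c("aqueous", "oil"))
    msgs <- c(msgs, "angleThrough must be 'aqueous' or 'oil'")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn FluidProperties-class constructor with the standard SiO-1000 /
#'   aqueous property set.
#' @param densitySiO,densityAqueous,viscositySiO,viscosityAqueous,interfacialTension,contactAngleStatic,contactAngleAdvancing,contactAngleReceding,gravity,angleThrough see slots.
#' @export
fluidProperties <- function(densitySiO = 980, densityAqueous = 997,
                            viscositySiO = 1000, viscosityAqueous = 1,
                            interfacialTension = 0.044,
                            contactAngleStatic = 16.2,
                            contactAngleAdvancing = 21.2,
                            contactAngleReceding = 11.2,
                            gravity = 9.81,
                            angleThrough = "aqueous") {
  new("FluidProperties",
      densitySiO = densitySiO, densityAqueous = densityAqueous,
      viscositySiO = viscositySiO, viscosityAqueous = viscosityAqueous,
      interfacialTension = interfacialTension,
      contactAngleStatic = contactAngleStatic,
      contactAngleAdvancing = contactAngleAdvancing,
      contactAngleReceding = contactAngleReceding,
      gravity = gravity, angleThrough = angleThrough)
}

setMethod("show", "FluidProperties", function(object) {
  cat(sprintf(
    "FluidProperties: rho %g/%g kg/m^3, mu %g/%g mPa.s, sigma %g N/m,\n",
    object@densitySiO, object@densityAqueous, object@viscositySiO,
    object@viscosityAqueous, object@interfacialTension))
  cat(sprintf("  theta_s %g deg (measured through %s), g %g m/s^2\n",
              object@contactAngleStatic, object@angleThrough, object@gravity))
})

#' Patient posture
#'
#' A named gravity direction in the eye frame: standing (gravity along -y),
#' supine / face-up (gravity toward the posterior pole, -z) and a 45-degree
#' upward tilt between the two.
#'
#' @slot name posture name.
#' @slot gravityDir unit vector of the gravitational acceleration.
#' @export
setClass("Posture",
  representation(name = "character", gravityDir = "numeric"))

setValidity("Posture", function(object) {
  if (length(object@gravityDir) != 3L) return("gravityDir must be length 3")
  if (abs(sqrt(sum(object@gravityDir^2)) - 1) > 1e-9)
    return("gravityDir must be a unit vector")
  TRUE
})

#' @describeIn Posture-class constructor.
#' @param name one of "standing", "tilt45", "supine", or "custom".
#' @param gravityDir override gravity direction (unit 3-vector), only needed
#'   for `name = "custom"`.
#' @export
posture <- function(name = c("standing", "tilt45", "supine", "custom"),
                    gravityDir = NULL) {
  name <- match.arg(name)
  if (is.null(gravityDir)) {
    gravityDir <- switch(name,
      standing = c(0, -1, 0),
      tilt45   = c(0, -sqrt(2) / 2, -sqrt(2) / 2),
      supine   = c(0, 0, -1),
      stop("gravityDir must be supplied for a custom posture"))
  }
  new("Posture", name = name, gravityDir = gravityDir / sqrt(sum(gravityDir^2)))
}

#' Posture names used throughout the package
#' @export
postureNames <- function() c("standing", "tilt45", "supine")

#' Voxelised oil-fraction field over the chamber interior
#'
#' A regular cubic voxel grid covering the mesh bounding box. `mask` flags
#' voxels inside the chamber; `alpha` is the oil volume fraction (0 outside
#' the domain). After equilibration the field carries the convergence state
#' and a per-sweep trace.
#'
#' @slot alpha numeric n x n x n array, oil fraction in [0, 1].
#' @slot mask logical n x n x n array, TRUE inside the chamber.
#' @slot origin coordinates (mm) of the centre of voxel (1,1,1).
#' @slot pitch voxel edge length (mm).
#' @slot fill oil volume fraction of the chamber (0-1); NA before solving.
#' @slot posture posture name; "" before solving.
#' @slot converged logical.
#' @slot sweeps number of threshold-dynamics sweeps performed.
#' @slot trace data.frame with per-sweep diagnostics (flips, oil volume).
#' @export
setClass("PhaseField",
  representation(
    alpha     = "array",
    mask      = "array",
    origin    = "numeric",
    pitch     = "numeric",
    fill      = "numeric",
    posture   = "character",
    converged = "logical",
    sweeps    = "integer",
    trace     = "data.frame"
  )
)

setValidity("PhaseField", function(object) {
  if (!identical(dim(object@alpha), dim(object@mask)))
    return("alpha and mask dimensions differ")
  if (length(object@origin) != 3L) return("origin must be length 3")
  if (object@pitch <= 0) return("pitch must be positive")
  if (any(object@alpha[!object@mask] != 0))
    return("alpha must be 0 outside the domain")
  TRUE
})

setMethod("show", "PhaseField", function(object) {
  d <- dim(object@alpha)
  cat(sprintf("PhaseField %dx%dx%d, pitch %.3f mm, %d domain voxels\n",
              d[1], d[2], d[3], sum(object@mask)))
  if (!is.na(object@fill))
    cat(sprintf("  fill %.1f%%, posture %s, %d sweeps, converged: %s\n",
                100 * object@fill, object@posture, object@sweeps,
                object@converged))
})

#' Per-region SiO contact report
#'
#' SiO-wetted area percentages for one (geometry, posture, fill) case. The
#' overall figure is the area-weighted mean over all non-lens regions
#' (retinal surface denominator).
#'
#' @slot variant geometry variant.
#' @slot posture posture name.
#' @slot fill fill fraction (0-1).
#' @slot table data.frame: region, hemifield, area_mm2, wetted_mm2,
#'   contact_pct.
#' @slot overall overall retinal contact percentage.
#' @slot faceWetted per-face wetted fraction in [0, 1].
#' @slot meta list of solver provenance (resolution, sweeps, converged, ...).
#' @export
setClass("ContactReport",
  representation(
    variant    = "character",
    posture    = "character",
    fill       = "numeric",
    table      = "data.frame",
    overall    = "numeric",
    faceWetted = "numeric",
    meta       = "list"
  )
)

setValidity("ContactReport", function(object) {
  tab <- object@table
  need <- c("region", "hemifield", "area_mm2", "wetted_mm2", "contact_pct")
  if (!all(need %in% names(tab))) return("table is missing columns")
  ok <- tab$contact_pct >= -1e-9 & tab$contact_pct <= 100 + 1e-9
  if (!all(ok | is.na(tab$contact_pct))) return("contact_pct outside [0, 100]")
  if (object@overall < -1e-9 || object@overall > 100 + 1e-9)
    return("overall outside [0, 100]")
  TRUE
})

setMethod("show", "ContactReport", function(object) {
  cat(sprintf("ContactReport: %s, %s, fill %.0f%% -> overall %.1f%%\n",
              object@variant, object@posture, 100 * object@fill,
              object@overall))
  print(object@table[, c("region", "hemifield", "contact_pct")],
        row.names = FALSE)
})

#' Saccade polynomial parameters
#'
#' Quintic angular-displacement law theta(t) = c0 + c1 t + ... + c5 t^5 for a
#' horizontal saccade about the +y axis. `boundary_condition` mode enforces
#' theta(0) = theta'(0) = 0, theta(T) = amplitude, theta'(T) = theta''(T) = 0
#' exactly; `table2_verbatim` carries the published coefficient set unchanged
#' (diagnostic only; it does not reach the stated amplitude).
#'
#' @slot amplitude saccade amplitude (deg).
#' @slot duration saccade duration T (s); the observation window is 2T.
#' @slot coefficients numeric c0..c5 (deg, deg/s, ..., deg/s^5).
#' @slot mode "boundary_condition" or "table2_verbatim".
#' @export
setClass("SaccadeParams",
  representation(
    amplitude    = "numeric",
    duration     = "numeric",
    coefficients = "numeric",
    mode         = "character"
  )
)

setValidity("SaccadeParams", function(object) {
  if (length(object@coefficients) != 6L) return("need six coefficients c0..c5")
  if (object@duration <= 0) return("duration must be positive")
  if (!object@mode %in% c("boundary_condition", "table2_verbatim"))
    return("unknown mode")
  TRUE
})

setMethod("show", "SaccadeParams", function(object) {
  cat(sprintf("SaccadeParams (%s): %g deg / %g s\n", object@mode,
              object@amplitude, object@duration))
  cat("  c0..c5:", format(object@coefficients, digits = 4), "\n")
})

# ---- internal helpers shared by validity methods -------------------------

faceAreasOf <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

signedVolumeOf <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
      a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}
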