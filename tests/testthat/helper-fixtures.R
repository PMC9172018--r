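# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

defaultParams <- function(sub = 4L) eyeGeometryParams(meshSubdivision = sub)

fxMesh <- function(variant = "emmetropic", sub = 4L) {
  fixture(paste0("mesh_", variant, "_", sub),
          function() buildEyeSurface(defaultParams(sub), variant))
}

fxMap <- function(variant = "emmetropic", sub = 4L) {
  fixture(paste0("map_", variant, "_", sub),
          function() labelRegions(fxMesh(variant, sub)))
}

# full sphere (no lens cap), used by closed-form volume/contact oracles
fxSphere <- function(sub = 4L) {
  fixture(paste0("sphere_", sub), function()
    buildEyeSurface(eyeGeometryParams(lensCapHeight = 0,
                                      meshSubdivision = sub), "emmetropic"))
}

# axis-aligned unit cube as a minimal closed mesh
unitCubeMesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  list(vertices = v, faces = f)
}

sphereVol <- function(R = 12) 4 / 3 * pi * R^3
capVol <- function(h, R = 12) pi * h^2 * (R - h / 3)
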