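# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# default head phantom at the 2 mm working resolution
phantom_2mm <- function() cached("phantom_2mm",
  build_phantom(phantom_config(voxel_size = 2)))

rois_2mm <- function() cached("rois_2mm", label_rois(phantom_2mm()))

# 1 mm phantom for footprint-area checks (matches the source imaging
# resolution)
phantom_1mm <- function() cached("phantom_1mm",
  build_phantom(phantom_config(voxel_size = 1)))

# layer set whose thinnest layer is 4 mm, for coarse-grid tests
thick_radii <- c(white = 52, gray = 68, CSF = 72, skull = 80,
                 fat = 84, skin = 92)

phantom_4mm <- function() cached("phantom_4mm",
  build_phantom(phantom_config(layer_radii = thick_radii, voxel_size = 4)))

paper_montages <- c("M1-SO", "DLPFC", "Cz-Oz", "HD-4x1", "HD-2x2")

# the five montage solutions on the default 2 mm phantom (the study
# conditions); shared by the acceptance checks
montage_solutions <- function() cached("montage_solutions", {
  vol <- phantom_2mm()
  sols <- lapply(paper_montages, function(m) solve_montage(vol, m))
  names(sols) <- paper_montages
  sols
})

# 1-D column of `n` tissue voxels with electrode voxels appended at both
# ends, embedded in a n+2 x 3 x 3 grid of air
column_system <- function(sigmas, voxel_size = 1) {
  n <- length(sigmas)
  sig <- array(NA_real_, c(n + 2, 3, 3))
  sig[2:(n + 1), 2, 2] <- sigmas
  sig[1, 2, 2] <- 5.99e7
  sig[n + 2, 2, 2] <- 5.99e7
  lin <- function(i) i + (2 - 1) * (n + 2) + (2 - 1) * (n + 2) * 3
  assemble_system(sig, list(anode_idx = lin(1), cathode_idx = lin(n + 2)),
                  voxel_size)
}

# the reference 5-shell validation head (fat merged away)
validation_layers <- function()
  sphere_layers(c(58, 72, 76, 83, 92), c(0.126, 0.276, 1.65, 0.01, 0.465))
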