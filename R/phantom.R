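# Synthetic layered-sphere head phantoms.
#
# The phantom emulates a segmented head volume: concentric shells of white
# matter, gray matter, CSF, skull, fat and skin embedded in air, on an
# isotropic voxel grid. Geometric stand-ins for the regions analysed in
# tDCS studies (PFC, M1, S1, occipital cortex, insulae, cingulate,
# thalamus, brainstem) are carved out of the gray/white compartments.

#' Tissue label codes used in labeled head volumes
#'
#' Integer codes for the tissue classes of a [head_volume()]. Code 0 is
#' air/background; electrode assemblies stamped by [stamp_electrode()] use
#' the `sponge_or_gel` and `electrode` codes.
#'
#' @return Named integer vector mapping tissue name to label code.
#' @export
tissue_codes <- function() {
  c(air = 0L, skin = 1L, fat = 2L, skull = 3L, CSF = 4L,
    gray = 5L, white = 6L, sponge_or_gel = 7L, electrode = 8L)
}

#' Isotropic tissue conductivities (S/m)
#'
#' The conductivity table of the forward model: skin 0.465, fat 0.025,
#' skull 0.01, CSF 1.65, gray matter 0.276, white matter 0.126, air 1e-15,
#' saline-soaked sponge or conductive gel 1.4, electrode (metal) 5.99e7.
#' CSF is the most conductive tissue, which is what makes it a preferential
#' current pathway. Air is nominally 1e-15 S/m; the solver honours it as a
#' perfect insulator by excluding air from the conductive domain.
#'
#' @return Named numeric vector, tissue name to conductivity in S/m.
#' @export
tissue_table <- function() {
  c(skin = 0.465, fat = 0.025, skull = 0.01, CSF = 1.65,
    gray = 0.276, white = 0.126, air = 1e-15,
    sponge_or_gel = 1.4, electrode = 5.99e7)
}

#' Phantom configuration
#'
#' Layer radii follow spherical-head conventions (mm, centre outward):
#' white 58, gray 72, CSF 76, skull 83, fat 85, skin 92. The optional
#' midsagittal CSF conduit stands in for a highly conductive intracerebral
#' artery running from under the vertex toward deep medial structures; it
#' is off by default.
#'
#' @param layer_radii Named numeric vector of outer radii (mm) for
#'   `white`, `gray`, `CSF`, `skull`, `fat`, `skin`, strictly increasing.
#' @param voxel_size Isotropic voxel edge length in mm. Must not exceed the
#'   thinnest layer.
#' @param medial_csf_conduit If `TRUE`, relabel a vertical midsagittal
#'   cylinder of brain tissue (from the centre up to the CSF shell) as CSF.
#' @param conduit_radius_mm Radius of that cylinder (mm).
#' @param perturb_amp_mm Amplitude (mm) of a smooth random radial
#'   perturbation applied to every layer boundary; 0 keeps perfect spheres.
#' @param seed Integer seed for the perturbation (ignored when amplitude
#'   is 0); generation is deterministic given (config, seed).
#' @param margin_mm Air margin around the scalp, sized to leave room for
#'   electrode assemblies.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(layer_radii = c(white = 58, gray = 72, CSF = 76,
                                           skull = 83, fat = 85, skin = 92),
                           voxel_size = 1,
                           medial_csf_conduit = FALSE,
                           conduit_radius_mm = 2,
                           perturb_amp_mm = 0,
                           seed = 0L,
                           margin_mm = 12) {
  needed <- c("white", "gray", "CSF", "skull", "fat", "skin")
  if (!all(needed %in% names(layer_radii)))
    stop("layer_radii must name all of: ", paste(needed, collapse = ", "),
         call. = FALSE)
  layer_radii <- layer_radii[needed]
  if (any(diff(layer_radii) <= 0) || layer_radii[1] <= 0)
    stop("configuration error: layer radii must be strictly increasing ",
         "(white < gray < CSF < skull < fat < skin)", call. = FALSE)
  thickness <- c(layer_radii[1], diff(layer_radii))
  if (voxel_size > min(thickness))
    stop("configuration error: voxel_size (", voxel_size,
         " mm) exceeds the thinnest layer (", min(thickness), " mm)",
         call. = FALSE)
  structure(list(layer_radii = layer_radii, voxel_size = voxel_size,
                 medial_csf_conduit = medial_csf_conduit,
                 conduit_radius_mm = conduit_radius_mm,
                 perturb_amp_mm = perturb_amp_mm, seed = as.integer(seed),
                 margin_mm = margin_mm),
            class = "phantom_config")
}

# Smooth random perturbation on the sphere: a fixed mixture of degree-2
# directional harmonics with N(0,1) coefficients. Returns a function of an
# n x 3 matrix of unit directions.
#' @keywords internal
perturbation_fn <- function(amp, seed) {
  if (amp == 0) return(function(u) rep(0, nrow(u)))
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs))
  set.seed(seed)
  k <- 6L
  dirs <- matrix(stats::rnorm(3 * k), k, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  coef <- stats::rnorm(k)
  function(u) {
    t <- u %*% t(dirs)            # n x k direction cosines
    amp * as.vector((t^2 - 1 / 3) %*% coef) / sqrt(k)
  }
}

#' @keywords internal
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

#' @keywords internal
.Random.seed_restore <- function(rs) {
  if (is.null(rs)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", rs, envir = globalenv())
}

#' Build a labeled head phantom
#'
#' Discretizes the concentric-shell head onto an isotropic voxel grid.
#' Along any ray from the centre the tissues appear in the fixed radial
#' order white, gray, CSF, skull, fat, skin, then air.
#'
#' @param config A [phantom_config()].
#' @return A `head_volume`: list with `labels` (3-D integer array),
#'   `voxel_size` (mm), `origin` (world mm of voxel (1,1,1) centre),
#'   `label_codes`, `meta` (radii, perturbation), and an empty `electrodes`
#'   list to be filled by [stamp_electrode()].
#' @export
build_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  radii <- config$layer_radii
  vs <- config$voxel_size
  half <- ceiling((max(radii) + config$margin_mm) / vs)
  n <- 2L * half + 1L
  dim <- c(n, n, n)
  origin <- rep(-half * vs, 3)
  r2 <- radius2_array(dim, vs, origin)
  r <- sqrt(r2)

  codes <- tissue_codes()
  labels <- array(codes[["air"]], dim)
  pert <- perturbation_fn(config$perturb_amp_mm, config$seed)
  if (config$perturb_amp_mm > 0) {
    co <- coord_arrays(dim, vs, origin)
    rr <- pmax(r, 1e-9)
    u <- cbind(as.vector(co$x), as.vector(co$y), as.vector(co$z)) / as.vector(rr)
    u[r2 == 0, ] <- c(0, 0, 1)
    delta <- array(pert(u), dim)
  } else delta <- 0
  # outermost first so inner assignments overwrite
  order_out_in <- c("skin", "fat", "skull", "CSF", "gray", "white")
  for (tis in order_out_in) {
    labels[r <= radii[[tis]] + delta] <- codes[[tis]]
  }

  if (isTRUE(config$medial_csf_conduit)) {
    co <- coord_arrays(dim, vs, origin)
    cyl <- (co$x^2 + co$y^2 <= config$conduit_radius_mm^2) &
      co$z >= 0 & co$z <= radii[["CSF"]]
    brain <- labels == codes[["gray"]] | labels == codes[["white"]]
    labels[cyl & brain] <- codes[["CSF"]]
  }

  structure(list(labels = labels, voxel_size = vs, origin = origin,
                 label_codes = codes,
                 meta = list(layer_radii = radii, perturb = pert,
                             skin_radius = radii[["skin"]],
                             config = config),
                 electrodes = list()),
            class = "head_volume")
}

#' @export
print.head_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat("head_volume: ", paste(d, collapse = " x "), " voxels @ ",
      x$voxel_size, " mm\n", sep = "")
  tab <- table(factor(x$labels, levels = x$label_codes,
                      labels = names(x$label_codes)))
  print(tab[tab > 0])
  if (length(x$electrodes))
    cat("electrodes:", paste(vapply(x$electrodes, function(e)
      paste0(e$name, "(", e$polarity, ")"), ""), collapse = ", "), "\n")
  invisible(x)
}

#' Map tissue labels to a conductivity lattice
#'
#' @param vol A `head_volume`.
#' @param table Named conductivity vector, as from [tissue_table()].
#' @return 3-D numeric array of conductivities (S/m); air voxels are `NA`,
#'   marking them excluded from the conductive domain (electrically
#'   insulated outer boundary).
#' @export
assign_conductivity <- function(vol, table = tissue_table()) {
  stopifnot(inherits(vol, "head_volume"))
  codes <- vol$label_codes
  used <- sort(unique(as.vector(vol$labels)))
  known <- codes[names(codes) %in% names(table)]
  bad <- setdiff(used, c(known, codes[["air"]]))
  if (length(bad))
    stop("labeling error: no conductivity for label code(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  lut <- rep(NA_real_, max(codes) + 1L)
  for (nm in names(table)) if (nm %in% names(codes))
    lut[codes[[nm]] + 1L] <- table[[nm]]
  lut[codes[["air"]] + 1L] <- NA_real_   # air excluded from the domain
  sigma <- array(lut[vol$labels + 1L], dim(vol$labels))
  sigma
}

#' Geometric ROI stand-ins on the phantom
#'
#' Places nine regions on the unstamped phantom: PFC (anterior gray cap),
#' M1 (gray cap about the C3 radial direction), S1 (gray cap immediately
#' posterior to M1), occipital cortex (posterior gray cap), left/right
#' insula (mid-depth lateral gray patches), cingulate (superior
#' parasagittal gray slab), thalamus (central ellipsoid in white matter)
#' and brainstem (inferior axial cylinder). Regions are assigned in a fixed
#' priority order, which guarantees pairwise disjointness.
#'
#' @param vol A `head_volume` without electrodes.
#' @param scheme ROI scheme name; only `"default"` is defined.
#' @return A `roi_volume`: list with `labels` (3-D integer array, 0 =
#'   no ROI), `label_codes`, and the geometry of the source phantom.
#' @export
label_rois <- function(vol, scheme = "default") {
  stopifnot(inherits(vol, "head_volume"))
  if (!identical(scheme, "default"))
    stop("configuration error: unknown ROI scheme '", scheme, "'",
         call. = FALSE)
  if (length(vol$electrodes))
    stop("label_rois expects an unstamped phantom", call. = FALSE)
  codes <- vol$label_codes
  dim <- dim(vol$labels)
  co <- coord_arrays(dim, vol$voxel_size, vol$origin)
  r <- sqrt(co$x^2 + co$y^2 + co$z^2)
  gray <- vol$labels == codes[["gray"]]
  white <- vol$labels == codes[["white"]]
  brain <- gray | white
  rw <- vol$meta$layer_radii[["white"]]

  cap <- function(dir, half_angle, within) {
    # angular cap about a direction, intersected with a tissue mask
    ct <- (co$x * dir[1] + co$y * dir[2] + co$z * dir[3]) / pmax(r, 1e-9)
    within & ct >= cos(half_angle * pi / 180)
  }
  c3 <- standard_position("C3")
  a <- 25 * pi / 180  # posterior offset of S1 centre about the vertical axis
  s1dir <- c(c3[1] * cos(a), c3[1] * sin(a), c3[3])

  defs <- list(  # priority order; later regions yield to earlier ones
    thalamus  = ((co$x / 10)^2 + (co$y / 14)^2 + (co$z / 9)^2 <= 1) & white,
    brainstem = (co$x^2 + co$y^2 <= 8^2) & co$z <= -30 & co$z >= -70 & brain,
    M1        = cap(c3, 10, gray),
    S1        = cap(s1dir, 10, gray),
    PFC       = cap(c(0, 1, 0), 35, gray),
    occipital = cap(c(0, -1, 0), 35, gray),
    insula_L  = cap(c(-1, 0, 0), 25, gray & r <= rw + 5),
    insula_R  = cap(c(1, 0, 0), 25, gray & r <= rw + 5),
    cingulate = gray & abs(co$x) <= 5 & co$z > 0
  )
  roi <- array(0L, dim)
  roi_codes <- integer(0)
  for (i in seq_along(defs)) {
    m <- defs[[i]] & roi == 0L
    roi[m] <- i
    roi_codes[[names(defs)[i]]] <- i
  }
  structure(list(labels = roi, label_codes = roi_codes,
                 voxel_size = vol$voxel_size, origin = vol$origin),
            class = "roi_volume")
}
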