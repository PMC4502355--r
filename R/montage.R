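# 10-10 / 10-20 electrode positions and montage stamping.
#
# Scalp positions are computed by the standard proportional arc
# construction on the unit sphere (not an embedded lookup table):
#   * midline arc nasion -> Cz -> inion, subdivided in 10% steps
#     (Fpz 10%, Fz 30%, Cz 50%, Pz 70%, Oz 90%, plus the 10-10
#     intermediates AFz, FCz, CPz, POz);
#   * ear-to-ear arc through Cz (T7 10%, C5 20%, C3 30%, ..., T8 90%);
#   * the outer 10% circle through Fpz, T7, Oz, T8 carrying Fp1/2, AF7/8,
#     F7/8, FT7/8, TP7/8, P7/8, PO7/8, O1/2 at 5% circumference steps;
#   * intermediate rows (F, FC, CP, P, AF, PO) on the circle through their
#     two outer-ring ends and their midline point, subdivided into equal
#     arcs (e.g. F7 F5 F3 F1 Fz F2 F4 F6 F8).
# Head frame: +z vertex, +y nasion, +x right preauricular.

.fieldlab_env <- new.env(parent = emptyenv())

# circle through three points on the unit sphere, subdivided into `k`
# equal arcs from p1 through pm to p2; returns (k+1) x 3 unit vectors
#' @keywords internal
arc_points <- function(p1, pm, p2, k) {
  nrm <- normalize3(cross3(p1 - pm, p2 - pm))
  d <- sum(nrm * p1)
  centre <- d * nrm
  rho <- sqrt(max(0, 1 - d^2))
  e1 <- normalize3(p1 - centre)
  e2v <- pm - centre - sum((pm - centre) * e1) * e1
  e2 <- normalize3(e2v)
  ang <- function(p) atan2(sum((p - centre) * e2), sum((p - centre) * e1))
  t2 <- ang(p2)
  if (t2 < 0) t2 <- t2 + 2 * pi   # go the way that passes through pm (t>0)
  tt <- seq(0, t2, length.out = k + 1)
  pts <- t(vapply(tt, function(t) centre + rho * (cos(t) * e1 + sin(t) * e2),
                  numeric(3)))
  pts / sqrt(rowSums(pts^2))
}

#' @keywords internal
build_1010_table <- function() {
  pos <- list()
  add <- function(name, v) pos[[name]] <<- v / sqrt(sum(v^2))

  # midline: fraction f of the 180 deg nasion->inion arc
  mid <- function(f) {
    a <- pi * f
    c(0, cos(a), sin(a))
  }
  midline <- c(Nz = 0, Fpz = .1, AFz = .2, Fz = .3, FCz = .4, Cz = .5,
               CPz = .6, Pz = .7, POz = .8, Oz = .9, Iz = 1)
  for (nm in names(midline)) add(nm, mid(midline[[nm]]))

  # coronal ear-to-ear arc: fraction from the left preauricular point
  cor <- function(f) {
    b <- pi * f
    c(-cos(b), 0, sin(b))
  }
  coronal <- c(T7 = .1, C5 = .2, C3 = .3, C1 = .4, C2 = .6, C4 = .7,
               C6 = .8, T8 = .9)
  for (nm in names(coronal)) add(nm, cor(coronal[[nm]]))

  # outer 10% circle: colatitude of Fpz, azimuth from +y in 5% (18 deg)
  # circumference steps; left hemisphere has azimuth rotated toward -x
  colat <- acos(pos$Fpz[3])
  ring <- function(g_left) {       # g = fraction of circumference from Fpz
    phi <- pi / 2 + 2 * pi * g_left
    c(sin(colat) * cos(phi), sin(colat) * sin(phi), cos(colat))
  }
  left <- c(Fp1 = .05, AF7 = .10, F7 = .15, FT7 = .20, TP7 = .30,
            P7 = .35, PO7 = .40, O1 = .45)
  for (nm in names(left)) add(nm, ring(left[[nm]]))
  right <- c(Fp2 = .05, AF8 = .10, F8 = .15, FT8 = .20, TP8 = .30,
             P8 = .35, PO8 = .40, O2 = .45)
  for (nm in names(right)) add(nm, ring(-right[[nm]]))

  rows <- list(
    F  = list(ends = c("F7", "F8"),  midl = "Fz",
              names = c("F5", "F3", "F1", NA, "F2", "F4", "F6"), k = 8),
    FC = list(ends = c("FT7", "FT8"), midl = "FCz",
              names = c("FC5", "FC3", "FC1", NA, "FC2", "FC4", "FC6"), k = 8),
    CP = list(ends = c("TP7", "TP8"), midl = "CPz",
              names = c("CP5", "CP3", "CP1", NA, "CP2", "CP4", "CP6"), k = 8),
    P  = list(ends = c("P7", "P8"),  midl = "Pz",
              names = c("P5", "P3", "P1", NA, "P2", "P4", "P6"), k = 8),
    AF = list(ends = c("AF7", "AF8"), midl = "AFz",
              names = c("AF3", NA, "AF4"), k = 4),
    PO = list(ends = c("PO7", "PO8"), midl = "POz",
              names = c("PO3", NA, "PO4"), k = 4)
  )
  for (rw in rows) {
    pts <- arc_points(pos[[rw$ends[1]]], pos[[rw$midl]], pos[[rw$ends[2]]],
                      rw$k)
    for (i in seq_along(rw$names)) {
      if (!is.na(rw$names[i])) add(rw$names[i], pts[i + 1, ])
    }
  }
  do.call(rbind, pos)
}

#' Standard 10-10 scalp direction
#'
#' Unit direction (head frame: +z vertex, +y nasion, +x right) of a 10-10
#' or 10-20 electrode position, from the proportional arc construction.
#'
#' @param label Position name, e.g. `"C3"`, `"Cz"`, `"Fp2"`, `"FC5"`.
#' @return Unit 3-vector.
#' @export
#' @examples
#' standard_position("Cz")            # (0, 0, 1)
#' angle <- acos(sum(standard_position("Cz") * standard_position("C3")))
#' angle * 180 / pi                   # 36 degrees
standard_position <- function(label) {
  if (is.null(.fieldlab_env$pos1010))
    .fieldlab_env$pos1010 <- build_1010_table()
  tab <- .fieldlab_env$pos1010
  if (!label %in% rownames(tab))
    stop("naming error: unknown 10-10 label '", label, "'; supported: ",
         paste(sort(rownames(tab)), collapse = ", "), call. = FALSE)
  tab[label, ]
}

#' All supported 10-10 labels
#' @return Character vector of position names.
#' @export
supported_positions <- function() {
  if (is.null(.fieldlab_env$pos1010))
    .fieldlab_env$pos1010 <- build_1010_table()
  sort(rownames(.fieldlab_env$pos1010))
}

#' Project a direction onto the scalp surface
#'
#' Marches along the ray from the head centre and returns the world
#' coordinate of the outermost skin-labeled point.
#'
#' @param direction Nonzero 3-vector (need not be unit length).
#' @param vol A `head_volume`.
#' @return World coordinate (mm) on the scalp.
#' @export
project_to_scalp <- function(direction, vol) {
  stopifnot(inherits(vol, "head_volume"))
  u <- normalize3(direction)
  vs <- vol$voxel_size
  dim <- dim(vol$labels)
  rmax <- max(abs(c(vol$origin, vol$origin + (dim - 1) * vs)))
  radii <- seq(rmax, 0, by = -vs / 4)
  pts <- outer(radii, u)
  lin <- nearest_linear_index(pts, dim, vs, vol$origin)
  ok <- !is.na(lin)
  skin <- vol$label_codes[["skin"]]
  hit <- which(ok & vol$labels[ifelse(ok, lin, 1L)] == skin)
  if (!length(hit))
    stop("geometry error: ray misses the scalp", call. = FALSE)
  radii[hit[1]] * u
}

#' Electrode specification
#'
#' Conventional sponge pads are 50 x 70 mm rectangles; high-definition
#' (HD) electrodes are 12 mm diameter disks over a conductive-gel layer.
#' For rectangles, orientation `"vertical"` aligns the 70 mm axis with the
#' local meridian (toward the vertex) and `"horizontal"` with the local
#' parallel; at the vertex itself the meridian degenerates and the
#' nasion-inion direction takes its place, so a `"horizontal"` pad at Cz
#' runs ear to ear.
#'
#' @param position 10-10 label (see [standard_position()]); alternatively
#'   supply `direction` directly.
#' @param polarity `"anode"` or `"cathode"`.
#' @param shape `"rectangle"` (pad) or `"disk"` (HD).
#' @param dims_mm For rectangles `c(width, length)` = c(50, 70); for disks
#'   the diameter (12).
#' @param orientation `"vertical"`, `"horizontal"` or `"n/a"` (disks).
#' @param sponge_mm Sponge/gel layer thickness (5 mm pads, 2 mm HD gel).
#' @param conductor_mm Metal conductor layer thickness (2 mm).
#' @param direction Optional explicit unit direction overriding `position`.
#' @return A list of class `electrode_spec`.
#' @export
electrode_spec <- function(position, polarity,
                           shape = c("rectangle", "disk"),
                           dims_mm = NULL,
                           orientation = "n/a",
                           sponge_mm = NULL, conductor_mm = 2,
                           direction = NULL) {
  shape <- match.arg(shape)
  polarity <- match.arg(polarity, c("anode", "cathode"))
  if (is.null(dims_mm)) dims_mm <- if (shape == "rectangle") c(50, 70) else 12
  if (is.null(sponge_mm)) sponge_mm <- if (shape == "rectangle") 5 else 2
  if (shape == "rectangle" && !orientation %in% c("vertical", "horizontal"))
    stop("rectangle pads need orientation 'vertical' or 'horizontal'",
         call. = FALSE)
  structure(list(position = if (is.null(direction)) position else NA_character_,
                 direction = direction, polarity = polarity, shape = shape,
                 dims_mm = dims_mm, orientation = orientation,
                 sponge_mm = sponge_mm, conductor_mm = conductor_mm),
            class = "electrode_spec")
}

#' @keywords internal
electrode_frame <- function(u0) {
  # local meridian (toward vertex) and parallel (toward the right ear for
  # +y-ish positions); at the poles the nasion axis substitutes
  zhat <- c(0, 0, 1)
  if (abs(sum(u0 * zhat)) > 0.999) {
    m <- c(0, 1, 0)
    m <- normalize3(m - sum(m * u0) * u0)
  } else {
    m <- normalize3(zhat - sum(zhat * u0) * u0)
  }
  list(normal = u0, meridian = m, parallel = cross3(m, u0))
}

#' Stamp an electrode assembly onto the phantom
#'
#' Adds a scalp-conforming sponge (or gel) layer labeled `sponge_or_gel`
#' topped by a metal layer labeled `electrode` over the footprint of the
#' electrode, and records the conductor voxel mask with its polarity in
#' `vol$electrodes`.
#'
#' @param vol A `head_volume`.
#' @param spec An [electrode_spec()].
#' @param name Optional electrode name (defaults to its position label).
#' @return The modified `head_volume`.
#' @export
stamp_electrode <- function(vol, spec, name = NULL) {
  stopifnot(inherits(vol, "head_volume"), inherits(spec, "electrode_spec"))
  codes <- vol$label_codes
  u0 <- if (!is.null(spec$direction)) normalize3(spec$direction)
        else standard_position(spec$position)
  if (is.null(name))
    name <- if (!is.na(spec$position)) spec$position else "electrode"
  centre <- project_to_scalp(u0, vol)
  r0 <- sqrt(sum(centre^2))
  fr <- electrode_frame(u0)
  vs <- vol$voxel_size
  dim <- dim(vol$labels)

  half_extent <- if (spec$shape == "disk") spec$dims_mm[1] / 2
                 else sqrt(sum((spec$dims_mm / 2)^2))
  # layer thicknesses quantized to whole voxels (at least one each) so
  # thin layers survive coarse grids; error <= half a voxel per layer
  sponge_th <- max(1, round(spec$sponge_mm / vs)) * vs
  cond_th <- max(1, round(spec$conductor_mm / vs)) * vs
  depth <- sponge_th + cond_th
  sag <- r0 * (1 - cos(min(half_extent / r0, pi / 2)))  # curvature drop
  pad <- half_extent + depth + sag + 2 * vs

  lo <- pmax(1, floor((centre - pad - vol$origin) / vs) + 1)
  hi <- pmin(dim, ceiling((centre + pad - vol$origin) / vs) + 1)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  ax <- voxel_axes(dim, vs, vol$origin)
  gx <- ax[[1]][ii]; gy <- ax[[2]][jj]; gz <- ax[[3]][kk]
  nb <- c(length(ii), length(jj), length(kk))
  px <- array(rep(gx, times = nb[2] * nb[3]), nb)
  py <- array(rep(rep(gy, each = nb[1]), times = nb[3]), nb)
  pz <- array(rep(gz, each = nb[1] * nb[2]), nb)
  r <- sqrt(px^2 + py^2 + pz^2)
  rr <- pmax(r, 1e-9)
  ux <- px / rr; uy <- py / rr; uz <- pz / rr

  ct <- pmin(1, pmax(-1, ux * fr$normal[1] + uy * fr$normal[2] +
                       uz * fr$normal[3]))
  gam <- acos(ct)
  # lateral extent measured along the assembly's own surface, so a pad
  # keeps its 50 x 70 mm cross-section through the sponge and conductor
  arc <- r * gam
  # tangential components of the direction relative to the centre
  tx <- ux - ct * fr$normal[1]; ty <- uy - ct * fr$normal[2]
  tz <- uz - ct * fr$normal[3]
  tn <- pmax(sqrt(tx^2 + ty^2 + tz^2), 1e-12)
  xi  <- arc * (tx * fr$meridian[1] + ty * fr$meridian[2] +
                  tz * fr$meridian[3]) / tn
  eta <- arc * (tx * fr$parallel[1] + ty * fr$parallel[2] +
                  tz * fr$parallel[3]) / tn

  foot <- if (spec$shape == "disk") {
    arc <= spec$dims_mm[1] / 2
  } else {
    hw <- spec$dims_mm[1] / 2; hl <- spec$dims_mm[2] / 2
    if (spec$orientation == "vertical") abs(xi) <= hl & abs(eta) <= hw
    else                                abs(xi) <= hw & abs(eta) <= hl
  }

  # scalp radius along each direction (analytic shell + perturbation)
  rs <- vol$meta$skin_radius
  if (!is.null(vol$meta$perturb)) {
    uu <- cbind(as.vector(ux), as.vector(uy), as.vector(uz))
    rs <- rs + array(vol$meta$perturb(uu), nb)
  }
  sponge <- foot & r > rs & r <= rs + sponge_th
  cond <- foot & r > rs + sponge_th & r <= rs + depth

  sub_lin <- function(mask) {
    w <- which(mask, arr.ind = TRUE)
    as.integer(ii[w[, 1]] + (jj[w[, 2]] - 1L) * dim[1] +
                 (kk[w[, 3]] - 1L) * dim[1] * dim[2])
  }
  sp_idx <- sub_lin(sponge)
  cd_idx <- sub_lin(cond)
  if (!length(cd_idx) || !length(sp_idx))
    stop("geometry error: electrode footprint produced no voxels",
         call. = FALSE)
  # the assembly must lie strictly inside the grid
  all_idx <- c(sp_idx, cd_idx) - 1L
  iii <- all_idx %% dim[1] + 1L
  jjj <- (all_idx %/% dim[1]) %% dim[2] + 1L
  kkk <- all_idx %/% (dim[1] * dim[2]) + 1L
  if (any(iii == 1L | iii == dim[1] | jjj == 1L | jjj == dim[2] |
          kkk == 1L | kkk == dim[3]))
    stop("geometry error: electrode footprint extends past the grid",
         call. = FALSE)
  cur <- vol$labels[c(sp_idx, cd_idx)]
  if (any(cur == codes[["sponge_or_gel"]] | cur == codes[["electrode"]]))
    stop("placement error: electrode '", name,
         "' overlaps an existing electrode", call. = FALSE)
  keep_sp <- vol$labels[sp_idx] == codes[["air"]]
  keep_cd <- vol$labels[cd_idx] == codes[["air"]]
  sp_idx <- sp_idx[keep_sp]; cd_idx <- cd_idx[keep_cd]
  vol$labels[sp_idx] <- codes[["sponge_or_gel"]]
  vol$labels[cd_idx] <- codes[["electrode"]]
  vol$electrodes[[length(vol$electrodes) + 1L]] <-
    list(name = name, polarity = spec$polarity, conductor_idx = cd_idx,
         sponge_idx = sp_idx, direction = u0, centre = centre)
  vol
}

#' Montage constructor
#'
#' @param name Montage name.
#' @param electrodes List of [electrode_spec()]s; at least one anode and
#'   one cathode.
#' @param total_current_mA Total injected current (mA), default 1.
#' @return A list of class `montage`.
#' @export
montage <- function(name, electrodes, total_current_mA = 1) {
  pol <- vapply(electrodes, function(e) e$polarity, "")
  if (!any(pol == "anode") || !any(pol == "cathode"))
    stop("montage needs at least one anode and one cathode", call. = FALSE)
  structure(list(name = name, electrodes = electrodes,
                 total_current_mA = total_current_mA),
            class = "montage")
}

#' The five named tDCS montages
#'
#' * `M1-SO`: 5x7 cm pads, anode vertical over C3, cathode horizontal over
#'   the contralateral supraorbital region (Fp2).
#' * `DLPFC`: 5x7 cm pads, anode and cathode vertical over F3 and F4.
#' * `Cz-Oz`: 5x7 cm pads, anode centred on the vertex Cz with its long
#'   axis ear to ear, cathode horizontal over Oz.
#' * `HD-4x1`: 12 mm disks, anode on C3, four cathodes on Cz, F3, T7, P3
#'   (surrounding the anode roughly 90 degrees apart in azimuth).
#' * `HD-2x2`: 12 mm disks, anodes on C3 and C5, cathodes on FC3 and FC5.
#'
#' All montages inject 1 mA total current.
#'
#' @param name One of `"M1-SO"`, `"DLPFC"`, `"Cz-Oz"`, `"HD-4x1"`,
#'   `"HD-2x2"`.
#' @return A [montage()].
#' @export
get_montage <- function(name) {
  pad <- function(pos, pol, ori) electrode_spec(pos, pol, "rectangle",
                                                orientation = ori)
  disk <- function(pos, pol) electrode_spec(pos, pol, "disk")
  m <- switch(name,
    "M1-SO" = list(pad("C3", "anode", "vertical"),
                   pad("Fp2", "cathode", "horizontal")),
    "DLPFC" = list(pad("F3", "anode", "vertical"),
                   pad("F4", "cathode", "vertical")),
    "Cz-Oz" = list(pad("Cz", "anode", "horizontal"),
                   pad("Oz", "cathode", "horizontal")),
    "HD-4x1" = list(disk("C3", "anode"), disk("Cz", "cathode"),
                    disk("F3", "cathode"), disk("T7", "cathode"),
                    disk("P3", "cathode")),
    "HD-2x2" = list(disk("C3", "anode"), disk("C5", "anode"),
                    disk("FC3", "cathode"), disk("FC5", "cathode")),
    stop("naming error: unknown montage '", name, "'; valid montages: ",
         "M1-SO, DLPFC, Cz-Oz, HD-4x1, HD-2x2", call. = FALSE)
  )
  montage(name, m)
}

#' Stamp every electrode of a montage
#'
#' @param vol A `head_volume`.
#' @param mont A [montage()].
#' @return The stamped `head_volume`.
#' @export
stamp_montage <- function(vol, mont) {
  stopifnot(inherits(mont, "montage"))
  for (spec in mont$electrodes) vol <- stamp_electrode(vol, spec)
  vol
}

#' Read / write a montage as YAML
#'
#' @param mont A [montage()].
#' @param path File path.
#' @return `read_montage_yaml` returns a [montage()].
#' @export
write_montage_yaml <- function(mont, path) {
  lst <- list(name = mont$name, total_current_mA = mont$total_current_mA,
              electrodes = lapply(mont$electrodes, function(e)
                list(label = e$position, shape = e$shape,
                     dims_mm = as.numeric(e$dims_mm),
                     orientation = e$orientation, polarity = e$polarity,
                     sponge_mm = e$sponge_mm, conductor_mm = e$conductor_mm)))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_montage_yaml
#' @export
read_montage_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  specs <- lapply(lst$electrodes, function(e)
    electrode_spec(e$label, e$polarity, e$shape, dims_mm = e$dims_mm,
                   orientation = e$orientation, sponge_mm = e$sponge_mm,
                   conductor_mm = e$conductor_mm))
  montage(lst$name, specs, lst$total_current_mA)
}
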