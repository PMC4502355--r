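# Analytic potential for point-current electrodes on an N-layer
# concentric sphere, used as the numerical ground truth for the voxel
# solver.
#
# With a point source (+I) and sink (-I) on the outer surface (radius R),
# the potential in layer l is an axisymmetric Legendre series
#   V(r, x) = sum_n R_n(r) [ P_n(cos g_src) - P_n(cos g_snk) ],
#   R_n(r) = A_ln r^n + B_ln r^(-(n+1)),
# where g_* is the angle to the source / sink direction. The coefficients
# are fixed per degree by regularity at the centre (B = 0 innermost),
# continuity of V and of the radial current sigma dV/dr at every
# interface, and the surface flux condition whose degree-n source term is
# (2n+1) I / (4 pi R^2) per point electrode. The n = 0 terms of source
# and sink cancel, so the series runs over n >= 1 and automatically has
# zero mean over the outer surface (the gauge). Radial basis functions
# are scaled per layer ((r/r_l)^n and (r_{l-1}/r)^(n+1)) so that high
# degrees neither overflow nor underflow.

#' Concentric sphere layers
#'
#' @param radii_mm Outer radius of each layer (mm), strictly increasing,
#'   innermost first.
#' @param sigmas Conductivity of each layer (S/m), same length.
#' @return A list of class `sphere_layers`.
#' @export
sphere_layers <- function(radii_mm, sigmas) {
  if (length(radii_mm) != length(sigmas))
    stop("radii and conductivities must have equal length", call. = FALSE)
  if (any(diff(radii_mm) <= 0) || radii_mm[1] <= 0)
    stop("configuration error: radii must be strictly increasing",
         call. = FALSE)
  if (any(sigmas <= 0))
    stop("configuration error: conductivities must be positive",
         call. = FALSE)
  structure(list(radii_mm = radii_mm, sigmas = sigmas),
            class = "sphere_layers")
}

#' Fit the Legendre series for two surface point electrodes
#'
#' @param layers A [sphere_layers()].
#' @param source_dir,sink_dir Unit directions of the +I and -I electrodes.
#' @param I_mA Injected current (mA).
#' @param N Maximum Legendre degree (default 300).
#' @return A `legendre_solution` with per-degree, per-layer coefficients
#'   in the scaled basis.
#' @export
fit_series <- function(layers, source_dir, sink_dir, I_mA = 1, N = 300) {
  stopifnot(inherits(layers, "sphere_layers"))
  if (N < 50) stop("N must be >= 50", call. = FALSE)
  source_dir <- normalize3(source_dir)
  sink_dir <- normalize3(sink_dir)
  r_m <- layers$radii_mm / 1000
  sig <- layers$sigmas
  L <- length(r_m)
  R <- r_m[L]
  I_A <- I_mA / 1000

  # scaled basis in layer l (inner edge a_l, outer edge b_l):
  #   u_l(r) = (r/b_l)^n,  w_l(r) = (a_l/r)^(n+1)  [w unused for l = 1]
  a_edge <- c(0, r_m[-L])
  b_edge <- r_m

  # unknowns: c = (u_1; u_2, w_2; ...; u_L, w_L), 2L-1 of them
  A_coef <- matrix(0, N, L)   # coefficient of u_l per degree
  B_coef <- matrix(0, N, L)   # coefficient of w_l per degree
  for (n in seq_len(N)) {
    M <- matrix(0, 2 * L - 1, 2 * L - 1)
    rhs <- numeric(2 * L - 1)
    ucol <- function(l) if (l == 1) 1L else 2L * (l - 1L)
    wcol <- function(l) 2L * (l - 1L) + 1L
    row <- 0L
    for (l in seq_len(L - 1)) {
      r <- b_edge[l]
      # values and radial derivatives of the scaled basis at the interface
      u_l <- 1; du_l <- n / r
      w_l <- (a_edge[l] / r)^(n + 1); dw_l <- -(n + 1) / r * w_l
      u_r <- (r / b_edge[l + 1])^n; du_r <- n / r * u_r
      w_r <- 1; dw_r <- -(n + 1) / r
      row <- row + 1L   # potential continuity
      M[row, ucol(l)] <- u_l
      if (l > 1) M[row, wcol(l)] <- w_l
      M[row, ucol(l + 1)] <- -u_r
      M[row, wcol(l + 1)] <- -w_r
      row <- row + 1L   # radial current continuity
      M[row, ucol(l)] <- sig[l] * du_l
      if (l > 1) M[row, wcol(l)] <- sig[l] * dw_l
      M[row, ucol(l + 1)] <- -sig[l + 1] * du_r
      M[row, wcol(l + 1)] <- -sig[l + 1] * dw_r
    }
    row <- row + 1L     # outer surface flux
    M[row, ucol(L)] <- sig[L] * n / R
    if (L > 1) M[row, wcol(L)] <- sig[L] * (-(n + 1) / R) * (a_edge[L] / R)^(n + 1)
    rhs[row] <- (2 * n + 1) * I_A / (4 * pi * R^2)
    cf <- solve(M, rhs)
    A_coef[n, 1] <- cf[1]
    if (L > 1) {
      A_coef[n, 2:L] <- cf[2L * (2:L - 1L)]
      B_coef[n, 2:L] <- cf[2L * (2:L - 1L) + 1L]
    }
  }
  structure(list(layers = layers, A = A_coef, B = B_coef, N = N,
                 source_dir = source_dir, sink_dir = sink_dir, I_mA = I_mA,
                 a_edge_m = a_edge, b_edge_m = b_edge),
            class = "legendre_solution")
}

# Legendre polynomials P_1..P_N at a vector x: matrix length(x) x N.
#' @keywords internal
legendre_matrix <- function(x, N) {
  out <- matrix(0, length(x), N)
  pm1 <- rep(1, length(x))
  p <- x
  out[, 1] <- p
  for (n in 1:(N - 1)) {
    pn1 <- ((2 * n + 1) * x * p - n * pm1) / (n + 1)
    pm1 <- p
    p <- pn1
    out[, n + 1] <- p
  }
  out
}

#' Evaluate the analytic potential
#'
#' @param sol A `legendre_solution`.
#' @param points n x 3 matrix (or length-3 vector) of world points in mm;
#'   all must lie inside the outer radius.
#' @return Potential in volts at each point.
#' @export
oracle_potential <- function(sol, points) {
  stopifnot(inherits(sol, "legendre_solution"))
  if (is.null(dim(points))) points <- matrix(points, 1)
  p_m <- points / 1000
  r <- sqrt(rowSums(p_m^2))
  R <- sol$b_edge_m[length(sol$b_edge_m)]
  if (any(r > R * (1 + 1e-9)))
    stop("domain error: point outside the sphere", call. = FALSE)
  layer <- findInterval(r, sol$b_edge_m, left.open = TRUE) + 1L
  layer[layer > length(sol$b_edge_m)] <- length(sol$b_edge_m)

  rr <- pmax(r, 1e-12)
  cs <- (p_m %*% sol$source_dir) / rr
  ck <- (p_m %*% sol$sink_dir) / rr
  cs <- pmin(1, pmax(-1, cs)); ck <- pmin(1, pmax(-1, ck))
  N <- sol$N
  Ps <- legendre_matrix(as.vector(cs), N)
  Pk <- legendre_matrix(as.vector(ck), N)

  V <- numeric(nrow(p_m))
  for (l in sort(unique(layer))) {
    m <- layer == l
    rl <- r[m]
    # radial functions, vectorised over degree via outer powers
    nn <- seq_len(N)
    lu <- outer(log(pmax(rl, 1e-300) / sol$b_edge_m[l]), nn)
    U <- exp(lu)                       # (r/b_l)^n
    if (l > 1) {
      lw <- outer(log(sol$a_edge_m[l] / rl), nn + 1)
      W <- exp(lw)
    } else W <- 0
    Rn <- U * rep(sol$A[, l], each = sum(m))
    if (l > 1) Rn <- Rn + W * rep(sol$B[, l], each = sum(m))
    V[m] <- rowSums(Rn * (Ps[m, , drop = FALSE] - Pk[m, , drop = FALSE]))
  }
  # at the exact centre only n = 1 could contribute; r -> 0 handled above
  V
}

#' Analytic electric field by high-order differencing
#'
#' Central differences of [oracle_potential()] with a small step; the
#' series itself is smooth, so a 0.05 mm step leaves a relative error far
#' below the voxel-solver errors this oracle is used to measure.
#'
#' @param sol A `legendre_solution`.
#' @param points n x 3 matrix of world points (mm), strictly inside the
#'   sphere by more than `h_mm`.
#' @param h_mm Differencing step (mm).
#' @return n x 3 matrix of E (V/m).
#' @export
oracle_efield <- function(sol, points, h_mm = 0.05) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  E <- matrix(0, nrow(points), 3)
  h_m <- h_mm / 1000
  for (ax in 1:3) {
    dp <- points; dp[, ax] <- dp[, ax] + h_mm
    dm <- points; dm[, ax] <- dm[, ax] - h_mm
    E[, ax] <- -(oracle_potential(sol, dp) - oracle_potential(sol, dm)) /
      (2 * h_m)
  }
  E
}

#' Validate the voxel solver against the sphere oracle
#'
#' Builds the voxel phantom matching `layers`, stamps two small disk
#' electrodes at the given angular separation (symmetric about +z), solves
#' at 1 mA, and compares |E| with the analytic series on a mid-shell
#' sample of the target layer, excluding polar caps under each electrode
#' where a disk and a point electrode legitimately differ.
#'
#' @param layers A [sphere_layers()]; the target layer for comparison is
#'   `compare_layer` (default: innermost-but-one, i.e. the gray shell of a
#'   white/gray/CSF/skull/skin head).
#' @param separation_deg Angular separation of the two electrodes.
#' @param voxel_size Voxel edge (mm).
#' @param disk_diameter_mm Disk electrode diameter (default 8).
#' @param n_samples Number of sample points on the comparison shell.
#' @param exclude_cap_deg Half-angle of the excluded caps (default 20).
#' @param compare_radius_mm Radius of the comparison shell; defaults to
#'   the middle of `compare_layer`.
#' @param compare_layer Index of the layer whose mid-shell is sampled.
#' @param N Legendre degree for the oracle.
#' @param rel_tol Solver tolerance.
#' @return List with `median_rel_err`, `p90_rel_err`, `n_points`, and the
#'   per-point errors.
#' @export
validate_solver <- function(layers, separation_deg = 90, voxel_size = 2,
                            disk_diameter_mm = 8, n_samples = 2000,
                            exclude_cap_deg = 20, compare_radius_mm = NULL,
                            compare_layer = NULL, N = 300, rel_tol = 1e-8) {
  stopifnot(inherits(layers, "sphere_layers"))
  L <- length(layers$radii_mm)
  if (is.null(compare_layer)) compare_layer <- max(1L, L - 3L)
  if (is.null(compare_radius_mm)) {
    inner <- if (compare_layer == 1) 0 else layers$radii_mm[compare_layer - 1]
    compare_radius_mm <- (inner + layers$radii_mm[compare_layer]) / 2
  }
  half <- separation_deg / 2 * pi / 180
  d1 <- c(sin(half), 0, cos(half))
  d2 <- c(-sin(half), 0, cos(half))

  vol <- build_layer_volume(layers, voxel_size)
  gel <- 1.4
  table <- c(vol$sigma_table, sponge_or_gel = gel,
             electrode = 5.99e7)
  vol$meta$skin_radius <- max(layers$radii_mm)
  spec1 <- electrode_spec(NA, "anode", "disk", dims_mm = disk_diameter_mm,
                          sponge_mm = 2, direction = d1)
  spec2 <- electrode_spec(NA, "cathode", "disk", dims_mm = disk_diameter_mm,
                          sponge_mm = 2, direction = d2)
  vol <- stamp_electrode(vol, spec1, name = "src")
  vol <- stamp_electrode(vol, spec2, name = "snk")
  sigma <- assign_conductivity(vol, table)
  an <- vol$electrodes[[1]]$conductor_idx
  ca <- vol$electrodes[[2]]$conductor_idx
  sys <- assemble_system(sigma, list(anode_idx = an, cathode_idx = ca),
                         voxel_size, check_topology = FALSE)
  sol <- compute_efield(solve_potential(sys, 1, rel_tol))

  dirs <- fibonacci_sphere(n_samples)
  keep <- acos(pmin(1, pmax(-1, dirs %*% d1))) > exclude_cap_deg * pi / 180 &
    acos(pmin(1, pmax(-1, dirs %*% d2))) > exclude_cap_deg * pi / 180
  pts <- dirs[keep, , drop = FALSE] * compare_radius_mm

  osol <- fit_series(layers, d1, d2, I_mA = 1, N = N)
  Eo <- oracle_efield(osol, pts)
  Eo_mag <- sqrt(rowSums(Eo^2))
  Ev <- sapply(1:3, function(ax)
    trilinear(sol$E[, , , ax], pts, voxel_size, vol$origin))
  Ev_mag <- sqrt(rowSums(Ev^2))
  ok <- !is.na(Ev_mag) & Eo_mag > 0
  rel <- abs(Ev_mag[ok] - Eo_mag[ok]) / Eo_mag[ok]
  list(median_rel_err = stats::median(rel),
       p90_rel_err = stats::quantile(rel, 0.9, names = FALSE),
       n_points = sum(ok), rel_err = rel,
       diagnostics = sol$diagnostics)
}

# voxelize an arbitrary layered sphere as a head_volume-compatible object;
# layer l gets label code l (air = 0); sigma_table maps "L<l>" -> sigma
#' @keywords internal
build_layer_volume <- function(layers, voxel_size, margin_mm = 10) {
  radii <- layers$radii_mm
  half <- ceiling((max(radii) + margin_mm) / voxel_size)
  n <- 2L * half + 1L
  dim <- c(n, n, n)
  origin <- rep(-half * voxel_size, 3)
  r <- sqrt(radius2_array(dim, voxel_size, origin))
  labels <- array(0L, dim)
  for (l in rev(seq_along(radii))) labels[r <= radii[l]] <- l
  codes <- c(air = 0L, stats::setNames(seq_along(radii),
                                       paste0("L", seq_along(radii))),
             sponge_or_gel = length(radii) + 1L,
             electrode = length(radii) + 2L)
  # skin code alias so project_to_scalp finds the outermost layer
  codes[["skin"]] <- length(radii)
  sigma_table <- stats::setNames(layers$sigmas, paste0("L", seq_along(radii)))
  sigma_table[["skin"]] <- layers$sigmas[length(radii)]
  structure(list(labels = labels, voxel_size = voxel_size, origin = origin,
                 label_codes = codes,
                 meta = list(layer_radii = radii, perturb = NULL,
                             skin_radius = max(radii)),
                 electrodes = list(), sigma_table = sigma_table),
            class = "head_volume")
}
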