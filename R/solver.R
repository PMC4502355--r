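# Finite-volume discretization and conjugate-gradient solution of the
# quasi-static continuity equation div(sigma grad V) = 0 on the voxel
# grid.
#
# Each voxel is a control volume; the conductance of the face between two
# neighbouring conductive voxels is the harmonic mean of their
# conductivities times face-area / spacing (for isotropic voxels of edge
# h this is h * 2*s1*s2/(s1+s2), in siemens with h in metres). Air voxels
# are excluded from the domain, which realises the insulated outer
# boundary; electrode-metal voxels are Dirichlet nodes (the metal is
# essentially equipotential at 5.99e7 S/m, and the harmonic mean then
# reduces to the half-cell conductance of the tissue side of the contact
# face). The anode set is held at a provisional 1 V, the cathodes at 0 V,
# and the solved potential is rescaled linearly so that the delivered
# current equals the requested total current - valid because the problem
# is linear. With several anodes or cathodes the current split between
# them emerges from the equipotential condition rather than being
# prescribed.

#' Assemble the discrete volume-conductor system
#'
#' @param sigma 3-D conductivity array (S/m); `NA` marks air (excluded).
#' @param electrode_masks List with integer vectors `anode_idx` and
#'   `cathode_idx` of linear voxel indices held at the provisional anode /
#'   cathode potentials (e.g. pooled `conductor_idx` from
#'   `vol$electrodes`).
#' @param voxel_size Voxel edge length (mm).
#' @param check_topology If `TRUE`, verify that the cathode is reachable
#'   from the anode through conductive voxels (flood fill) and raise a
#'   topology error otherwise.
#' @return A `linear_system` list: sparse SPD operator `A` over the
#'   unknowns, right-hand side `b`, index maps, and geometry.
#' @export
assemble_system <- function(sigma, electrode_masks, voxel_size,
                            check_topology = TRUE) {
  dim <- dim(sigma)
  an <- electrode_masks$anode_idx
  ca <- electrode_masks$cathode_idx
  if (!length(an) || !length(ca))
    stop("montage error: empty anode or cathode mask", call. = FALSE)
  if (length(intersect(an, ca)))
    stop("montage error: anode and cathode masks overlap", call. = FALSE)
  cond <- !is.na(sigma)
  if (!all(cond[an]) || !all(cond[ca]))
    stop("montage error: electrode voxels must be conductive", call. = FALSE)

  if (check_topology) {
    seed <- array(FALSE, dim); seed[an] <- TRUE
    reach <- flood_fill6(cond, seed)
    if (!any(reach[ca]))
      stop("topology error: no conductive path between anode and cathode",
           call. = FALSE)
  }

  dirichlet <- array(FALSE, dim)
  dirichlet[an] <- TRUE
  dirichlet[ca] <- TRUE
  vdir <- array(0, dim)
  vdir[an] <- 1

  unknown <- cond & !dirichlet
  n_unk <- sum(unknown)
  if (n_unk == 0) stop("montage error: no interior unknowns", call. = FALSE)
  umap <- array(0L, dim)
  umap[unknown] <- seq_len(n_unk)

  h_m <- voxel_size / 1000
  n12 <- dim[1] * dim[2]
  strides <- c(1L, dim[1], n12)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(n_unk)
  b <- numeric(n_unk)

  lin_all <- seq_len(prod(dim))
  for (ax in 1:3) {
    # faces between voxel p and neighbour p + e_ax
    keep <- slice.index(sigma, ax) < dim[ax]
    p <- lin_all[keep]
    q <- p + strides[ax]
    both <- cond[p] & cond[q]
    p <- p[both]; q <- q[both]
    g <- h_m * 2 * sigma[p] * sigma[q] / (sigma[p] + sigma[q])

    up <- umap[p]; uq <- umap[q]
    # unknown-unknown faces
    m <- up > 0L & uq > 0L
    ii <- c(ii, up[m], uq[m]); jj <- c(jj, uq[m], up[m]); xx <- c(xx, g[m], g[m])
    acc <- rowsum(c(g[m], g[m]), c(up[m], uq[m]))
    diag_acc[as.integer(rownames(acc))] <- diag_acc[as.integer(rownames(acc))] + acc
    # unknown-Dirichlet faces contribute to diagonal and RHS
    m1 <- up > 0L & uq == 0L & dirichlet[q]
    if (any(m1)) {
      a <- rowsum(g[m1], up[m1]); r <- as.integer(rownames(a))
      diag_acc[r] <- diag_acc[r] + a
      bb <- rowsum(g[m1] * vdir[q[m1]], up[m1])
      b[as.integer(rownames(bb))] <- b[as.integer(rownames(bb))] + bb
    }
    m2 <- uq > 0L & up == 0L & dirichlet[p]
    if (any(m2)) {
      a <- rowsum(g[m2], uq[m2]); r <- as.integer(rownames(a))
      diag_acc[r] <- diag_acc[r] + a
      bb <- rowsum(g[m2] * vdir[p[m2]], uq[m2])
      b[as.integer(rownames(bb))] <- b[as.integer(rownames(bb))] + bb
    }
  }

  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n_unk)),
                            j = c(jj, seq_len(n_unk)),
                            x = c(-xx, diag_acc),
                            dims = c(n_unk, n_unk))
  structure(list(A = A, b = b, umap = umap, unknown = unknown,
                 dirichlet = dirichlet, vdir = vdir, sigma = sigma,
                 cond = cond, dim = dim, voxel_size = voxel_size,
                 anode_idx = an, cathode_idx = ca),
            class = "linear_system")
}

# Jacobi-preconditioned conjugate gradients; deterministic.
#' @keywords internal
pcg <- function(A, b, rel_tol, max_iter) {
  n <- length(b)
  dinv <- 1 / Matrix::diag(A)
  x <- numeric(n)
  r <- b
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = x, iterations = 0L, rel_residual = 0))
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(max_iter)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / bnorm
    if (res <= rel_tol)
      return(list(x = x, iterations = it, rel_residual = res))
    z <- dinv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, iterations = max_iter, rel_residual = res, converged = FALSE)
}

#' Solve for the electric potential
#'
#' Solves the assembled system with conjugate gradients, integrates the
#' current delivered through the anode contact, and rescales the potential
#' so that the delivered current equals `total_current_mA` exactly (the
#' problem is linear in the boundary values).
#'
#' @param system A `linear_system` from [assemble_system()].
#' @param total_current_mA Total injected current (mA).
#' @param rel_tol Relative residual tolerance (default 1e-8).
#' @param max_iter Iteration cap; defaults to `50 * n^(1/3)` with a floor
#'   of 2000.
#' @return A `field_solution` with the potential `V` (volts; `NA` outside
#'   the conductive domain), conductivity, geometry and solver
#'   diagnostics. `E` and `J` are added by [compute_efield()] and
#'   [compute_current_density()].
#' @export
solve_potential <- function(system, total_current_mA = 1, rel_tol = 1e-8,
                            max_iter = NULL) {
  stopifnot(inherits(system, "linear_system"))
  if (!(rel_tol > 0 && rel_tol <= 1e-4))
    stop("rel_tol must be in (0, 1e-4]", call. = FALSE)
  n <- length(system$b)
  if (is.null(max_iter)) max_iter <- max(2000L, ceiling(50 * n^(1 / 3)))
  sol <- pcg(system$A, system$b, rel_tol, max_iter)
  if (isFALSE(sol$converged))
    stop("convergence error: relative residual ", format(sol$rel_residual),
         " after ", sol$iterations, " iterations", call. = FALSE)

  V <- array(NA_real_, system$dim)
  V[system$unknown] <- sol$x
  V[system$anode_idx] <- 1
  V[system$cathode_idx] <- 0

  I_del <- electrode_current(V, system, system$anode_idx)     # amps
  scale <- (total_current_mA / 1000) / I_del
  V <- V * scale

  structure(list(V = V, sigma = system$sigma, cond = system$cond,
                 dim = system$dim, voxel_size = system$voxel_size,
                 anode_idx = system$anode_idx,
                 cathode_idx = system$cathode_idx,
                 diagnostics = list(iterations = sol$iterations,
                                    rel_residual = sol$rel_residual,
                                    scale_factor = scale,
                                    delivered_mA = total_current_mA,
                                    unknowns = n)),
            class = "field_solution")
}

# Net current (amps) flowing out of a set of Dirichlet voxels into the
# rest of the conductive domain.
#' @keywords internal
electrode_current <- function(V, system, idx) {
  dim <- system$dim
  h_m <- system$voxel_size / 1000
  inset <- array(FALSE, dim); inset[idx] <- TRUE
  strides <- c(1L, dim[1], dim[1] * dim[2])
  total <- 0
  lin_all <- seq_len(prod(dim))
  sigma <- system$sigma
  for (ax in 1:3) {
    keep <- slice.index(sigma, ax) < dim[ax]
    p <- lin_all[keep]; q <- p + strides[ax]
    m <- system$cond[p] & system$cond[q] & xor(inset[p], inset[q])
    p <- p[m]; q <- q[m]
    if (!length(p)) next
    g <- h_m * 2 * sigma[p] * sigma[q] / (sigma[p] + sigma[q])
    sgn <- ifelse(inset[p], 1, -1)
    total <- total + sum(sgn * g * (V[p] - V[q]))
  }
  total
}

#' Electric field from the potential
#'
#' E = -grad V by central differences in the interior of the conductive
#' domain and one-sided differences where a neighbour is missing (air or
#' grid edge). Units V/m.
#'
#' @param solution A `field_solution` (or a bare potential array via
#'   `V`/`voxel_size`).
#' @return The solution with a 4-D array `E` (`dim x 3`) and `Emag` added.
#' @export
compute_efield <- function(solution) {
  stopifnot(inherits(solution, "field_solution"))
  V <- solution$V
  dim <- solution$dim
  h_m <- solution$voxel_size / 1000
  E <- array(0, c(dim, 3))
  for (ax in 1:3) {
    Vp <- shift_arr(V, ax, -1L)   # value at index+1
    Vm <- shift_arr(V, ax, +1L)   # value at index-1
    ok_p <- !is.na(Vp); ok_m <- !is.na(Vm); ok_0 <- !is.na(V)
    d <- array(NA_real_, dim)
    c2 <- ok_p & ok_m
    d[c2] <- (Vp[c2] - Vm[c2]) / (2 * h_m)
    f1 <- ok_p & !ok_m & ok_0
    d[f1] <- (Vp[f1] - V[f1]) / h_m
    b1 <- !ok_p & ok_m & ok_0
    d[b1] <- (V[b1] - Vm[b1]) / h_m
    d[ok_0 & !ok_p & !ok_m] <- 0
    E[, , , ax] <- -d
  }
  solution$E <- E
  solution$Emag <- sqrt(E[, , , 1]^2 + E[, , , 2]^2 + E[, , , 3]^2)
  solution
}

# shift an array along axis `ax` by `by` voxels (by = +1 moves values to
# higher indices), padding with NA
#' @keywords internal
shift_arr <- function(a, ax, by) {
  dim <- dim(a)
  out <- array(NA_real_, dim)
  idx_src <- lapply(dim, seq_len)
  idx_dst <- idx_src
  if (by > 0) {
    idx_dst[[ax]] <- (1 + by):dim[ax]
    idx_src[[ax]] <- 1:(dim[ax] - by)
  } else if (by < 0) {
    idx_dst[[ax]] <- 1:(dim[ax] + by)
    idx_src[[ax]] <- (1 - by):dim[ax]
  }
  do.call(`[<-`, c(list(out), idx_dst, list(do.call(`[`, c(list(a), idx_src)))))
}

#' Current density from the electric field
#'
#' J = sigma * E voxelwise (A/m^2). Note that the physically consistent
#' relation is J = sigma E (Ohm's law); a field of 0.18 V/m in tissue of
#' 0.126 S/m carries 0.0227 A/m^2.
#'
#' @param solution A `field_solution` with `E` computed.
#' @return The solution with `J` (4-D) and `Jmag` added.
#' @export
compute_current_density <- function(solution) {
  stopifnot(inherits(solution, "field_solution"), !is.null(solution$E))
  s <- solution$sigma
  s[is.na(s)] <- 0
  J <- solution$E * as.vector(s)
  solution$J <- J
  solution$Jmag <- solution$Emag * s
  solution
}

#' Current through a separating surface
#'
#' Discrete flux of J through the boundary of a voxel region: the sum of
#' face currents from voxels inside `region` to conductive voxels outside
#' it. For a region containing the anode (and not the cathode) this
#' returns the injected current.
#'
#' @param solution A `field_solution`.
#' @param region Logical array (same dims) defining the inside of the
#'   surface.
#' @return Current in mA.
#' @export
surface_current <- function(solution, region) {
  stopifnot(inherits(solution, "field_solution"))
  if (!identical(dim(region), solution$dim))
    stop("geometry error: region dimensions do not match the solution",
         call. = FALSE)
  sys <- list(dim = solution$dim, voxel_size = solution$voxel_size,
              sigma = solution$sigma, cond = solution$cond)
  electrode_current(solution$V, sys, which(region)) * 1000
}

#' Solve a montage end to end on a phantom
#'
#' Stamps the montage onto a copy of the phantom, assigns conductivities,
#' assembles and solves the system, and derives E and J.
#'
#' @param vol An unstamped `head_volume`.
#' @param mont A [montage()] or montage name.
#' @param table Conductivity table.
#' @param rel_tol Solver tolerance.
#' @param check_topology Passed to [assemble_system()].
#' @return A `field_solution` (with `montage`, `labels` and electrode
#'   masks attached).
#' @export
solve_montage <- function(vol, mont, table = tissue_table(),
                          rel_tol = 1e-8, check_topology = FALSE) {
  if (is.character(mont)) mont <- get_montage(mont)
  stamped <- stamp_montage(vol, mont)
  sigma <- assign_conductivity(stamped, table)
  an <- unlist(lapply(stamped$electrodes,
                      function(e) if (e$polarity == "anode") e$conductor_idx))
  ca <- unlist(lapply(stamped$electrodes,
                      function(e) if (e$polarity == "cathode") e$conductor_idx))
  sys <- assemble_system(sigma, list(anode_idx = an, cathode_idx = ca),
                         stamped$voxel_size, check_topology = check_topology)
  sol <- solve_potential(sys, mont$total_current_mA, rel_tol)
  sol <- compute_current_density(compute_efield(sol))
  # current split between electrodes (emerges from the equipotential
  # condition rather than being prescribed)
  sol$diagnostics$electrode_mA <- vapply(stamped$electrodes, function(e)
    electrode_current(sol$V, sol, e$conductor_idx) * 1000, 0)
  names(sol$diagnostics$electrode_mA) <-
    vapply(stamped$electrodes, function(e) e$name, "")
  sol$montage <- mont$name
  sol$labels <- stamped$labels
  sol$label_codes <- stamped$label_codes
  sol$origin <- stamped$origin
  sol$electrodes <- stamped$electrodes
  sol
}
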