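# Finite-volume assembly, conjugate-gradient solve, field derivation.

test_that("assembly conserves flux and uses harmonic-mean faces", {
  sys <- column_system(rep(1, 10))
  # interior rows (no Dirichlet neighbour) sum to zero: pure flux balance;
  # unknowns are ordered along the column, ends touch the electrodes
  rs <- Matrix::rowSums(sys$A)
  expect_lt(max(abs(rs[2:9])), 1e-18)
  # two-material interface: face conductance is the harmonic mean
  sys2 <- column_system(c(1, 0.5))
  A <- as.matrix(sys2$A)
  # off-diagonal between the two tissue unknowns = -h * 2*s1*s2/(s1+s2)
  expect_equal(A[1, 2], -0.001 * 2 * 1 * 0.5 / (1 + 0.5))
})

test_that("a column with an air gap raises a topology error", {
  sig <- array(NA_real_, c(12, 3, 3))
  sig[2:11, 2, 2] <- 1
  sig[6, 2, 2] <- NA          # air gap
  sig[1, 2, 2] <- 5.99e7
  sig[12, 2, 2] <- 5.99e7
  lin <- function(i) i + 12 + 12 * 3
  expect_error(assemble_system(sig, list(anode_idx = lin(1),
                                         cathode_idx = lin(12)), 1),
               "topology error")
  expect_error(assemble_system(sig, list(anode_idx = integer(0),
                                         cathode_idx = lin(12)), 1),
               "montage error")
})

test_that("the solved column obeys Ohm's law and series resistance", {
  # 10 mm uniform column, sigma = 1 S/m, area 1 mm^2, 1 mA -> 10 V
  sol <- solve_potential(column_system(rep(1, 10)), 1)
  dV <- max(sol$V, na.rm = TRUE) - min(sol$V, na.rm = TRUE)
  expect_equal(dV, 10, tolerance = 1e-7)
  # series halves sigma = 1 then 0.5: drops split 1:2
  sol2 <- solve_potential(column_system(c(rep(1, 5), rep(0.5, 5))), 1)
  expect_equal(max(sol2$V, na.rm = TRUE), 15, tolerance = 1e-7)
  v <- sol2$V[2:11, 2, 2]
  # analytic piecewise-linear potential at voxel centres (anode side 1 S/m)
  expect_equal(v[1], 15 - 0.5, tolerance = 1e-6)
  expect_equal(v[10], 1, tolerance = 1e-6)
})

test_that("solutions scale exactly linearly with injected current", {
  sys <- column_system(c(rep(1, 5), rep(0.5, 5)))
  v1 <- solve_potential(sys, 1)$V
  v2 <- solve_potential(sys, 2)$V
  expect_identical(v2, 2 * v1)
})

test_that("swapping anode and cathode negates the field", {
  vol <- phantom_4mm()
  sigma <- assign_conductivity(vol)
  s1 <- stamp_electrode(vol, electrode_spec("C3", "anode", "disk"))
  s1 <- stamp_electrode(s1, electrode_spec("Cz", "cathode", "disk"))
  sigma <- assign_conductivity(s1)
  an <- s1$electrodes[[1]]$conductor_idx
  ca <- s1$electrodes[[2]]$conductor_idx
  sysA <- assemble_system(sigma, list(anode_idx = an, cathode_idx = ca), 4,
                          check_topology = FALSE)
  sysB <- assemble_system(sigma, list(anode_idx = ca, cathode_idx = an), 4,
                          check_topology = FALSE)
  a <- compute_efield(solve_potential(sysA, 1))
  b <- compute_efield(solve_potential(sysB, 1))
  scale <- max(abs(a$E), na.rm = TRUE)
  expect_lt(max(abs(a$E + b$E), na.rm = TRUE) / scale, 1e-5)
})

test_that("electric field differentiation is second-order accurate", {
  # cubic potential on a uniform cube: interior central differences give
  # a Richardson error ratio ~4 when the spacing halves
  err_at <- function(h) {
    n <- round(20 / h) + 1
    x <- (seq_len(n) - 1) * h / 1000   # metres
    V <- array(rep(x^3, times = n * n), c(n, n, n)) * 1e6
    sol <- structure(list(V = V, dim = c(n, n, n), voxel_size = h,
                          sigma = array(1, c(n, n, n))),
                     class = "field_solution")
    sol <- compute_efield(sol)
    i <- 2:(n - 1)
    max(abs(sol$E[i, 2, 2, 1] - (-3e6 * x[i]^2)))
  }
  ratio <- err_at(2) / err_at(1)
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 4.5)
  # linear potential: constant field, exact
  n <- 11
  V <- array(rep(-(seq_len(n) - 1) * 0.001, times = n * n), c(n, n, n))
  sol <- structure(list(V = V, dim = c(n, n, n), voxel_size = 1,
                        sigma = array(1, c(n, n, n))),
                   class = "field_solution")
  sol <- compute_efield(sol)
  expect_equal(unique(round(as.vector(sol$E[, , , 1]), 9)), 1)
  expect_true(all(sol$E[, , , 2] == 0))
})

test_that("current density follows J = sigma E", {
  n <- 5
  sol <- structure(list(V = array(0, c(n, n, n)), dim = c(n, n, n),
                        voxel_size = 1,
                        sigma = array(0.126, c(n, n, n))),
                   class = "field_solution")
  sol$E <- array(0, c(n, n, n, 3))
  sol$E[, , , 1] <- 0.18
  sol$Emag <- sqrt(sol$E[, , , 1]^2 + sol$E[, , , 2]^2 + sol$E[, , , 3]^2)
  sol <- compute_current_density(sol)
  expect_equal(unique(as.vector(sol$Jmag)), 0.18 * 0.126)
  expect_equal(round(unique(as.vector(sol$Jmag)), 4), 0.0227)
  sol$E[] <- 0
  sol$Emag[] <- 0
  sol <- compute_current_density(sol)
  expect_true(all(sol$Jmag == 0))
  sol$Emag[] <- 1
  sol$sigma[] <- 0.276
  sol <- compute_current_density(sol)
  expect_equal(unique(as.vector(sol$Jmag)), 0.276)
})

test_that("flux through separating surfaces equals the injected current", {
  sys <- column_system(c(rep(1, 5), rep(0.5, 5)))
  sol <- solve_potential(sys, 1)
  region <- array(FALSE, sys$dim)
  region[1:6, , ] <- TRUE     # cuts the column mid-way
  expect_equal(surface_current(sol, region), 1, tolerance = 1e-6)
  # region containing both electrodes: zero net flux
  all_reg <- array(TRUE, sys$dim)
  expect_equal(surface_current(sol, all_reg), 0, tolerance = 1e-9)
  expect_error(surface_current(sol, array(TRUE, c(2, 2, 2))),
               "geometry error")
})

test_that("multi-electrode current split emerges from equipotential", {
  sols <- montage_solutions()
  hd <- sols[["HD-4x1"]]
  iel <- hd$diagnostics$electrode_mA
  expect_equal(unname(iel["C3"]), 1, tolerance = 0.005)
  cat_names <- c("Cz", "F3", "T7", "P3")
  expect_equal(sum(iel[cat_names]), -1, tolerance = 0.005)
  # every cathode takes a nontrivial share
  expect_true(all(iel[cat_names] < -0.05))
})
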