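# Layered-sphere head phantom: tissue table, geometry, ROIs.

test_that("tissue conductivity table holds the model's values", {
  tab <- tissue_table()
  expect_equal(tab[["skin"]], 0.465)
  expect_equal(tab[["fat"]], 0.025)
  expect_equal(tab[["skull"]], 0.01)
  expect_equal(tab[["CSF"]], 1.65)
  expect_equal(tab[["gray"]], 0.276)
  expect_equal(tab[["white"]], 0.126)
  expect_equal(tab[["air"]], 1e-15)
  expect_equal(tab[["sponge_or_gel"]], 1.4)
  expect_equal(tab[["electrode"]], 5.99e7)
  expect_true(all(tab > 0))
  non_electrode <- tab[setdiff(names(tab), "electrode")]
  expect_equal(names(which.max(non_electrode)), "CSF")
})

test_that("phantom configuration rejects invalid geometry", {
  expect_error(phantom_config(layer_radii = c(white = 70, gray = 60,
                                              CSF = 76, skull = 83,
                                              fat = 85, skin = 92)),
               "strictly increasing")
  expect_error(phantom_config(voxel_size = 4), "thinnest layer")
})

test_that("phantom labels respect the concentric geometry", {
  vol <- phantom_2mm()
  codes <- vol$label_codes
  at <- function(p) {
    i <- round((p - vol$origin) / vol$voxel_size) + 1
    vol$labels[i[1], i[2], i[3]]
  }
  expect_equal(at(c(0, 0, 0)), codes[["white"]])
  expect_equal(at(c(0, 0, 100)), codes[["air"]])
  # skull shell voxel count within 2% of the analytic shell volume
  n_skull <- sum(vol$labels == codes[["skull"]])
  analytic <- 4 / 3 * pi * (83^3 - 76^3) / vol$voxel_size^3
  expect_lt(abs(n_skull / analytic - 1), 0.02)
})

test_that("tissue codes appear in radial order along random rays", {
  vol <- phantom_2mm()
  codes <- vol$label_codes
  rank <- rep(NA_integer_, max(codes) + 1)
  order_names <- c("white", "gray", "CSF", "skull", "fat", "skin", "air")
  for (i in seq_along(order_names))
    rank[codes[[order_names[i]]] + 1] <- i
  set.seed(42)
  dirs <- matrix(rnorm(3000), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  radii <- seq(0, 100, by = vol$voxel_size / 2)
  bad <- 0L
  for (k in seq_len(nrow(dirs))) {
    pts <- outer(radii, dirs[k, ])
    lin <- fieldlab:::nearest_linear_index(pts, dim(vol$labels),
                                           vol$voxel_size, vol$origin)
    labs <- vol$labels[lin[!is.na(lin)]]
    if (any(diff(rank[labs + 1]) < 0)) bad <- bad + 1L
  }
  expect_equal(bad, 0L)
})

test_that("shell voxel volumes converge to analytic volumes", {
  radii <- thick_radii
  err <- sapply(c(4, 2, 1), function(h) {
    v <- build_phantom(phantom_config(layer_radii = radii, voxel_size = h))
    sapply(names(radii), function(nm) {
      lo <- if (nm == "white") 0 else radii[which(names(radii) == nm) - 1]
      vol_an <- 4 / 3 * pi * (radii[[nm]]^3 - lo^3)
      abs(sum(v$labels == v$label_codes[[nm]]) * h^3 / vol_an - 1)
    })
  })
  # worst-shell error shrinks monotonically under refinement
  worst <- apply(err, 2, max)
  expect_true(all(diff(worst) < 0))
  expect_lt(worst[2], 0.005)   # 2 mm: all shells within 0.5%
})

test_that("phantom generation is deterministic given config and seed", {
  cfg <- phantom_config(voxel_size = 2, perturb_amp_mm = 1, seed = 7)
  v1 <- build_phantom(cfg)
  v2 <- build_phantom(cfg)
  expect_identical(v1$labels, v2$labels)
  v3 <- build_phantom(phantom_config(voxel_size = 2, perturb_amp_mm = 1,
                                     seed = 8))
  expect_false(identical(v1$labels, v3$labels))
})

test_that("non-air voxels form a single 6-connected component", {
  vol <- phantom_2mm()
  nonair <- vol$labels != vol$label_codes[["air"]]
  seed <- array(FALSE, dim(nonair))
  seed[round(dim(nonair) / 2)[1], round(dim(nonair) / 2)[2],
       round(dim(nonair) / 2)[3]] <- TRUE
  reach <- fieldlab:::flood_fill6(nonair, seed)
  expect_identical(reach, nonair)
})

test_that("medial CSF conduit relabels a midsagittal brain cylinder", {
  vol <- build_phantom(phantom_config(voxel_size = 2,
                                      medial_csf_conduit = TRUE))
  codes <- vol$label_codes
  at <- function(p) {
    i <- round((p - vol$origin) / vol$voxel_size) + 1
    vol$labels[i[1], i[2], i[3]]
  }
  expect_equal(at(c(0, 0, 30)), codes[["CSF"]])   # was white
  expect_equal(at(c(0, 0, 66)), codes[["CSF"]])   # was gray
  expect_equal(at(c(0, 0, 80)), codes[["skull"]]) # skull not pierced
  base <- phantom_2mm()
  expect_gt(sum(vol$labels == codes[["CSF"]]),
            sum(base$labels == codes[["CSF"]]))
})

test_that("conductivity assignment maps labels and excludes air", {
  vol <- phantom_2mm()
  sigma <- assign_conductivity(vol)
  codes <- vol$label_codes
  expect_equal(unique(sigma[vol$labels == codes[["skull"]]]), 0.01)
  expect_equal(unique(sigma[vol$labels == codes[["CSF"]]]), 1.65)
  expect_true(all(is.na(sigma[vol$labels == codes[["air"]]])))
  bad <- vol
  bad$labels[1, 1, 1] <- 99L
  bad$label_codes <- c(bad$label_codes, mystery = 99L)
  expect_error(assign_conductivity(bad), "99")
})

test_that("default ROI scheme places nine disjoint regions in brain tissue", {
  vol <- phantom_2mm()
  rois <- label_rois(vol)
  expect_setequal(names(rois$label_codes),
                  c("PFC", "M1", "S1", "occipital", "insula_L", "insula_R",
                    "cingulate", "thalamus", "brainstem"))
  brain <- vol$labels == vol$label_codes[["gray"]] |
    vol$labels == vol$label_codes[["white"]]
  for (nm in names(rois$label_codes)) {
    m <- rois$labels == rois$label_codes[[nm]]
    expect_gt(sum(m), 0)
    expect_true(all(brain[m]))
  }
  # disjointness is structural (one label per voxel), centroids are not:
  co <- fieldlab:::coord_arrays(dim(vol$labels), vol$voxel_size, vol$origin)
  cen <- function(nm) {
    m <- rois$labels == rois$label_codes[[nm]]
    c(mean(co$x[m]), mean(co$y[m]), mean(co$z[m]))
  }
  expect_lt(sqrt(sum(cen("thalamus")^2)), 2)
  m1c <- cen("M1")
  expect_lt(fieldlab:::angle_deg(m1c, standard_position("C3")), 10)
  expect_error(label_rois(vol, "fancy"), "unknown ROI scheme")
})
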