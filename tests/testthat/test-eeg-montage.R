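# 10-10 positions, scalp projection, electrode stamping, montages.

test_that("proportional-arc positions have their definitional angles", {
  cz <- standard_position("Cz")
  expect_equal(cz, c(0, 0, 1), tolerance = 1e-12)
  ang <- function(a, b)
    fieldlab:::angle_deg(standard_position(a), standard_position(b))
  expect_lt(abs(ang("Cz", "C3") - 36), 0.5)
  expect_lt(abs(ang("Cz", "T7") - 72), 0.5)
  expect_lt(abs(ang("Cz", "C5") - 54), 0.5)
  # left/right mirror symmetry across the midsagittal plane
  for (pair in list(c("F3", "F4"), c("Fp1", "Fp2"), c("C3", "C4"),
                    c("FC5", "FC6"))) {
    l <- standard_position(pair[1])
    r <- standard_position(pair[2])
    expect_lt(max(abs(l - r * c(-1, 1, 1))), 1e-9)
  }
  expect_error(standard_position("C99"), "unknown 10-10 label")
})

test_that("HD-4x1 cathodes surround the anode about 90 degrees apart", {
  c3 <- standard_position("C3")
  fr <- fieldlab:::electrode_frame(c3)
  az <- sapply(c("Cz", "F3", "T7", "P3"), function(l) {
    u <- standard_position(l)
    t <- u - sum(u * c3) * c3
    atan2(sum(t * fr$parallel), sum(t * fr$meridian)) * 180 / pi
  })
  gaps <- diff(c(sort(az), min(az) + 360))
  expect_true(all(gaps > 60 & gaps < 120))
  # ring radius ~36 deg of arc for all four
  d <- sapply(c("Cz", "F3", "T7", "P3"), function(l)
    fieldlab:::angle_deg(c3, standard_position(l)))
  expect_true(all(abs(d - 36) < 2))
})

test_that("scalp projection lands on the outermost skin voxel", {
  vol <- phantom_2mm()
  p <- project_to_scalp(c(0, 0, 1), vol)
  expect_lt(max(abs(p - c(0, 0, 92))), vol$voxel_size / 2 + 1e-9)
  p <- project_to_scalp(c(1, 0, 0), vol)
  expect_lt(max(abs(p - c(92, 0, 0))), vol$voxel_size / 2 + 1e-9)
  p <- project_to_scalp(c(1, 1, 1), vol)
  expect_lt(abs(sqrt(sum(p^2)) - 92), vol$voxel_size)
})

test_that("stamped footprints match their nominal areas", {
  vol <- phantom_1mm()
  vs <- vol$voxel_size
  disk <- stamp_electrode(vol, electrode_spec("Cz", "anode", "disk"))
  e <- disk$electrodes[[1]]
  area <- length(e$conductor_idx) * vs^3 / 2   # conductor layer is 2 mm
  expect_lt(abs(area / (pi * 6^2) - 1), 0.15)
  pad <- stamp_electrode(vol, electrode_spec("C3", "anode", "rectangle",
                                             orientation = "vertical"))
  e <- pad$electrodes[[1]]
  area <- length(e$conductor_idx) * vs^3 / 2
  expect_lt(abs(area / 3500 - 1), 0.10)
})

test_that("electrode assemblies sit on the scalp and never overlap", {
  vol <- phantom_2mm()
  st <- stamp_electrode(vol, electrode_spec("C3", "anode", "disk"))
  expect_error(stamp_electrode(st, electrode_spec("C3", "cathode", "disk")),
               "overlaps an existing electrode")
  # conductor adjacent to sponge, sponge adjacent to skin (6-connectivity)
  codes <- st$label_codes
  adjacent_codes <- function(idx) {
    d <- dim(st$labels)
    strides <- c(1, d[1], d[1] * d[2], -1, -d[1], -d[1] * d[2])
    unique(as.vector(st$labels[rep(idx, each = 6) +
                                 rep(strides, times = length(idx))]))
  }
  e <- st$electrodes[[1]]
  expect_true(codes[["sponge_or_gel"]] %in% adjacent_codes(e$conductor_idx))
  expect_true(codes[["skin"]] %in% adjacent_codes(e$sponge_idx))
  # electrode labels never replace tissue
  expect_equal(sum(st$labels != vol$labels),
               length(e$conductor_idx) + length(e$sponge_idx))
})

test_that("the five named montages match their definitions", {
  m <- get_montage("M1-SO")
  expect_equal(m$total_current_mA, 1)
  pol <- vapply(m$electrodes, `[[`, "", "polarity")
  pos <- vapply(m$electrodes, `[[`, "", "position")
  expect_equal(pos[pol == "anode"], "C3")
  expect_equal(pos[pol == "cathode"], "Fp2")
  expect_equal(m$electrodes[[1]]$orientation, "vertical")
  expect_equal(m$electrodes[[2]]$orientation, "horizontal")
  expect_equal(m$electrodes[[1]]$dims_mm, c(50, 70))

  m <- get_montage("HD-4x1")
  pol <- vapply(m$electrodes, `[[`, "", "polarity")
  pos <- vapply(m$electrodes, `[[`, "", "position")
  expect_equal(pos[pol == "anode"], "C3")
  expect_setequal(pos[pol == "cathode"], c("Cz", "F3", "T7", "P3"))
  expect_true(all(vapply(m$electrodes, `[[`, "", "shape") == "disk"))
  expect_equal(m$electrodes[[1]]$dims_mm, 12)

  m <- get_montage("HD-2x2")
  pol <- vapply(m$electrodes, `[[`, "", "polarity")
  pos <- vapply(m$electrodes, `[[`, "", "position")
  expect_setequal(pos[pol == "anode"], c("C3", "C5"))
  expect_setequal(pos[pol == "cathode"], c("FC3", "FC5"))

  m <- get_montage("Cz-Oz")
  pol <- vapply(m$electrodes, `[[`, "", "polarity")
  pos <- vapply(m$electrodes, `[[`, "", "position")
  expect_equal(pos[pol == "anode"], "Cz")
  expect_equal(pos[pol == "cathode"], "Oz")
  # anode pad runs ear to ear: "horizontal" at the vertex
  expect_equal(m$electrodes[[which(pol == "anode")]]$orientation,
               "horizontal")

  expect_error(get_montage("M1_SO_typo"), "valid montages")
})

test_that("all five montages stamp without overlap at 1 and 2 mm", {
  for (vol in list(phantom_2mm(), phantom_1mm())) {
    for (nm in paper_montages) {
      st <- stamp_montage(vol, get_montage(nm))
      expect_equal(length(st$electrodes),
                   length(get_montage(nm)$electrodes))
    }
  }
})

test_that("montages survive a YAML round trip", {
  m <- get_montage("HD-2x2")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_montage_yaml(m, path)
  m2 <- read_montage_yaml(path)
  expect_equal(m2$name, m$name)
  expect_equal(m2$total_current_mA, m$total_current_mA)
  expect_equal(lapply(m2$electrodes, unclass),
               lapply(m$electrodes, unclass))
})
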