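# DIA core: filtering, thresholding, coverage, volume, alignment, spread

test_that("3x3 median filter matches a brute-force sort-of-9 oracle", {
  set.seed(42)
  m <- matrix(sample(0:4095, 256, replace = TRUE), 16, 16)
  got <- median_filter_slice(m)
  pad <- rbind(m[1, ], m, m[16, ])
  pad <- cbind(pad[, 1], pad, pad[, 16])
  oracle <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16)
    oracle[i, j] <- median(pad[i:(i + 2), j:(j + 2)])
  expect_equal(got, oracle)
})

test_that("median filter leaves constants and removes impulses", {
  const <- matrix(7, 10, 10)
  expect_equal(median_filter_slice(const), const)
  imp <- matrix(0, 10, 10); imp[5, 5] <- 4095
  expect_equal(median_filter_slice(imp), matrix(0, 10, 10))
})

test_that("stack filtering is per-slice", {
  a <- array(0, c(2, 8, 8)); a[2, 4, 4] <- 100
  comp <- component_zstack(a, "cells", fake_geometry())
  f <- median_filter_stack(comp)
  expect_equal(f$abundances[1, , ], matrix(0, 8, 8))
  expect_equal(f$abundances[2, 4, 4], 0)  # impulse removed in its slice
})

test_that("area coverage is positives over total pixels", {
  expect_equal(area_coverage(matrix(TRUE, 832, 832)), 1.0)
  expect_equal(area_coverage(matrix(FALSE, 10, 10)), 0.0)
  m <- matrix(FALSE, 832, 832); m[seq_len(346112)] <- TRUE
  expect_equal(area_coverage(m), 0.5)
})

test_that("coverage-vs-threshold is exact for a two-level slice and
           monotone for random ones", {
  comp <- two_level_stack(nz = 1L, n = 32L, lo = 100L, hi = 3000L)
  tab <- coverage_vs_threshold(comp)
  expect_equal(tab[1:100, 1], rep(1, 100))       # t <= 100: everything
  expect_equal(tab[101:3000, 1], rep(0.5, 2900)) # plateau
  expect_equal(tab[3001:4095, 1], rep(0, 1095))
  # threshold 1 labels every pixel with value >= 1 positive
  expect_equal(tab[1, 1], 1)
  set.seed(9)
  rnd <- component_zstack(array(sample(0:4095, 2 * 16 * 16, TRUE),
                                c(2, 16, 16)), "x", fake_geometry())
  tab2 <- coverage_vs_threshold(rnd)
  for (z in 1:2) expect_true(all(diff(tab2[, z]) <= 0))
})

test_that("thresholding round-trips against the coverage table", {
  set.seed(10)
  comp <- component_zstack(array(sample(0:4095, 3 * 12 * 12, TRUE),
                                 c(3, 12, 12)), "x", fake_geometry())
  tab <- coverage_vs_threshold(comp)
  for (t in c(1L, 500L, 2048L, 4095L)) {
    b <- apply_threshold(comp, t)
    cov <- vapply(1:3, function(z) area_coverage(b$mask[z, , ]),
                  numeric(1))
    expect_equal(cov, unname(tab[t, ]))
  }
  expect_error(apply_threshold(comp, 0), "1..4095")
  expect_error(apply_threshold(comp, 4096), "1..4095")
  all_low <- component_zstack(array(4094, c(1, 4, 4)), "x",
                              fake_geometry())
  expect_equal(sum(apply_threshold(all_low, 4095)$mask), 0)
})

test_that("plateau threshold selection lands inside the analytic plateau", {
  set.seed(12)
  ens <- lapply(1:4, function(i) two_level_stack())
  t <- suppressWarnings(select_threshold(ens, step = 8L))
  expect_gte(as.integer(t), 101L)
  expect_lte(as.integer(t), 3000L)
  expect_equal(as.integer(t), 1549L)  # median of the evaluated plateau
  w <- attr(t, "window")
  expect_gte(w[1], 101L); expect_lte(w[2], 3000L)
  # identical FOVs: degenerate Kruskal-Wallis, same plateau logic
  t2 <- suppressWarnings(select_threshold(list(two_level_stack(),
                                               two_level_stack())))
  expect_gte(as.integer(t2), 101L)
  expect_lte(as.integer(t2), 3000L)
  # constant-zero coverage errors
  zero <- component_zstack(array(0, c(1, 8, 8)), "x", fake_geometry())
  expect_error(suppressWarnings(select_threshold(list(zero, zero))),
               "zero coverage")
})

test_that("noisy replicate ensembles still select inside the plateau", {
  set.seed(13)
  mk <- function() {
    a <- array(0L, c(2, 24, 24))
    a[] <- pmax(0L, pmin(4095L, as.integer(
      rnorm(length(a), 100, 10))))
    a[, 1:12, ] <- pmax(0L, pmin(4095L, as.integer(
      rnorm(2 * 12 * 24, 3000, 50))))
    component_zstack(a, "cells", fake_geometry())
  }
  ens <- lapply(1:5, function(i) mk())
  t <- select_threshold(ens, step = 8L)
  expect_gt(as.integer(t), 150L)   # above the noisy background band
  expect_lt(as.integer(t), 2850L)  # below the noisy signal band
})

test_that("volume is depth step x image area x summed coverage", {
  prof <- structure(data.frame(raw_index = 0:2,
                               coverage = c(0.5, 1.0, 0.5)),
                    class = c("area_profile", "data.frame"),
                    component_id = "cells")
  expect_equal(compute_volume(prof, 2.35, 176400), 829080)
  prof0 <- structure(data.frame(raw_index = 0:2, coverage = c(0, 0, 0)),
                     class = c("area_profile", "data.frame"))
  expect_equal(compute_volume(prof0), 0)
  expect_error(compute_volume(prof, -1, 10), "positive")
})

test_that("volume linearity: disjoint-slice components add", {
  p1 <- structure(data.frame(raw_index = 0:3,
                             coverage = c(0.2, 0.4, 0, 0)),
                  class = c("area_profile", "data.frame"))
  p2 <- structure(data.frame(raw_index = 0:3,
                             coverage = c(0, 0, 0.3, 0.1)),
                  class = c("area_profile", "data.frame"))
  pu <- structure(data.frame(raw_index = 0:3,
                             coverage = c(0.2, 0.4, 0.3, 0.1)),
                  class = c("area_profile", "data.frame"))
  expect_equal(compute_volume(p1) + compute_volume(p2),
               compute_volume(pu))
})

test_that("volume agrees with a voxel-count oracle on random masks", {
  set.seed(14)
  for (i in 1:50) {
    nz <- sample(2:6, 1); n <- sample(c(8L, 12L, 16L), 1)
    mask <- array(runif(nz * n * n) < runif(1, 0.1, 0.9), c(nz, n, n))
    px <- runif(1, 0.3, 1)
    b <- structure(list(mask = mask, component_id = "x",
                        slice_interval_um = 2.35, optical_slice_um = 4.7,
                        pixel_size_um = px, water_side = "first"),
                   class = "binary_zstack")
    prof <- area_profile(b)
    vol <- compute_volume(prof, 2.35, px^2 * n * n)
    expect_equal(vol, sum(mask) * px^2 * 2.35, tolerance = 1e-12)
  }
})

test_that("alignment labels the cell peak 0 with water-side negative", {
  mkprof <- function(cov, id) structure(
    data.frame(raw_index = seq_along(cov) - 1L, coverage = cov),
    class = c("area_profile", "data.frame"), component_id = id)
  cells <- mkprof(c(rep(0.1, 7), 0.9, rep(0.1, 3)), "cells")  # max raw 7
  carb <- mkprof(c(rep(0.05, 6), 0.8, rep(0.05, 4)), "carbohydrates")
  al <- align_to_cell_peak(list(cells = cells, carbohydrates = carb))
  expect_equal(al$cells$aligned_index, -7:3)
  expect_equal(peak_location(al$cells), 0L)
  expect_equal(peak_location(al$carbohydrates), -1L)
  expect_equal(al$cells$normalised_depth_um, (-7:3) * 4.7)
  # idempotence
  al2 <- align_to_cell_peak(al)
  expect_equal(al2$cells$aligned_index, al$cells$aligned_index)
  expect_equal(al2$carbohydrates$normalised_depth_um,
               al$carbohydrates$normalised_depth_um)
  # all-zero cell profile cannot anchor
  zero <- mkprof(rep(0, 11), "cells")
  expect_error(align_to_cell_peak(list(cells = zero)), "all zero")
})

test_that("peak ties break toward the substratum and monotone profiles
           peak at the water-most slice", {
  mkprof <- function(cov, id = "x") structure(
    data.frame(raw_index = seq_along(cov) - 1L, coverage = cov),
    class = c("area_profile", "data.frame"), component_id = id)
  cells <- mkprof(c(0.2, 0.9, 0.9, 0.1), "cells")
  al <- align_to_cell_peak(list(cells = cells))
  # the two tied 0.9s sit at aligned -1 and 0; the tie goes to 0
  expect_equal(peak_location(al$cells), 0L)
  dec <- mkprof(c(0.9, 0.7, 0.4, 0.1), "cells")
  ald <- align_to_cell_peak(list(cells = dec, x = mkprof(c(0.5, 0.4,
                                                           0.2, 0.1))))
  expect_equal(peak_location(ald$x), 0L)
  expect_equal(min(ald$x$aligned_index), 0L)  # peak at water-most slice
  zero <- mkprof(rep(0, 4))
  zal <- align_to_cell_peak(list(cells = dec, x = zero))
  expect_warning(pl <- peak_location(zal$x), "undefined")
  expect_true(is.na(pl))
})

test_that("spread equals depth step x slice count for uniform profiles,
           at any coverage", {
  set.seed(15)
  for (i in 1:50) {
    k <- sample(1:12, 1)
    f <- runif(1, 0.01, 1)
    area <- runif(1, 1e3, 2e5)
    vol <- 2.35 * area * k * f
    expect_equal(compute_spread(vol, f, area), 2.35 * k,
                 tolerance = 1e-12)
  }
  # worked arithmetic: V = 829,080 um^3 at full peak coverage of a
  # 176,400 um^2 field is 4.7 um of spread
  expect_equal(compute_spread(829080, 1.0, 176400), 4.7)
  expect_error(compute_spread(100, 0, 176400), "> 0")
})

test_that("composition ratios are per-FOV with undefined flags", {
  vols <- data.frame(
    fov = rep(1:2, each = 3),
    component = rep(c("cells", "carbohydrates", "proteins"), 2),
    volume_um3 = c(10, 40, 8, 5, 10, 0))
  cr <- composition_ratios(vols)
  f1 <- cr$per_fov[cr$per_fov$fov == 1, ]
  expect_equal(f1$eps, 48)
  expect_equal(f1$eps_to_cells, 4.8)
  expect_equal(f1$carbohydrates_to_proteins, 5.0)
  f2 <- cr$per_fov[cr$per_fov$fov == 2, ]
  expect_true(is.na(f2$carbohydrates_to_proteins))
  s <- cr$summary
  cp <- s[s$ratio == "carbohydrates_to_proteins", ]
  expect_equal(cp$n_undefined, 1L)
  expect_equal(cp$median, 5.0)  # the NA FOV is excluded, not zeroed
})

test_that("median of per-FOV ratios differs from ratio of medians and is
           what gets reported", {
  vols <- data.frame(
    fov = rep(1:3, each = 3),
    component = rep(c("cells", "carbohydrates", "proteins"), 3),
    volume_um3 = c(10, 20, 2,   100, 900, 10,   1, 9, 1))
  cr <- composition_ratios(vols)
  per_fov <- cr$per_fov$carbohydrates_to_cells   # 2, 9, 9
  expect_equal(cr$summary[cr$summary$ratio == "carbohydrates_to_cells",
                          "median"],
               median(per_fov))
  ratio_of_medians <- median(c(20, 900, 9)) / median(c(10, 100, 1))
  expect_false(isTRUE(all.equal(median(per_fov), ratio_of_medians)))
})

test_that("group comparison reports rank-sum W matching a brute-force
           rank computation", {
  set.seed(16)
  x <- c(3.1, 4.5, 2.2, 6.6, 5.0, 3.9)
  y <- c(7.2, 8.1, 6.9, 9.4, 7.7, 8.8)
  res <- compare_groups(c(x, y), rep(c("a", "b"), each = 6))
  r <- rank(c(x, y))
  W_oracle <- sum(r[1:6]) - 6 * 7 / 2
  expect_equal(res$statistic, W_oracle)
  expect_equal(res$test, "wilcoxon")
  # disjoint ranges of size 5: the exactly minimal attainable p
  res2 <- compare_groups(c(1:5, 101:105), rep(c("a", "b"), each = 5))
  expect_equal(res2$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  # identical groups: p ~ 1
  res3 <- compare_groups(rep(c(1, 2, 3, 4), 2),
                         rep(c("a", "b"), each = 4))
  expect_gt(res3$p_value, 0.9)
  expect_error(compare_groups(1:3, c("a", "a", "b")), ">= 2")
  # three groups switch to Kruskal-Wallis
  res4 <- compare_groups(rnorm(9), rep(c("a", "b", "c"), each = 3))
  expect_equal(res4$test, "kruskal-wallis")
})

test_that("VTK overlay round-trips voxel counts and physical coordinates", {
  g <- fake_geometry()
  mk <- function(fill) {
    m <- array(FALSE, c(2, 4, 4)); m[fill] <- TRUE
    structure(list(mask = m, threshold_value = 1L, component_id = "x",
                   slice_interval_um = g$slice_interval_um,
                   optical_slice_um = g$optical_slice_um,
                   pixel_size_um = g$pixel_size_um,
                   water_side = "first"),
              class = "binary_zstack")
  }
  cells <- mk(cbind(1, 2, 3))            # one voxel z=1,y=2,x=3
  carb <- mk(rbind(cbind(1, 2, 3), cbind(2, 1, 1)))
  path <- file.path(withr::local_tempdir(), "ov.vtk")
  export_overlay(list(cells = cells, carbohydrates = carb), path,
                 write_png = TRUE)
  back <- biofilmq:::read_overlay_vtk(path)
  expect_equal(sum(back$cells), 1)
  expect_equal(sum(back$carbohydrates), 2)
  expect_equal(which(back$cells == 1, arr.ind = TRUE)[1, ],
               c(dim1 = 1, dim2 = 2, dim3 = 3))
  # co-localisation preserved: both scalars set at the shared voxel
  expect_equal(back$carbohydrates[1, 2, 3], 1L)
  # spacing line carries the voxel geometry
  expect_true(any(grepl("SPACING 0.505 0.505 2.35",
                        readLines(path), fixed = TRUE)))
  expect_true(file.exists(file.path(dirname(path), "ov_slices",
                                    "slice_001.png")))
  bad <- mk(cbind(1, 1, 1)); bad$mask <- bad$mask[, 1:3, , drop = FALSE]
  expect_error(export_overlay(list(a = cells, b = bad),
                              tempfile(fileext = ".vtk")), "geometry")
})
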