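test_that("rasterization matches the per-voxel point-in-polygon oracle", {
  g <- unit_grid(c(4, 4, 1))
  sq <- contour_set("sq", list(list(z = 0, xy = rbind(c(0.5, 0.5), c(2.5, 0.5),
                                                      c(2.5, 2.5), c(0.5, 2.5)))))
  m <- rasterize_contours(sq, g)
  expect_equal(mask_count(m), 4)
  expect_true(all(m$occupancy[2:3, 2:3, 1]))

  # polygon squeezed between voxel centers: empty, with a warning
  tiny <- contour_set("tiny", list(list(z = 0, xy = rbind(c(0.1, 0.1), c(0.4, 0.1),
                                                          c(0.4, 0.4), c(0.1, 0.4)))))
  expect_warning(m0 <- rasterize_contours(tiny, g), class = "kbdvh_empty_mask_warning")
  expect_true(m0$empty)

  # ring: outer square with a concentric inner hole, even-odd rule
  g2 <- unit_grid(c(8, 8, 1))
  ring <- contour_set("ring", list(
    list(z = 0, xy = rbind(c(0.5, 0.5), c(6.5, 0.5), c(6.5, 6.5), c(0.5, 6.5))),
    list(z = 0, xy = rbind(c(2.5, 2.5), c(4.5, 2.5), c(4.5, 4.5), c(2.5, 4.5)))
  ))
  m2 <- rasterize_contours(ring, g2)
  # oracle: independent even-odd crossing count per voxel center
  ax <- grid_axes(g2)
  ctr <- expand.grid(x = ax$x, y = ax$y)
  crossings <- function(px, py, poly) {
    n <- nrow(poly); cnt <- 0
    for (e in seq_len(n)) {
      a <- poly[e, ]; b <- poly[if (e == n) 1 else e + 1, ]
      if ((a[2] > py) != (b[2] > py)) {
        xint <- a[1] + (py - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
        if (px < xint) cnt <- cnt + 1
      }
    }
    cnt
  }
  oracle <- mapply(function(px, py)
    (crossings(px, py, ring$contours[[1]]$xy) +
     crossings(px, py, ring$contours[[2]]$xy)) %% 2 == 1, ctr$x, ctr$y)
  expect_identical(as.vector(m2$occupancy[, , 1]), as.vector(oracle))

  # randomized polygons vs the same oracle
  for (seed in 1:5) {
    set.seed(seed)
    ang <- sort(runif(7, 0, 2 * pi))
    rad <- runif(7, 1, 3.4)
    poly <- cbind(3.5 + rad * cos(ang), 3.5 + rad * sin(ang))
    cs <- contour_set("rnd", list(list(z = 0, xy = poly)))
    m3 <- suppressWarnings(rasterize_contours(cs, g2))
    oracle3 <- mapply(function(px, py) crossings(px, py, poly) %% 2 == 1,
                      ctr$x, ctr$y)
    expect_identical(as.vector(m3$occupancy[, , 1]), as.vector(oracle3),
                     label = paste("random polygon seed", seed))
  }
})

test_that("rasterization rejects bad contours and off-grid slices", {
  g <- unit_grid(c(4, 4, 1))
  expect_error(contour_set("bad", list(list(z = 0, xy = rbind(c(0, 0), c(1, 1))))),
               class = "kbdvh_invalid_contour_error")
  far <- contour_set("far", list(list(z = 5, xy = rbind(c(0.5, 0.5), c(2.5, 0.5),
                                                        c(2.5, 2.5)))))
  expect_warning(expect_warning(rasterize_contours(far, g),
                                class = "kbdvh_contour_slice_warning"),
                 class = "kbdvh_empty_mask_warning")
  expect_warning(rasterize_contours(contour_set("none", list()), g),
                 class = "kbdvh_empty_contour_warning")
})

test_that("mask subtraction obeys the partition identity", {
  g <- unit_grid(c(5, 5, 5))
  a_occ <- array(FALSE, g$shape); a_occ[2:4, 2:4, 2:4] <- TRUE
  b_occ <- array(FALSE, g$shape); b_occ[3, 3, 3] <- TRUE
  a <- structure_mask(g, a_occ, "A"); b <- structure_mask(g, b_occ, "B")
  d <- subtract_masks(a, b)
  expect_equal(mask_count(d), 26)
  expect_equal(d$name, "A-B")
  expect_false(any(d$occupancy & b$occupancy))
  expect_equal(mask_count(d) + sum(a$occupancy & b$occupancy), mask_count(a))

  # disjoint: identity; superset: empty with warning
  c_occ <- array(FALSE, g$shape); c_occ[1, 1, 1] <- TRUE
  cc <- structure_mask(g, c_occ, "C")
  expect_identical(subtract_masks(a, cc)$occupancy, a$occupancy)
  expect_warning(e <- subtract_masks(b, a), class = "kbdvh_empty_mask_warning")
  expect_true(e$empty)
  expect_error(subtract_masks(a, structure_mask(unit_grid(c(4, 4, 4)),
                                                array(FALSE, c(4, 4, 4)), "X")),
               class = "kbdvh_geometry_error")
})

test_that("dose resampling is exact on identity, constants, and a hand case", {
  g <- unit_grid(c(4, 4, 4))
  set.seed(2)
  d <- dose_grid(g, array(runif(64, 0, 50), g$shape))
  expect_equal(resample_dose(d, g)$dose, d$dose)

  # constant field preserved at any in-extent target
  du <- dose_grid(g, array(10, g$shape))
  tg <- volume_grid(c(3, 3, 3), c(0.7, 0.9, 1.1), c(0.2, 0.3, 0.1))
  expect_equal(max(abs(resample_dose(du, tg)$dose - 10)), 0, tolerance = 1e-12)

  # midway between 0 and 20 Gy along x -> 10 Gy (hand trilinear value)
  src <- volume_grid(c(2, 1, 1), c(1, 1, 1))
  dd <- dose_grid(src, array(c(0, 20), c(2, 1, 1)))
  mid <- volume_grid(c(1, 1, 1), c(1, 1, 1), c(0.5, 0, 0))
  expect_equal(as.numeric(resample_dose(dd, mid)$dose), 10)

  # out-of-extent voxels get 0 Gy and are counted
  big <- volume_grid(c(6, 1, 1), c(1, 1, 1), c(-2, 0, 0))
  r <- resample_dose(dd, big)
  expect_equal(attr(r, "n_out_of_extent"), 4)
  expect_equal(as.numeric(r$dose), c(0, 0, 0, 20, 0, 0))

  far <- volume_grid(c(2, 2, 2), c(1, 1, 1), c(100, 100, 100))
  expect_error(resample_dose(dd, far), class = "kbdvh_geometry_error")
})
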