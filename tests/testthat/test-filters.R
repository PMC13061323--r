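test_that("small-patch removal keeps components at or above the threshold", {
  m <- matrix(FALSE, 60, 60)
  m[1:10, 1:10] <- TRUE                       # 100 px
  m[1:13, 20:31] <- TRUE                      # 156 px (13x12)
  m[30:49, 30:49] <- TRUE                     # 400 px
  sizes_in <- sort(tabulate(oracle_label(m, 8)[oracle_label(m, 8) > 0]))
  expect_equal(sizes_in, c(100, 156, 400))
  out <- remove_small_patches(m, 156)
  lab <- oracle_label(out, 8)
  expect_equal(sort(tabulate(lab[lab > 0], max(lab))), c(156, 400))
  # nothing added
  expect_true(all(!out | m))
})

test_that("isolated pixels and empty maps are handled", {
  m <- matrix(FALSE, 10, 10)
  expect_equal(remove_small_patches(m, 156), m)
  m[5, 5] <- TRUE
  expect_false(any(remove_small_patches(m, 156)))
})

test_that("labelling agrees with the flood-fill oracle at both connectivities", {
  # a diagonal chain: one 8-connected component, many 4-connected ones
  d <- matrix(FALSE, 6, 6)
  diag(d) <- TRUE
  expect_equal(max(label_patches(d, 8)), 1L)
  expect_equal(max(label_patches(d, 4)), 6L)
  set.seed(17)
  for (i in 1:20) {
    m <- matrix(runif(32 * 32) < 0.4, 32, 32)
    for (conn in c(4, 8))
      expect_true(same_partition(label_patches(m, conn), oracle_label(m, conn)))
  }
})

test_that("morphological opening/closing fixes shapes as hand-traced", {
  # a solid convex square is a fixed point
  sq <- rect_mask(14, 14, 3, 12, 3, 12)
  expect_equal(morphological_refine(sq), sq)
  # a 1-pixel-wide protrusion is removed by the square opening
  prot <- rect_mask(14, 14, 3, 12, 3, 10)
  prot[7, 11:13] <- TRUE
  expect_equal(morphological_refine(prot), rect_mask(14, 14, 3, 12, 3, 10))
  # a 1-pixel interior hole is filled by the closing
  hole <- rect_mask(14, 14, 3, 12, 3, 12)
  hole[7, 7] <- FALSE
  expect_equal(morphological_refine(hole), sq)
})

test_that("NBR floor reclassifies vegetated pixels with a strict boundary", {
  m <- matrix(TRUE, 2, 2)
  nbr <- matrix(c(0.3, -0.5, -0.1, NA), 2, 2)
  out <- apply_nbr_floor(m, nbr, -0.1)
  expect_false(out[1, 1])    # +0.3 > -0.1: vegetated, dropped
  expect_true(out[2, 1])     # -0.5 stays burned
  expect_true(out[1, 2])     # exactly -0.1 stays burned (strict >)
  expect_true(out[2, 2])     # NA NBR leaves the pixel untouched
  expect_false(any(apply_nbr_floor(matrix(FALSE, 2, 2), nbr, -0.1)))
})

test_that("hotspot masking keeps scars with in-window fire evidence only", {
  g <- grid_spec(40, 40, 20)
  scar <- rect_mask(40, 40, 10, 19, 10, 19)   # 200x200 m scar
  ctr <- pixel_centres(g, 15, 15)
  hs <- function(x, y, date) data.frame(date = as.Date(date), x = x, y = y,
                                        sensor_resolution_m = 375)
  # hotspot inside the scar -> survives
  out <- mask_with_hotspots(scar, hs(ctr[1], ctr[2], "2019-09-10"), g, "2019-09")
  expect_equal(out, scar)
  # nearest burned-pixel centre 150 m away -> removed (beyond the 100-m buffer)
  edge <- pixel_centres(g, 15, 19)   # centre of the scar's east edge pixel
  far <- hs(edge[1] + 150, edge[2], "2019-09-10")
  expect_false(any(mask_with_hotspots(scar, far, g, "2019-09")))
  near <- hs(edge[1] + 95, edge[2], "2019-09-10")
  expect_equal(mask_with_hotspots(scar, near, g, "2019-09"), scar)
  # hotspot dated outside the window -> removed
  stale <- hs(ctr[1], ctr[2], "2019-04-10")
  expect_false(any(mask_with_hotspots(scar, stale, g, "2019-09",
                                      window_months = 4)))
  # window length matters: May is in a 5-month window, not in 4
  may <- hs(ctr[1], ctr[2], "2019-05-20")
  expect_false(any(mask_with_hotspots(scar, may, g, "2019-09", window_months = 4)))
  expect_equal(mask_with_hotspots(scar, may, g, "2019-09", window_months = 5), scar)
  # empty hotspot table removes everything
  none <- data.frame(date = as.Date(character()), x = numeric(),
                     y = numeric(), sensor_resolution_m = numeric())
  expect_false(any(mask_with_hotspots(scar, none, g, "2019-09")))
})

test_that("hotspot masking matches the exhaustive Euclidean oracle", {
  set.seed(31)
  g <- grid_spec(48, 48, 20)
  for (i in 1:25) {
    m <- matrix(runif(48 * 48) < 0.25, 48, 48)
    n_hs <- sample.int(6, 1)
    hs <- data.frame(
      date = as.Date("2019-09-01") + sample.int(80, n_hs) - 40,
      x = runif(n_hs, g$origin[1] - 100, g$origin[1] + 48 * 20 + 100),
      y = runif(n_hs, g$origin[2] - 48 * 20 - 100, g$origin[2] + 100),
      sensor_resolution_m = 375)
    for (conn in c(8, 4)) {
      got <- mask_with_hotspots(m, hs, g, "2019-09", buffer_m = 100,
                                window_months = 4, connectivity = conn)
      want <- oracle_hotspot_filter(m, hs, g, "2019-09", 100, 4, conn)
      expect_identical(got, want)
    }
  }
})

test_that("repeat masking flags recent re-detections and respects the lookback", {
  g <- grid_spec(4, 4)
  h <- burn_history(g)
  all_burn <- matrix(TRUE, 4, 4)
  # first detection in 2019-02: everything burned_new
  r <- mask_repeats(all_burn, h, "2019-02", lookback = 3)
  expect_true(all(r$map$state == BURN_STATE[["burned_new"]]))
  h <- r$history
  # re-detected in 03, 04, 05: burned_repeat each time, never re-counted
  for (m in c("2019-03", "2019-04", "2019-05")) {
    r <- mask_repeats(all_burn, h, m, lookback = 3)
    expect_true(all(r$map$state == BURN_STATE[["burned_repeat"]]))
    h <- r$history
  }
  expect_true(all(h$count == 1L))
  # 4 months after the last burned_new (2019-02 -> 2019-06): new again
  r <- mask_repeats(all_burn, h, "2019-06", lookback = 3)
  expect_true(all(r$map$state == BURN_STATE[["burned_new"]]))
  expect_true(all(r$history$count == 2L))
  # history after the reference month is rejected
  expect_error(mask_repeats(all_burn, r$history, "2019-01"), "reference month")
})

test_that("unobserved pixels are coded distinctly by repeat masking", {
  g <- grid_spec(3, 3)
  m <- matrix(FALSE, 3, 3); m[1, 1] <- TRUE
  unobs <- matrix(FALSE, 3, 3); unobs[3, 3] <- TRUE
  r <- mask_repeats(m, burn_history(g), "2019-05", unobserved = unobs)
  expect_equal(r$map$state[1, 1], BURN_STATE[["burned_new"]])
  expect_equal(r$map$state[3, 3], BURN_STATE[["unobserved"]])
  expect_equal(r$map$state[2, 2], BURN_STATE[["unburned"]])
})

test_that("filters never create burned pixels outside the component region", {
  set.seed(55)
  for (i in 1:10) {
    m <- matrix(runif(40 * 40) < 0.35, 40, 40)
    a <- remove_small_patches(m, 10)
    expect_true(all(!a | m))
    b <- morphological_refine(m)
    # closing may fill holes but never reaches beyond a 1-pixel dilation of
    # the opened map, which itself is inside m's dilation
    dil <- dilate_by_disc_test(m, 1)
    expect_true(all(!b | dil))
    nbr <- matrix(runif(1600, -1, 1), 40, 40)
    expect_true(all(!apply_nbr_floor(m, nbr, -0.1) | m))
  }
})

test_that("burn maps round-trip through raster files", {
  g <- grid_spec(12, 12)
  st <- matrix(BURN_STATE[["unburned"]], 12, 12)
  st[2:5, 2:5] <- BURN_STATE[["burned_new"]]
  st[8, 8] <- BURN_STATE[["burned_repeat"]]
  st[1, 12] <- BURN_STATE[["unobserved"]]
  bm <- toy_burn_map(st, "2019-07", g)
  f <- tempfile(fileext = ".asc")
  write_burn_map(bm, f)
  back <- read_burn_map(f, "2019-07")
  expect_identical(back$state, st)
  expect_equal(format(back$month), "2019-07")
})
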