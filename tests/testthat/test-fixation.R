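test_that("the PPM is zero centrally and peaks at a peripheral item", {
  img <- list(colorA = matrix(0, 64, 64))
  img$colorA[10:14, 50:54] <- 1
  p <- compute_ppm(img, central_radius_px = 15)
  inside <- disk_mask(64, 64, c(32, 32), 15)
  expect_true(all(p$grid[inside] == 0))
  pk <- select_pfoa(p, k = 1)
  expect_true(abs(pk$row - 12) <= 3 && abs(pk$col - 52) <= 3)
  # a uniform image has no feature contrast anywhere
  pu <- compute_ppm(list(colorA = matrix(0.7, 64, 64)), central_radius_px = 10)
  expect_true(all(pu$grid == 0))
  expect_equal(nrow(select_pfoa(pu, k = 5)), 0L)
})

test_that("peripheral peaks come out strongest-first with stable tie-breaks", {
  img <- list(colorA = matrix(0, 96, 96))
  cts <- list(c(15, 15), c(15, 80), c(80, 15), c(80, 80), c(48, 10))
  vals <- c(1, 0.8, 0.6, 0.4, 0.2)
  for (i in seq_along(cts))
    img$colorA[cts[[i]][1] + (-2:2), cts[[i]][2] + (-2:2)] <- vals[i]
  p <- compute_ppm(img, central_radius_px = 10)
  pk <- select_pfoa(p, k = 3, excl_radius = 8)
  expect_equal(nrow(pk), 3L)
  expect_true(all(diff(pk$value) <= 0))
  for (i in 1:3)
    expect_lt(max(abs(c(pk$row[i], pk$col[i]) - cts[[i]])), 4)
  # two equal isolated peaks: both returned, lexicographic order
  img2 <- list(colorA = matrix(0, 64, 64))
  img2$colorA[10, 10] <- 1; img2$colorA[10, 50] <- 1
  p2 <- compute_ppm(img2, central_radius_px = 5)
  pk2 <- select_pfoa(p2, k = 2, excl_radius = 5)
  expect_equal(pk2$col, c(10, 50))
})

test_that("FHM weights decay geometrically and entries expire at epsilon", {
  fhm <- new_fhm(lambda = 0.5, epsilon = 0.01)
  fhm <- update_fhm(fhm, make_fixation(c(10, 10), "overt", 1))
  for (i in 1:3)
    fhm <- update_fhm(fhm, make_fixation(c(20 + i, 20), "overt", 1 + i))
  w <- vapply(fhm$entries, `[[`, 0, "weight")
  expect_equal(w[1], 0.125)     # 0.5^3
  # an entry survives exactly 6 further updates at lambda=0.5, eps=0.01
  fhm2 <- new_fhm(lambda = 0.5, epsilon = 0.01)
  fhm2 <- update_fhm(fhm2, make_fixation(c(5, 5), "overt", 1))
  for (i in 1:6) fhm2 <- update_fhm(fhm2, make_fixation(c(9, 9), "overt", i))
  pos <- vapply(fhm2$entries, function(e) e$pos[1], 0)
  expect_true(5 %in% pos)       # 0.5^6 = 0.0156 >= 0.01
  fhm2 <- update_fhm(fhm2, make_fixation(c(9, 9), "overt", 8))
  pos <- vapply(fhm2$entries, function(e) e$pos[1], 0)
  expect_false(5 %in% pos)      # 0.5^7 < 0.01
})

test_that("FHM world positions are invariant under saccades", {
  fhm <- new_fhm(lambda = 1, epsilon = 0)
  fhm <- update_fhm(fhm, make_fixation(c(40, 40), "overt", 1))
  v1 <- gaze_view(c(40, 40), c(64, 64))
  v2 <- gaze_view(c(70, 55), c(64, 64))   # after a (30,15) saccade
  expect_equal(fhm$entries[[1]]$pos, c(40, 40))
  r1 <- world_to_ret(v1, c(40, 40))[1, ]
  r2 <- world_to_ret(v2, c(40, 40))[1, ]
  expect_equal(r2 - r1, c(-30, -15))
  # the retinal inhibition footprint follows the entry under the new view
  i2 <- visattn:::fhm_inhibition(fhm, v2)
  expect_equal(i2[r2[1], r2[2]], 1)
})

test_that("the HBPM combines saliency with history inhibition", {
  img <- list(colorA = matrix(0, 64, 64))
  img$colorA[10:14, 10:14] <- 1
  img$colorA[10:14, 50:54] <- 1
  ppm <- compute_ppm(img, central_radius_px = 8)
  view <- gaze_view(c(32, 32), c(64, 64))
  fhm <- new_fhm(lambda = 1, epsilon = 0)
  # no history: the HBPM equals the PPM
  h0 <- compose_hbpm(pfoa = select_pfoa(ppm, 2), fhm = fhm, ppm = ppm,
                     view = view)
  expect_identical(h0$grid, ppm$grid)
  # a weight-1 entry zeroes priority under its footprint
  fhm <- update_fhm(fhm, make_fixation(c(12, 12), "overt", 1), radius = 6)
  h1 <- compose_hbpm(pfoa = select_pfoa(ppm, 2), fhm = fhm, ppm = ppm,
                     view = view)
  expect_true(all(h1$grid[10:14, 10:14] == 0))
  expect_identical(h1$grid[10:14, 50:54], ppm$grid[10:14, 50:54])
  # the task-demand override ignores history entirely
  ho <- compose_hbpm(pfoa = select_pfoa(ppm, 2), fhm = fhm, ppm = ppm,
                     view = view, override = TRUE)
  expect_identical(ho$grid, ppm$grid)
})

test_that("next-fixation selection honors constraints and the floor", {
  img <- list(colorA = matrix(0, 64, 64))
  img$colorA[10:14, 10:14] <- 1
  ppm <- compute_ppm(img, central_radius_px = 8)
  view <- gaze_view(c(32, 32), c(64, 64))
  fhm <- new_fhm(lambda = 1, epsilon = 0)
  h <- compose_hbpm(pfoa = select_pfoa(ppm, 2), fhm = fhm, ppm = ppm,
                    view = view)
  fx <- select_next_fixation(h, view)
  expect_false(is.null(fx))
  expect_identical(fx$kind, "overt")
  # a constraint can veto every candidate
  expect_null(select_next_fixation(h, view, constraint = function(w, r) FALSE))
  # fully inhibited map: nothing above the floor
  fhm <- update_fhm(fhm, make_fixation(c(12, 12), "overt", 1), radius = 10)
  h2 <- compose_hbpm(pfoa = select_pfoa(ppm, 2), fhm = fhm, ppm = ppm,
                     view = view)
  expect_null(select_next_fixation(h2, view))
})

test_that("saccades re-center the retina with zero padding at the world edge", {
  world <- list(colorA = matrix(seq_len(64 * 64) / (64 * 64), 64, 64))
  ctr <- execute_saccade(world, make_fixation(c(32, 32), "overt"), c(64, 64))
  expect_identical(ctr$image$colorA, world$colorA)
  edge <- execute_saccade(world, make_fixation(c(5, 32), "overt"), c(64, 64))
  expect_true(all(edge$image$colorA[1:27, ] == 0))    # rows above the world
  expect_identical(edge$image$colorA[28:64, ], world$colorA[1:37, ])
  expect_error(execute_saccade(world, make_fixation(c(200, 5), "overt"),
                               c(64, 64)), "bounds")
})

test_that("location IOR forbids an immediate return saccade until it decays", {
  # two-target world; saccade A -> B, then B -> A must be blocked while the
  # FHM entry for A is fresh, and allowed again once it has decayed
  world <- list(colorA = matrix(0, 96, 96))
  world$colorA[46:50, 28:32] <- 1    # A
  world$colorA[46:50, 64:68] <- 1    # B
  sac <- execute_saccade(world, make_fixation(c(48, 66), "overt", 2), c(96, 96))
  ppm <- compute_ppm(sac$image, central_radius_px = 10)
  # undecayed history (lambda = 1): returning to A is not selectable
  fhm1 <- new_fhm(lambda = 1, epsilon = 0)
  fhm1 <- update_fhm(fhm1, make_fixation(c(48, 30), "overt", 1), radius = 6)
  fhm1 <- update_fhm(fhm1, make_fixation(c(48, 66), "overt", 2), radius = 6)
  h <- compose_hbpm(pfoa = select_pfoa(ppm, 3), fhm = fhm1, ppm = ppm,
                    view = sac$view)
  expect_null(select_next_fixation(h, sac$view))   # A inhibited, B central
  # but the task-demand override makes A immediately available again
  ho <- compose_hbpm(pfoa = select_pfoa(ppm, 3), fhm = fhm1, ppm = ppm,
                     view = sac$view, override = TRUE)
  expect_false(is.null(select_next_fixation(ho, sac$view)))
  # with decay, the entry for A expires after enough updates and is allowed
  fhm2 <- new_fhm(lambda = 0.4, epsilon = 0.05)
  fhm2 <- update_fhm(fhm2, make_fixation(c(48, 30), "overt", 1), radius = 6)
  for (i in 2:6) fhm2 <- update_fhm(fhm2, make_fixation(c(48, 66), "overt", i))
  h2 <- compose_hbpm(pfoa = select_pfoa(ppm, 3), fhm = fhm2, ppm = ppm,
                     view = sac$view)
  fx <- select_next_fixation(h2, sac$view)
  expect_false(is.null(fx))
  expect_lt(max(abs(fx$pos - c(48, 30))), 4)
})
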