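two_chan <- c("colorA", "colorB")

fresh_vh <- function(dim = 64, levels = 4, central = 10, dpp = 0.5)
  build_hierarchy(c(dim, dim), two_chan, n_levels = levels,
                  central_radius_deg = central, deg_per_pixel = dpp)

rand_img <- function(dim = 64, seed = 1) {
  set.seed(seed)
  list(colorA = matrix(runif(dim * dim), dim),
       colorB = matrix(runif(dim * dim), dim))
}

test_that("construction tiles the pyramid and starts in a neutral state", {
  vh <- fresh_vh()
  expect_equal(vh$dims[[4]], c(8L, 8L))          # 64 / 2^3
  expect_equal(vh$central_radius_px, 20)          # 10 deg at 0.5 deg/px
  for (l in 1:4) for (ch in two_chan) {
    expect_true(all(vh$suppression[[l]][[ch]] == 1))
    expect_true(all(vh$inhib_left[[l]][[ch]] == 0L))
  }
  expect_true(all(vh$channel_gains == 1))
  expect_error(build_hierarchy(c(63, 63), two_chan), "inconsistent resolutions")
  expect_error(build_hierarchy(c(64, 64), two_chan, n_levels = 2))
})

test_that("feedforward is linear and a blank image stays silent", {
  vh <- fresh_vh()
  blank <- list(colorA = matrix(0, 64, 64), colorB = matrix(0, 64, 64))
  a0 <- feedforward_pass(vh, blank)
  for (l in 1:4) for (ch in two_chan) expect_true(all(a0[[l]][[ch]] == 0))
  i1 <- rand_img(seed = 1); i2 <- rand_img(seed = 2)
  mix <- list(colorA = 0.3 * i1$colorA + 1.7 * i2$colorA,
              colorB = 0.3 * i1$colorB + 1.7 * i2$colorB)
  am <- feedforward_pass(vh, mix)
  a1 <- feedforward_pass(vh, i1); a2 <- feedforward_pass(vh, i2)
  for (l in 1:4) for (ch in two_chan)
    expect_equal(am[[l]][[ch]], 0.3 * a1[[l]][[ch]] + 1.7 * a2[[l]][[ch]],
                 tolerance = 1e-12)
  expect_error(feedforward_pass(vh, list(colorA = matrix(0, 32, 32),
                                         colorB = matrix(0, 32, 32))),
               "resolution mismatch")
})

test_that("a unit impulse propagates by the window-mean normalizers", {
  vh <- fresh_vh()
  img <- list(colorA = matrix(0, 64, 64), colorB = matrix(0, 64, 64))
  img$colorA[1, 1] <- 1
  a <- feedforward_pass(vh, img)
  # one impulse through three 2x2 mean poolings: (1/4)^3 at the top corner
  expect_equal(a[[4]]$colorA[1, 1], (1 / 4)^3)
  expect_equal(sum(a[[4]]$colorA), (1 / 4)^3)
  expect_true(all(a[[4]]$colorB == 0))
})

test_that("priming doubles a channel's responses at every level", {
  vh <- fresh_vh()
  img <- rand_img(seed = 3)
  base <- feedforward_pass(vh, img)
  vhp <- apply_priming(vh, bias_spec(c(colorA = 2)))
  primed <- feedforward_pass(vhp, img)
  for (l in 1:4) {
    expect_equal(primed[[l]]$colorA, 2 * base[[l]]$colorA, tolerance = 1e-12)
    expect_equal(primed[[l]]$colorB, base[[l]]$colorB)
  }
  # empty bias is the identity; unknown channels are named in the error
  expect_identical(apply_priming(vh, bias_spec()), vh)
  expect_error(apply_priming(vh, bias_spec(c(nope = 2))), "nope")
})

test_that("pathway inhibition silences contributions upward and expires", {
  vh <- fresh_vh()
  img <- rand_img(seed = 4)
  base <- feedforward_pass(vh, img)
  sample <- structure(list(
    root = list(level = 4L, row = 1L, col = 1L),
    levels = list("1" = data.frame(channel = "colorA", row = 3L, col = 3L)),
    edges = data.frame()), class = "attentional_sample")
  vhi <- inhibit_pathways(vh, sample, horizon = 2L)
  a <- feedforward_pass(vhi, img)
  # the parent of (3,3) at level 2 is (2,2); it loses that contribution
  w <- img$colorA[3:4, 3:4]
  expect_equal(a[[2]]$colorA[2, 2], sum(w[-1]) / 3)
  # all other level-2 units unchanged
  d <- a[[2]]$colorA != base[[2]]$colorA
  expect_identical(which(d), which(matrix(seq_len(32 * 32), 32) == 34))
  # expiry after the horizon
  vhi <- vh_tick_inhibition(vh_tick_inhibition(vhi))
  expect_true(all(vhi$inhib_left[[1]]$colorA == 0L))
  expect_identical(inhibit_pathways(vh, NULL), vh)
})

test_that("surround suppression attenuates the annulus but never the selection", {
  vh <- fresh_vh()
  sample <- structure(list(
    root = list(level = 4L, row = 2L, col = 2L),
    levels = list("4" = data.frame(channel = "colorA", row = 2L, col = 2L)),
    edges = data.frame()), class = "attentional_sample")
  vhs <- impose_surround_suppression(vh, sample, spatial_extent = 1L,
                                     feature_extent = "colorB", factor = 0)
  s <- vhs$suppression[[4]]$colorA
  expect_equal(s[2, 2], 1)                      # self-exclusion
  expect_equal(s[1, 1], 0); expect_equal(s[3, 3], 0)
  expect_equal(s[4, 4], 1)                      # outside the annulus
  # sibling-feature suppression at the selected location only
  expect_equal(vhs$suppression[[4]]$colorB[2, 2], 0)
  expect_error(impose_surround_suppression(vh, sample, factor = 1),
               "factor")
})

test_that("lifting suppression restores a fresh hierarchy except inhibition", {
  vh <- fresh_vh()
  img <- rand_img(seed = 5)
  sample <- structure(list(
    root = list(level = 4L, row = 2L, col = 2L),
    levels = list("4" = data.frame(channel = "colorA", row = 2L, col = 2L),
                  "1" = data.frame(channel = "colorA", row = 9L, col = 9L)),
    edges = data.frame()), class = "attentional_sample")
  vhs <- impose_surround_suppression(vh, sample, factor = 0.2)
  vhl <- lift_surround_suppression(vhs)
  expect_identical(vhl$suppression, vh$suppression)
  expect_identical(lift_surround_suppression(vh), vh)   # idempotent on fresh
  # state separation: suppression reset leaves inhibition untouched
  vhx <- inhibit_pathways(vhs, sample)
  vhx <- lift_surround_suppression(vhx)
  expect_true(vhx$inhib_left[[1]]$colorA[9, 9] > 0)
  a_lift <- feedforward_pass(vh_clear_inhibition(vhx), img)
  a_base <- feedforward_pass(vh, img)
  for (l in 1:4) for (ch in two_chan)
    expect_identical(a_lift[[l]][[ch]], a_base[[l]][[ch]])
})
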