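test_that("skeletonisation preserves topology of simple shapes", {
  # 5-px-wide straight bar thins to a single 1-px path
  bar <- matrix(FALSE, 15, 40)
  bar[6:10, 5:36] <- TRUE
  sk <- skeletonise(bar)
  expect_true(all(rowSums(sk)[-(6:10)] == 0))
  deg <- sum(skeleton_endpoints(sk))
  expect_equal(deg, 2L)
  expect_equal(nrow(decompose_needles(sk)), 1L)
  # ring: closed curve thins to a skeleton with no endpoints
  th <- seq(0, 2 * pi, length.out = 200)
  ring <- draw_pixels(41, 41, lapply(th, function(t) {
    c(round(21 + 12 * sin(t)), round(21 + 12 * cos(t)))
  }))
  skr <- skeletonise(ring)
  expect_equal(sum(skeleton_endpoints(skr)), 0L)
  # a clean pixel diamond (every pixel of degree 2) is one closed segment
  pts <- list()
  for (k in 0:7) {
    pts <- c(pts, list(c(13 + k, 21 + k), c(29 - k, 21 + k),
                       c(13 + k, 21 - k), c(29 - k, 21 - k)))
  }
  pts <- c(pts, list(c(21, 29), c(21, 13)))
  diamond <- draw_pixels(41, 41, unique(pts))
  expect_equal(sum(skeleton_endpoints(diamond)), 0L)
  segs <- decompose_needles(diamond)
  expect_equal(nrow(segs), 1L)
  expect_true(segs$closed)
  expect_equal(segs$length, 32 * sqrt(2), tolerance = 1e-9)
})

test_that("Y and X junctions decompose into the expected segments", {
  # Y: three arms meeting at (21, 21)
  y_arms <- c(lapply(0:14, function(k) c(21 - k, 21)),        # up
              lapply(1:14, function(k) c(21 + k, 21 - k)),    # down-left
              lapply(1:14, function(k) c(21 + k, 21 + k)))    # down-right
  yshape <- draw_pixels(41, 41, y_arms)
  sk <- skeletonise(yshape)
  expect_equal(sum(skeleton_endpoints(sk)), 3L)
  deg <- cccfp:::.neighbour_count(sk)
  expect_gte(sum(sk & deg >= 3), 1L)                          # branch point
  expect_equal(nrow(decompose_needles(sk)), 3L)
  # X: two crossing diagonals, 4 segments at one node
  x_arms <- c(lapply(-14:14, function(k) c(21 + k, 21 + k)),
              lapply(-14:14, function(k) c(21 + k, 21 - k)))
  xshape <- draw_pixels(41, 41, x_arms)
  skx <- skeletonise(xshape)
  expect_equal(sum(skeleton_endpoints(skx)), 4L)
  expect_equal(nrow(decompose_needles(skx)), 4L)
})

test_that("structure features reproduce hand-measured needle counts", {
  # three disjoint horizontal runs of 11, 22 and 31 pixels:
  # step-sum lengths 10, 21 and 30
  m <- draw_pixels(30, 40, c(hrun(5, 3, 11), hrun(15, 3, 22), hrun(25, 3, 31)))
  sk <- skeletonise(m)  # already 1-px wide; must be preserved
  segs <- decompose_needles(sk)
  expect_setequal(round(segs$length), c(10, 21, 30))
  f <- structure_features(segs, sk)
  expect_equal(unname(f["lend"]), 6)
  expect_equal(unname(f["l220"]), 1)   # 21 in [19.2, 22)
  expect_equal(unname(f["l250"]), 1)   # 30 >= 22
  # boundary: length exactly 22 falls in the top bin (right-open bins)
  m22 <- draw_pixels(10, 30, hrun(5, 3, 23))
  sk22 <- skeletonise(m22)
  f22 <- structure_features(decompose_needles(sk22), sk22)
  expect_equal(unname(f22["l220"]), 0)
  expect_equal(unname(f22["l250"]), 1)
  # empty skeleton: all counts zero
  sk0 <- matrix(FALSE, 5, 5)
  f0 <- structure_features(decompose_needles(sk0), sk0)
  expect_true(all(f0 == 0))
})

test_that("length bins conserve the segment count and respond to scaling", {
  img <- simulate_fingerprint(growth_params(n_seeds = 6, branch_prob = 0.15,
                                            plate_radius = 64), seed = 3)
  fg <- binarise(img)
  sk <- skeletonise(fg)
  segs <- decompose_needles(sk, binary = fg)
  f <- structure_features(segs, sk)
  lbins <- f[grep("^l\\d", names(f))]
  wbins <- f[grep("^w\\d", names(f))]
  expect_length(lbins, 15L)
  expect_length(wbins, 15L)
  expect_equal(sum(lbins), unname(f["n_needles"]))
  expect_equal(sum(wbins), unname(f["n_needles"]))
  # doubling all lengths moves mass toward the top bin
  segs2 <- segs
  segs2$length <- segs2$length * 2
  f2 <- structure_features(segs2, sk)
  expect_gte(f2[["l250"]], f[["l250"]])
})

test_that("endpoint counts match a brute-force neighbourhood scan", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      img <- simulate_fingerprint(
        growth_params(n_seeds = sample(1:4, 1), branch_prob = runif(1, 0, 0.3),
                      length_scale = runif(1, 15, 35), plate_radius = 64,
                      texture_grain = c(0.05, 2)),
        seed = sample.int(10000, 1))
      sk <- skeletonise(binarise(img))
      expect_equal(sum(skeleton_endpoints(sk)), brute_endpoints(sk))
    }
  })
})

test_that("tree-skeleton parity: lend = 2*components + degree surplus", {
  # for an acyclic skeleton, every branch event of degree k (k >= 3)
  # converts k - 2 would-be endpoints; verified on a two-component fixture
  arms <- c(lapply(0:10, function(k) c(15 - k, 20)),
            lapply(1:10, function(k) c(15 + k, 20 - k)),
            lapply(1:10, function(k) c(15 + k, 20 + k)))
  comp2 <- hrun(28, 2, 12)
  m <- draw_pixels(32, 40, c(arms, comp2))
  sk <- skeletonise(m)
  deg <- cccfp:::.neighbour_count(sk)
  lend <- sum(skeleton_endpoints(sk))
  # Y component: 3 endpoints + 1 branch of degree 3; bar: 2 endpoints
  expect_equal(lend, 5L)
  expect_equal(sum(sk & deg >= 3L), 1L)
  # parity: 2 components, one degree-3 branch -> 2*2 + (3 - 2) = 5
  n_comp <- count_components8(sk)
  surplus <- sum(pmax(deg[sk] - 2L, 0L))
  expect_equal(lend, 2L * n_comp + surplus)
})

test_that("binarisation is robust to a linear illumination ramp", {
  img <- simulate_fingerprint(growth_params(n_seeds = 3, branch_prob = 0,
                                            plate_radius = 64,
                                            texture_grain = c(0, 0)), seed = 5)
  ramp <- img
  grad <- round(outer(seq_len(nrow(img$pixels)), rep(1, ncol(img$pixels))) / 8)
  ramp$pixels <- pmax(pmin(img$pixels + grad, 255L), 0L)
  storage.mode(ramp$pixels) <- "integer"
  n_comp <- function(im) count_components8(binarise(im))
  expect_equal(n_comp(ramp), n_comp(img))
  # blank plate: empty foreground with a warning
  blank <- ccc_image(matrix(60L, 129, 129), plate_radius = 64)
  expect_warning(fg <- binarise(blank), "empty foreground")
  expect_false(any(fg))
})
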