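test_that("grid fixtures are two overlapping 3x3 patterns", {
  ps <- make_grid_patterns()
  expect_length(ps, 2)
  for (p in ps) {
    expect_length(p$pixels, 9)
    expect_gte(sum(p$pixels), 2)   # bidirectional pairs can form
  }
  expect_true(any(ps[[1]]$pixels != ps[[2]]$pixels))
  expect_gt(sum(ps[[1]]$pixels & ps[[2]]$pixels), 0)  # partial overlap
})

test_that("synthetic contours are thin, centered and reproducible", {
  for (shape in c("circle", "polygon", "blob")) {
    p <- synth_contour_image(shape, 32, seed = 3)
    expect_equal(c(p$width, p$height), c(32L, 32L))
    a <- sum(p$pixels)
    # a closed outline, not a filled disk: pixel count scales with the
    # perimeter, well below the enclosed area
    expect_gt(a, 30)
    expect_lt(a, 200)
    m <- as_matrix(p)
    rc <- which(m == 1, arr.ind = TRUE)
    expect_lt(abs(mean(rc[, 1]) - 16.5), 1)
    expect_lt(abs(mean(rc[, 2]) - 16.5), 1)
    expect_identical(p, synth_contour_image(shape, 32, seed = 3))
  }
  expect_false(identical(synth_contour_image("blob", 32, 1),
                         synth_contour_image("blob", 32, 2)))
  expect_error(synth_contour_image("circle", 4), "size")
  expect_error(synth_contour_image("circle", 32, radius_frac = 0),
               "degenerate")
})

test_that("edge detection marks intensity steps (brute-force oracle)", {
  img <- matrix(0, 5, 5)
  img[, 4:5] <- 1                      # vertical step between cols 3|4
  p <- edge_detect(img, 0.5, center = FALSE)
  m <- as_matrix(p)
  expect_true(all(m %in% c(0, 1)))
  # brute-force 4-neighbour oracle
  ref <- matrix(0L, 5, 5)
  for (r in 1:5) for (cc in 1:5) {
    for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
      rr <- r + d[1]; ccc <- cc + d[2]
      if (rr >= 1 && rr <= 5 && ccc >= 1 && ccc <= 5 &&
          abs(img[r, cc] - img[rr, ccc]) > 0.5) ref[r, cc] <- 1L
    }
  }
  expect_identical(m, ref)
  expect_true(all(which(ref == 1, arr.ind = TRUE)[, 2] %in% c(3, 4)))
  # constant image: empty pattern, reported but not raised
  expect_warning(p0 <- edge_detect(matrix(1, 4, 4), 0.5), "empty|threshold")
  expect_identical(sum(p0$pixels), 0L)
})

test_that("fragmentation keeps a nested random subset", {
  p <- synth_contour_image("circle", 32, seed = 1)
  a <- sum(p$pixels)
  expect_identical(fragment_pattern(p, 1, seed = 9)$pixels, p$pixels)
  f5 <- fragment_pattern(p, 0.5, seed = 9)
  expect_identical(sum(f5$pixels), as.integer(ceiling(0.5 * a)))
  expect_true(all(active_pixels(f5) %in% active_pixels(p)))
  expect_identical(f5, fragment_pattern(p, 0.5, seed = 9))
  # nesting under a shared seed
  f3 <- fragment_pattern(p, 0.3, seed = 9)
  expect_true(all(active_pixels(f3) %in% active_pixels(f5)))
})

test_that("stimulus programs encode the coding schemes", {
  np <- default_neuron()
  # temporal: 9 pixels, stride 17 ms, no overlap, single loop
  sp <- temporal_program(pattern(rep(1L, 9), 3), stride_ms = 17,
                         item_ms = 17, I0_ext = 1e-3, loops = 1,
                         gap_ms = 0)
  expect_equal(sum(sp$durations_ms), 9 * 17)
  # at most one item active at any instant without overlap
  expect_true(all(rowSums(sp$currents > 0) <= 1))
  # overlapping items: at most two active, currents never add up
  sp2 <- temporal_program(pattern(rep(1L, 9), 3), stride_ms = 17,
                          item_ms = 34, I0_ext = 1e-3, loops = 1,
                          gap_ms = 0)
  expect_true(all(rowSums(sp2$currents > 0) <= 2))
  expect_true(all(sp2$currents <= 1e-3 + 1e-15))
  # four images at 19.2 ms for 500 loops span 38.4 s
  imgs <- replicate(4, pattern(c(1, rep(0, 8)), 3), simplify = FALSE)
  sp3 <- temporal_program(imgs, stride_ms = 19.2, item_ms = 19.2,
                          I0_ext = 1e-3, loops = 500, gap_ms = 0)
  expect_equal(sum(sp3$durations_ms) * sp3$repeats, 4 * 19.2 * 500)
  # rate program: four patterns cycled every 19.2 ms for 7.2 s
  rp <- rate_program(make_grid_patterns(), I0_ext = 1e-3,
                     window_ms = 19.2, cycles = 188)
  expect_equal(sum(rp$durations_ms) * rp$repeats, 2 * 19.2 * 188)
})

test_that("completion quality is the normalized mean internal rate", {
  tgt <- pattern(c(1, 1, 1, 0), 2)
  fake <- structure(list(
    spikes = data.frame(neuron = c(rep(1L, 10), rep(2L, 5)),
                        t_ms = seq(1, 999, length.out = 15)),
    duration_ms = 1000, config = list(n = 4)),
    class = "simulation_result")
  # neurons 1 and 2 are internal targets (3 was stimulated): rates 10, 5
  expect_equal(completion_quality(fake, tgt, 3L, f_max = 10), 0.75)
  # all at f_max -> 1; silence -> 0
  expect_equal(completion_quality(fake, tgt, c(2L, 3L), f_max = 10), 1)
  fake0 <- fake; fake0$spikes <- fake0$spikes[0, ]
  expect_equal(completion_quality(fake0, tgt, 3L, f_max = 10), 0)
  expect_error(completion_quality(fake, tgt, 3L, f_max = 0), "f_max")
  # invariance to target-neuron relabeling: a = 2, rates (f_max, 0)
  tgt2 <- pattern(c(0, 1, 0, 1), 2)
  fake2 <- fake; fake2$spikes <- data.frame(neuron = rep(2L, 10),
                                            t_ms = seq(1, 999, 100))
  expect_equal(completion_quality(fake2, tgt2, integer(0), f_max = 10),
               0.5)
})

test_that("connection census matches an exhaustive reference", {
  p <- default_plast()
  # symmetric matrix: index 1, no unidirectional edges
  w <- init_network(6, "uniform", p, seed = 4)
  ws <- (w + t(w)) / 2; diag(ws) <- 0
  cen <- connection_census(ws, 0.525)
  expect_equal(cen$symmetry_index, 1)
  expect_identical(cen$unidirectional, 0L)
  # directed chain: strong forward, weak backward
  wc <- matrix(0.1, 9, 9); diag(wc) <- 0
  for (i in 1:8) wc[i, i + 1] <- 0.9
  cen2 <- connection_census(wc, 0.525)
  expect_identical(cen2$unidirectional, 8L)
  expect_identical(cen2$bidirectional, 0L)
  # everything below threshold
  cen3 <- connection_census(matrix(0.1, 3, 3) - diag(0.1, 3), 0.525)
  expect_identical(c(cen3$bidirectional, cen3$unidirectional), c(0L, 0L))
  expect_true(is.finite(cen3$symmetry_index))
  # exhaustive O(n^2) oracle on random matrices up to n = 50
  set.seed(99)
  for (n in c(5, 17, 50)) {
    w <- init_network(n, "uniform", p, seed = n + 1)
    thr <- 0.525
    bid <- 0L; uni <- 0L
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      sij <- w[i, j] >= thr; sji <- w[j, i] >= thr
      if (sij && !sji) uni <- uni + 1L
      if (i < j && sij && sji) bid <- bid + 1L
    }
    num <- 0; den <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      num <- num + abs(w[i, j] - w[j, i]); den <- den + w[i, j] + w[j, i]
    }
    cen <- connection_census(w, thr)
    expect_identical(cen$bidirectional, bid)
    expect_identical(cen$unidirectional, uni)
    expect_equal(cen$symmetry_index, 1 - num / den, tolerance = 1e-12)
  }
})

test_that("patterns round-trip through the plain-text image formats", {
  p <- synth_contour_image("polygon", 16, seed = 5)
  for (ext in c(".pbm", ".pgm", ".txt")) {
    f <- tempfile(fileext = ext)
    write_pattern(p, f)
    expect_identical(read_pattern(f)$pixels, p$pixels)
  }
})
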