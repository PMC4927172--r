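# Transform correctness: annihilation of constants, impulse responses,
# energy conservation, perfect reconstruction, shift equivariance, the
# DWT-from-MODWT subsampling identity, MRA additivity, agreement with the
# direct equivalent-filter oracle and with the frozen cross-library fixture,
# and the scale -> frequency mapping.

test_that("wavelet coefficients annihilate constant series", {
  x <- rep(3.7, 96)
  for (nm in c("D2", "D8", "LA8", "C6")) {
    d <- suppressWarnings(modwt(x, nm, 4))
    for (j in 1:4) expect_lt(max(abs(d$W[[j]])), 1e-10)
    dd <- dwt(x, nm, 3)
    for (j in 1:3) expect_lt(max(abs(dd$W[[j]])), 1e-10)
  }
})

test_that("Haar MODWT of a unit impulse has two coefficients of magnitude 1/2", {
  x <- c(1, rep(0, 7))
  d <- modwt(x, "D2", 1)
  w <- d$W[[1]]
  expect_equal(sort(abs(w[w != 0])), c(0.5, 0.5))
  expect_equal(sum(w != 0), 2)
})

test_that("MODWT conserves energy and reconstructs exactly", {
  set.seed(42)
  for (spec in list(list(n = 128, f = "D8"), list(n = 100, f = "C6"),
                    list(n = 177, f = "LA8"))) {
    x <- rnorm(spec$n)
    d <- modwt(x, spec$f, 4)
    energy <- sum(vapply(d$W, function(w) sum(w^2), 0)) + sum(d$V^2)
    expect_lt(abs(energy - sum(x^2)) / sum(x^2), 1e-8)
    expect_lt(max(abs(imodwt(d) - x)), 1e-10)
  }
})

test_that("zeroed coefficients invert to the zero series", {
  d <- modwt(rnorm(64), "D4", 3)
  d$W <- lapply(d$W, function(w) w * 0)
  d$V <- d$V * 0
  expect_equal(imodwt(d), rep(0, 64))
})

test_that("MODWT round trip recovers an impulse", {
  x <- c(rep(0, 10), 1, rep(0, 21))
  d <- modwt(x, "D4", 3)
  expect_lt(max(abs(imodwt(d) - x)), 1e-12)
})

test_that("MODWT is equivariant under circular shifts", {
  set.seed(7)
  x <- rnorm(96)
  d0 <- modwt(x, "LA8", 3)
  for (k in c(1, 5, 40)) {
    dk <- modwt(circ_shift(x, k), "LA8", 3)
    for (j in 1:3) expect_equal(dk$W[[j]], circ_shift(d0$W[[j]], k))
    expect_equal(dk$V, circ_shift(d0$V, k))
  }
})

test_that("MODWT pyramid agrees with the direct equivalent-filter transform", {
  set.seed(13)
  x <- rnorm(64)
  for (nm in c("D4", "LA8", "C6")) {
    d <- modwt(x, nm, 3)
    o <- modwt_direct(x, wavelet_filter(nm), 3)
    for (j in 1:3) expect_equal(d$W[[j]], o$W[[j]], tolerance = 1e-12)
    expect_equal(d$V, o$V, tolerance = 1e-12)
  }
})

test_that("MODWT matches the frozen independent-library fixture", {
  d <- suppressWarnings(modwt(pywt_fixture_x, "LA8", 3))
  expect_equal(d$W[[1]], pywt_fixture_la8_w1, tolerance = 1e-8)
  expect_equal(d$W[[2]], pywt_fixture_la8_w2, tolerance = 1e-8)
  expect_equal(d$W[[3]], pywt_fixture_la8_w3, tolerance = 1e-8)
  expect_equal(d$V, pywt_fixture_la8_v3, tolerance = 1e-8)
  d <- suppressWarnings(modwt(pywt_fixture_x, "C6", 3))
  expect_equal(d$W[[1]], pywt_fixture_c6_w1, tolerance = 1e-8)
  expect_equal(d$W[[2]], pywt_fixture_c6_w2, tolerance = 1e-8)
  expect_equal(d$W[[3]], pywt_fixture_c6_w3, tolerance = 1e-8)
  expect_equal(d$V, pywt_fixture_c6_v3, tolerance = 1e-8)
})

test_that("DWT of a constant collapses to the scaled mean", {
  d <- dwt(rep(1, 8), "D2", 3)
  for (j in 1:3) expect_lt(max(abs(d$W[[j]])), 1e-12)
  expect_equal(d$V, 2 * sqrt(2))
})

test_that("DWT handles the study's post-deletion length with the carry rule", {
  set.seed(3)
  x <- rnorm(177)
  for (nm in c("D2", "LA8", "C6")) {
    d <- suppressWarnings(dwt(x, nm, 4))
    expect_equal(vapply(d$W, length, 0L), c(88L, 44L, 22L, 11L))
    expect_equal(length(d$V), 12L)   # 11 smooth + 1 carried coefficient
    total <- sum(vapply(d$W, length, 0L)) + length(d$V)
    expect_equal(total, 177L)
    expect_lt(max(abs(idwt(d) - x)), 1e-10)
  }
})

test_that("DWT is orthonormal and invertible for power-of-two lengths", {
  set.seed(8)
  x <- rnorm(64)
  d <- suppressWarnings(dwt(x, "LA8", 4))
  energy <- sum(vapply(d$W, function(w) sum(w^2), 0)) + sum(d$V^2)
  expect_lt(abs(energy - sum(x^2)) / sum(x^2), 1e-12)
  expect_lt(max(abs(idwt(d) - x)), 1e-10)
  # odd intermediate lengths round-trip too
  y <- rnorm(100)
  expect_lt(max(abs(idwt(dwt(y, "C6", 4)) - y)), 1e-10)
})

test_that("DWT equals rescaled subsampled MODWT for power-of-two lengths", {
  set.seed(21)
  x <- rnorm(64)
  for (nm in c("D4", "LA8")) {
    dm <- modwt(x, nm, 3)
    dw <- dwt(x, nm, 3)
    for (j in 1:3) {
      idx <- 2^j * seq_len(64 / 2^j)      # zero-based 2^j (t+1) - 1
      expect_lt(max(abs(dw$W[[j]] - 2^(j / 2) * dm$W[[j]][idx])), 1e-10)
    }
  }
})

test_that("MRA details are additive and defined only for MODWT", {
  set.seed(5)
  x <- rnorm(80)
  m <- mra(suppressWarnings(modwt(x, "D8", 4)))
  expect_lt(max(abs(Reduce(`+`, m$D) + m$S - x)), 1e-10)
  expect_equal(vapply(m$D, length, 0L), rep(80L, 4))
  # constants: all detail in the smooth
  mc <- mra(modwt(rep(2, 32), "D4", 3))
  for (j in 1:3) expect_lt(max(abs(mc$D[[j]])), 1e-12)
  expect_equal(mc$S, rep(2, 32), tolerance = 1e-12)
  # single-scale Haar case still additive
  m1 <- mra(modwt(x, "D2", 1))
  expect_lt(max(abs(m1$D[[1]] + m1$S - x)), 1e-10)
  expect_error(mra(dwt(x, "D4", 2)), "MODWT")
})

test_that("matrix input decomposes each column like the vector transform", {
  set.seed(9)
  X <- matrix(rnorm(64 * 3), 64, 3)
  dM <- modwt(X, "D4", 3)
  for (col in 1:3) {
    dv <- modwt(X[, col], "D4", 3)
    for (j in 1:3) expect_equal(dM$W[[j]][, col], dv$W[[j]])
  }
  dD <- dwt(X, "LA8", 2)
  dv <- dwt(X[, 2], "LA8", 2)
  expect_equal(dD$W[[2]][, 2], dv$W[[2]])
})

test_that("degenerate inputs and method mismatches are rejected", {
  expect_error(modwt(numeric(0), "D4"), "2 timepoints")
  expect_error(modwt(c(1, NA, 3), "D4"), "non-finite")
  expect_error(imodwt(dwt(rnorm(32), "D4", 2)), "MODWT")
  expect_error(idwt(modwt(rnorm(32), "D4", 2)), "DWT")
  expect_warning(modwt(rnorm(16), "LA20", 4), "exceeds series length")
})

test_that("scale-to-frequency mapping matches the TR = 2 s band edges", {
  b1 <- scale_to_band(2.0, 1)
  expect_equal(c(b1$low_hz, b1$high_hz), c(0.125, 0.25))
  b2 <- scale_to_band(2.0, 2)
  expect_equal(c(b2$low_hz, b2$high_hz), c(0.0625, 0.125))
  b <- scale_to_band(1.0, 1)
  expect_equal(c(b$low_hz, b$high_hz), c(0.25, 0.5))
  expect_lt(b2$low_hz, b2$high_hz)
})
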