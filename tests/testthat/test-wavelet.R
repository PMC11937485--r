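test_that("2x2 worked examples follow the subband orientation convention", {
  sb <- haar_dwt2(matrix(1, 2, 2))
  expect_equal(sb$CA, matrix(2), ignore_attr = TRUE)
  expect_equal(sb$CH, matrix(0), ignore_attr = TRUE)
  expect_equal(sb$CV, matrix(0), ignore_attr = TRUE)
  expect_equal(sb$CD, matrix(0), ignore_attr = TRUE)

  x <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  sb <- haar_dwt2(x)
  expect_equal(sb$CA[1, 1], 5)
  expect_equal(sb$CH[1, 1], -2)  # horizontal-edge content: rows 1 vs 2
  expect_equal(sb$CV[1, 1], -1)  # vertical-edge content: cols 1 vs 2
  expect_equal(sb$CD[1, 1], 0)

  # inverse of the constant case
  rec <- haar_idwt2(list(CA = matrix(2), CH = matrix(0), CV = matrix(0),
                         CD = matrix(0)))
  expect_equal(rec, matrix(1, 2, 2))
})

test_that("subbands halve even dimensions, including 256 -> 128", {
  img <- matrix(stats::rnorm(256 * 256), 256, 256)
  sb <- haar_dwt2(img)
  for (nm in c("CA", "CH", "CV", "CD")) {
    expect_identical(dim(sb[[nm]]), c(128L, 128L))
  }
  expect_identical(dim(haar_dwt2(matrix(0, 10, 6))$CD), c(5L, 3L))
})

test_that("perfect reconstruction and Parseval hold on random even images", {
  set.seed(401)
  for (i in 1:100) {
    h <- 2L * sample(2:24, 1)
    w <- 2L * sample(2:24, 1)
    x <- matrix(stats::rnorm(h * w), h, w)
    sb <- haar_dwt2(x)
    expect_lt(max(abs(haar_idwt2(sb) - x)), 1e-10)
    e_in <- sum(x^2)
    e_out <- sum(sb$CA^2) + sum(sb$CH^2) + sum(sb$CV^2) + sum(sb$CD^2)
    expect_lt(abs(e_in - e_out) / e_in, 1e-8)
  }
})

test_that("transform matches the brute-force 2x2 block oracle", {
  set.seed(402)
  for (i in 1:20) {
    x <- matrix(stats::rnorm(64), 8, 8)
    got <- haar_dwt2(x)
    want <- oracle_haar2(x)
    for (nm in names(want)) {
      expect_lt(max(abs(got[[nm]] - want[[nm]])), 1e-10)
    }
  }
})

test_that("the transform is linear", {
  set.seed(403)
  x <- matrix(stats::rnorm(36), 6, 6)
  y <- matrix(stats::rnorm(36), 6, 6)
  a <- 2.5
  b <- -1.25
  lhs <- haar_dwt2(a * x + b * y)
  sx <- haar_dwt2(x)
  sy <- haar_dwt2(y)
  for (nm in c("CA", "CH", "CV", "CD")) {
    expect_equal(lhs[[nm]], a * sx[[nm]] + b * sy[[nm]])
  }
})

test_that("odd sizes use periodization and still round-trip", {
  set.seed(404)
  x <- matrix(stats::rnorm(7 * 9), 7, 9)
  sb <- haar_dwt2(x)
  expect_identical(dim(sb$CA), c(4L, 5L))  # ceiling(n/2)
  expect_lt(max(abs(haar_idwt2(sb) - x)), 1e-10)
})

test_that("degenerate and mismatched inputs are rejected", {
  expect_error(haar_dwt2(matrix(1, 1, 5)), "at least 2x2")
  expect_error(
    haar_idwt2(list(CA = matrix(0, 2, 2), CH = matrix(0, 2, 2),
                    CV = matrix(0, 2, 2), CD = matrix(0, 3, 2))),
    "shapes differ"
  )
})

test_that("volumes decompose slice-wise into half-size stacks", {
  vol <- array(stats::rnorm(6 * 16 * 16), dim = c(6, 16, 16))
  sb <- decompose_volume(vol)
  expect_identical(dim(sb$CD), c(6L, 8L, 8L))

  # no cross-slice mixing: each slice equals its own 2D transform
  for (j in c(1, 4, 6)) {
    expect_equal(sb$CH[j, , ], haar_dwt2(vol[j, , ])$CH)
  }

  # constant slices carry no detail
  cvol <- array(3, dim = c(4, 8, 8))
  sbc <- decompose_volume(cvol)
  expect_true(all(sbc$CH == 0) && all(sbc$CV == 0) && all(sbc$CD == 0))

  # slice-wise inverse restores the volume
  rec <- vapply(seq_len(dim(vol)[1]), function(j) {
    haar_idwt2(list(CA = sb$CA[j, , ], CH = sb$CH[j, , ],
                    CV = sb$CV[j, , ], CD = sb$CD[j, , ]))
  }, matrix(0, 16, 16))
  expect_lt(max(abs(aperm(rec, c(3, 1, 2)) - vol)), 1e-10)
})

test_that("ideal radial filters pass, block and split frequencies correctly", {
  set.seed(405)
  img <- matrix(stats::rnorm(32 * 32), 32, 32)

  # lowpass at the Nyquist radius is all-pass
  expect_lt(max(abs(frequency_filter(img, nyquist_radius(img), "lowpass") -
                      img)), 1e-8)

  # highpass removes DC entirely
  expect_lt(max(abs(frequency_filter(matrix(5, 16, 16), 2, "highpass"))),
            1e-10)

  # pure sinusoid at radius 4 (cycles/image) lives on one side of the cutoff
  n <- 32
  sin4 <- outer(rep(1, n), sin(2 * pi * 4 * (0:(n - 1)) / n))
  lo3 <- frequency_filter(sin4, 3, "lowpass")
  lo5 <- frequency_filter(sin4, 5, "lowpass")
  expect_lt(sum(lo3^2) / sum(sin4^2), 1e-12)
  expect_lt(max(abs(lo5 - sin4)), 1e-8)

  expect_error(frequency_filter(img, 0, "lowpass"), "cutoff")
  expect_error(frequency_filter(img, nyquist_radius(img) + 1, "highpass"),
               "cutoff")
})
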