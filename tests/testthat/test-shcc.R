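test_that("resampling picks S+1 snapped sample indices without interpolation", {
  cv <- erp_curve(1:204, rnorm(204))
  rc <- resample_curve(cv, 16)
  expect_equal(nrow(rc), 17)
  expect_equal(rc$x, seq(1, 193, by = 12))  # Delta = 204/17 = 12
  expect_true(all(rc$y %in% cv$y))

  # S = T - 1 keeps every sample (the no-interpolation maximum)
  cv10 <- erp_curve(1:10, rnorm(10))
  expect_equal(resample_curve(cv10, 9)$x, 1:10)

  # T = 10, S = 1: round(1 + m * 5) for m = 0, 1
  expect_equal(resample_curve(cv10, 1)$x, c(1, 6))

  expect_error(resample_curve(cv10, 10), "S must satisfy")
})

test_that("unit-square normalization handles affine and flat curves", {
  cv <- erp_curve(1:3, c(-5, 0, 5))
  nc <- normalize_curve(cv)
  expect_equal(nc$x, c(0, 0.5, 1))
  expect_equal(nc$y, c(0, 0.5, 1))

  # idempotence on an already-normalized curve
  nc2 <- normalize_curve(erp_curve(c(1, 2, 3), c(0, 0.5, 1)))
  expect_equal(normalize_curve(nc2)$y, nc2$y)

  # flat-curve convention: constant y maps to zeros
  flat <- normalize_curve(erp_curve(1:4, rep(3, 4)))
  expect_equal(flat$y, rep(0, 4))
})

test_that("chain encoding matches closed-form slopes and odd symmetry", {
  # horizontal curve -> all-zero chain
  flat <- erp_curve(1:20, rep(1, 20))
  expect_equal(as.numeric(encode_chain(flat, 4)), rep(0, 4))

  # straight ramp: every segment runs along the unit-square diagonal with
  # slope (1/S) / (1/S) = 1, i.e. 45 degrees -> symbol 0.50
  ramp <- erp_curve(1:204, 2 + 0.1 * (1:204))
  ch <- encode_chain(ramp, 16)
  expect_equal(as.numeric(ch), rep(round(atan(1) * 180 / pi / 90, 2), 16))

  # y-mirroring negates every symbol
  cv <- erp_curve(1:204, sin(2 * pi * (1:204) / 204) + 0.3 * cos(7 * (1:204) / 204))
  up <- encode_chain(cv, 16)
  dn <- encode_chain(erp_curve(cv$x, -cv$y), 16)
  expect_equal(as.numeric(dn), -as.numeric(up))
})

test_that("chain encoding is invariant under amplitude translation", {
  cv <- erp_curve(1:100, cumsum(rnorm(100)))
  base <- encode_chain(cv, 12)
  for (shift in c(-40, 3.7, 1e4)) {
    expect_equal(as.numeric(encode_chain(erp_curve(cv$x, cv$y + shift), 12)),
                 as.numeric(base))
  }
  # both codec modes share the invariance
  expect_equal(as.numeric(encode_chain(erp_curve(cv$x, cv$y + 5), 12, "rise")),
               as.numeric(encode_chain(cv, 12, "rise")))
})

test_that("perturbing unselected samples leaves the chain unchanged; a shared
           endpoint touches at most its two segments", {
  withr::with_seed(21, {
    cv <- erp_curve(1:204, rnorm(204))
  })
  base <- encode_chain(cv, 16)
  sel <- seq(1, 193, by = 12)
  # perturb a sample strictly between two selected endpoints
  inside <- setdiff(1:204, sel)[5]
  y2 <- cv$y
  # keep the perturbation inside the existing y-range so min/max are stable
  y2[inside] <- (max(cv$y) + min(cv$y)) / 2
  expect_equal(as.numeric(encode_chain(erp_curve(cv$x, y2), 16)),
               as.numeric(base))

  # perturb one interior selected endpoint that is not the min/max of the
  # selected values (so the unit-square normalization is unchanged)
  selv <- cv$y[sel]
  ok <- setdiff(2:16, c(which.min(selv), which.max(selv)))
  ep <- sel[ok[5]]
  y3 <- cv$y
  y3[ep] <- (max(selv) + min(selv)) / 2
  pert <- encode_chain(erp_curve(cv$x, y3), 16)
  expect_lte(sum(as.numeric(pert) != as.numeric(base)), 2)
})

test_that("chain distance reproduces the printed worked examples", {
  ch <- make_fixture_chains()
  expect_equal(chain_distance(ch$template, ch$p300), 0.55)
  expect_equal(chain_distance(ch$template, ch$nonp300), 0.92)
  expect_equal(chain_distance(ch$template, ch$template), 0)
  expect_error(chain_distance(ch$template, shcc_chain(c(0.1, 0.2))), "lengths")
})

test_that("chain distance satisfies the metric axioms on random chains", {
  withr::with_seed(77, {
    for (i in 1:300) {
      a <- random_chain(16); b <- random_chain(16); c <- random_chain(16)
      dab <- chain_distance(a, b)
      expect_gte(dab, 0)
      expect_equal(dab, chain_distance(b, a))
      expect_equal(chain_distance(a, a), 0)
      expect_lte(chain_distance(a, c), dab + chain_distance(b, c) + 1e-12)
    }
  })
})

test_that("tortuosity reproduces the printed example and its bounds", {
  ch <- make_fixture_chains()
  expect_equal(tortuosity(ch$fig1), 0.64)
  expect_equal(tortuosity(shcc_chain(rep(0, 16))), 0)
  expect_equal(tortuosity(shcc_chain(c(0.5, -0.5))), 1.0)

  withr::with_seed(5, {
    for (i in 1:50) {
      x <- random_chain(12)
      expect_lte(tortuosity(x), 12 * max(abs(as.numeric(x))))
      # monotone under elementwise magnitude increase
      bigger <- shcc_chain(pmin(pmax(round(as.numeric(x) * 1.5, 2), -0.99), 0.99))
      expect_gte(tortuosity(bigger), tortuosity(x))
    }
  })
})

test_that("chains serialize in the two-decimal space-separated dialect", {
  ch <- make_fixture_chains()
  f <- withr::local_tempfile(fileext = ".txt")
  write_chains(ch, f)
  back <- read_chains(f)
  expect_equal(lapply(back, as.numeric), lapply(unname(ch), as.numeric))
  expect_match(readLines(f)[1], "^0\\.05 -0\\.02")

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines("0.05 zebra 0.01", f2)
  expect_error(read_chains(f2), "non-numeric token")
})

test_that("chain construction rejects out-of-alphabet symbols", {
  expect_error(shcc_chain(c(0.5, 1.0)), "inside")
  expect_error(shcc_chain(c(0.123)), "two decimals")
  expect_error(shcc_chain(numeric(0)), "at least one")
})
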