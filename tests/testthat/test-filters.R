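# Butterworth design + zero-lag filtering.

test_that("Butterworth designs match independently computed coefficients", {
  # frozen oracle: scipy.signal.butter(4, [20, 500], fs=2000, 'bandpass')
  # and butter(4, 5, fs=2000, 'low'), computed during development
  bp <- butter_design(4, c(20, 500), 2000, "bandpass")
  b_ref <- c(0.08267262046299347, 0, -0.33069048185197386, 0,
             0.4960357227779608, 0, -0.33069048185197386, 0,
             0.08267262046299347)
  a_ref <- c(1, -3.90294152584608, 6.295899618843083, -5.912853444916814,
             4.05842349746671, -2.108941249738028, 0.6513288131850998,
             -0.09902933066729717, 0.01813707703045073)
  expect_equal(bp$b, b_ref, tolerance = 1e-12)
  expect_equal(bp$a, a_ref, tolerance = 1e-12)

  lp <- butter_design(4, 5, 2000, "low")
  expect_equal(lp$b,
               c(3.728051643262425e-09, 1.491220657304970e-08,
                 2.236830985957455e-08, 1.491220657304970e-08,
                 3.728051643262425e-09), tolerance = 1e-10)
  expect_equal(lp$a,
               c(1, -3.958953318647084, 5.877700273536146,
                 -3.8785305490517348, 0.9597836538114992),
               tolerance = 1e-12)
})

test_that("band-pass preserves pass-band and rejects stop-band sinusoids", {
  t <- seq(0, 2, by = 1 / 2000)
  core <- 1000:3000
  y100 <- bandpass_zero_lag(sin(2 * pi * 100 * t), 2000)
  expect_lt(abs(max(y100[core]) - 1), 0.02)
  # zero phase: same zero crossings as the input
  expect_lt(max(abs(y100[core] - sin(2 * pi * 100 * t)[core])), 0.02)
  # 1 Hz deep in the stop band: |H|^2 of a 4th-order 20 Hz high-pass edge
  # at 1 Hz is ~(1/20)^8 ~ 4e-11, so essentially anything below 0.01 passes
  y1 <- bandpass_zero_lag(sin(2 * pi * 1 * t), 2000)
  expect_lt(max(abs(y1[core])), 0.01)
  expect_error(bandpass_zero_lag(rnorm(100), 900, high = 500), "Nyquist")
})

test_that("zero-lag filtering preserves symmetry about a pulse center", {
  n <- 4001
  x <- exp(-((seq_len(n) - 2001) / 40)^2)
  for (f in list(function(s) bandpass_zero_lag(s, 2000),
                 function(s) lowpass_envelope(s, 2000))) {
    y <- f(x)
    expect_equal(which.max(abs(y[1000:3000])) + 999, 2001, tolerance = 1)
    expect_equal(y[2001 + 1:500], y[2001 - 1:500], tolerance = 1e-6)
  }
})

test_that("remove_offset and rectify obey their contracts", {
  expect_equal(remove_offset(rep(3.2, 10)), rep(0, 10))
  s <- sin(seq(0, 4 * pi, length.out = 1001))[-1001]
  expect_equal(remove_offset(s + 0.7), s, tolerance = 1e-12)
  expect_equal(mean(remove_offset(s)), 0)
  expect_error(remove_offset(numeric(0)), "empty")

  expect_equal(rectify(c(-1, 2, -3)), c(1, 2, 3))
  expect_equal(rectify(c(0.5, 1)), c(0.5, 1))
  # closed form: mean of |sin| over whole periods is 2/pi
  expect_equal(mean(rectify(sin(seq(0, 2 * pi, length.out = 20001)[-1]))),
               2 / pi, tolerance = 0.01)
})

test_that("envelope low-pass tracks an amplitude modulator", {
  t <- seq(0, 3, by = 1 / 2000)
  m <- 1 + 0.5 * sin(2 * pi * 1 * t)
  env <- lowpass_envelope(rectify(m * sin(2 * pi * 100 * t)), 2000)
  core <- 1500:4500
  expect_gt(cor(env[core], m[core]), 0.99)
  expect_true(all(env >= 0))
  # DC gain 1: constant input reproduced
  expect_equal(lowpass_envelope(rep(2, 3000), 2000)[1000:2000],
               rep(2, 1001), tolerance = 1e-4)
})
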