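test_that("channel selection keeps order, rebuilds montage, errors on unknown labels", {
  ep <- tiny_epochs()
  sel <- select_channels(ep, c("C3", "C4"))
  expect_equal(sel$montage$channel_names, c("C3", "C4"))
  expect_equal(dim(sel$data), c(6L, 2L, 64L))
  expect_equal(sel$data[3, 1, ], ep$data[3, 3, ])   # C3 content preserved
  expect_equal(length(sel$montage$left_idx), 1L)
  expect_equal(length(sel$montage$midline_idx), 0L)

  # identity case
  all_sel <- select_channels(ep, ep$montage$channel_names)
  expect_identical(all_sel$data, ep$data)

  expect_error(select_channels(ep, c("C3", "Oz")), "Oz")
})

test_that("KU montage partitions 20 channels into 9 mirror pairs + 2 midline", {
  m <- ku_motor_montage()
  expect_length(m$left_idx, 9L)
  expect_length(m$right_idx, 9L)
  expect_setequal(m$channel_names[m$midline_idx], c("Cz", "CPz"))
  # left/right alignment is homologous: C1<->C2, FC5<->FC6, ...
  left <- m$channel_names[m$left_idx]
  right <- m$channel_names[m$right_idx]
  num <- function(x) as.integer(sub("^[A-Za-z]+", "", x))
  pre <- function(x) sub("[0-9]+$", "", x)
  expect_equal(pre(left), pre(right))
  expect_equal(num(left) + 1L, num(right))
})

test_that("downsampling by an integer factor preserves content below Nyquist", {
  ep <- sine_epochs(5, fs = 1000, n_samples = 4000L)
  out <- downsample(ep, 250)
  expect_equal(out$fs, 250)
  expect_equal(dim(out$data)[3], 1000L)
  # 5 Hz tone survives decimation: dominant FFT peak still at 5 Hz
  expect_equal(dominant_freq(out$data[1, 1, ], 250), 5, tolerance = 1e-8)
  # identity when target equals fs
  expect_identical(downsample(ep, 1000), ep)
  expect_error(downsample(ep, 300), "integer multiple")
})

test_that("downsampling anti-aliases: energy above target Nyquist is suppressed", {
  # 200 Hz tone at fs 1000 would alias to 50 Hz at fs 250 without filtering
  ep <- sine_epochs(200, fs = 1000, n_samples = 4000L)
  out <- downsample(ep, 250)
  x <- out$data[1, 1, ]
  spec <- Mod(stats::fft(x))[seq_len(500)]
  # residual energy (any frequency) at least 20 dB below the original tone
  expect_lt(max(spec) / (0.5 * 4000 / 4), 10^(-20 / 20))
})

test_that("bandpass passes in-band tones, attenuates out-of-band, keeps dims", {
  alpha <- band_spec("alpha", 7, 12)
  ep10 <- sine_epochs(10, fs = 250, n_samples = 1000L)
  out10 <- bandpass(ep10, alpha)
  expect_equal(dim(out10$data), dim(ep10$data))
  # steady-state amplitude within 5% (ignore filter edge transients)
  mid <- 300:700
  amp <- max(abs(out10$data[1, 1, mid]))
  expect_lt(abs(amp - 1), 0.05)

  ep25 <- sine_epochs(25, fs = 250, n_samples = 1000L)
  out25 <- bandpass(ep25, alpha)
  amp25 <- max(abs(out25$data[1, 1, mid]))
  expect_lt(amp25, 10^(-20 / 20))      # >= 20 dB down

  # raw passthrough and Nyquist guard
  expect_identical(bandpass(ep10, band_spec("raw")), ep10)
  expect_error(bandpass(ep10, band_spec("wide", 13, 130)), "Nyquist")
})

test_that("zscore standardizes per trial and channel with population SD", {
  # closed form: [1,2,3] -> (x - 2) / sqrt(2/3)
  ep <- make_epochs(array(c(1, 2, 3), dim = c(1, 1, 3)), 10, 0L, 1L,
                    make_montage("Cz"))
  z <- zscore(ep)
  expect_equal(as.vector(z$data), c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  ep2 <- tiny_epochs()
  z2 <- zscore(ep2)
  for (i in 1:2) for (c in 1:4) {
    x <- z2$data[i, c, ]
    expect_lt(abs(mean(x)), 1e-6)
    expect_lt(abs(sqrt(mean((x - mean(x))^2)) - 1), 1e-6)
  }
  # idempotent
  expect_equal(zscore(z2)$data, z2$data, tolerance = 1e-6)
  # zero-variance guard names trial and channel
  flat <- tiny_epochs()
  flat$data[2, 3, ] <- 5
  expect_error(zscore(flat), "trial 2.*C3")
})

test_that("make_multiband returns (raw, alpha, beta) z-scored and dimension-identical", {
  ep <- sine_epochs(10, fs = 250, n_samples = 1000L)
  ep$data <- ep$data + array(rnorm(length(ep$data), sd = 0.1), dim(ep$data))
  mb <- make_multiband(ep)
  expect_s3_class(mb, "lgct_multiband")
  expect_length(mb$epochs, 3L)
  expect_equal(vapply(mb$bands, `[[`, "", "name"), c("raw", "alpha", "beta"))
  dims <- lapply(mb$epochs, function(e) dim(e$data))
  expect_equal(dims[[1]], dims[[2]])
  expect_equal(dims[[1]], dims[[3]])
  # the 10 Hz tone dominates the alpha band input; beta band kept little of it
  # pre-normalization (compare band energies before the z-score rescales)
  alpha_raw <- bandpass(ep, band_spec("alpha", 7, 12))
  beta_raw <- bandpass(ep, band_spec("beta", 13, 32))
  expect_gt(mean(alpha_raw$data^2) / mean(beta_raw$data^2), 100)
  # alpha entry retains the oscillation after z-scoring
  expect_equal(dominant_freq(mb$epochs[[2]]$data[1, 1, ], 250), 10,
               tolerance = 0.3)
})

test_that("preprocessing commutes with trial permutation", {
  ep <- tiny_epochs(n_trials = 5L)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  alpha <- band_spec("a", 7, 12)
  expect_equal(bandpass(subset_trials(ep, perm), alpha)$data,
               subset_trials(bandpass(ep, alpha), perm)$data)
  expect_equal(zscore(subset_trials(ep, perm))$data,
               subset_trials(zscore(ep), perm)$data)
  ep2 <- tiny_epochs(n_samples = 128L, fs = 128)
  expect_equal(downsample(subset_trials(ep2, perm), 64)$data,
               subset_trials(downsample(ep2, 64), perm)$data)
})
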