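test_that("Laws features vanish on constant input and match impulse", {
  expect_equal(unname(laws_features(matrix(7, 9, 9))), rep(0, 10))
  # centred unit impulse: valid responses enumerate the flipped mask,
  # so the mean absolute response is sum(|mask|) / valid-area
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  f <- laws_features(imp)
  v <- laws_vectors()
  masks <- list(outer(v$L, v$E), outer(v$E, v$L), outer(v$S, v$L),
                outer(v$E, v$E), outer(v$L, v$S))
  expect_equal(unname(f[1:5]),
               vapply(masks, function(m) sum(abs(m)) / 25, numeric(1)))
  expect_error(laws_features(matrix(0, 4, 4)), "at least")
})

test_that("Laws features agree with the brute-force convolution oracle", {
  for (seed in 1:5) {
    blk <- random_block(seed, nr = 11)
    expect_equal(unname(laws_features(blk)),
                 oracle_laws(blk, laws_vectors()), tolerance = 1e-10)
  }
})

test_that("dependence features match hand counts and the oracle", {
  f <- ngldm_features(matrix(5L, 6, 6))
  expect_equal(unname(f[c("small_number_emphasis", "large_number_emphasis",
                          "entropy")]),
               c(1 / 64, 64, 0))
  chk <- outer(1:6, 1:6, function(r, c) (r + c) %% 2L)
  f <- ngldm_features(chk)
  expect_equal(unname(f["large_number_emphasis"]), 16)
  for (seed in 1:5) {
    q <- quantize_gray(random_block(seed, nr = 8), 6)
    expect_equal(unname(ngldm_features(q)), oracle_ngldm(q),
                 tolerance = 1e-12)
  }
})

test_that("gray-tone difference features handle flat and raised-pixel input", {
  f <- ngtdm_features(matrix(3L, 5, 5), epsilon = 1e-6)
  expect_equal(unname(f[c("busyness", "contrast", "complexity")]),
               c(0, 0, 0))
  expect_equal(unname(f["coarseness"]), 1e6)
  # one interior pixel raised: s concentrates on two levels
  blk <- matrix(0L, 5, 5); blk[3, 3] <- 2L
  expect_equal(unname(ngtdm_features(blk)), oracle_ngtdm(blk),
               tolerance = 1e-12)
  for (seed in 1:5) {
    q <- quantize_gray(random_block(seed, nr = 8), 6)
    expect_equal(unname(ngtdm_features(q)), oracle_ngtdm(q),
                 tolerance = 1e-12)
  }
})

test_that("Haar LL subband has gain 2, correct size, and matches the oracle", {
  expect_equal(wavelet_ll(matrix(3, 8, 8)), matrix(6, 4, 4))
  expect_equal(dim(wavelet_ll(matrix(0, 23, 23))), c(12L, 12L))
  for (seed in 1:5) {
    blk <- random_block(seed, nr = 9 + seed)
    expect_equal(wavelet_ll(blk), oracle_wavelet_ll(blk),
                 tolerance = 1e-12)
  }
})

test_that("local Fourier features match DC-only and impulse spectra", {
  f <- local_fourier_features(matrix(10, 5, 5))
  expect_equal(unname(f[1]), 80)           # mean |F0| = 8c
  expect_equal(unname(f[2:8]), rep(0, 7))  # higher harmonics vanish
  expect_equal(unname(f[17:32]), rep(0, 16))  # all SDs zero
  # single east neighbor set to 1: |F_u| = 1 for all u at that pixel
  blk <- matrix(0, 3, 3); blk[2, 3] <- 1
  f <- local_fourier_features(blk)
  expect_equal(unname(f[1:8]), rep(1, 8))
  for (seed in 1:3) {
    blk <- random_block(seed, nr = 6)
    expect_equal(unname(local_fourier_features(blk)), oracle_fourier(blk),
                 tolerance = 1e-10)
  }
})

test_that("full extraction is ordered, deterministic and compositional", {
  blk <- random_block(99)
  cfg <- texture_config()
  fv <- extract_features(blk, cfg)
  expect_length(fv, 126)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), paste0("F", 1:126))
  expect_identical(fv, extract_features(blk, cfg))
  # family slices equal the family operations
  q <- quantize_gray(blk, cfg$quant_levels)
  expect_equal(unname(fv[1:7]), unname(histogram_features(blk)))
  expect_equal(unname(fv[8:20]), unname(glcm_features(q, 32)))
  expect_equal(unname(fv[22:26]), unname(glrlm_features(q, 32)))
  expect_equal(unname(fv[27:36]), unname(laws_features(blk)))
  expect_equal(unname(fv[95:126]), unname(local_fourier_features(blk)))
  # wavelet slice equals applying the families to the LL subband
  expect_equal(unname(fv[47:94]), unname(wavelet_features(blk, cfg)))
  ll <- wavelet_ll(blk)
  expect_equal(unname(fv["F73"]), mean(ll))
})

test_that("constant block yields the fully determined degenerate vector", {
  fv <- extract_features(matrix(42, 23, 23))
  expect_equal(unname(fv[c(1, 2, 4, 7)]), c(1, 0, 42, 0))
  expect_equal(unname(fv[16:18]), c(1, 0, 1))    # GLCM energy/entropy/homog
  expect_equal(unname(fv[27:36]), rep(0, 10))    # Laws
  expect_equal(unname(fv["F43"]), 1e6)           # guarded coarseness
  expect_equal(unname(fv["F73"]), 84)            # LL mean = 2c
  expect_equal(unname(fv["F74"]), 0)
  expect_equal(unname(fv["F95"]), 8 * 42)
  expect_true(all(fv[paste0("F", 111:126)] == 0))
})

test_that("feature names follow the bank numbering", {
  nm <- feature_names()
  expect_length(nm, 126)
  expect_equal(nm[4], "Mean")
  expect_equal(nm[21], "Dissimilarity")
  expect_equal(nm[46], "Textural Strength")
  expect_equal(nm[73], "Wavelet Mean")
})
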