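test_that("quantizer reproduces the four-level equal-width binning of the
           12-bit range", {
  q <- quantizer()
  x <- ecg_signal(c(0, 1023, 1024, 2047, 2048, 3071, 3072, 4095), 360,
                  unit = "adc")
  expect_identical(quantize(q, x), c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_error(
    quantize(q, structure(list(samples = c(-1, 5), fs = 360, unit = "adc",
                               adc_max = 4095L), class = "ecg_signal")),
    "outside")
})

test_that("quantization of random count vectors equals per-sample
           brute-force bin search", {
  withr::with_seed(3, {
    q <- quantizer()
    counts <- sample.int(4096, 500) - 1L
    got <- quantize(q, ecg_signal(counts, 360, unit = "adc"))
    width <- 4096 / 4
    oracle <- vapply(counts, function(v) {
      for (k in 1:4) if (v < k * width) return(k)
      4L
    }, integer(1))
    expect_identical(got, oracle)
  })
})

test_that("supervised Layer-1 training recovers hand-computed smoothed
           frequencies and the 60% minimum-duration rule", {
  # one path dwelling exactly d samples per state, twice around the cycle
  d <- 10L
  path <- rep(rep(1:6, each = d), 2)
  syms <- rep(c(1L, 2L, 1L, 3L, 1L, 2L), each = d, times = 2)
  p <- train_hmm1(list(path), list(syms))
  expect_identical(unname(p$min_duration), rep(as.integer(0.6 * d), 6L))

  # a path that never leaves ISO1: unsmoothed mass entirely on the self-loop
  p2 <- train_hmm1(list(rep(1L, 50)), list(rep(1L, 50)))
  allowed <- which(hmm1_topology()[1, ])
  expect_equal(unname(p2$trans[1, 1]), (49 + 1) / (49 + length(allowed)))

  # two-path corpus with hand-countable transitions
  pa <- c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 6L, 6L)
  pb <- c(1L, 1L, 1L, 3L, 3L, 4L, 4L, 5L, 5L, 6L, 6L, 1L)
  sa <- c(1L, 1L, 2L, 2L, 1L, 1L, 4L, 4L, 1L, 1L, 2L, 2L)
  sb <- c(1L, 1L, 1L, 1L, 1L, 4L, 4L, 1L, 1L, 2L, 2L, 1L)
  p3 <- train_hmm1(list(pa, pb), list(sa, sb))
  # ISO1 transitions: self 1+2=3, to P 1, to ISO2 1; add-one over 3 allowed
  expect_equal(unname(p3$trans[1, c(1, 2, 3)]),
               c(3 + 1, 1 + 1, 1 + 1) / (5 + 3))
  # QRS emissions: 4 counts of symbol 4; add-one over 4 symbols
  expect_equal(unname(p3$emis[4, ]), c(0 + 1, 0 + 1, 0 + 1, 4 + 1) / (4 + 4))
  # both paths start in ISO1
  expect_equal(unname(p3$init), c(3, rep(1, 5)) / 8)

  expect_error(train_hmm1(list(), list()), "empty")
  expect_error(train_hmm1(list(c(1L, 4L)), list(c(1L, 1L))), "topology")
})

test_that("duration-constrained Viterbi with vacuous constraints equals
           classical decoding (exhaustive oracle), and honours minimum
           dwells against brute-force enumeration", {
  withr::with_seed(42, {
    n_agree <- 0
    for (case in 1:40) {
      n <- sample(2:3, 1)
      T_ <- sample(4:10, 1)
      mask <- diag(n) > 0
      for (i in seq_len(n)) mask[i, sample.int(n, 1)] <- TRUE
      mask[cbind(seq_len(n), c(seq_len(n)[-1], 1))] <- TRUE  # cycle
      trans <- rand_stoch(n, mask = mask)
      emis <- rand_stoch(n, 3)
      init <- as.numeric(rand_stoch(1, n))
      mind <- sample(1:3, n, replace = TRUE)
      obs <- sample.int(3, T_, replace = TRUE)
      par <- list(trans = trans, emis = emis, init = init,
                  min_duration = mind, mask = mask)
      ref <- oracle_viterbi_min_dur(trans, emis, init, mind, mask, obs)
      if (!is.finite(ref$lp)) {
        expect_error(viterbi_min_duration(par, obs), "feasible")
        next
      }
      got <- viterbi_min_duration(par, obs)
      # the decoded path must achieve the enumerated optimum (repeated
      # observation symbols can make several optimal paths tie)
      expect_equal(got$logp, ref$lp, tolerance = 1e-9)
      # self-consistency: reported score is the path's own log-probability
      expect_equal(got$logp,
                   oracle_logprob(trans, emis, init, got$path, obs),
                   tolerance = 1e-9)
      # dwell and topology feasibility
      expect_true(path_is_feasible(got$path, mask, mind))
      # vacuous constraint = classical Viterbi
      par1 <- par; par1$min_duration <- rep(1L, n)
      cls <- viterbi_min_duration(par1, obs)
      full <- oracle_viterbi_full(trans, emis, init, obs)
      expect_equal(cls$logp, full$lp, tolerance = 1e-9)
      n_agree <- n_agree + 1
    }
    expect_gt(n_agree, 20)  # most random instances must be feasible
  })
})

test_that("decoding a noise-free synthetic record recovers the generator's
           state path almost everywhere", {
  cfg <- synth_config(duration_s = 30, seed = 7)
  rec <- generate_record(cfg)
  pc <- train_pipeline_models(generate_record(
    synth_config(duration_s = 60, seed = 8)))
  syms <- quantize(quantizer(), condition_ecg(rec$ecg))
  dec <- viterbi_min_duration(pc$hmm1, syms)$path
  agree <- mean(dec == rec$truth$state_path)
  expect_gt(agree, 0.85)  # boundaries wobble by a few samples; runs align
})

test_that("path_to_beats reconstructs per-beat subwave boundaries, handles
           missing P waves and empty paths", {
  # four textbook beats
  one <- rep(1:6, times = c(30, 20, 15, 20, 25, 40))
  seg <- path_to_beats(rep(one, 4), 360)
  expect_equal(nrow(seg$beats), 4)
  expect_true(all(!is.na(seg$beats$p_on)))
  expect_true(all(!is.na(seg$beats$t_on)))
  expect_equal(seg$beats$qrs_on[1], 65)
  expect_equal(seg$beats$qrs_off[1], 85)
  expect_equal(seg$beats$fiducial, 65 + 150 * (0:3))

  # P-skip beat (ISO1 -> ISO2) yields an absent P
  skip <- rep(c(1L, 3L, 4L, 5L, 6L), times = c(50, 15, 20, 25, 40))
  seg2 <- path_to_beats(c(one, skip, one), 360)
  expect_equal(nrow(seg2$beats), 3)
  expect_true(is.na(seg2$beats$p_on[2]))
  expect_false(any(is.na(seg2$beats$p_on[c(1, 3)])))

  empty <- path_to_beats(integer(0), 360)
  expect_equal(nrow(empty$beats), 0)
})

test_that("segmentation round-trips the generator's subwave boundaries
           exactly on the true state path", {
  cfg <- synth_config(duration_s = 40, pvc_rate = 0.15, apc_rate = 0.1,
                      seed = 31)
  rec <- generate_record(cfg)
  seg <- path_to_beats(rec$truth$state_path, 360)
  tb <- rec$truth$beats
  # generator truth may omit a trailing partial beat kept by the decoder
  m <- match(tb$fiducial, seg$beats$fiducial)
  expect_false(any(is.na(m)))
  got <- seg$beats[m, ]
  expect_equal(got$qrs_on, tb$qrs_on)
  expect_equal(got$qrs_off, tb$qrs_off)
  expect_equal(got$p_on, tb$p_on)
  expect_equal(got$t_on, tb$t_on)
  expect_equal(got$t_off, tb$t_off)
})

test_that("Baum-Welch refinement never decreases the data log-likelihood", {
  withr::with_seed(9, {
    cfg <- synth_config(duration_s = 20, seed = 9)
    rec <- generate_record(cfg)
    syms <- quantize(quantizer(), condition_ecg(rec$ecg))
    pc <- train_pipeline_models(rec)
    ref <- baum_welch(pc$hmm1, syms, n_iter = 5)
    ll <- attr(ref, "loglik")
    expect_true(all(diff(ll) > -1e-6))
    # structural zeros of the topology stay zero
    expect_true(all(ref$trans[!pc$hmm1$mask] == 0))
  })
})
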