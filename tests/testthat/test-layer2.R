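test_that("beat encoding maps the canonical PVC and all-normal beats and is
           a bijection over the 36-cell product alphabet", {
  cb <- feature_codebook()
  # wide, premature, no P, reliable: the textbook PVC
  pvc <- encode_beat(cb, qrs_ms = 130, pr_ms = NA, rr_ms = 0.7 * 800,
                     p_present = FALSE, activity = "standing",
                     rr_median = 800)
  # narrow, on-time, normal P, reliable: the all-normal beat
  nrm <- encode_beat(cb, qrs_ms = 90, pr_ms = 160, rr_ms = 800,
                     p_present = TRUE, activity = "lying", rr_median = 800)
  expect_identical(pvc, 2L + 0L + 12L + 0L)  # wide, premature, absent
  expect_identical(nrm, 1L + 2L)             # narrow, normal rr, normal P

  # enumerate every feature combination: all 36 symbols, each exactly once
  qrs_vals <- c(90, 130)
  rr_vals <- c(0.7, 1.0, 1.3) * 800
  p_vals <- list(c(TRUE, 150), c(TRUE, 230), c(FALSE, NA))
  act_vals <- c("standing", "walking")
  syms <- integer(0)
  for (a in act_vals) for (p in p_vals) for (r in rr_vals)
    for (q in qrs_vals)
      syms <- c(syms, encode_beat(cb, q, p[[2]], r, as.logical(p[[1]]),
                                  a, 800))
  expect_identical(sort(syms), 1:36)
})

test_that("encoding handles absent intervals: first beat and missing P", {
  cb <- feature_codebook()
  s <- encode_beat(cb, 90, 160, NA, TRUE, "standing", NA)
  expect_identical(s, 1L + 2L)  # rr falls back to the normal code
  s2 <- encode_beat(cb, 90, NA, 800, FALSE, "standing", 800)
  expect_identical(s2, 1L + 2L + 12L)  # absent P dominates the P code
})

test_that("supervised Layer-2 training equals hand-computed smoothed counts
           and flags degenerate corpora", {
  labels <- c(1L, 1L, 2L, 1L, 3L, 1L, 1L, 4L, 1L, 1L)
  syms <- c(3L, 3L, 14L, 3L, 7L, 3L, 3L, 20L, 3L, 3L)
  p <- train_hmm2(labels, syms)
  # transitions from Normal: 1->1 x3, 1->2, 1->3, 1->4 one each (6 total)
  expect_equal(unname(p$trans[1, ]), c(3 + 1, 1 + 1, 1 + 1, 1 + 1) / (6 + 4))
  # emissions of Normal: symbol 3 seven times out of 7
  expect_equal(unname(p$emis[1, 3]), (7 + 1) / (7 + 36))
  expect_equal(unname(p$emis[2, 14]), (1 + 1) / (1 + 36))
  expect_equal(unname(p$init), c(1 + 1, 1, 1, 1) / (1 + 4))
  expect_error(train_hmm2(integer(0), integer(0)), "empty")
  expect_error(train_hmm2(c(1L, 5L), c(1L, 1L)), "4-state")

  # an all-Normal corpus puts maximal transition mass on Normal->Normal
  pn <- train_hmm2(rep(1L, 50), rep(3L, 50))
  expect_equal(which.max(pn$trans["Normal", ]), c(Normal = 1L))
})

test_that("supervised training on a large simulated corpus recovers the
           generating matrices", {
  withr::with_seed(33, {
    # dominant entries form a permutation (uniform state occupancy) and
    # probabilities stay near 0 or 1, keeping the estimator's sampling
    # noise well inside the tolerance at this corpus size
    trans <- matrix(0.05, 4, 4)
    trans[cbind(1:4, c(2, 3, 4, 1))] <- 0.85
    emis <- matrix(0.4 / 31, 4, 36)
    for (s in 1:4) emis[s, (s - 1) * 5 + 1:5] <- 0.12
    init <- rep(0.25, 4)
    n <- 10000
    states <- integer(n); obs <- integer(n)
    states[1] <- sample.int(4, 1, prob = init)
    for (t in 2:n) states[t] <- sample.int(4, 1, prob = trans[states[t - 1], ])
    for (t in 1:n) obs[t] <- sample.int(36, 1, prob = emis[states[t], ])
    est <- train_hmm2(states, obs)
    expect_lt(max(abs(est$trans - trans)), 0.02)
    expect_lt(max(abs(est$emis - emis)), 0.02)
  })
})

test_that("batch decoding equals exhaustive enumeration over all 4^n label
           paths on short sequences", {
  withr::with_seed(44, {
    for (case in 1:25) {
      n <- sample(2:8, 1)
      trans <- rand_stoch(4)
      emis <- rand_stoch(4, 36)
      init <- as.numeric(rand_stoch(1, 4))
      par <- hmm2_params(trans, emis, init)
      obs <- sample.int(36, n, replace = TRUE)
      got <- classify_beats(par, obs)
      ref <- oracle_viterbi_full(trans, emis, init, obs)
      expect_equal(got, ref$path)
    }
  })
})

test_that("relabeling invariance: permuting states and parameters permutes
           the decode", {
  withr::with_seed(55, {
    trans <- rand_stoch(4); emis <- rand_stoch(4, 36)
    init <- as.numeric(rand_stoch(1, 4))
    obs <- sample.int(36, 30, replace = TRUE)
    base <- classify_beats(hmm2_params(trans, emis, init), obs)
    perm <- c(3L, 1L, 4L, 2L)  # state i of the original becomes perm[i]
    inv <- order(perm)
    par2 <- hmm2_params(trans[inv, inv], emis[inv, ], init[inv])
    expect_equal(classify_beats(par2, obs), perm[base])
  })
})

test_that("motion-coded beats can only decode Invalid once the activity
           gate is applied", {
  withr::with_seed(66, {
    for (case in 1:10) {
      par <- gate_motion(hmm2_params(rand_stoch(4), rand_stoch(4, 36),
                                     as.numeric(rand_stoch(1, 4))))
      obs <- sample.int(36, 40, replace = TRUE)
      motion <- obs > 18
      if (!any(motion)) next
      lab <- classify_beats(par, obs)
      expect_true(all(lab[motion] == 4L))
    }
  })
})

test_that("online fixed-lag decoding matches batch decoding on a stable
           sequence", {
  withr::with_seed(77, {
    emis <- matrix(0.2 / 35, 4, 36)
    emis[cbind(1:4, c(3, 14, 7, 20))] <- 0.8
    emis <- emis / rowSums(emis)
    trans <- matrix(0.04, 4, 4); diag(trans) <- 0.88
    par <- hmm2_params(trans, emis, rep(0.25, 4))
    states <- rep(c(1L, 2L, 1L, 3L), times = c(12, 6, 12, 6))
    obs <- vapply(states, function(s)
      sample.int(36, 1, prob = emis[s, ]), integer(1))
    expect_equal(classify_beats(par, obs, mode = "online", lag = 5),
                 classify_beats(par, obs, mode = "batch"))
  })
})

test_that("planted ectopic beats in clean synthetic records are recovered
           with high per-class sensitivity and precision", {
  pc <- train_pipeline_models(generate_record(training_config(101)))
  cfg_te <- synth_config(duration_s = 150, pvc_rate = 0.1, apc_rate = 0.05,
                         seed = 102)
  rec <- generate_record(cfg_te)
  res <- run_pipeline(pc, rec$ecg, rec$accel)
  s <- evaluate_beats(res$beats, rec$truth$beats, 360)
  expect_true(all(s$classes$se >= 95))
  expect_true(all(s$classes$pp >= 95))
})
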