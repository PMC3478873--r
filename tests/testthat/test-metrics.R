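mk <- function(samples, labels)
  data.frame(sample = samples, label = labels, stringsAsFactors = FALSE)

test_that("beat matching pairs identical fiducials, counts missed beats,
           and agrees with exhaustive optimal assignment under jitter", {
  fs <- 360
  ref <- mk(c(100, 400, 700), c("Normal", "PVC", "Normal"))
  m <- match_beats(ref, ref, fs)
  expect_equal(nrow(m$pairs), 3)
  expect_length(m$unpaired_pred, 0)
  expect_length(m$unpaired_ref, 0)

  m2 <- match_beats(mk(numeric(0), character(0)), mk(100, "Normal"), fs)
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$unpaired_ref, 1L)

  tol <- 150 * fs / 1000
  withr::with_seed(21, {
    for (case in 1:25) {
      nr <- sample(2:8, 1)
      refs <- cumsum(sample(80:400, nr, replace = TRUE))
      jitter <- round(rnorm(nr, 0, tol / 6))
      drop <- runif(nr) < 0.2
      preds <- (refs + jitter)[!drop]
      m3 <- match_beats(mk(preds, rep("Normal", length(preds))),
                        mk(refs, rep("Normal", nr)), fs)
      opt <- oracle_assignment(preds, refs, tol)
      expect_equal(nrow(m3$pairs), opt$nmatch)
      if (opt$nmatch > 0) {
        got <- m3$pairs[order(m3$pairs$ref_i), c("pred_i", "ref_i")]
        ref_pairs <- opt$pairs[order(opt$pairs[, 2]), , drop = FALSE]
        expect_equal(unname(as.matrix(got)), unname(ref_pairs))
      }
    }
  })
})

test_that("per-record scores follow the Ac/Se/+P formulas, report N/A for
           empty classes and never fabricate 0 or 100", {
  fs <- 360
  # a record like the published all-correct PVC record: every beat correct
  ref <- mk(seq(0, by = 300, length.out = 20),
            rep(c("Normal", "PVC"), 10))
  s <- score_record(match_beats(ref, ref, fs), ref, ref)
  expect_equal(s$ac, 100)
  expect_equal(s$classes$se, c(100, 100, NA))
  expect_equal(s$classes$pp, c(100, 100, NA))

  # hand-built confusion: 3 Normal (1 called PVC), 1 PVC correct, 1 APC
  # missed entirely
  ref2 <- mk(c(0, 300, 600, 900, 1200),
             c("Normal", "Normal", "Normal", "PVC", "APC"))
  pred2 <- mk(c(0, 300, 600, 900),
              c("Normal", "PVC", "Normal", "PVC"))
  s2 <- score_record(match_beats(pred2, ref2, fs), pred2, ref2)
  expect_equal(s2$n_t, 5)
  expect_equal(s2$n_e, 2)          # one mislabeled + one missed
  expect_equal(s2$ac, 100 * 3 / 5)
  expect_equal(s2$classes$tp, c(2, 1, 0))
  expect_equal(s2$classes$fn, c(1, 0, 1))
  expect_equal(s2$classes$fp, c(0, 1, 0))
  expect_equal(s2$classes$se, c(100 * 2 / 3, 100, 0))
  expect_equal(s2$classes$pp, c(100, 50, NA))

  # random confusion counts equal direct formula evaluation
  withr::with_seed(31, {
    for (case in 1:10) {
      n <- 30
      refs <- seq(0, by = 300, length.out = n)
      rl <- sample(c("Normal", "PVC", "APC"), n, replace = TRUE,
                   prob = c(0.7, 0.2, 0.1))
      pl <- ifelse(runif(n) < 0.8, rl,
                   sample(c("Normal", "PVC", "APC"), n, replace = TRUE))
      sc <- score_record(match_beats(mk(refs, pl), mk(refs, rl), fs),
                         mk(refs, pl), mk(refs, rl))
      for (ci in 1:3) {
        cl <- c("Normal", "PVC", "APC")[ci]
        tp <- sum(pl == cl & rl == cl)
        fn <- sum(rl == cl) - tp
        fp <- sum(pl == cl & rl != cl)
        expect_equal(sc$classes$tp[ci], tp)
        if (tp + fn > 0) expect_equal(sc$classes$se[ci], 100 * tp / (tp + fn))
        if (tp + fp > 0) expect_equal(sc$classes$pp[ci], 100 * tp / (tp + fp))
      }
      expect_equal(sc$ac, 100 * sum(pl == rl) / n)
    }
  })
})

test_that("Invalid predictions on annotated beats count as errors but do
           not pollute class precision", {
  fs <- 360
  ref <- mk(c(0, 300, 600), c("Normal", "Normal", "PVC"))
  pred <- mk(c(0, 300, 600), c("Normal", "Invalid", "PVC"))
  s <- score_record(match_beats(pred, ref, fs), pred, ref)
  expect_equal(s$n_e, 1)
  expect_equal(s$classes$fp, c(0, 0, 0))
  expect_equal(s$classes$se, c(50, 100, NA))
})

test_that("accuracy equals the beat-weighted combination of per-class
           sensitivities on the same record", {
  withr::with_seed(41, {
    n <- 40
    refs <- seq(0, by = 300, length.out = n)
    rl <- sample(c("Normal", "PVC", "APC"), n, replace = TRUE)
    pl <- ifelse(runif(n) < 0.85, rl,
                 sample(c("Normal", "PVC", "APC", "Invalid"), n,
                        replace = TRUE))
    s <- score_record(match_beats(mk(refs, pl), mk(refs, rl), fs = 360),
                      mk(refs, pl), mk(refs, rl))
    cl <- s$classes
    recon <- sum(ifelse(is.na(cl$se), 0, cl$se) * cl$n_b) / sum(cl$n_b)
    expect_equal(s$ac, recon)
  })
})

test_that("weighted averages reduce to the arithmetic mean under equal
           weights, skip N/A records, and are invariant to splitting a
           record proportionally", {
  expect_equal(weighted_average(c(90, 100), c(5, 5)), 95)
  expect_equal(weighted_average(c(90, NA, 100), c(5, 99, 5)), 95)
  expect_true(is.na(weighted_average(c(NA, NA), c(1, 2))))
  # splitting one record into two with proportional counts, equal values
  expect_equal(weighted_average(c(97, 80), c(10, 6)),
               weighted_average(c(97, 97, 80), c(4, 6, 6)))
})

test_that("the published 16-record table reproduces every weighted-average
           cell and the total-row counts exactly", {
  tab <- mitbih_reference_scores()
  expect_equal(nrow(tab), 16)
  expect_equal(sum(tab$n_t), 34799)
  expect_equal(sum(tab$n_normal), 32655)
  expect_equal(sum(tab$n_pvc), 2000)
  expect_equal(sum(tab$n_apc), 144)
  r2 <- function(x) floor(x * 100 + 0.5) / 100
  expect_equal(r2(weighted_average(tab$ac, tab$n_t)), 99.20)
  expect_equal(r2(weighted_average(tab$se_normal, tab$n_normal)), 99.72)
  expect_equal(r2(weighted_average(tab$pp_normal, tab$n_normal)), 99.64)
  expect_equal(r2(weighted_average(tab$se_pvc, tab$n_pvc)), 97.75)
  expect_equal(r2(weighted_average(tab$pp_pvc, tab$n_pvc)), 96.63)
  expect_equal(r2(weighted_average(tab$se_apc, tab$n_apc)), 99.48)
  expect_equal(r2(weighted_average(tab$pp_apc, tab$n_apc)), 95.77)
})

test_that("the assembled report carries per-record rows, column-sum totals
           and weighted-average cells", {
  fs <- 360
  ref_a <- mk(c(0, 300, 600, 900), c("Normal", "Normal", "PVC", "Normal"))
  pred_a <- mk(c(0, 300, 600, 900), c("Normal", "Normal", "PVC", "PVC"))
  ref_b <- mk(c(0, 300), c("Normal", "APC"))
  pred_b <- mk(c(0, 300), c("Normal", "APC"))
  scores <- list(
    a = score_record(match_beats(pred_a, ref_a, fs), pred_a, ref_a),
    b = score_record(match_beats(pred_b, ref_b, fs), pred_b, ref_b))
  rep <- eval_report(scores)
  expect_equal(rep$n_t[rep$record == "Total"], 6)
  expect_equal(rep$n_normal[rep$record == "Total"], 4)
  wa <- rep[rep$record == "Weighted Average", ]
  expect_equal(wa$se_normal, floor(100 * (3 * 2 / 3 + 1) / 4 * 100 + 0.5) / 100)
  expect_equal(wa$se_apc, 100)
})
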