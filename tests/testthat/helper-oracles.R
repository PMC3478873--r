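# Independent oracles used across the suite. These deliberately avoid the
# package's own decoding/filtering code paths: brute-force recursions and
# exhaustive enumerations only.

# direct-form difference equation, sample by sample
oracle_iir <- function(b, a, x) {
  y <- numeric(length(x))
  for (n in seq_along(x)) {
    y[n] <- b[1] * x[n]
    if (n >= 2) y[n] <- y[n] + b[2] * x[n - 1] - a[2] * y[n - 1]
    if (n >= 3) y[n] <- y[n] + b[3] * x[n - 2] - a[3] * y[n - 2]
  }
  y
}

# per-window explicit least-squares polynomial fit, reflect padding
oracle_sg <- function(x, window, order) {
  h <- (window - 1) %/% 2
  padded <- c(x[(h + 1):2], x, x[(length(x) - 1):(length(x) - h)])
  tt <- seq(-h, h)
  X <- outer(tt, 0:order, "^")
  vapply(seq_along(x), function(i) {
    w <- padded[i:(i + window - 1)]
    fit <- qr.solve(X, w)
    fit[1]  # polynomial evaluated at the window center
  }, numeric(1))
}

# joint log-probability of path+obs under an HMM given as plain matrices
oracle_logprob <- function(trans, emis, init, path, obs) {
  lp <- log(init[path[1]]) + sum(log(emis[cbind(path, obs)]))
  if (length(path) > 1)
    lp <- lp + sum(log(trans[cbind(path[-length(path)], path[-1])]))
  lp
}

# exhaustive maximum-probability path subject to topology mask and
# per-state minimum run lengths; enumerates run structures recursively
oracle_viterbi_min_dur <- function(trans, emis, init, min_dur, mask, obs) {
  T_ <- length(obs)
  n <- nrow(trans)
  cum <- rbind(0, apply(log(emis[, obs, drop = FALSE]), 1, cumsum))
  # cum[t+1, s] = sum of log emis of state s over obs[1..t]
  best <- list(lp = -Inf, path = NULL)
  recurse <- function(pos, state, runs, lp) {
    for (len in min_dur[state]:(T_ - pos)) {
      seg_lp <- lp + (cum[pos + len + 1, state] - cum[pos + 1, state]) +
        (len - 1) * log(trans[state, state])
      new_runs <- rbind(runs, c(state, len))
      if (pos + len == T_) {
        if (seg_lp > best$lp)
          best <<- list(lp = seg_lp,
                        path = rep.int(new_runs[, 1], new_runs[, 2]))
      } else {
        for (nxt in seq_len(n)) {
          if (nxt == state || !mask[state, nxt]) next
          if (pos + len + min_dur[nxt] > T_) next
          recurse(pos + len, nxt, new_runs,
                  seg_lp + log(trans[state, nxt]))
        }
      }
    }
  }
  for (s in seq_len(n)) {
    if (min_dur[s] > T_) next
    recurse(0, s, NULL, log(init[s]))
  }
  best
}

# exhaustive decoding over all n_state^T label paths (vectorized)
oracle_viterbi_full <- function(trans, emis, init, obs) {
  T_ <- length(obs); n <- nrow(trans)
  M <- arrayInd(seq_len(n^T_), rep(n, T_))
  lp <- log(init[M[, 1]]) + log(emis[cbind(M[, 1], obs[1])])
  for (t in seq_len(T_ - 1)) {
    lp <- lp + log(trans[cbind(M[, t], M[, t + 1])]) +
      log(emis[cbind(M[, t + 1], obs[t + 1])])
  }
  i <- which.max(lp)
  list(lp = lp[i], path = M[i, ])
}

# random row-stochastic matrix with optional mask
rand_stoch <- function(n, m = n, mask = NULL) {
  x <- matrix(runif(n * m, 0.05, 1), n, m)
  if (!is.null(mask)) x[!mask] <- 0
  x / rowSums(x)
}

# exhaustive optimal one-to-one beat assignment (max matches, then min
# total distance) for small instances
oracle_assignment <- function(pred, ref, tol) {
  np <- length(pred); nr <- length(ref)
  best <- list(nmatch = -1, dist = Inf, pairs = NULL)
  assign_next <- function(j, used_p, pairs) {
    if (j > nr) {
      nm <- if (is.null(pairs)) 0 else nrow(pairs)
      d <- if (nm) sum(abs(pred[pairs[, 1]] - ref[pairs[, 2]])) else 0
      if (nm > best$nmatch || (nm == best$nmatch && d < best$dist))
        best <<- list(nmatch = nm, dist = d, pairs = pairs)
      return(invisible())
    }
    assign_next(j + 1, used_p, pairs)  # leave ref j unmatched
    for (i in seq_len(np)) {
      if (used_p[i] || abs(pred[i] - ref[j]) > tol) next
      used_p[i] <- TRUE
      assign_next(j + 1, used_p, rbind(pairs, c(i, j)))
      used_p[i] <- FALSE
    }
  }
  assign_next(1, logical(np), NULL)
  best
}
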