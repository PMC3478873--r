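#' Unsupervised Baum-Welch refinement
#'
#' Optional EM refinement of an HMM's transition, emission and initial
#' distributions on an unlabeled symbol stream (standard scaled
#' forward-backward). Structural zeros of the transition matrix — the
#' Layer-1 topology mask — remain zero under the updates, and minimum
#' durations are left untouched, so a refined Layer-1 model keeps its
#' decoding constraints. Off by default everywhere: supervised estimates
#' are used unless this is called explicitly.
#'
#' @param params an `hmm1_params`, `hmm2_params`, or compatible list.
#' @param symbols integer observation sequence.
#' @param n_iter number of EM iterations (default 10).
#' @return `params` with updated `trans`, `emis`, `init`, plus a numeric
#'   `loglik` attribute with the per-iteration log-likelihood trace
#'   (non-decreasing).
#' @export
baum_welch <- function(params, symbols, n_iter = 10L) {
  obs <- as.integer(symbols)
  if (length(obs) < 2L)
    stop_input("Baum-Welch needs at least 2 observations")
  A <- unclass(params$trans); B <- unclass(params$emis)
  pi0 <- as.numeric(params$init)
  n <- nrow(A); T_ <- length(obs)
  trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    # scaled forward/backward
    alpha <- matrix(0, T_, n); beta <- matrix(0, T_, n); cvec <- numeric(T_)
    a <- pi0 * B[, obs[1]]
    cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
    for (t in 2:T_) {
      a <- (alpha[t - 1, ] %*% A)[1, ] * B[, obs[t]]
      cvec[t] <- sum(a)
      alpha[t, ] <- a / cvec[t]
    }
    beta[T_, ] <- 1
    for (t in (T_ - 1):1)
      beta[t, ] <- (A %*% (B[, obs[t + 1]] * beta[t + 1, ]))[, 1] / cvec[t + 1]
    trace[it] <- sum(log(cvec))
    gamma <- alpha * beta
    gamma <- gamma / rowSums(gamma)
    xi_num <- matrix(0, n, n)
    for (t in seq_len(T_ - 1))
      xi_num <- xi_num + (alpha[t, ] %o% (B[, obs[t + 1]] * beta[t + 1, ])) *
        A / cvec[t + 1]
    A <- xi_num / pmax(rowSums(xi_num), .Machine$double.xmin)
    Bn <- matrix(0, n, ncol(B))
    for (k in seq_len(ncol(B)))
      Bn[, k] <- colSums(gamma[obs == k, , drop = FALSE])
    B <- Bn / rowSums(Bn)
    pi0 <- gamma[1, ]
  }
  out <- params
  dimnames(A) <- dimnames(params$trans)
  dimnames(B) <- dimnames(params$emis)
  out$trans <- A; out$emis <- B
  out$init <- stats::setNames(pi0, names(params$init))
  attr(out, "loglik") <- trace
  out
}
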