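# Mean-field image-matrix dynamics and linear stability analysis.
#
# The image matrix m has entry m[k, i] = observer k's reputation of player
# i. The deterministic map replaces each entry by
#   (1-q) m_ki + q/(N-1) * sum_{j != i} alpha_k(m_ki, beta_i(m_ii, m_ij), m_kj),
# i.e. observer k re-assesses donor i averaged over all possible recipients
# j. Everyone cooperating with a perfect reputation (all-ones matrix) is a
# fixed point for any cooperative norm.

validate_image_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("image matrix must be square", call. = FALSE)
  }
  if (nrow(m) < 2) stop("population size N must be >= 2", call. = FALSE)
  if (anyNA(m) || any(m < 0 | m > 1)) {
    stop("image-matrix entries must lie in [0, 1]", call. = FALSE)
  }
  invisible(m)
}

norm_list <- function(norms, N) {
  if (inherits(norms, c("norm_pair", "norm_table")) || is.character(norms)) {
    norms <- list(as_norm_pair(norms))
  }
  norms <- lapply(norms, as_norm_pair)
  if (length(norms) == 1) norms <- rep(norms, N)
  if (length(norms) != N) {
    stop("need one norm, or one norm per player (", N, ")", call. = FALSE)
  }
  norms
}

#' One step of the mean-field image-matrix map
#'
#' @param m square image matrix with entries in \[0,1\]; `m[k, i]` is
#'   observer k's view of player i.
#' @param norms a single norm (homogeneous population) or a list of N
#'   `norm_pair` objects, one per player.
#' @param q observation probability in (0, 1\].
#' @param self_certain if `TRUE`, self-reputations (the diagonal) are
#'   updated with probability one instead of q. Default `FALSE`: diagonal
#'   and off-diagonal entries are treated on an equal footing.
#' @return the updated image matrix (the input is not modified).
#' @examples
#' m <- matrix(1, 3, 3); m[1, 2] <- 0.9
#' meanfield_step(m, "L3", q = 0.4)
#' @export
meanfield_step <- function(m, norms, q, self_certain = FALSE) {
  validate_image_matrix(m)
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q > 1) {
    stop("q must be a single number in (0, 1]", call. = FALSE)
  }
  N <- nrow(m)
  norms <- norm_list(norms, N)
  homogeneous <- length(unique(norms)) == 1
  # B[i, j] = beta_i(m_ii, m_ij): donor i's degree of cooperation toward j
  selfrep <- matrix(diag(m), N, N)
  if (homogeneous) {
    B <- norms[[1]]$beta(selfrep, m)
  } else {
    B <- matrix(0, N, N)
    for (i in seq_len(N)) B[i, ] <- norms[[i]]$beta(m[i, i], m[i, ])
  }
  out <- m
  for (k in seq_len(N)) {
    X <- matrix(m[k, ], N, N)               # (i, j) -> m_ki
    Z <- matrix(m[k, ], N, N, byrow = TRUE) # (i, j) -> m_kj
    A <- norms[[k]]$alpha(X, B, Z)
    assessed <- (rowSums(A) - diag(A)) / (N - 1)
    qk <- rep(q, N)
    if (self_certain) qk[k] <- 1
    out[k, ] <- (1 - qk) * m[k, ] + qk * assessed
  }
  out
}

#' Recovery criterion Q
#'
#' `Q = -1 + Ax + Az + Ay * (Bx + By)` is q^-1 times the largest eigenvalue
#' of the linearized image-matrix dynamics around the fully cooperative
#' state (when all slopes are non-negative). `Q < 0` is a sufficient
#' first-order condition for small disagreements in reputation to heal;
#' norms with `Q > 0` amplify them. Simple Standing sits exactly at
#' `Q = 0` and recovers only through higher-order terms.
#'
#' @param slopes a [slope_set()], or anything [norm_slopes()] accepts.
#' @return a single number.
#' @examples
#' compute_Q("L3")                              # 0
#' compute_Q(slope_set(0, 0.9, 0, 0, 0.9))      # -0.19
#' @export
compute_Q <- function(slopes) {
  s <- as_slope_set(slopes)
  unname(-1 + s[["Ax"]] + s[["Az"]] + s[["Ay"]] * (s[["Bx"]] + s[["By"]]))
}

#' Closed-form eigenvalue spectrum of the linearized dynamics
#'
#' The N^2 x N^2 linearization of the mean-field map around the all-ones
#' state has exactly four eigenvalue families:
#' \describe{
#'   \item{Lambda1, multiplicity (N-1)^2}{`q(-1 + Ax - Az/(N-1))`}
#'   \item{Lambda2, multiplicity N-1}{`q(-1 + Ax + Az)`}
#'   \item{Lambda3, multiplicity N-1}{`q(-1 + Ax - Az/(N-1) + Ay*Bx - Ay*By/(N-1))`}
#'   \item{Lambda4, multiplicity 1}{`q(-1 + Ax + Az + Ay*Bx + Ay*By) = q*Q`}
#' }
#' The pattern is exact for small N (verified symbolically up to N = 5 in
#' the original analysis) and validated numerically against
#' [jacobian_matrix()] here; Lambda4 equals q times [compute_Q()].
#'
#' @inheritParams compute_Q
#' @param q observation probability.
#' @param N population size, >= 2.
#' @return a data.frame of class `eigen_spectrum` with columns `family`,
#'   `value`, `multiplicity`.
#' @export
eigen_spectrum <- function(slopes, q, N) {
  s <- as_slope_set(slopes)
  stopifnot(N >= 2, q > 0, q <= 1)
  Ax <- s[["Ax"]]; Ay <- s[["Ay"]]; Az <- s[["Az"]]
  Bx <- s[["Bx"]]; By <- s[["By"]]
  out <- data.frame(
    family = paste0("Lambda", 1:4),
    value = c(q * (-1 + Ax - Az / (N - 1)),
              q * (-1 + Ax + Az),
              q * (-1 + Ax - Az / (N - 1) + Ay * Bx - Ay * By / (N - 1)),
              q * (-1 + Ax + Az + Ay * Bx + Ay * By)),
    multiplicity = c((N - 1)^2, N - 1, N - 1, 1)
  )
  attr(out, "N") <- N
  attr(out, "q") <- q
  class(out) <- c("eigen_spectrum", "data.frame")
  out
}

#' Dense Jacobian of the linearized image-matrix dynamics
#'
#' Writing m_ki = 1 - eps_ki, the continuous-time linearization reads
#' `d(eps_ki)/dt = -q(1-Ax) eps_ki + q Ay Bx eps_ii
#'  + q/(N-1) * sum_{j != i} (Ay By eps_ij + Az eps_kj)`.
#' This assembles the corresponding N^2 x N^2 matrix L acting on the
#' flattened deviation vector (index (k-1)*N + i), with the coincident
#' terms on k = i rows added up. Intended for moderate N (dense storage).
#'
#' @inheritParams eigen_spectrum
#' @return an N^2 x N^2 matrix.
#' @export
jacobian_matrix <- function(slopes, q, N) {
  s <- as_slope_set(slopes)
  stopifnot(N >= 2)
  Ax <- s[["Ax"]]; Ay <- s[["Ay"]]; Az <- s[["Az"]]
  Bx <- s[["Bx"]]; By <- s[["By"]]
  pos <- function(k, i) (k - 1) * N + i
  L <- matrix(0, N^2, N^2)
  for (k in seq_len(N)) {
    for (i in seq_len(N)) {
      r <- pos(k, i)
      L[r, pos(k, i)] <- L[r, pos(k, i)] - q * (1 - Ax)
      L[r, pos(i, i)] <- L[r, pos(i, i)] + q * Ay * Bx
      js <- setdiff(seq_len(N), i)
      L[r, pos(i, js)] <- L[r, pos(i, js)] + q * Ay * By / (N - 1)
      L[r, pos(k, js)] <- L[r, pos(k, js)] + q * Az / (N - 1)
    }
  }
  L
}

#' Randomly perturbed image matrix
#'
#' Sets a random subset of entries (diagonal included) of the all-ones
#' matrix to `value`; the standard initial condition for recovery
#' experiments is 20% of entries at 0.9.
#'
#' @param N population size.
#' @param fraction fraction of the N^2 entries to perturb; `ceiling(fraction
#'   * N^2)` distinct positions are drawn.
#' @param value the perturbed reputation value.
#' @param seed optional integer seed.
#' @return an N x N image matrix.
#' @export
perturbed_image_matrix <- function(N, fraction = 0.2, value = 0.9,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(N >= 2, fraction >= 0, fraction <= 1, value >= 0, value <= 1)
  m <- matrix(1, N, N)
  n_hit <- ceiling(fraction * N^2)
  if (n_hit > 0) m[sample.int(N^2, n_hit)] <- value
  m
}

#' Deterministic recovery trajectory
#'
#' Iterates [meanfield_step()] and records the mean deviation
#' `eps_bar(t) = mean(1 - m)` over all N^2 entries after each step.
#'
#' @param m0 initial image matrix.
#' @param norms norm(s), as in [meanfield_step()].
#' @param q observation probability.
#' @param steps number of map iterations.
#' @param snapshot_every if > 0, store full matrix snapshots every that many
#'   steps (attribute `snapshots`).
#' @param self_certain passed to [meanfield_step()].
#' @return a data.frame of class `trajectory` with columns `t` (0..steps)
#'   and `mean_eps`.
#' @export
recovery_trajectory <- function(m0, norms, q, steps, snapshot_every = 0,
                                self_certain = FALSE) {
  validate_image_matrix(m0)
  stopifnot(steps >= 1)
  N <- nrow(m0)
  norms <- norm_list(norms, N)
  m <- m0
  eps <- numeric(steps + 1)
  eps[1] <- mean(1 - m)
  snapshots <- list()
  for (t in seq_len(steps)) {
    m <- meanfield_step(m, norms, q, self_certain = self_certain)
    eps[t + 1] <- mean(1 - m)
    if (snapshot_every > 0 && t %% snapshot_every == 0) {
      snapshots[[as.character(t)]] <- m
    }
  }
  out <- data.frame(t = 0:steps, mean_eps = eps)
  class(out) <- c("trajectory", "data.frame")
  attr(out, "final_matrix") <- m
  if (length(snapshots)) attr(out, "snapshots") <- snapshots
  out
}

#' Asymptotic decay rate of a trajectory
#'
#' Least-squares slope of `-log(mean_eps)` against `t` over the last
#' `window` steps, i.e. the late-time exponential decay rate per step.
#' Returns `NA` if the tail contains zeros.
#'
#' @param traj a data.frame with columns `t`, `mean_eps`.
#' @param window number of trailing points to fit.
#' @return decay rate per step (positive = decaying).
#' @export
trajectory_decay_rate <- function(traj, window = 50) {
  tail_df <- traj[traj$t > max(traj$t) - window, ]
  if (any(tail_df$mean_eps <= 0)) return(NA_real_)
  fit <- lm(log(mean_eps) ~ t, data = tail_df)
  -unname(coef(fit)[2])
}
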