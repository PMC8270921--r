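# Stochastic agent-based simulation of the donation game.
#
# Each round: an ordered donor-recipient pair (i, j) is drawn uniformly;
# the donor acts a = beta_i(m_ii, m_ij), replaced by a uniform draw with
# probability gamma (implementation error; the erroneous action is what
# everyone observes and what payoffs use); the recipient gains b*a and the
# donor pays c*a; every observer k != i independently sees the interaction
# with probability q and stores alpha_k(m_ki, a, m_kj), replaced by a
# uniform draw with probability e (perception error). The donor's own view
# m_ii is updated by the same rule when self_update = TRUE (the default;
# the alternative matters little at large N).

abm_config_check <- function(N, M, q, e, gamma) {
  stopifnot(N >= 2, M >= 1, q > 0, q <= 1, e >= 0, e <= 1,
            gamma >= 0, gamma <= 1)
}

corner_matrices <- function(norms, N) {
  norms <- norm_list(norms, N)
  acorn <- t(vapply(norms, alpha_corners_binary, numeric(8)))
  bcorn <- t(vapply(norms, beta_corners_binary, numeric(4)))
  list(acorn = acorn, bcorn = bcorn)
}

#' Run the agent-based donation game
#'
#' Simulates `M` rounds among `N` players with private continuous
#' reputations. Reproducible under `set.seed()`. Norms must be
#' corner-representable (see [as_corner_norm()]); heterogeneous
#' populations are specified as a list of one norm per player.
#'
#' @param norms a single norm or a list of N norms.
#' @param N population size (may be omitted when `norms` is a list).
#' @param M number of rounds.
#' @param q observation probability in (0, 1\].
#' @param e perception-error probability.
#' @param gamma implementation-error probability.
#' @param b,c donation-game benefit and cost.
#' @param m0 initial image matrix (default all-ones).
#' @param self_update update the donor's self-reputation like any other
#'   observer's (default `TRUE`).
#' @param traj_every if > 0, record the mean deviation and running
#'   cooperation rate every `traj_every` rounds.
#' @return a list of class `abm_result` with elements `payoff` (per-player
#'   accumulated payoff normalized by M/N, so the cooperative error-free
#'   baseline is `b - c`), `coop_rate` (mean realized action over rounds),
#'   `final_matrix`, `trajectory` (data.frame or NULL), and `params`.
#' @examples
#' set.seed(1)
#' res <- run_simulation("L3", N = 10, M = 200, q = 0.4)
#' res$coop_rate  # exactly 1: no error, cooperative start
#' @export
run_simulation <- function(norms, N = NULL, M = 1e4, q = 0.4, e = 0,
                           gamma = 0, b = 2, c = 1, m0 = NULL,
                           self_update = TRUE, traj_every = 0) {
  if (is.null(N)) {
    N <- if (is.list(norms) && !inherits(norms, c("norm_pair", "norm_table")))
      length(norms) else if (!is.null(m0)) nrow(m0) else
        stop("N must be given when norms is a single norm and m0 is NULL",
             call. = FALSE)
  }
  abm_config_check(N, M, q, e, gamma)
  game <- game_params(b, c)
  if (is.null(m0)) m0 <- matrix(1, N, N)
  validate_image_matrix(m0)
  stopifnot(nrow(m0) == N)
  cm <- corner_matrices(norms, N)
  raw <- abm_run_cpp(m0, cm$acorn, cm$bcorn, as.integer(M), q, e, gamma,
                     game$b, game$c, self_update, as.integer(traj_every),
                     -1L, -1L)
  traj <- NULL
  if (traj_every > 0) {
    traj <- data.frame(round = raw$traj_round, mean_eps = raw$traj_eps,
                       coop_rate = raw$traj_coop)
  }
  structure(list(payoff = raw$payoff, coop_rate = raw$coop_rate,
                 final_matrix = raw$final_matrix, trajectory = traj,
                 params = list(N = N, M = M, q = q, e = e, gamma = gamma,
                               b = game$b, c = game$c,
                               self_update = self_update)),
            class = "abm_result")
}

#' @export
print.abm_result <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "ABM run: N=%d M=%g q=%g e=%g gamma=%g b=%g c=%g\n", p$N, p$M, p$q,
    p$e, p$gamma, p$b, p$c))
  cat(sprintf("  cooperation rate %.4f; mean payoff %.4f\n",
              x$coop_rate, mean(x$payoff)))
  invisible(x)
}

#' Play a single round
#'
#' One round of the agent-based dynamics, optionally with a pinned donor
#' and/or recipient (useful for comparing the ensemble-averaged stochastic
#' update against the deterministic mean-field map).
#'
#' @inheritParams run_simulation
#' @param m current image matrix.
#' @param donor,recipient optional 1-based player indices; drawn uniformly
#'   when NULL.
#' @return a list with `matrix` (updated), `payoff_delta` (length-N, raw
#'   payoff change), and `action` (the realized action).
#' @export
play_round <- function(m, norms, q, e = 0, gamma = 0, b = 2, c = 1,
                       donor = NULL, recipient = NULL, self_update = TRUE) {
  validate_image_matrix(m)
  N <- nrow(m)
  abm_config_check(N, 1, q, e, gamma)
  cm <- corner_matrices(norms, N)
  fd <- if (is.null(donor)) -1L else as.integer(donor - 1)
  fr <- if (is.null(recipient)) -1L else as.integer(recipient - 1)
  if (fd >= N || fr >= N || (fd >= 0 && fd == fr)) {
    stop("invalid donor/recipient indices", call. = FALSE)
  }
  raw <- abm_run_cpp(m, cm$acorn, cm$bcorn, 1L, q, e, gamma, b, c,
                     self_update, 0L, fd, fr)
  list(matrix = raw$final_matrix,
       payoff_delta = raw$payoff / N,  # undo the per-run normalization
       action = raw$coop_rate)
}

#' Mutant-versus-resident payoff experiment
#'
#' Assigns `ceiling(p * N)` players the mutant norm and the rest the
#' resident norm, runs independent replicas from the all-ones matrix, and
#' returns the within-run payoff difference (mean mutant payoff minus mean
#' resident payoff) averaged over replicas with its standard error.
#'
#' @param resident,mutant norms (corner-representable).
#' @param N population size.
#' @param p mutant fraction; `ceiling(p * N)` must be in 1..N-1 for a
#'   two-type comparison.
#' @param M rounds per replica.
#' @param samples number of independent replicas.
#' @inheritParams run_simulation
#' @return a list of class `mutant_experiment` with `dpi0_mean`, `dpi0_se`,
#'   `dpi0` (per-replica values), and `coop_rate` (replica mean).
#' @export
mutant_experiment <- function(resident, mutant, N = 50, p = 0.5, M = 1e4,
                              samples = 100, q = 0.4, e = 0.1, gamma = 0.1,
                              b = 2, c = 1, self_update = TRUE) {
  n_mut <- ceiling(p * N)
  if (n_mut < 1 || n_mut >= N) {
    stop("ceiling(p * N) must leave at least one player of each type",
         call. = FALSE)
  }
  resident <- as_corner_norm(as_norm_pair(resident))
  mutant <- as_corner_norm(as_norm_pair(mutant))
  norms <- c(rep(list(mutant), n_mut), rep(list(resident), N - n_mut))
  is_mut <- seq_len(N) <= n_mut
  dpi <- numeric(samples)
  coop <- numeric(samples)
  for (s in seq_len(samples)) {
    res <- run_simulation(norms, N = N, M = M, q = q, e = e, gamma = gamma,
                          b = b, c = c, self_update = self_update)
    dpi[s] <- mean(res$payoff[is_mut]) - mean(res$payoff[!is_mut])
    coop[s] <- res$coop_rate
  }
  structure(list(dpi0_mean = mean(dpi),
                 dpi0_se = if (samples > 1) sd(dpi) / sqrt(samples) else NA_real_,
                 dpi0 = dpi, coop_rate = mean(coop),
                 params = list(N = N, p = p, M = M, samples = samples,
                               q = q, e = e, gamma = gamma, b = b, c = c)),
            class = "mutant_experiment")
}

#' @export
print.mutant_experiment <- function(x, ...) {
  cat(sprintf(
    "Mutant experiment (%d replicas): dpi0 = %.5g +- %.2g (se), coop rate %.3f\n",
    x$params$samples, x$dpi0_mean, x$dpi0_se, x$coop_rate))
  invisible(x)
}

#' Random slope-mutant scatter
#'
#' Generates random corner mutants of Simple Standing (assessment corners
#' uniform with `alpha(1,1,1) = 1`, behaviour = Simple Standing's), runs a
#' [mutant_experiment()] for each at mutant fraction `p`, and tabulates the
#' mutant's recovery criterion Q against its payoff difference. Across many
#' mutants, Q and the payoff difference are negatively rank-correlated: the
#' same quantity that governs recovery from disagreement predicts how a
#' minority norm fares.
#'
#' @param n_norms number of random mutants.
#' @param resident resident norm (default interpolated Simple Standing).
#' @param M_per_N rounds per player (M = M_per_N * N).
#' @param samples replicas per mutant.
#' @inheritParams mutant_experiment
#' @return a data.frame with columns `norm_id`, `Q`, `dpi0`, `dpi0_se`.
#' @export
slope_mutant_scatter <- function(n_norms = 50, resident = "L3", N = 100,
                                 p = 0.1, M_per_N = 1000, samples = 1,
                                 q = 0.4, e = 0.1, gamma = 0.1, b = 2,
                                 c = 1) {
  stopifnot(n_norms >= 1)
  resident <- as_norm_pair(resident)
  M <- round(M_per_N * N)
  out <- vector("list", n_norms)
  for (i in seq_len(n_norms)) {
    mut <- random_corner_norm()
    ex <- mutant_experiment(resident, mut, N = N, p = p, M = M,
                            samples = samples, q = q, e = e, gamma = gamma,
                            b = b, c = c)
    out[[i]] <- data.frame(norm_id = i, Q = compute_Q(norm_slopes(mut)),
                           dpi0 = ex$dpi0_mean, dpi0_se = ex$dpi0_se)
  }
  do.call(rbind, out)
}
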