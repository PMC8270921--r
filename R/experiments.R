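# Canned experiments: recovery from disagreement, the benefit-cost
# threshold sweep, and fixture generation. Each writer also emits a
# manifest (parameters + seed + package version) sufficient to re-run the
# deterministic paths bit-identically.

#' The three reference recovery norms
#'
#' The standard positive/zero/negative-Q trio used in recovery
#' experiments: a clamped planar norm with slopes (0.2, 0.9, 0.1)/(0.2,
#' 0.8) (Q = 0.2), interpolated Simple Standing (Q = 0), and the graded
#' Simple Standing variant with slopes (0, 0.9, 0)/(0, 0.9) (Q = -0.19),
#' realized exactly as the corner table `0.1 + 0.9 * action` /
#' `0.1 + 0.9 * recipient reputation`.
#'
#' @return a named list of three `norm_pair` objects
#'   (`Q_pos`, `Q_zero`, `Q_neg`).
#' @export
recovery_norms <- function() {
  list(Q_pos = slope_norm(0.2, 0.9, 0.1, 0.2, 0.8),
       Q_zero = interpolate_norm("L3"),
       Q_neg = standing_variant(0.9))
}

#' Graded Simple Standing variant
#'
#' The interpolated norm with assessment corners `0.1 + 0.9 * action` and
#' behaviour corners `0.1 + 0.9 * co-player reputation`, i.e. slopes
#' (Ax, Ay, Az) = (0, s, 0) and (Bx, By) = (0, s) with s = 0.9 by default.
#' It has Q = -1 + s^2 < 0 and a finite benefit-cost threshold 1/s^2, and
#' serves as the resident norm of the threshold sweep.
#'
#' @param s sensitivity in (0, 1\].
#' @return an interpolated `norm_pair`.
#' @export
standing_variant <- function(s = 0.9) {
  base <- 1 - s
  a <- setNames(numeric(8), ALPHA_KEYS)
  for (key in ALPHA_KEYS) {
    a[[key]] <- base + s * (substr(key, 4, 4) == "C")
  }
  b <- setNames(numeric(4), BETA_KEYS)
  for (key in BETA_KEYS) {
    b[[key]] <- base + s * (substr(key, 4, 4) == "1")
  }
  interpolate_norm(norm_table(a, b, name = sprintf("standing_variant(%g)", s)))
}

#' Mean-field recovery experiment
#'
#' Perturbs the all-ones image matrix (a random 20% of entries set to 0.9
#' by default) and iterates the deterministic map for each supplied norm,
#' returning the mean-deviation trajectories in long format.
#'
#' @param norms named list of norms (default [recovery_norms()]).
#' @param N population size.
#' @param q observation probability.
#' @param steps iterations of the map.
#' @param perturb_fraction,perturb_value initial perturbation (see
#'   [perturbed_image_matrix()]).
#' @param seed seed for the perturbation positions (shared across norms so
#'   all trajectories start from the same matrix).
#' @return data.frame with columns `norm`, `t`, `mean_eps`.
#' @export
recovery_experiment <- function(norms = recovery_norms(), N = 50, q = 0.4,
                                steps = 200, perturb_fraction = 0.2,
                                perturb_value = 0.9, seed = 1) {
  m0 <- perturbed_image_matrix(N, perturb_fraction, perturb_value, seed = seed)
  labels <- names(norms)
  if (is.null(labels)) labels <- paste0("norm", seq_along(norms))
  out <- lapply(seq_along(norms), function(i) {
    traj <- recovery_trajectory(m0, norms[[i]], q = q, steps = steps)
    data.frame(norm = labels[i], t = traj$t, mean_eps = traj$mean_eps)
  })
  do.call(rbind, out)
}

#' Benefit-cost threshold sweep
#'
#' Runs a [mutant_experiment()] at each benefit-cost ratio on a grid (cost
#' fixed at `c`), with the resident [standing_variant()] and its default
#' offset mutant, and reports the measured payoff differences next to the
#' analytic threshold `(1 - Ax)/(Ay By)`. The empirical sign change sits at
#' the analytic threshold when perception is error-free and is pushed
#' upward by perception error.
#'
#' @param bc_grid benefit-cost ratios to sweep.
#' @param resident resident norm.
#' @param delta1 mutant assessment offset.
#' @param samples replicas per grid point.
#' @inheritParams mutant_experiment
#' @return data.frame with columns `bc`, `dpi0_mean`, `dpi0_se`; the
#'   analytic threshold and the interpolated empirical sign change are
#'   attached as attributes `analytic_threshold` and `empirical_threshold`.
#' @export
threshold_sweep <- function(bc_grid = seq(1, 1.6, by = 0.05),
                            resident = standing_variant(0.9), delta1 = 0.02,
                            N = 50, M = 1e4, p = 0.5, samples = 50, q = 0.4,
                            e = 0, gamma = 0.1, c = 1) {
  resident <- as_norm_pair(resident)
  mutant <- offset_norm(resident, mutant_offset(delta1 = delta1))
  rows <- lapply(bc_grid, function(r) {
    ex <- mutant_experiment(resident, mutant, N = N, p = p, M = M,
                            samples = samples, q = q, e = e, gamma = gamma,
                            b = r * c, c = c)
    data.frame(bc = r, dpi0_mean = ex$dpi0_mean, dpi0_se = ex$dpi0_se)
  })
  out <- do.call(rbind, rows)
  attr(out, "analytic_threshold") <- bc_threshold(norm_slopes(resident))
  attr(out, "empirical_threshold") <- estimate_sign_change(out$bc, out$dpi0_mean)
  out
}

#' Linear-interpolation sign-change estimate
#'
#' Locates the first downward zero crossing of `y` along `x` by linear
#' interpolation between the bracketing grid points; `NA` if there is none.
#'
#' @param x ordered abscissae.
#' @param y values.
#' @return estimated crossing, or `NA`.
#' @export
estimate_sign_change <- function(x, y) {
  stopifnot(length(x) == length(y), !is.unsorted(x))
  for (i in seq_len(length(x) - 1)) {
    if (y[i] > 0 && y[i + 1] <= 0) {
      return(x[i] + (x[i + 1] - x[i]) * y[i] / (y[i] - y[i + 1]))
    }
  }
  NA_real_
}

#' Write an experiment manifest
#'
#' @param path output file.
#' @param params named list of parameters (seed included by the caller).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, params) {
  stopifnot(is.list(params))
  lines <- c(sprintf("package = contrep %s",
                     as.character(utils::packageVersion("contrep"))),
             sprintf("date = %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             vapply(names(params), function(k) {
               sprintf("%s = %s", k, paste(format(params[[k]]), collapse = ","))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Generate seeded fixture files
#'
#' Writes small plain-text fixtures: an all-ones N = 3 image matrix, a
#' perturbed image matrix (exactly `ceiling(0.2 N^2)` entries at 0.9), the
#' L3 norm file, and `n_norms` random corner norms with the cooperative
#' corner fixed.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param N size of the perturbed matrix fixture.
#' @param n_norms number of random norm files.
#' @return character vector of written paths, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 1, N = 10, n_norms = 5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  paths <- character(0)
  p <- file.path(dir, "image_allones_N3.csv")
  write.csv(matrix(1, 3, 3), p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, sprintf("image_perturbed_N%d.csv", N))
  write.csv(perturbed_image_matrix(N, 0.2, 0.9), p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "norm_L3.txt")
  write_norm("L3", p)
  paths <- c(paths, p)
  for (i in seq_len(n_norms)) {
    p <- file.path(dir, sprintf("norm_random_%02d.txt", i))
    write_norm(random_corner_norm()$table, p)
    paths <- c(paths, p)
  }
  write_manifest(file.path(dir, "MANIFEST.txt"),
                 list(seed = seed, N = N, n_norms = n_norms))
  invisible(c(paths, file.path(dir, "MANIFEST.txt")))
}

#' Read an image matrix written by [generate_fixtures()]
#'
#' @param path CSV path.
#' @return a numeric matrix.
#' @export
read_image_matrix <- function(path) {
  m <- as.matrix(read.csv(path))
  dimnames(m) <- NULL
  validate_image_matrix(m)
  m
}
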