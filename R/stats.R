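#' Paired before/after design
#'
#' Per-cage summed running distances before and after an intervention (for
#' example a period of caloric restriction), ready for the paired sign-flip
#' permutation test. QC-excluded cages stay in the table, flagged, and are
#' dropped only inside the statistics — exclusion is always explicit.
#'
#' @param cage Unique cage labels.
#' @param before_cm,after_cm Non-negative summed distances (cm).
#' @param excluded Cage labels to exclude from analysis (must be a subset of
#'   `cage`), or a logical vector along `cage`.
#' @return A `paired_design` tibble: `cage`, `before_cm`, `after_cm`,
#'   `excluded`.
#' @export
paired_design <- function(cage, before_cm, after_cm, excluded = character()) {
  cage <- as.character(cage)
  if (anyDuplicated(cage)) validation_error("Cage labels must be unique.")
  if (any(before_cm < 0) || any(after_cm < 0)) {
    validation_error("Distances must be non-negative.")
  }
  if (is.logical(excluded)) {
    stopifnot(length(excluded) == length(cage))
    excl <- excluded
  } else {
    if (!all(excluded %in% cage)) {
      validation_error("excluded must be a subset of the cage labels.")
    }
    excl <- cage %in% excluded
  }
  out <- tibble::tibble(
    cage = cage, before_cm = as.numeric(before_cm),
    after_cm = as.numeric(after_cm), excluded = excl
  )
  class(out) <- c("paired_design", class(out))
  out
}

#' Read / write a paired design as CSV
#'
#' The CSV carries columns `cage`, `before_cm`, `after_cm` and optionally
#' `excluded`.
#'
#' @param path File path.
#' @param excluded Additional cage labels to mark excluded on read.
#' @return A [paired_design()] / `path` invisibly.
#' @export
read_paired_design <- function(path, excluded = character()) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  excl <- if ("excluded" %in% names(d)) {
    d$cage[as.logical(d$excluded)]
  } else character()
  paired_design(d$cage, d$before_cm, d$after_cm,
                excluded = union(as.character(excl), excluded))
}

#' @rdname read_paired_design
#' @param design A [paired_design()].
#' @export
write_paired_design <- function(design, path) {
  readr::write_csv(tibble::as_tibble(design), path)
  invisible(path)
}

design_diffs <- function(design, min_n = 1) {
  stopifnot(is.data.frame(design),
            all(c("cage", "before_cm", "after_cm") %in% names(design)))
  excl <- if ("excluded" %in% names(design)) design$excluded else FALSE
  keep <- !excl
  if (sum(keep) < min_n) {
    validation_error(sprintf("Need at least %d non-excluded cage(s).", min_n))
  }
  design$after_cm[keep] - design$before_cm[keep]
}

#' Observed paired statistic: mean of per-cage after - before differences
#'
#' @param design A [paired_design()] (or any data frame with `cage`,
#'   `before_cm`, `after_cm` and optionally `excluded` columns).
#' @return The mean difference (cm) over non-excluded cages.
#' @export
paired_mean_difference <- function(design) {
  mean(design_diffs(design, min_n = 1))
}

tail_count <- function(null_stats, observed, sidedness) {
  # ties count as extreme; the tolerance absorbs the one-ulp difference
  # between mean() and the matrix arithmetic producing the null stats, so
  # the identity assignment always registers as a tie
  eps <- 1e-8 * max(1, abs(observed))
  switch(sidedness,
    one_greater = sum(null_stats >= observed - eps),
    one_less = sum(null_stats <= observed + eps),
    two = sum(abs(null_stats) >= abs(observed) - eps),
    validation_error(sprintf("Unknown sidedness %s.", deparse(sidedness)))
  )
}

density_tail_p <- function(null_stats, observed, sidedness) {
  if (sd(null_stats) == 0) {
    # degenerate null: fall back to the empirical proportion
    return(tail_count(null_stats, observed, sidedness) / length(null_stats))
  }
  d <- density(null_stats)
  area_ge <- function(x0) trapezoid_tail(d$x, d$y, x0, upper = TRUE)
  area_le <- function(x0) trapezoid_tail(d$x, d$y, x0, upper = FALSE)
  total <- trapezoid_tail(d$x, d$y, -Inf, upper = TRUE)
  p <- switch(sidedness,
    one_greater = area_ge(observed),
    one_less = area_le(observed),
    two = area_ge(abs(observed)) + area_le(-abs(observed))
  ) / total
  min(max(p, .Machine$double.eps), 1)
}

trapezoid_tail <- function(x, y, x0, upper = TRUE) {
  if (!upper) return(trapezoid_tail(-rev(x), rev(y), -x0, upper = TRUE))
  if (x0 <= x[1]) {
    return(sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))
  }
  if (x0 >= x[length(x)]) return(0)
  i <- findInterval(x0, x)
  y0 <- y[i] + (y[i + 1] - y[i]) * (x0 - x[i]) / (x[i + 1] - x[i])
  xs <- c(x0, x[(i + 1):length(x)])
  ys <- c(y0, y[(i + 1):length(y)])
  sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
}

#' Paired sign-flip permutation test (Monte-Carlo)
#'
#' Tests whether the mean per-cage after - before difference departs from
#' the exchangeable null in which each cage's before/after labels are
#' arbitrary. Each of the `n_permutations` draws independently swaps (or
#' not, with probability 1/2) the labels within every cage — equivalently,
#' flips the sign of each cage's difference — and recomputes the mean;
#' these means form the null distribution. Duplicated draws are allowed.
#'
#' Three p-value estimators are computed side by side:
#' \describe{
#'   \item{empirical}{tail proportion `k / B`, ties counting as extreme.}
#'   \item{empirical_add_one}{`(k + 1) / (B + 1)`; never exactly zero,
#'     the default.}
#'   \item{density_auc}{tail area of a Gaussian kernel density fitted to
#'     the null means, beyond the observed statistic.}
#' }
#'
#' @param design A [paired_design()] with at least 2 non-excluded cages.
#' @param n_permutations Number of Monte-Carlo permutations (default 1000).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param sidedness `"one_greater"` (default; directed at an activity
#'   increase), `"one_less"`, or `"two"`.
#' @param estimator Which estimator populates `p_value`.
#' @return A `perm_test` object; see also [tidy.perm_test()],
#'   [glance.perm_test()], [autoplot.perm_test()].
#' @seealso [exact_sign_flip_test()] for the full enumeration oracle.
#' @export
permutation_test <- function(design, n_permutations = 1000, seed = NULL,
                             sidedness = c("one_greater", "one_less", "two"),
                             estimator = c("empirical_add_one", "empirical", "density_auc")) {
  sidedness <- match.arg(sidedness)
  estimator <- match.arg(estimator)
  if (n_permutations < 1) validation_error("n_permutations must be >= 1.")
  diffs <- design_diffs(design, min_n = 2)
  n <- length(diffs)
  B <- as.integer(n_permutations)
  observed <- mean(diffs)

  draw <- function() {
    signs <- matrix(sample(c(1, -1), B * n, replace = TRUE), nrow = B)
    as.vector(signs %*% diffs) / n
  }
  null_stats <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  k <- tail_count(null_stats, observed, sidedness)
  p <- list(
    empirical = k / B,
    empirical_add_one = (k + 1) / (B + 1),
    density_auc = density_tail_p(null_stats, observed, sidedness)
  )
  structure(
    list(
      observed_stat = observed,
      null_stats = null_stats,
      p_value = p[[estimator]],
      p_empirical = p$empirical,
      p_empirical_add_one = p$empirical_add_one,
      p_density_auc = p$density_auc,
      n_permutations = B,
      n_cages = n,
      sidedness = sidedness,
      estimator = estimator,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    ),
    class = "perm_test"
  )
}

#' Exact sign-flip test by full enumeration
#'
#' Enumerates all `2^n` before/after label assignments (sign patterns of
#' the per-cage differences) and returns the fraction whose null mean is at
#' least as extreme as the observed one, ties counting as extreme. Serves
#' as the exact oracle for [permutation_test()].
#'
#' @inheritParams permutation_test
#' @return The exact p-value, with the full null distribution attached as
#'   attribute `null_stats`.
#' @export
exact_sign_flip_test <- function(design,
                                 sidedness = c("one_greater", "one_less", "two")) {
  sidedness <- match.arg(sidedness)
  diffs <- design_diffs(design, min_n = 1)
  n <- length(diffs)
  if (n > 20) {
    validation_error("Exact enumeration is limited to 20 cages (2^n assignments); use permutation_test() for larger designs.")
  }
  # subset sums by iterative doubling: all sums of flipped-cage differences
  ss <- 0
  for (d in diffs) ss <- c(ss, ss + d)
  null_stats <- (sum(diffs) - 2 * ss) / n
  observed <- mean(diffs)
  p <- tail_count(null_stats, observed, sidedness) / length(null_stats)
  structure(p, null_stats = null_stats, observed_stat = observed)
}

#' Simulate type-I error rate or power of the paired permutation test
#'
#' Draws `n_reps` synthetic paired designs whose per-cage differences are
#' Normal(`effect_cm`, `noise_sd_cm`), runs the Monte-Carlo test on each,
#' and reports the rejection rate at level `alpha`. With `effect_cm = 0`
#' this is the empirical type-I error; otherwise it is power.
#'
#' @param n_cages Cages per simulated design.
#' @param effect_cm True mean difference (cm); 0 simulates the null.
#' @param noise_sd_cm SD (cm) of the per-cage differences.
#' @param n_reps Number of simulated experiments (>= 1).
#' @param n_permutations Permutations per test.
#' @param seed Integer seed for the whole simulation.
#' @param alpha Rejection level.
#' @param sidedness Passed to [permutation_test()].
#' @return A one-row tibble: `rejection_rate`, `n_reps`, `n_cages`,
#'   `effect_cm`, `noise_sd_cm`, `n_permutations`, `alpha`, `sidedness`.
#' @export
simulate_operating_characteristics <- function(n_cages, effect_cm = 0,
                                               noise_sd_cm = 1, n_reps = 100,
                                               n_permutations = 1000,
                                               seed = 1L, alpha = 0.05,
                                               sidedness = "one_greater") {
  if (n_reps < 1) validation_error("n_reps must be >= 1.")
  rejections <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      diffs <- rnorm(n_cages, effect_cm, noise_sd_cm)
      design <- paired_design(
        cage = paste0("cage", seq_len(n_cages)),
        before_cm = pmax(-diffs, 0),
        after_cm = pmax(diffs, 0)
      )
      res <- permutation_test(design, n_permutations = n_permutations,
                              seed = NULL, sidedness = sidedness)
      res$p_value <= alpha
    }, logical(1))
  })
  tibble::tibble(
    rejection_rate = mean(rejections), n_reps = as.integer(n_reps),
    n_cages = as.integer(n_cages), effect_cm = effect_cm,
    noise_sd_cm = noise_sd_cm, n_permutations = as.integer(n_permutations),
    alpha = alpha, sidedness = sidedness
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> paired sign-flip permutation test (%d cages, B = %d, %s)\n",
    x$n_cages, x$n_permutations, x$sidedness
  ))
  cat(sprintf("  observed mean difference: %.4g cm\n", x$observed_stat))
  cat(sprintf("  p (empirical)        = %.4g\n", x$p_empirical))
  cat(sprintf("  p (add-one, default) = %.4g\n", x$p_empirical_add_one))
  cat(sprintf("  p (density AUC)      = %.4g\n", x$p_density_auc))
  invisible(x)
}

#' Tidy a permutation-test result
#'
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @return One row per p-value estimator: `estimate`, `estimator`,
#'   `p.value`, `sidedness`, `n_permutations`.
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$observed_stat,
    estimator = c("empirical", "empirical_add_one", "density_auc"),
    p.value = c(x$p_empirical, x$p_empirical_add_one, x$p_density_auc),
    sidedness = x$sidedness,
    n_permutations = x$n_permutations
  )
}

#' One-row summary of a permutation-test result
#'
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @return A one-row tibble with the default-estimator p-value.
#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$observed_stat, p.value = x$p_value,
    estimator = x$estimator, sidedness = x$sidedness,
    n_cages = x$n_cages, n_permutations = x$n_permutations,
    seed = x$seed
  )
}
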