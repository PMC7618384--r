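#' Per-group measurements
#'
#' A labelled vector of per-animal measurements (e.g. region-averaged mural
#' counts, one value per animal).
#'
#' @param label condition/region tag.
#' @param values finite numeric vector, length >= 1.
#' @return a `group_counts` object.
#' @export
group_counts <- function(label, values) {
  values <- as.numeric(values)
  if (!length(values)) stop("group '", label, "' is empty", call. = FALSE)
  if (any(!is.finite(values)))
    stop("group '", label, "' contains non-finite values", call. = FALSE)
  structure(list(label = as.character(label), values = values),
            class = "group_counts")
}

as_group_values <- function(g) {
  if (inherits(g, "group_counts")) g$values else {
    v <- as.numeric(g)
    if (!length(v)) stop("empty group", call. = FALSE)
    if (any(!is.finite(v))) stop("non-finite group values", call. = FALSE)
    v
  }
}

# sum of t^3 - t over tie groups of a pooled sample
tie_term <- function(pooled) {
  t <- table(pooled)
  sum(t^3 - t)
}

# tie-corrected normal-approximation two-sided p for the U statistic
mwu_p_asymptotic <- function(U, n1, n2, tie_sum = 0, continuity = TRUE) {
  N <- n1 + n2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_sum / (N * (N - 1)))
  if (sigma2 <= 0) return(list(z = rep(0, length(U)), p = rep(1, length(U))))
  cc <- if (continuity) 0.5 else 0
  dev <- U - mu
  z <- (dev - sign(dev) * pmin(cc, abs(dev))) / sqrt(sigma2)
  list(z = z, p = pmin(1, 2 * stats::pnorm(-abs(z))))
}

# exact two-sided p via the null U distribution (no ties) or, with ties,
# full enumeration of rank-subset assignments
mwu_p_exact <- function(U, r, n1, n2) {
  N <- n1 + n2
  if (!any(duplicated(r))) {
    p <- 2 * min(stats::pwilcox(U, n1, n2), stats::pwilcox(n1 * n2 - U, n1, n2))
    return(min(1, p))
  }
  if (choose(N, n1) > 2e5)
    stop("exact test with ties needs choose(n1+n2, n1) <= 2e5 enumerations; ",
         "use mode = 'asymptotic'", call. = FALSE)
  subsets <- utils::combn(N, n1)
  u_all <- colSums(matrix(r[subsets], nrow = n1)) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
}

#' Mann-Whitney U test (Wilcoxon rank-sum), two-sided
#'
#' Exact mode uses the null distribution of U (full enumeration of rank
#' assignments when ties are present); asymptotic mode uses the tie-corrected
#' normal approximation with optional continuity correction. `auto` picks
#' exact for small tie-free samples (n1 + n2 <= 16) and asymptotic otherwise.
#'
#' @param a,b numeric vectors or [group_counts()] objects.
#' @param mode `"auto"`, `"exact"` or `"asymptotic"`.
#' @param continuity use the 0.5 continuity correction in asymptotic mode.
#' @return a `test_result` with the U statistic of the first group, the
#'   two-sided p-value, the mode actually used and group sizes.
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "asymptotic"),
                         continuity = TRUE) {
  mode <- match.arg(mode)
  va <- as_group_values(a)
  vb <- as_group_values(b)
  n1 <- length(va); n2 <- length(vb); N <- n1 + n2
  r <- rank(c(va, vb))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(va, vb)))
  used <- if (mode == "auto") {
    if (N <= 16 && !ties) "exact" else "asymptotic"
  } else mode
  if (used == "exact") {
    p <- mwu_p_exact(U, r, n1, n2)
    z <- NA_real_
  } else {
    as <- mwu_p_asymptotic(U, n1, n2, tie_sum = tie_term(c(va, vb)),
                           continuity = continuity)
    p <- as$p; z <- as$z
  }
  structure(list(method = "mann_whitney", mode = used,
                 statistic = c(U = U), z = z, p_value = p,
                 n = c(n1 = n1, n2 = n2)),
            class = "test_result")
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' k - 1 degrees of freedom. When every observation is identical the test is
#' degenerate and returns H = 0, p = 1.
#'
#' @param groups named list of numeric vectors, or list of [group_counts()].
#' @return a `test_result` with `statistic` (H), `df`, `p_value` and the
#'   pooled mean ranks per group.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  vals <- lapply(groups, as_group_values)
  labs <- group_labels(groups)
  pooled <- unlist(vals, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(vals), lengths(vals))
  rbar <- tapply(r, idx, mean)
  ni <- lengths(vals)
  H0 <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  C <- 1 - tie_term(pooled) / (N^3 - N)
  if (C <= 0) { H <- 0; p <- 1 } else {
    H <- H0 / C
    p <- stats::pchisq(H, df = length(vals) - 1L, lower.tail = FALSE)
  }
  structure(list(method = "kruskal_wallis", statistic = c(H = H),
                 df = length(vals) - 1L, p_value = p,
                 mean_ranks = stats::setNames(as.numeric(rbar), labs),
                 n = stats::setNames(ni, labs)),
            class = "test_result")
}

group_labels <- function(groups) {
  labs <- names(groups)
  from_obj <- vapply(groups, function(g)
    if (inherits(g, "group_counts")) g$label else NA_character_, "")
  if (is.null(labs)) labs <- from_obj
  labs[is.na(labs) | labs == ""] <- from_obj[is.na(labs) | labs == ""]
  labs[is.na(labs)] <- paste0("group", which(is.na(labs)))
  labs
}

#' Dunn's post-hoc multiple comparisons
#'
#' Pairwise z statistics from pooled mean ranks with tie correction,
#' z = (rbar_i - rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j)),
#' where T is the tie term. The family adjustment multiplies each unadjusted
#' p by the number of requested comparisons (Bonferroni-style), capped at 1.
#'
#' @param groups named list of numeric vectors or [group_counts()].
#' @param comparisons list of length-2 character vectors naming group pairs;
#'   default all pairs.
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return a `test_result` whose `comparisons` data.frame has one row per
#'   pair: `z`, `p`, `p_adj`.
#' @export
dunn_posthoc <- function(groups, comparisons = NULL,
                         adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  vals <- lapply(groups, as_group_values)
  labs <- group_labels(groups)
  names(vals) <- labs
  pooled <- unlist(vals, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(vals), lengths(vals))
  rbar <- tapply(r, idx, mean)
  ni <- lengths(vals)
  TS <- tie_term(pooled)
  if (is.null(comparisons))
    comparisons <- utils::combn(labs, 2L, simplify = FALSE)
  m <- length(comparisons)
  rows <- lapply(comparisons, function(cp) {
    if (!all(cp %in% labs))
      stop("comparison names an absent group: ", paste(cp, collapse = " vs "),
           call. = FALSE)
    i <- match(cp[1], labs); j <- match(cp[2], labs)
    V <- (N * (N + 1) / 12 - TS / (12 * (N - 1))) * (1 / ni[i] + 1 / ni[j])
    z <- if (V <= 0) 0 else (rbar[i] - rbar[j]) / sqrt(V)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    data.frame(group1 = cp[1], group2 = cp[2], z = as.numeric(z), p = p)
  })
  cmp <- do.call(rbind, rows)
  cmp$p_adj <- if (adjust == "bonferroni") pmin(1, m * cmp$p) else cmp$p
  structure(list(method = "dunn_posthoc", adjust = adjust,
                 comparisons = cmp, m = m),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat("Test:", x$method)
  if (!is.null(x$mode)) cat(" (", x$mode, ")", sep = "")
  cat("\n")
  if (!is.null(x$statistic))
    cat("  statistic:", paste(names(x$statistic), "=",
                              signif(x$statistic, 5)), "\n")
  if (!is.null(x$p_value)) cat("  p-value:", format.pval(x$p_value), "\n")
  if (!is.null(x$comparisons)) {
    cat("  comparisons:\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}

# vectorized power of the two-sided Mann-Whitney test under a normal shift d.
# The power simulation follows the power-analysis convention: the normal
# approximation WITHOUT continuity correction (the correction is a
# small-sample p-value adjustment, not part of sample-size planning; with it,
# the detectable effect comes out ~0.05 larger). Continuous data, so ties
# have probability zero.
mwu_power_sim <- function(d, n_per_group, alpha, reps, continuity = FALSE) {
  n <- n_per_group
  N <- 2L * n
  x <- matrix(stats::rnorm(reps * N), nrow = reps)
  x[, (n + 1L):N] <- x[, (n + 1L):N] + d
  U <- apply(x, 1L, function(row) {
    r <- rank(row)
    n * n + n * (n + 1) / 2 - sum(r[seq_len(n)])  # U of the shifted sample
  })
  p <- mwu_p_asymptotic(U, n, n, tie_sum = 0, continuity = continuity)$p
  mean(p <= alpha)
}

#' Minimum detectable effect of the Mann-Whitney test by simulation
#'
#' Sensitivity analysis: simulates two samples of `n_per_group` from N(0, 1)
#' and N(d, 1) over a grid of standardized effect sizes d, applies a
#' two-sided Mann-Whitney test at `alpha` to each replicate pair, and returns
#' the smallest grid d whose estimated power reaches the target. A coarse
#' scan brackets the crossing first; the fine grid (step `d_step`) is then
#' evaluated at the full replicate count. Following power-analysis
#' convention, the simulated test is the tie-corrected normal approximation
#' without continuity correction (the convention the ARE closed form
#' [mde_t_are()] also embodies); the continuity-corrected or exact test is
#' slightly conservative and shifts the detectable effect up by about 0.05.
#'
#' @param n_per_group sample size per group.
#' @param alpha two-sided significance level.
#' @param power target power in (0, 1).
#' @param reps Monte-Carlo replicates per fine-grid point (>= 1000 advised;
#'   10000 reproduces the printed sensitivity value stably).
#' @param seed integer seed.
#' @param d_step fine grid step in d (must be <= 0.02 for the headline use).
#' @param d_max search ceiling; power not reaching the target by `d_max` is a
#'   divergence error.
#' @return an `mde_result`: the minimum detectable `d`, a Monte-Carlo
#'   confidence interval for the power-curve crossing, and the evaluated grid.
#' @export
minimum_detectable_effect <- function(n_per_group, alpha = 0.05, power = 0.80,
                                      reps = 10000L, seed = 1L, d_step = 0.02,
                                      d_max = 10) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)", call. = FALSE)
  if (reps < 2) stop("reps must exceed 1", call. = FALSE)
  reps_coarse <- max(500L, reps %/% 10L)
  coarse <- seq(0.2, d_max, by = 0.2)
  hit <- NA_real_
  for (k in seq_along(coarse)) {
    set.seed(derive_seed(seed, k))
    if (mwu_power_sim(coarse[k], n_per_group, alpha, reps_coarse) >= power) {
      hit <- coarse[k]; break
    }
  }
  if (is.na(hit))
    stop("power target not attainable for d <= ", d_max, call. = FALSE)
  lo <- max(d_step, hit - 0.4)
  hi <- min(d_max, hit + 0.2)
  grid <- seq(lo, hi, by = d_step)
  pw <- numeric(length(grid))
  for (k in seq_along(grid)) {
    set.seed(derive_seed(seed, 1000L + k))
    pw[k] <- mwu_power_sim(grid[k], n_per_group, alpha, reps)
  }
  while (!any(pw >= power)) {
    lo2 <- hi + d_step
    hi <- min(d_max, hi + 0.4)
    if (lo2 > hi) stop("power target not attainable for d <= ", d_max, call. = FALSE)
    ext <- seq(lo2, hi, by = d_step)
    pw2 <- numeric(length(ext))
    for (k in seq_along(ext)) {
      set.seed(derive_seed(seed, 2000L + length(grid) + k))
      pw2[k] <- mwu_power_sim(ext[k], n_per_group, alpha, reps)
    }
    grid <- c(grid, ext); pw <- c(pw, pw2)
  }
  i <- which(pw >= power)[1L]
  d_hat <- grid[i]
  # Monte-Carlo CI of the crossing: translate the binomial CI on power at the
  # crossing point into d via the local slope of the power curve
  se <- sqrt(pw[i] * (1 - pw[i]) / reps)
  slope <- if (i > 1L) max((pw[i] - pw[i - 1L]) / d_step, 1e-6) else
    if (i < length(grid)) max((pw[i + 1L] - pw[i]) / d_step, 1e-6) else 1e-6
  half <- 1.96 * se / slope
  structure(list(d = d_hat, d_ci = c(d_hat - half, d_hat + half),
                 n_per_group = n_per_group, alpha = alpha,
                 power_target = power, reps = reps,
                 grid = data.frame(d = grid, power = pw)),
            class = "mde_result")
}

#' @export
print.mde_result <- function(x, ...) {
  cat(sprintf("Minimum detectable effect (Mann-Whitney, n = %d/group, alpha = %g, power = %g):\n",
              x$n_per_group, x$alpha, x$power_target))
  cat(sprintf("  d = %.2f (MC crossing CI %.2f - %.2f, %d reps/grid point)\n",
              x$d, x$d_ci[1], x$d_ci[2], x$reps))
  invisible(x)
}

#' Closed-form minimum detectable effect via the t-test and ARE
#'
#' The two-sample t-test's detectable d at the same (n, alpha, power),
#' inflated by 1/sqrt(0.955) — the asymptotic relative efficiency of the
#' Mann-Whitney test against the t-test under normal shift alternatives.
#' Serves as an independent closed-form comparator for
#' [minimum_detectable_effect()].
#'
#' @param n_per_group,alpha,power as in [minimum_detectable_effect()].
#' @return a single numeric d.
#' @export
mde_t_are <- function(n_per_group, alpha = 0.05, power = 0.80) {
  d_t <- stats::power.t.test(n = n_per_group, sig.level = alpha, power = power,
                             type = "two.sample")$delta
  d_t / sqrt(0.955)
}
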