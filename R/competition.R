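# Selection-coefficient estimation from pairwise competition time series.
# The selection coefficient is the slope of ln(N_mutant / N_reference)
# against generations, fit by ordinary least squares over the linear phase
# of the competition.

assert_competition_series <- function(series, single_replicate = FALSE) {
  needed <- c("replicate", "generations", "count_mutant", "count_reference")
  missing <- setdiff(needed, names(series))
  if (length(missing)) {
    stop("competition series lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(series$count_mutant < 0) || any(series$count_reference < 0)) {
    stop("counts must be non-negative")
  }
  for (r in unique(series$replicate)) {
    g <- series$generations[series$replicate == r]
    if (any(diff(g) <= 0)) {
      stop(sprintf("generations must be strictly increasing (replicate %s)", r))
    }
  }
  if (single_replicate && length(unique(series$replicate)) != 1L) {
    stop("a single-replicate series is required; split by replicate first")
  }
  invisible(series)
}

ln_ratio <- function(series, pseudocount = 0) {
  cm <- series$count_mutant + pseudocount
  cr <- series$count_reference + pseudocount
  if (any(cm <= 0) || any(cr <= 0)) {
    stop("zero count inside the fitted window; re-window the series ",
         "(select_linear_phase) or set pseudocount = 0.5")
  }
  log(cm / cr)
}

# R^2 that treats an exact fit of a flat line as perfect rather than 0/0
window_r2 <- function(x, y) {
  fit <- lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  sse <- sum(residuals(fit)^2)
  if (sst < 1e-12) return(if (sse < 1e-12) 1 else 0)
  1 - sse / sst
}

#' Select the linear phase of a competition series
#'
#' Competitions leave their log-linear phase when one competitor nears
#' fixation or detection limits.  This picks, among all contiguous
#' sub-series with at least `min_points` samples that drop no more than
#' `max_dropped_fraction` of the data, the window maximizing the regression
#' \eqn{R^2} of log ratio against generations.  Ties favour longer windows,
#' then earlier ones, so an already-linear series is returned unchanged.
#'
#' @param series Single-replicate competition data frame
#'   (see [gen_competition_series()]).
#' @param min_points Minimum samples in the window (>= 3).
#' @param max_dropped_fraction Maximum fraction of samples dropped.
#' @param pseudocount Added to both counts before taking the log ratio;
#'   default 0 (zero counts make a window inadmissible).
#' @return The sub-series, with attribute `window` giving the first and
#'   last generation retained.
#' @export
select_linear_phase <- function(series, min_points = 5,
                                max_dropped_fraction = 0.5,
                                pseudocount = 0) {
  assert_competition_series(series, single_replicate = TRUE)
  n <- nrow(series)
  min_points <- max(3L, as.integer(min_points))
  if (min_points > n) {
    stop(sprintf("min_points (%d) exceeds the series length (%d)",
                 min_points, n))
  }
  max_drop <- floor(max_dropped_fraction * n)
  best <- NULL
  best_key <- c(-Inf, -Inf, Inf)  # r2, length, -start
  for (i in seq_len(n)) {
    for (j in i:n) {
      len <- j - i + 1L
      if (len < min_points || n - len > max_drop) next
      sub <- series[i:j, , drop = FALSE]
      if (any(sub$count_mutant + pseudocount <= 0) ||
          any(sub$count_reference + pseudocount <= 0)) next
      r2 <- window_r2(sub$generations, ln_ratio(sub, pseudocount))
      key <- c(r2, len, -i)
      if (key[1] > best_key[1] + 1e-12 ||
          (abs(key[1] - best_key[1]) <= 1e-12 &&
           (key[2] > best_key[2] ||
            (key[2] == best_key[2] && key[3] > best_key[3])))) {
        best_key <- key
        best <- c(i, j)
      }
    }
  }
  if (is.null(best)) {
    stop("no admissible window: every candidate violates min_points, ",
         "max_dropped_fraction, or contains a zero count")
  }
  out <- series[best[1]:best[2], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window") <- c(first = out$generations[1],
                           last = out$generations[nrow(out)])
  out
}

new_selection_estimate <- function(s, se, ci95, n_replicates, normalized,
                                   window = c(NA_real_, NA_real_),
                                   df = NA_real_,
                                   method = "single-regression") {
  structure(
    list(s = unname(s), se = unname(se),
         ci95 = unname(ci95), n_replicates = as.integer(n_replicates),
         normalized = isTRUE(normalized),
         linear_window = unname(window), df = df, method = method,
         convention = "s = OLS slope of ln(mutant/reference) per generation; w = 1 + s"),
    class = "selection_estimate"
  )
}

#' Construct a selection estimate by hand
#'
#' Mostly useful for entering published selection coefficients or building
#' test fixtures; estimates from data come from [estimate_selection()].
#'
#' @param s Per-generation selection coefficient.
#' @param se Standard error of `s`.
#' @param ci95 Length-2 confidence bounds; default `s ± 1.96 se`.
#' @param n_replicates Number of replicates behind the estimate.
#' @param normalized Has the wild-type control been subtracted?
#' @return A `selection_estimate`.
#' @export
selection_estimate <- function(s, se, ci95 = s + c(-1.96, 1.96) * se,
                               n_replicates = 1, normalized = FALSE) {
  stopifnot(se >= 0, length(ci95) == 2L, ci95[1] <= s, s <= ci95[2])
  new_selection_estimate(s, se, ci95, n_replicates, normalized,
                         method = "manual")
}

#' Estimate a selection coefficient from one competition series
#'
#' Fits ordinary least squares of \eqn{\ln(N_{mut}/N_{ref})} on generations
#' for a single replicate.  The slope is the per-generation selection
#' coefficient; its standard error and 95% confidence interval come from
#' the regression (t critical value at \eqn{n - 2} degrees of freedom, as
#' `confint()` computes).
#'
#' @inheritParams select_linear_phase
#' @return A `selection_estimate` with `normalized = FALSE`.
#' @examples
#' cfg <- sim_config(seed = 11)
#' ser <- gen_competition_series(0.1, cfg)
#' estimate_selection(subset(ser, replicate == "r1"))
#' @export
estimate_selection <- function(series, pseudocount = 0) {
  assert_competition_series(series, single_replicate = TRUE)
  ok <- (series$count_mutant + pseudocount) > 0 &
    (series$count_reference + pseudocount) > 0
  if (sum(ok) < 3L) {
    stop("at least 3 samples with both counts positive are required")
  }
  y <- ln_ratio(series, pseudocount)
  x <- series$generations
  fit <- lm(y ~ x)
  # slope SE and t-based 95% CI in closed form (equal to confint(fit, "x"),
  # but defined even for an exact fit)
  n <- length(x)
  s <- coef(fit)[["x"]]
  sxx <- sum((x - mean(x))^2)
  se <- sqrt(sum(residuals(fit)^2) / (n - 2) / sxx)
  tcrit <- stats::qt(0.975, n - 2)
  new_selection_estimate(
    s = s,
    se = se,
    ci95 = s + c(-tcrit, tcrit) * se,
    n_replicates = 1L,
    normalized = FALSE,
    window = c(min(x), max(x)),
    df = n - 2
  )
}

#' Pool selection estimates across biological replicates
#'
#' The pooled coefficient is the mean of the replicate coefficients; its
#' standard error is the standard error of that mean, and the confidence
#' interval is `mean ± 1.96 SEM` (the convention for replicate-pooled
#' quantities).  A single estimate passes through unchanged.
#'
#' @param estimates List of `selection_estimate`s with the same
#'   `normalized` flag.
#' @return A pooled `selection_estimate`.
#' @export
pool_replicates <- function(estimates) {
  if (inherits(estimates, "selection_estimate")) estimates <- list(estimates)
  stopifnot(length(estimates) >= 1L,
            all(vapply(estimates, inherits, TRUE, "selection_estimate")))
  norm <- vapply(estimates, `[[`, TRUE, "normalized")
  if (length(unique(norm)) != 1L) {
    stop("cannot pool a mixture of normalized and unnormalized estimates")
  }
  if (length(estimates) == 1L) {
    out <- estimates[[1L]]
    out$method <- "replicate-pool"
    return(out)
  }
  svals <- vapply(estimates, `[[`, 1.0, "s")
  s <- mean(svals)
  se <- sd(svals) / sqrt(length(svals))
  windows <- unlist(lapply(estimates, `[[`, "linear_window"))
  new_selection_estimate(
    s = s, se = se, ci95 = s + c(-1.96, 1.96) * se,
    n_replicates = length(svals), normalized = norm[1L],
    window = if (all(is.na(windows))) c(NA_real_, NA_real_)
             else range(windows, na.rm = TRUE),
    method = "replicate-pool"
  )
}

#' Normalize a selection estimate against the wild-type control
#'
#' Subtracts the wild-type control's mean selection coefficient (wild-type
#' vs wild-type competitions from the same cross, which should be neutral)
#' from the mutant's, propagating the standard errors in quadrature:
#' \eqn{s_{norm} = s_{mut} - s_{wt}},
#' \eqn{se_{norm} = \sqrt{se_{mut}^2 + se_{wt}^2}}.
#'
#' @param mutant,wt_control Unnormalized `selection_estimate`s.
#' @return A `selection_estimate` with `normalized = TRUE`.
#' @export
normalize_selection <- function(mutant, wt_control) {
  stopifnot(inherits(mutant, "selection_estimate"),
            inherits(wt_control, "selection_estimate"))
  if (mutant$normalized || wt_control$normalized) {
    stop("inputs must be unnormalized (double normalization is refused)")
  }
  s <- mutant$s - wt_control$s
  se <- sqrt(mutant$se^2 + wt_control$se^2)
  new_selection_estimate(
    s = s, se = se, ci95 = s + c(-1.96, 1.96) * se,
    n_replicates = mutant$n_replicates, normalized = TRUE,
    window = mutant$linear_window,
    method = paste0(mutant$method, "+wt-normalized")
  )
}

#' Relative fitness from a normalized selection coefficient
#'
#' Uses the convention \eqn{w = 1 + s} (per-generation selection coefficient
#' added to the wild-type fitness of 1); the confidence interval is mapped
#' through the same transform.  The convention is recorded in the result.
#'
#' @param est A normalized `selection_estimate`.
#' @return List with `w`, `ci95` and `convention`.
#' @export
relative_fitness <- function(est) {
  stopifnot(inherits(est, "selection_estimate"))
  if (!est$normalized) {
    stop("relative fitness is defined for wild-type-normalized estimates; ",
         "call normalize_selection() first")
  }
  list(w = 1 + est$s, ci95 = 1 + est$ci95, convention = "w = 1 + s")
}

#' ANCOVA test for a difference in competition slopes
#'
#' Compares, on the pooled log-ratio data of a mutant and a wild-type
#' competition, a model with independent slopes per strain against one with
#' a common slope (analysis of covariance).  A small p-value means the
#' mutant's selection coefficient differs significantly from the control's.
#'
#' @param mutant_series,wt_series Competition data frames (replicates
#'   allowed; points are pooled within each group).
#' @param pseudocount Added to counts before the log ratio.
#' @return List with the `F` statistic, `p` value, and numerator/denominator
#'   degrees of freedom.
#' @export
ancova_slope_test <- function(mutant_series, wt_series, pseudocount = 0) {
  assert_competition_series(mutant_series)
  assert_competition_series(wt_series)
  dat <- rbind(
    data.frame(g = mutant_series$generations,
               y = ln_ratio(mutant_series, pseudocount), grp = "mutant"),
    data.frame(g = wt_series$generations,
               y = ln_ratio(wt_series, pseudocount), grp = "wt")
  )
  if (nrow(dat) < 5L) stop("too few points for the independent-slopes model")
  full <- lm(y ~ g * grp, data = dat)
  reduced <- lm(y ~ g + grp, data = dat)
  # nested-model F computed from the residual sums of squares directly
  # (equivalent to anova(reduced, full), but robust when the models differ
  # only at rounding level)
  rss_full <- sum(residuals(full)^2)
  rss_red <- sum(residuals(reduced)^2)
  df2 <- full$df.residual                    # n - 4
  f_stat <- max(0, rss_red - rss_full) / (rss_full / df2)
  list(F = f_stat, p = stats::pf(f_stat, 1, df2, lower.tail = FALSE),
       df1 = 1L, df2 = df2)
}

#' Fit a multi-replicate competition experiment end to end
#'
#' Convenience wrapper: optionally restrict each replicate to its linear
#' phase, estimate a selection coefficient per replicate, then pool.
#'
#' @param series Competition data frame with one or more replicates.
#' @param window Apply [select_linear_phase()] per replicate first?
#' @param ... Passed to [select_linear_phase()] / [estimate_selection()].
#' @return A pooled `selection_estimate`.
#' @export
fit_competition <- function(series, window = FALSE, ...) {
  assert_competition_series(series)
  reps <- split(series, series$replicate)
  ests <- lapply(reps, function(r) {
    if (window) r <- select_linear_phase(r, ...)
    estimate_selection(r)
  })
  pool_replicates(unname(ests))
}

#' @export
print.selection_estimate <- function(x, ...) {
  cat(sprintf(
    "Selection estimate: s = %.4f per generation (SE %.4f)\n", x$s, x$se))
  cat(sprintf("  95%% CI [%.4f, %.4f]   replicates: %d   normalized: %s\n",
              x$ci95[1], x$ci95[2], x$n_replicates,
              ifelse(x$normalized, "yes", "no")))
  if (!all(is.na(x$linear_window))) {
    cat(sprintf("  fitted window: generations %.2f to %.2f (%s)\n",
                x$linear_window[1], x$linear_window[2], x$method))
  }
  invisible(x)
}
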