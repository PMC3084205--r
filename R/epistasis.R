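# Epistasis between pairs of mutations, quantified on the selection-
# coefficient scale: eps = s_xy - (s_x + s_y), with the standard error
# propagated in quadrature and significance judged against a 95% null
# interval centered at zero.

new_epistasis_result <- function(epsilon, se, significant, class_label,
                                 inputs, interpretation = NULL) {
  structure(
    list(
      epsilon = epsilon,
      se_epsilon = se,
      ci95 = epsilon + c(-1.96, 1.96) * se,
      null_interval = c(-1.96, 1.96) * se,
      significant = significant,
      class_label = class_label,
      inputs = inputs,
      interpretation = interpretation,
      convention = paste(
        "eps = s_xy - (s_x + s_y); se = sqrt(sum of squared SEs);",
        "significant iff |eps| > 1.96 * se (null interval centered at 0)")
    ),
    class = "epistasis_result"
  )
}

#' Quantify epistasis between two mutations
#'
#' \eqn{\epsilon = s_{xy} - (s_x + s_y)}, where the \eqn{s} are wild-type-
#' normalized per-generation selection coefficients of the two single
#' mutants and the double mutant.  The standard error is propagated as
#' \eqn{\sqrt{se_x^2 + se_y^2 + se_{xy}^2}} and the interaction is called
#' significant when \eqn{|\epsilon| > 1.96\, se_\epsilon}, i.e. when it
#' falls outside the 95% null interval centered at zero.
#'
#' @param sx,sy Normalized `selection_estimate`s of the single mutants.
#' @param sxy Normalized `selection_estimate` of the double mutant.
#' @return An `epistasis_result` (class label unset; see
#'   [classify_epistasis()]).
#' @examples
#' est <- function(s) selection_estimate(s, 0.01, normalized = TRUE)
#' epistasis_epsilon(est(0.2), est(0.3), est(0.4))
#' @export
epistasis_epsilon <- function(sx, sy, sxy) {
  ests <- list(sx = sx, sy = sy, sxy = sxy)
  ok <- vapply(ests, inherits, TRUE, "selection_estimate")
  if (!all(ok)) stop("all three inputs must be selection_estimate objects")
  if (!all(vapply(ests, `[[`, TRUE, "normalized"))) {
    stop("all selection estimates must be wild-type normalized")
  }
  eps <- sxy$s - (sx$s + sy$s)
  se <- sqrt(sx$se^2 + sy$se^2 + sxy$se^2)
  new_epistasis_result(
    epsilon = eps, se = se,
    significant = abs(eps) > 1.96 * se,
    class_label = NA_character_,
    inputs = ests
  )
}

#' Classify a two-locus epistatic interaction
#'
#' Works on the four relative fitnesses of wild type, single mutants and
#' double mutant, gated by the significance of \eqn{\epsilon}: a
#' non-significant interaction is called `additive` regardless of the point
#' estimates, preventing noise-driven sign calls.  A significant
#' interaction is
#'
#' * `reciprocal_sign` when both single mutants beat the wild type but the
#'   double mutant is less fit than the wild type and both singles (each
#'   mutation beneficial alone, deleterious on the other's background —
#'   the two-peaked-landscape pattern);
#' * `sign` when exactly one mutation flips from beneficial on the
#'   wild-type background to deleterious on the other single's background
#'   (the flipping locus is reported in the `"flipped_locus"` attribute);
#' * otherwise `negative` or `positive` magnitude epistasis by the sign of
#'   \eqn{\epsilon}.
#'
#' The supplied `wxy` must agree with the value implied by \eqn{\epsilon}
#' and the single-mutant fitnesses (consistency check at tolerance `tol`).
#'
#' @param w0,wx,wy,wxy Relative fitnesses (> 0) of genotypes 00, 10, 01, 11.
#' @param eps An `epistasis_result` for the same pair.
#' @param tol Relative tolerance of the consistency check (default 1e-9,
#'   appropriate for exact inputs; loosen when estimates carry error).
#' @return The class label (character), with attribute `flipped_locus` for
#'   sign epistasis.
#' @examples
#' est <- function(s) selection_estimate(s, 0.005, normalized = TRUE)
#' e <- epistasis_epsilon(est(0.2), est(0.3), est(-0.2))
#' classify_epistasis(1, 1.2, 1.3, 0.8, e)
#' @export
classify_epistasis <- function(w0, wx, wy, wxy, eps, tol = 1e-9) {
  stopifnot(inherits(eps, "epistasis_result"),
            w0 > 0, wx > 0, wy > 0, wxy > 0)
  implied_sxy <- (wx - w0) + (wy - w0) + eps$epsilon
  if (abs((wxy - w0) - implied_sxy) > tol * max(1, abs(wxy - w0))) {
    stop("wxy is inconsistent with epsilon and the single-mutant fitnesses ",
         sprintf("(wxy - w0 = %.6g, implied = %.6g)", wxy - w0, implied_sxy))
  }
  if (!eps$significant) return("additive")
  flips <- locus_flips(w0, wx, wy, wxy)
  if (wx > w0 && wy > w0 && wxy < w0 && wxy < min(wx, wy)) {
    return("reciprocal_sign")
  }
  if (sum(flips) == 1L) {
    return(structure("sign", flipped_locus = names(flips)[flips]))
  }
  if (eps$epsilon < 0) "negative" else "positive"
}

#' Classify a genotype-fitness table directly
#'
#' Convenience route from a 4-genotype table (as produced by
#' [gen_landscape_scenario()]) to an epistasis class: selection coefficients
#' are taken as \eqn{s = w - w_0} with a common standard error `se`.
#'
#' @param table Data frame with columns `genotype` (00/10/01/11) and
#'   `fitness`.
#' @param se Standard error attached to each selection coefficient.
#' @return The class label.
#' @export
classify_scenario_table <- function(table, se = 0.005) {
  stopifnot(all(c("genotype", "fitness") %in% names(table)))
  w <- setNames(table$fitness, table$genotype)
  needed <- c("00", "10", "01", "11")
  if (!all(needed %in% names(w))) {
    stop("table must contain genotypes 00, 10, 01, 11")
  }
  est <- function(s) selection_estimate(s, se, normalized = TRUE)
  eps <- epistasis_epsilon(est(w[["10"]] - w[["00"]]),
                           est(w[["01"]] - w[["00"]]),
                           est(w[["11"]] - w[["00"]]))
  classify_epistasis(w[["00"]], w[["10"]], w[["01"]], w[["11"]], eps)
}

#' Do the singly adaptive mutations recapitulate a clone's fitness?
#'
#' Sums the selection coefficients of the individually adaptive mutations
#' derived from a clone and compares the sum to the clone's own selection
#' coefficient within the epistasis framework:
#' \eqn{\epsilon = s_{clone} - \sum_i s_i}, standard error propagated over
#' all terms.  A significantly positive \eqn{\epsilon} indicates adaptive
#' effect unexplained by the identified mutations (additional adaptive
#' mutations); a significantly negative one indicates sub-additivity
#' (negative epistasis among the clone's mutations).
#'
#' @param clone_s Normalized `selection_estimate` of the whole clone.
#' @param singles List of normalized `selection_estimate`s of the clone's
#'   individually adaptive mutations.
#' @return An `epistasis_result` with an `interpretation` field.
#' @export
additivity_test <- function(clone_s, singles) {
  if (inherits(singles, "selection_estimate")) singles <- list(singles)
  if (length(singles) < 1L) {
    stop("at least one single-mutation estimate is required")
  }
  stopifnot(inherits(clone_s, "selection_estimate"),
            all(vapply(singles, inherits, TRUE, "selection_estimate")))
  if (!clone_s$normalized ||
      !all(vapply(singles, `[[`, TRUE, "normalized"))) {
    stop("all selection estimates must be wild-type normalized")
  }
  eps <- clone_s$s - sum(vapply(singles, `[[`, 1.0, "s"))
  se <- sqrt(clone_s$se^2 + sum(vapply(singles, `[[`, 1.0, "se")^2))
  significant <- abs(eps) > 1.96 * se
  label <- if (!significant) "additive" else if (eps < 0) "negative" else "positive"
  interpretation <- if (!significant) {
    "singles recapitulate the clone's fitness (no significant deviation)"
  } else if (eps > 0) {
    "positive: unexplained adaptive effect (possible additional adaptive mutations)"
  } else {
    "negative: sub-additive; singles over-explain the clone's fitness"
  }
  new_epistasis_result(eps, se, significant, label,
                       inputs = c(list(clone = clone_s), singles),
                       interpretation = interpretation)
}

#' @export
print.epistasis_result <- function(x, ...) {
  cat(sprintf("Epistasis: eps = %.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
              x$epsilon, x$se_epsilon, x$ci95[1], x$ci95[2]))
  cat(sprintf("  significant: %s%s\n",
              ifelse(x$significant, "yes", "no"),
              ifelse(is.na(x$class_label), "",
                     sprintf("   class: %s", x$class_label))))
  if (!is.null(x$interpretation)) cat(" ", x$interpretation, "\n")
  invisible(x)
}
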