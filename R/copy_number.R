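# Copy-number estimation of a tandem amplification, two ways: read-depth
# ratio of a clone over its ancestor (mean-normalized, median-smoothed) and
# qPCR delta-delta-Ct against a non-varying reference locus.

#' Mean-normalized clone/ancestor depth ratio
#'
#' Per base, \eqn{r_i = (c_i \cdot \bar a / \bar c) / a_i}: the clone's
#' coverage is normalized to the ancestor's average coverage and divided by
#' the ancestor's per-base coverage, so a region present in \eqn{k} copies
#' has expected ratio near \eqn{k} (exactly \eqn{k} when the amplified
#' segment is a negligible fraction of the profile).  Positions with zero
#' ancestral depth yield `NA`, never infinities.  The ratio is invariant to
#' globally rescaling either profile.
#'
#' @param clone,ancestor Depth profiles: data frames with columns `chrom`,
#'   `pos`, `depth` over identical positions.
#' @return Data frame with columns `chrom`, `pos`, `ratio`.
#' @export
coverage_ratio <- function(clone, ancestor) {
  stopifnot(all(c("chrom", "pos", "depth") %in% names(clone)),
            all(c("chrom", "pos", "depth") %in% names(ancestor)))
  if (!identical(as.character(clone$chrom), as.character(ancestor$chrom)) ||
      !identical(as.numeric(clone$pos), as.numeric(ancestor$pos))) {
    stop("clone and ancestor profiles must cover identical positions")
  }
  scale <- mean(ancestor$depth) / mean(clone$depth)
  ratio <- ifelse(ancestor$depth > 0,
                  clone$depth * scale / ancestor$depth, NA_real_)
  data.frame(chrom = clone$chrom, pos = clone$pos, ratio = ratio,
             stringsAsFactors = FALSE)
}

#' Centered running median with shrinking edge windows
#'
#' Smooths a numeric vector with a centered running median of odd width
#' `window`; near the edges the window shrinks symmetrically-truncated to
#' what fits, so the output has the input's length.  The interior uses
#' [stats::runmed()].
#'
#' @param values Numeric vector (NAs tolerated; they are ignored within
#'   each window).
#' @param window Odd window width (>= 1; 1 is the identity).
#' @return Smoothed vector of the same length.
#' @export
running_median <- function(values, window) {
  stopifnot(is.numeric(window), length(window) == 1L, window >= 1)
  if (window %% 2 == 0) stop("window must be odd")
  n <- length(values)
  if (n == 0L) return(values)
  if (window == 1) return(values)
  if (window > n) stop("window exceeds the profile length")
  h <- (window - 1) / 2
  out <- if (anyNA(values)) {
    # runmed propagates NA; fall back to direct medians throughout
    vapply(seq_len(n), function(i) {
      median(values[max(1, i - h):min(n, i + h)], na.rm = TRUE)
    }, numeric(1L))
  } else {
    sm <- runmed(values, window, endrule = "keep")
    edge <- c(seq_len(min(h, n)), seq(max(1, n - h + 1), n))
    sm[edge] <- vapply(edge, function(i) {
      median(values[max(1, i - h):min(n, i + h)])
    }, numeric(1L))
    as.numeric(sm)          # drop runmed's bookkeeping attributes
  }
  out
}

#' Copy-number estimate for a genomic segment
#'
#' Point estimate: the median of the (smoothed) depth ratio inside the
#' region; the median ratio outside the region is reported as the flanking
#' baseline for contrast.
#'
#' @param ratio_profile Data frame with columns `pos` and `ratio` (as from
#'   [coverage_ratio()], optionally smoothed with [running_median()]).
#' @param region Length-2 numeric: 1-based closed interval `c(start, end)`.
#' @return List with `estimate`, `baseline`, `region`, `n_inside`.
#' @export
segment_copy_number <- function(ratio_profile, region) {
  stopifnot(all(c("pos", "ratio") %in% names(ratio_profile)),
            length(region) == 2L, region[1] <= region[2])
  inside <- ratio_profile$pos >= region[1] & ratio_profile$pos <= region[2]
  if (!any(inside)) stop("region contains no positions of the profile")
  list(
    estimate = median(ratio_profile$ratio[inside], na.rm = TRUE),
    baseline = if (any(!inside)) {
      median(ratio_profile$ratio[!inside], na.rm = TRUE)
    } else {
      NA_real_
    },
    region = region,
    n_inside = sum(inside)
  )
}

#' qPCR measurement of a target locus against a reference locus
#'
#' Ct (cycle-threshold) values per replicate for the target and reference
#' locus in the sample of interest, plus the same pair for a calibrator
#' sample of known copy number (e.g. an unamplified ancestor, normalized to
#' a non-varying locus to control for input DNA amount).
#'
#' @param ct_target,ct_reference Sample Ct values, one per replicate.
#' @param calibrator_ct_target,calibrator_ct_reference Calibrator Ct
#'   values.
#' @param calibrator_copies Known copy count of the calibrator (default 1).
#' @param target_locus,reference_locus Labels.
#' @return Object of class `qpcr_measurement`.
#' @export
qpcr_measurement <- function(ct_target, ct_reference,
                             calibrator_ct_target, calibrator_ct_reference,
                             calibrator_copies = 1,
                             target_locus = "target",
                             reference_locus = "reference") {
  stopifnot(length(ct_target) >= 1L,
            length(ct_target) == length(ct_reference),
            length(calibrator_ct_target) == length(calibrator_ct_reference),
            all(is.finite(c(ct_target, ct_reference,
                            calibrator_ct_target, calibrator_ct_reference))),
            calibrator_copies > 0)
  structure(
    list(ct_target = ct_target, ct_reference = ct_reference,
         calibrator_ct_target = calibrator_ct_target,
         calibrator_ct_reference = calibrator_ct_reference,
         calibrator_copies = calibrator_copies,
         target_locus = target_locus, reference_locus = reference_locus),
    class = "qpcr_measurement"
  )
}

#' Copy number from qPCR by the delta-delta-Ct method
#'
#' Per replicate, \eqn{\Delta C_t = C_t^{target} - C_t^{ref}};
#' \eqn{\Delta\Delta C_t = \Delta C_t^{sample} - \overline{\Delta C_t}^{cal}};
#' copy number \eqn{= k_{cal} \cdot E^{-\Delta\Delta C_t}} with
#' amplification efficiency \eqn{E} (default 2, perfect doubling per
#' cycle).  The point estimate is the replicate mean and the 95% confidence
#' interval is `mean ± 1.96 SEM`; a single replicate yields a flagged
#' estimate with undefined CI.
#'
#' @param m A [qpcr_measurement()].
#' @param efficiency Per-cycle amplification factor.
#' @return List with `estimate`, `se`, `ci95`, `replicates` (per-replicate
#'   copy numbers), `n`, `single_replicate`.
#' @examples
#' m <- qpcr_measurement(c(20.1, 20.0, 19.9), c(23.2, 23.1, 23.0),
#'                       23.0, 23.0)
#' qpcr_copy_number(m)
#' @export
qpcr_copy_number <- function(m, efficiency = 2) {
  stopifnot(inherits(m, "qpcr_measurement"), efficiency > 1)
  dct <- m$ct_target - m$ct_reference
  dct_cal <- mean(m$calibrator_ct_target - m$calibrator_ct_reference)
  ddct <- dct - dct_cal
  copies <- m$calibrator_copies * efficiency^(-ddct)
  n <- length(copies)
  est <- mean(copies)
  if (n == 1L) {
    return(list(estimate = est, se = NA_real_,
                ci95 = c(NA_real_, NA_real_), replicates = copies,
                n = 1L, single_replicate = TRUE))
  }
  sem <- sd(copies) / sqrt(n)
  list(estimate = est, se = sem, ci95 = est + c(-1.96, 1.96) * sem,
       replicates = copies, n = n, single_replicate = FALSE)
}

#' Minimum number of unequal mitotic recombination events
#'
#' Under the model in which a tandem array grows from a single promoter
#' copy and one unequal mitotic recombination event can at most double the
#' promoter count, the minimum number of events reaching `promoter_copies`
#' is \eqn{\lceil \log_2(\text{copies}) \rceil}.  When an ORF count is
#' supplied, the array-structure model (ORFs = promoters + 1 for a tandem
#' array flanked by one extra coding copy) is checked and a deviation
#' produces a warning.
#'
#' @param promoter_copies Observed promoter copy count (>= 1).
#' @param orf_copies Optional observed ORF copy count.
#' @return Minimum event count (integer).
#' @examples
#' min_recombination_events(9)  # 4
#' min_recombination_events(7)  # 3
#' @export
min_recombination_events <- function(promoter_copies, orf_copies = NULL) {
  stopifnot(length(promoter_copies) == 1L, promoter_copies >= 1,
            promoter_copies == as.integer(promoter_copies))
  if (!is.null(orf_copies) && orf_copies != promoter_copies + 1) {
    warning(sprintf(
      "array model violated: expected ORFs = promoters + 1 = %d, got %d (deviation %+d)",
      promoter_copies + 1, orf_copies, orf_copies - (promoter_copies + 1)))
  }
  e <- 0L
  reach <- 1
  while (reach < promoter_copies) {
    reach <- reach * 2
    e <- e + 1L
  }
  e
}
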