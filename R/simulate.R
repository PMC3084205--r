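#' Simulation configuration for synthetic competition experiments
#'
#' Bundles the experimental-design parameters of a pairwise competitive
#' chemostat: how often the culture is sampled, at what dilution rate it
#' runs, for how many generations, how many biological replicates are
#' performed and how many flow-cytometry events are counted per sample.
#' Generations accrue from wall time as \eqn{g = D t / \ln 2} (chemostat
#' doubling convention).
#'
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param n_replicates Number of biological replicates (default 3,
#'   "at least biological triplicate").
#' @param events_per_sample Flow-cytometry events counted per time point.
#' @param sampling_interval_h Hours between samples (default 6).
#' @param dilution_rate_per_h Chemostat dilution rate in 1/h (default 0.2).
#' @param total_generations Length of the experiment in generations
#'   (default 25).
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$total_generations
#' @export
sim_config <- function(seed,
                       n_replicates = 3,
                       events_per_sample = 30000,
                       sampling_interval_h = 6,
                       dilution_rate_per_h = 0.2,
                       total_generations = 25) {
  stopifnot(
    is.numeric(seed), length(seed) == 1L, is.finite(seed),
    n_replicates >= 1, events_per_sample > 0,
    sampling_interval_h > 0, dilution_rate_per_h > 0,
    total_generations > 0
  )
  structure(
    list(
      seed = seed,
      n_replicates = as.integer(n_replicates),
      events_per_sample = as.integer(events_per_sample),
      sampling_interval_h = sampling_interval_h,
      dilution_rate_per_h = dilution_rate_per_h,
      total_generations = total_generations
    ),
    class = "sim_config"
  )
}

#' Convert chemostat wall time to generations
#'
#' \eqn{g = D t / \ln 2}: at dilution rate \eqn{D} the culture doubles every
#' \eqn{\ln 2 / D} hours.
#'
#' @param hours Elapsed time in hours.
#' @param dilution_rate_per_h Dilution rate in 1/h.
#' @return Generations elapsed.
#' @export
hours_to_generations <- function(hours, dilution_rate_per_h) {
  dilution_rate_per_h * hours / log(2)
}

#' Simulate a pairwise competition time series
#'
#' Generates counts of a mutant and a reference strain sampled from a
#' competitive chemostat.  The expected log ratio
#' \eqn{\ln(N_{mut}/N_{ref})} is linear in generations with slope `s_true`
#' (the per-generation selection coefficient); observed counts are drawn
#' binomially from `events_per_sample` cytometry events.  Replicates are
#' independent given the seed.
#'
#' If a replicate's mutant count reaches 0 or `events_per_sample` exactly
#' (proportion 0 or 1, log ratio undefined), the replicate is truncated just
#' before that sample and flagged in the `"truncated"` attribute.
#'
#' @param s_true True per-generation selection coefficient.
#' @param cfg A [sim_config()].
#' @param init_prop Initial mutant proportion, in (0, 1); default 0.5
#'   (a 50:50 competition start).
#' @param noise If `FALSE`, counts are the exact binomial expectations
#'   (non-integer), so the log ratio reproduces the closed form
#'   \eqn{\mathrm{logit}(p_0) + s g} exactly.
#' @return A data frame with columns `replicate`, `hours`, `generations`,
#'   `count_mutant`, `count_reference`, and attributes `s_true`,
#'   `init_prop`, `truncated` (named logical per replicate).
#' @examples
#' cfg <- sim_config(seed = 42)
#' head(gen_competition_series(0.1, cfg))
#' @export
gen_competition_series <- function(s_true, cfg, init_prop = 0.5,
                                   noise = TRUE) {
  stopifnot(inherits(cfg, "sim_config"),
            init_prop > 0, init_prop < 1)
  hours <- seq(0, by = cfg$sampling_interval_h,
               length.out = ceiling(cfg$total_generations /
                 hours_to_generations(cfg$sampling_interval_h,
                                      cfg$dilution_rate_per_h)) + 1L)
  gens <- hours_to_generations(hours, cfg$dilution_rate_per_h)
  keep <- gens <= cfg$total_generations + 1e-9
  hours <- hours[keep]
  gens <- gens[keep]
  lnr <- qlogis(init_prop) + s_true * gens
  p <- plogis(lnr)
  n_ev <- cfg$events_per_sample

  truncated <- logical(cfg$n_replicates)
  names(truncated) <- paste0("r", seq_len(cfg$n_replicates))
  out <- vector("list", cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    cm <- if (noise) {
      with_substream(cfg$seed, paste0("competition_r", r),
                     rbinom(length(p), n_ev, p))
    } else {
      n_ev * p
    }
    cr <- n_ev - cm
    bad <- which(cm == 0 | cr == 0)
    last <- if (length(bad)) bad[1L] - 1L else length(cm)
    if (last < length(cm)) {
      truncated[r] <- TRUE
      warning(sprintf(
        "replicate %d: proportion reached 0 or 1 at sample %d; series truncated",
        r, bad[1L]))
    }
    idx <- seq_len(last)
    out[[r]] <- data.frame(
      replicate = names(truncated)[r],
      hours = hours[idx],
      generations = gens[idx],
      count_mutant = cm[idx],
      count_reference = cr[idx],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "s_true") <- s_true
  attr(res, "init_prop") <- init_prop
  attr(res, "truncated") <- truncated
  res
}

scenario_names <- c("additive", "negative", "positive", "sign",
                    "reciprocal_sign")

scenario_defaults <- list(
  additive        = c(w0 = 1, wx = 1.10, wy = 1.10, wxy = 1.20),
  negative        = c(w0 = 1, wx = 1.20, wy = 1.30, wxy = 1.35),
  positive        = c(w0 = 1, wx = 1.10, wy = 1.10, wxy = 1.35),
  sign            = c(w0 = 1, wx = 1.25, wy = 1.10, wxy = 1.18),
  reciprocal_sign = c(w0 = 1, wx = 1.20, wy = 1.30, wxy = 0.80)
)

# Which single mutations flip from beneficial on the wild-type background to
# deleterious on the other single's background (the defining question for
# sign and reciprocal sign epistasis).
locus_flips <- function(w0, wx, wy, wxy) {
  c(x = (wx > w0) && (wxy < wy),
    y = (wy > w0) && (wxy < wx))
}

validate_scenario <- function(name, w0, wx, wy, wxy) {
  add <- w0 + (wx - w0) + (wy - w0)   # additive expectation for wxy
  fail <- function(ineq) {
    stop(sprintf("scenario '%s' inconsistent with fitness values: requires %s",
                 name, ineq), call. = FALSE)
  }
  flips <- locus_flips(w0, wx, wy, wxy)
  switch(name,
    additive = {
      if (abs(wxy - add) > 1e-9) fail("wxy == w0 + (wx - w0) + (wy - w0)")
    },
    negative = {
      if (!(wxy < add)) fail("wxy < w0 + (wx - w0) + (wy - w0)")
      if (!(wxy > max(wx, wy))) fail("wxy > max(wx, wy)")
    },
    positive = {
      if (!(wxy > add)) fail("wxy > w0 + (wx - w0) + (wy - w0)")
    },
    sign = {
      if (sum(flips) != 1L) {
        fail("exactly one of [wx > w0 & wxy < wy], [wy > w0 & wxy < wx]")
      }
    },
    reciprocal_sign = {
      if (!(wx > w0)) fail("wx > w0")
      if (!(wy > w0)) fail("wy > w0")
      if (!(wxy < w0)) fail("wxy < w0")
      if (!(wxy < min(wx, wy))) fail("wxy < min(wx, wy)")
    }
  )
  invisible(TRUE)
}

#' Two-locus fitness scenario
#'
#' Defines the relative fitnesses of the four genotypes (wild type, the two
#' single mutants, the double mutant) for a named epistasis pattern, and
#' validates at construction that the fitness ordering is consistent with
#' the name.  Defaults mirror the patterns seen in glucose-limited yeast
#' evolution: the reciprocal-sign scenario has both single mutants fitter
#' than wild type and a double mutant less fit than wild type.
#'
#' @param name One of `"additive"`, `"negative"`, `"positive"`, `"sign"`,
#'   `"reciprocal_sign"`.
#' @param w0,wx,wy,wxy Relative fitnesses of genotypes 00, 10, 01, 11;
#'   defaults depend on `name`.
#' @return An object of class `landscape_scenario`.
#' @examples
#' landscape_scenario("reciprocal_sign")
#' @export
landscape_scenario <- function(name, w0 = NULL, wx = NULL, wy = NULL,
                               wxy = NULL) {
  name <- match.arg(name, scenario_names)
  d <- scenario_defaults[[name]]
  w0 <- if (is.null(w0)) d[["w0"]] else w0
  wx <- if (is.null(wx)) d[["wx"]] else wx
  wy <- if (is.null(wy)) d[["wy"]] else wy
  wxy <- if (is.null(wxy)) d[["wxy"]] else wxy
  stopifnot(w0 > 0, wx > 0, wy > 0, wxy > 0)
  validate_scenario(name, w0, wx, wy, wxy)
  structure(list(name = name, w0 = w0, wx = wx, wy = wy, wxy = wxy),
            class = "landscape_scenario")
}

#' Generate a genotype-fitness table from a two-locus scenario
#'
#' @param scenario A [landscape_scenario()] or a scenario name.
#' @return A data frame with columns `genotype` (`"00"`, `"10"`, `"01"`,
#'   `"11"`) and `fitness`.
#' @examples
#' gen_landscape_scenario("reciprocal_sign")
#' @export
gen_landscape_scenario <- function(scenario) {
  if (is.character(scenario)) scenario <- landscape_scenario(scenario)
  stopifnot(inherits(scenario, "landscape_scenario"))
  data.frame(
    genotype = c("00", "10", "01", "11"),
    fitness = c(scenario$w0, scenario$wx, scenario$wy, scenario$wxy),
    stringsAsFactors = FALSE
  )
}

#' @export
print.landscape_scenario <- function(x, ...) {
  cat(sprintf("Two-locus fitness scenario '%s'\n", x$name))
  cat(sprintf("  w00 = %.3f  w10 = %.3f  w01 = %.3f  w11 = %.3f\n",
              x$w0, x$wx, x$wy, x$wxy))
  invisible(x)
}

empty_variant_table <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             coverage = integer(), A = integer(), C = integer(),
             G = integer(), T = integer(), N = integer(),
             indels = character(), stringsAsFactors = FALSE)
}

# one clean (consensus == reference) site: coverage draws, sequencing errors
# scattered uniformly over the three non-reference bases
clean_site_counts <- function(ref, coverage, error_rate) {
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  if (coverage > 0) {
    err <- rbinom(1L, coverage, error_rate)
    counts[ref] <- coverage - err
    if (err > 0) {
      others <- setdiff(names(counts), ref)
      add <- rmultinom(1L, err, rep(1 / 3, 3))[, 1L]
      counts[others] <- counts[others] + add
    }
  }
  counts
}

#' Generate paired ancestor/evolved allele-count tables
#'
#' Builds per-site allele-count tables for an ancestor and an evolved clone
#' with planted true SNPs and indels plus background sites.  True variants
#' are constructed so that, at `error_rate = 0`, they pass every rule of
#' [filter_snps()] / [filter_indels()], while background sites share their
#' consensus between the two samples and therefore fail; ground-truth labels
#' are returned alongside.
#'
#' @param n_sites Number of candidate sites.
#' @param true_snps Number of true SNPs, or a vector of 1-based positions.
#' @param true_indels Number of true indels, or a vector of positions.
#' @param mean_coverage Mean per-site read depth (Poisson).
#' @param error_rate Per-read probability of a miscalled base.
#' @param seed Integer seed.
#' @param chrom Chromosome label for all sites.
#' @return A list with elements `ancestor`, `evolved` (variant tables with
#'   columns `chrom`, `pos`, `ref`, `coverage`, `A`, `C`, `G`, `T`, `N`,
#'   `indels`) and `truth` (positions, types and planted alleles).
#' @examples
#' tabs <- gen_variant_tables(50, true_snps = 3, true_indels = 1, seed = 7)
#' tabs$truth
#' @export
gen_variant_tables <- function(n_sites, true_snps = 0, true_indels = 0,
                               mean_coverage = 30, error_rate = 0,
                               seed = 1, chrom = "chr1") {
  stopifnot(n_sites >= 0, mean_coverage > 0,
            error_rate >= 0, error_rate < 1)
  if (n_sites == 0) {
    return(list(ancestor = empty_variant_table(),
                evolved = empty_variant_table(),
                truth = data.frame(pos = integer(), type = character(),
                                   allele = character(),
                                   stringsAsFactors = FALSE)))
  }
  with_substream(seed, "variant_tables", {
    # scalar = how many variants to plant (positions sampled); vector =
    # explicit 1-based positions
    pick <- function(x, avoid) {
      if (length(x) == 1L) {
        sample(setdiff(seq_len(n_sites), avoid), x)
      } else {
        as.integer(x)
      }
    }
    snp_pos <- pick(true_snps, integer())
    indel_pos <- pick(true_indels, snp_pos)
    all_true <- c(snp_pos, indel_pos)
    if (anyDuplicated(all_true)) {
      stop("duplicated true variant positions")
    }
    if (length(all_true) && (min(all_true) < 1 || max(all_true) > n_sites)) {
      stop("true variant positions must lie in [1, n_sites]")
    }

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_sites, replace = TRUE)
    anc_cov <- rpois(n_sites, mean_coverage)
    evo_cov <- rpois(n_sites, mean_coverage)

    make_table <- function(cov) {
      counts <- t(vapply(seq_len(n_sites), function(i) {
        clean_site_counts(ref[i], cov[i], error_rate)
      }, integer(4)))
      data.frame(chrom = chrom, pos = seq_len(n_sites), ref = ref,
                 coverage = cov,
                 A = counts[, 1L], C = counts[, 2L],
                 G = counts[, 3L], T = counts[, 4L],
                 N = 0L, indels = "", stringsAsFactors = FALSE)
    }
    anc <- make_table(anc_cov)
    evo <- make_table(evo_cov)

    snp_allele <- character(length(snp_pos))
    for (k in seq_along(snp_pos)) {
      i <- snp_pos[k]
      alt <- sample(setdiff(bases, ref[i]), 1L)
      snp_allele[k] <- alt
      cov <- max(evo_cov[i], 5L)          # enough reads to call a variant
      evo$coverage[i] <- cov
      n_alt <- as.integer(ceiling(0.9 * cov))
      counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
      counts[alt] <- n_alt
      counts[ref[i]] <- cov - n_alt
      evo[i, bases] <- as.list(counts)
    }

    indel_allele <- character(length(indel_pos))
    for (k in seq_along(indel_pos)) {
      i <- indel_pos[k]
      allele <- sample(c("+A", "+C", "+G", "+T", "-1", "-2"), 1L)
      indel_allele[k] <- allele
      cov <- max(evo_cov[i], 12L)         # indel rule needs coverage > 10
      evo$coverage[i] <- cov
      n_ind <- as.integer(ceiling(0.75 * cov))
      counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
      counts[ref[i]] <- cov - n_ind       # reads matching the reference
      evo[i, bases] <- as.list(counts)
      evo$indels[i] <- paste0(allele, ":", n_ind)
    }

    truth <- data.frame(
      pos = c(snp_pos, indel_pos),
      type = c(rep("snp", length(snp_pos)), rep("indel", length(indel_pos))),
      allele = c(snp_allele, indel_allele),
      stringsAsFactors = FALSE
    )
    truth <- truth[order(truth$pos), , drop = FALSE]
    rownames(truth) <- NULL
    list(ancestor = anc, evolved = evo, truth = truth)
  })
}

#' Generate ancestor and clone read-depth profiles with an amplified segment
#'
#' Per-base depth is Poisson around `mean_depth` in the ancestor everywhere,
#' and around `mean_depth * amp_copies` inside the amplified segment of the
#' clone (`[amp_start, amp_end]`, 1-based closed).
#'
#' @param length Profile length in bases.
#' @param mean_depth Mean haploid read depth.
#' @param amp_start,amp_end Amplified segment bounds (1-based, closed).
#' @param amp_copies Copy number of the segment in the clone (>= 1).
#' @param seed Integer seed.
#' @param noise If `FALSE`, depths are the exact expectations.
#' @param chrom Chromosome label.
#' @return A list with `ancestor` and `clone` depth profiles (data frames
#'   with columns `chrom`, `pos`, `depth`).
#' @examples
#' prof <- gen_coverage_profiles(1000, 30, 401, 600, 10, seed = 1)
#' mean(prof$clone$depth[401:600]) / mean(prof$ancestor$depth[401:600])
#' @export
gen_coverage_profiles <- function(length, mean_depth = 30, amp_start,
                                  amp_end, amp_copies, seed = 1,
                                  noise = TRUE, chrom = "chr4") {
  stopifnot(length >= 1, mean_depth > 0,
            amp_start >= 1, amp_start <= amp_end, amp_end <= length)
  if (amp_copies < 1) stop("amp_copies must be >= 1")
  lam_anc <- rep(mean_depth, length)
  lam_clone <- lam_anc
  lam_clone[amp_start:amp_end] <- mean_depth * amp_copies
  profile <- function(lam, name) {
    depth <- if (noise) {
      with_substream(seed, paste0("coverage_", name), rpois(length, lam))
    } else {
      lam
    }
    data.frame(chrom = chrom, pos = seq_len(length), depth = depth,
               stringsAsFactors = FALSE)
  }
  list(ancestor = profile(lam_anc, "ancestor"),
       clone = profile(lam_clone, "clone"))
}

#' Generate a clone genotype table at two loci
#'
#' Simulates genotyping of `n_clones` isolates at two mutant loci with
#' marginal mutant frequencies `freq_a`, `freq_b`.  With
#' `allow_double = FALSE` no clone can carry both mutations (loci are
#' mutually exclusive, as for selectively incompatible mutations); with
#' `allow_double = TRUE` the two loci are independent.
#'
#' @param n_clones Number of clones genotyped.
#' @param freq_a,freq_b Marginal mutant-allele frequencies in \\[0, 1\\].
#' @param allow_double Can a clone carry both mutant alleles?
#' @param seed Integer seed.
#' @param loci Column names for the two loci.
#' @return Data frame with columns `clone` and one 0/1 column per locus.
#' @examples
#' g <- gen_clone_genotypes(22, 0.4, 0.5, allow_double = FALSE, seed = 3)
#' colSums(g[-1])
#' @export
gen_clone_genotypes <- function(n_clones, freq_a, freq_b,
                                allow_double = TRUE, seed = 1,
                                loci = c("locus_a", "locus_b")) {
  stopifnot(n_clones >= 0, freq_a >= 0, freq_a <= 1,
            freq_b >= 0, freq_b <= 1, length(loci) == 2L)
  if (!allow_double && freq_a + freq_b > 1) {
    stop("allow_double = FALSE is infeasible when freq_a + freq_b > 1")
  }
  gt <- with_substream(seed, "clone_genotypes", {
    if (allow_double) {
      cbind(rbinom(n_clones, 1L, freq_a), rbinom(n_clones, 1L, freq_b))
    } else {
      cat3 <- sample(c("a", "b", "none"), n_clones, replace = TRUE,
                     prob = c(freq_a, freq_b, 1 - freq_a - freq_b))
      cbind(as.integer(cat3 == "a"), as.integer(cat3 == "b"))
    }
  })
  out <- data.frame(clone = paste0("c", seq_len(n_clones)),
                    a = if (n_clones) gt[, 1L] else integer(),
                    b = if (n_clones) gt[, 2L] else integer(),
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- loci
  out
}
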