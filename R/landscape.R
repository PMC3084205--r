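# Empirical fitness landscapes over binary loci: genotypes are strings of
# 0/1 (mutation absent/present per locus), edges connect genotypes at
# Hamming distance 1.

hamming_neighbors <- function(genotype) {
  chars <- strsplit(genotype, "")[[1L]]
  vapply(seq_along(chars), function(i) {
    flipped <- chars
    flipped[i] <- if (chars[i] == "0") "1" else "0"
    paste(flipped, collapse = "")
  }, character(1L))
}

#' Build a fitness landscape from a genotype-fitness table
#'
#' @param table Data frame with columns `genotype` (strings of 0/1, all of
#'   the same length, the all-zeros string being the wild type) and
#'   `fitness` (> 0).  Duplicate genotypes with identical fitness are
#'   collapsed; conflicting duplicates are an error.
#' @param loci Optional locus labels (defaults `L1`, `L2`, ...).
#' @return An object of class `fitness_landscape` with fields `loci`,
#'   `fitness` (named vector), `n_loci`, `complete` and `missing` (the
#'   absent genotypes, for partial landscapes).
#' @examples
#' ls <- build_landscape(gen_landscape_scenario("reciprocal_sign"))
#' ls
#' @export
build_landscape <- function(table, loci = NULL) {
  stopifnot(is.data.frame(table),
            all(c("genotype", "fitness") %in% names(table)))
  gt <- as.character(table$genotype)
  fit <- as.numeric(table$fitness)
  if (nrow(table) == 0L) stop("empty genotype-fitness table")
  if (length(unique(nchar(gt))) != 1L) {
    stop("all genotype strings must have the same length")
  }
  if (!all(grepl("^[01]+$", gt))) {
    stop("genotypes must be strings over {0, 1}")
  }
  if (anyDuplicated(gt)) {
    agg <- tapply(fit, gt, function(v) length(unique(v)))
    bad <- names(agg)[agg > 1L]
    if (length(bad)) {
      stop("duplicate genotype(s) with conflicting fitness: ",
           paste(bad, collapse = ", "))
    }
    keep <- !duplicated(gt)
    gt <- gt[keep]
    fit <- fit[keep]
  }
  if (any(fit <= 0)) stop("fitness values must be positive")
  n_loci <- nchar(gt[1L])
  wt <- strrep("0", n_loci)
  if (!(wt %in% gt)) {
    stop("the wild-type genotype (all zeros) must be present")
  }
  if (is.null(loci)) loci <- paste0("L", seq_len(n_loci))
  stopifnot(length(loci) == n_loci)
  all_gt <- apply(expand.grid(rep(list(c("0", "1")), n_loci))[
    , rev(seq_len(n_loci)), drop = FALSE], 1L, paste, collapse = "")
  missing <- setdiff(all_gt, gt)
  structure(
    list(loci = loci, fitness = setNames(fit, gt), n_loci = n_loci,
         complete = length(missing) == 0L, missing = missing),
    class = "fitness_landscape"
  )
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat(sprintf("Fitness landscape over %d loci (%s): %d of %d genotypes%s\n",
              x$n_loci, paste(x$loci, collapse = ", "),
              length(x$fitness), 2^x$n_loci,
              if (x$complete) "" else " [INCOMPLETE]"))
  print(round(x$fitness, 4))
  invisible(x)
}

#' Local and global fitness optima
#'
#' A genotype is a local optimum when its fitness strictly exceeds that of
#' every Hamming-1 neighbor; the global optimum is the fittest genotype
#' overall.  Exact ties with a neighbor disqualify both from being strict
#' optima and are reported explicitly rather than broken silently.
#'
#' @param ls A complete `fitness_landscape`.
#' @return List with `local` (character vector of local optima), `global`,
#'   and `ties` (data frame of tied neighbor pairs, possibly empty).
#' @examples
#' ls <- build_landscape(gen_landscape_scenario("reciprocal_sign"))
#' local_optima(ls)
#' @export
local_optima <- function(ls) {
  stopifnot(inherits(ls, "fitness_landscape"))
  if (!ls$complete) stop("local optima require a complete landscape")
  f <- ls$fitness
  ties <- list()
  is_opt <- vapply(names(f), function(g) {
    nb <- hamming_neighbors(g)
    tied <- nb[f[nb] == f[g]]
    if (length(tied)) {
      ties[[length(ties) + 1L]] <<- data.frame(genotype = g, neighbor = tied,
                                               stringsAsFactors = FALSE)
    }
    all(f[g] > f[nb])
  }, logical(1L))
  ties <- if (length(ties)) do.call(rbind, ties) else
    data.frame(genotype = character(), neighbor = character(),
               stringsAsFactors = FALSE)
  list(local = names(f)[is_opt],
       global = names(f)[which.max(f)],
       ties = ties)
}

# depth-first enumeration of strictly fitness-increasing paths
increasing_paths <- function(f, current, end, geodesic, target_diff) {
  if (current == end) return(list(end))
  nxt <- if (geodesic) {
    # flip one of the positions still differing from the end genotype
    cur <- strsplit(current, "")[[1L]]
    endc <- strsplit(end, "")[[1L]]
    diffs <- which(cur != endc)
    vapply(diffs, function(i) {
      step <- cur
      step[i] <- endc[i]
      paste(step, collapse = "")
    }, character(1L))
  } else {
    hamming_neighbors(current)
  }
  out <- list()
  for (g in nxt) {
    if (f[g] > f[current]) {
      for (p in increasing_paths(f, g, end, geodesic, target_diff)) {
        out[[length(out) + 1L]] <- c(current, p)
      }
    }
  }
  out
}

#' Selectively accessible mutational paths
#'
#' Enumerates the mutational paths from `start` to `end` along which
#' fitness strictly increases at every step.  By default paths are
#' restricted to Hamming geodesics (each step flips one locus towards the
#' end genotype, no back-mutation); `geodesic = FALSE` allows any monotone
#' walk (still cycle-free, since fitness must strictly increase).
#'
#' @param ls A complete `fitness_landscape` with at most 20 loci.
#' @param start,end Genotype strings present in the landscape.
#' @param geodesic Restrict to shortest paths?
#' @return List with `count` and `paths` (each path a character vector of
#'   genotypes from `start` to `end`; `start == end` yields the single
#'   empty path).
#' @examples
#' ls <- build_landscape(gen_landscape_scenario("reciprocal_sign"))
#' accessible_paths(ls, "00", "11")$count   # valley: no accessible path
#' @export
accessible_paths <- function(ls, start, end, geodesic = TRUE) {
  stopifnot(inherits(ls, "fitness_landscape"))
  if (ls$n_loci > 20L) stop("path enumeration refused for more than 20 loci")
  if (!ls$complete) stop("accessible paths require a complete landscape")
  f <- ls$fitness
  if (!(start %in% names(f)) || !(end %in% names(f))) {
    stop("start and end must be genotypes of the landscape")
  }
  if (start == end) return(list(count = 1L, paths = list(start)))
  paths <- increasing_paths(f, start, end, geodesic, NULL)
  list(count = length(paths), paths = paths)
}

#' Deterministic selection-mutation dynamics on a fitness landscape
#'
#' Discrete-generation replicator dynamics with symmetric per-locus
#' mutation in an effectively infinite population: each generation, every
#' genotype's frequency is weighted by its fitness and renormalized by the
#' population mean fitness, then a fraction `mu` of each genotype's
#' frequency moves to each of its Hamming-1 neighbors.  Suitable for
#' reproducing qualitative clonal-interference patterns, e.g. a transiently
#' rising single mutant outcompeted by a fitter one while the double mutant
#' stays at mutation-selection balance.
#'
#' @param ls A complete `fitness_landscape`.
#' @param mu Per-locus per-generation mutation probability (`0 <= mu <= 0.5`
#'   and `mu * n_loci <= 1`).
#' @param init Named frequency vector over all genotypes (sums to 1), or a
#'   single genotype string meaning a monomorphic start.
#' @param n_generations Number of generations to iterate.
#' @return Data frame: column `generation` (0..n) plus one frequency column
#'   per genotype.
#' @examples
#' ls <- build_landscape(gen_landscape_scenario("reciprocal_sign"))
#' tail(selection_dynamics(ls, mu = 1e-5, init = "00", n_generations = 100))
#' @export
selection_dynamics <- function(ls, mu, init, n_generations) {
  stopifnot(inherits(ls, "fitness_landscape"), mu >= 0, mu <= 0.5,
            n_generations >= 0)
  if (!ls$complete) stop("dynamics require a complete landscape")
  f <- ls$fitness
  gts <- names(f)
  if (mu * ls$n_loci > 1) stop("mu * n_loci must not exceed 1")
  if (is.character(init) && length(init) == 1L && init %in% gts) {
    p <- setNames(numeric(length(gts)), gts)
    p[init] <- 1
  } else {
    stopifnot(!is.null(names(init)), setequal(names(init), gts))
    p <- init[gts]
    if (any(p < 0)) stop("initial frequencies must be non-negative")
    if (abs(sum(p) - 1) > 1e-8) stop("initial frequencies must sum to 1")
    p <- p / sum(p)
  }
  # column-stochastic mutation matrix: stay with prob 1 - L*mu, move mu to
  # each of the L neighbors
  M <- diag(1 - ls$n_loci * mu, length(gts))
  dimnames(M) <- list(gts, gts)
  for (g in gts) M[hamming_neighbors(g), g] <- mu
  traj <- matrix(NA_real_, nrow = n_generations + 1L, ncol = length(gts),
                 dimnames = list(NULL, gts))
  traj[1L, ] <- p
  for (t in seq_len(n_generations)) {
    wbar <- sum(p * f)
    p <- as.vector(M %*% (p * f / wbar))
    names(p) <- gts
    stopifnot(all(p >= 0))                      # must be impossible to break
    stopifnot(abs(sum(p) - 1) < 1e-9)           # conservation of frequency
    p <- p / sum(p)                             # absorb rounding drift
    traj[t + 1L, ] <- p
  }
  out <- data.frame(generation = 0:n_generations, traj,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}
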