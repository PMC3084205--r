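# Neutral-mutation statistics: Poisson accumulation of neutral mutations
# over the course of an evolution experiment, population mutation supply,
# nonsense-capacity codon scanning and mutual-exclusivity counting.

#' Neutral mutation accumulation model
#'
#' @param genome_size Genome size in base pairs (default 1.2e7, the
#'   *S. cerevisiae* nuclear genome).
#' @param mu Mutation rate per bp per generation (default 5.12e-10).
#' @param generations Generations elapsed.
#' @param pop_size Population size in cells (default 2e9, a 20-ml chemostat
#'   at steady state), used for the mutation supply.
#' @return Object of class `neutral_model`.
#' @export
neutral_model <- function(genome_size = 1.2e7, mu = 5.12e-10,
                          generations = 0, pop_size = 2e9) {
  stopifnot(genome_size >= 0, mu >= 0, generations >= 0, pop_size >= 0)
  structure(list(genome_size = genome_size, mu = mu,
                 generations = generations, pop_size = pop_size),
            class = "neutral_model")
}

#' Expected number of neutral mutations per lineage
#'
#' \eqn{\lambda = G \mu g}: genome size times per-bp per-generation
#' mutation rate times generations.
#'
#' @param m A [neutral_model()].
#' @return Expected mutation count \eqn{\lambda}.
#' @examples
#' expected_neutral_mutations(neutral_model(generations = 266))  # ~1.6
#' @export
expected_neutral_mutations <- function(m) {
  stopifnot(inherits(m, "neutral_model"))
  m$genome_size * m$mu * m$generations
}

#' Poisson upper-tail probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Poisson(\eqn{\lambda}), computed
#' stably via the cumulative distribution.
#'
#' @param lam Expected count (\eqn{\lambda \ge 0}).
#' @param k Threshold count (non-negative integer).
#' @return \eqn{P(X \ge k)}; 1 when `k = 0`.
#' @examples
#' poisson_tail(expected_neutral_mutations(neutral_model(generations = 266)), 4)
#' @export
poisson_tail <- function(lam, k) {
  stopifnot(lam >= 0, k >= 0)
  if (k != as.integer(k)) stop("k must be a non-negative integer")
  ppois(k - 1, lam, lower.tail = FALSE)
}

#' Population mutation supply
#'
#' New mutations entering the population per generation:
#' \eqn{N G \mu}.
#'
#' @param m A [neutral_model()].
#' @return Mutations per generation.
#' @examples
#' mutation_supply(neutral_model())  # ~1.2e7
#' @export
mutation_supply <- function(m) {
  stopifnot(inherits(m, "neutral_model"))
  m$pop_size * m$genome_size * m$mu
}

stop_codons <- c("TAA", "TAG", "TGA")

codon_reaches_stop <- function(codon) {
  chars <- strsplit(codon, "")[[1L]]
  for (i in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == chars[i]) next
      mut <- chars
      mut[i] <- b
      if (paste(mut, collapse = "") %in% stop_codons) return(TRUE)
    }
  }
  FALSE
}

# all 64 codons scored once at load time
stop_reachable_table <- local({
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setNames(vapply(codons, codon_reaches_stop, logical(1L)), codons)
})

#' Nonsense capacity of a coding sequence
#'
#' Counts the sense codons that lie one single-nucleotide substitution away
#' from a stop codon (TAA, TAG, TGA) — i.e. the codons at which a point
#' mutation can truncate the protein.  The terminal stop codon is excluded
#' from both counts; internal stop codons trigger a warning and are
#' excluded too.  A codon counts once no matter how many of its nine
#' single-base variants are stops.
#'
#' @param cds Coding sequence: a character string over A/C/G/T with length
#'   divisible by 3, or a `Biostrings` `DNAString`/`DNAStringSet` (first
#'   sequence used).
#' @return List with `reachable` (codons one substitution from a stop) and
#'   `total_sense_codons`.
#' @examples
#' nonsense_capacity("TACGAAATG")  # TAC -> TAA, GAA -> TAA; ATG cannot
#' @export
nonsense_capacity <- function(cds) {
  if (inherits(cds, "DNAStringSet")) cds <- cds[[1L]]
  cds <- toupper(as.character(cds))
  stopifnot(length(cds) == 1L)
  if (nchar(cds) == 0L) {
    return(list(reachable = 0L, total_sense_codons = 0L))
  }
  if (nchar(cds) %% 3 != 0) stop("sequence length must be divisible by 3")
  if (grepl("[^ACGT]", cds)) {
    stop("ambiguous or non-DNA characters in coding sequence")
  }
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  n <- length(codons)
  if (codons[n] %in% stop_codons) codons <- codons[-n]
  internal_stops <- codons %in% stop_codons
  if (any(internal_stops)) {
    warning(sprintf("%d internal stop codon(s) excluded from the scan",
                    sum(internal_stops)))
    codons <- codons[!internal_stops]
  }
  list(reachable = sum(stop_reachable_table[codons]),
       total_sense_codons = length(codons))
}

#' Read a coding sequence from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning plain
#' character strings, for feeding gene sequences to [nonsense_capacity()].
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_cds <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(seqs), names(seqs))
}

#' Count co-occurrence of two mutations across genotyped clones
#'
#' Exact partition of a clone genotype table by carrier status at two loci.
#' Clones with a missing call at either locus go to an `n_unknown` bin and
#' are never silently dropped.
#'
#' @param table Clone genotype data frame with 0/1 (or NA) columns.
#' @param locus_a,locus_b Column names of the two loci.
#' @return Named list: `n_clones`, `n_a_only`, `n_b_only`, `n_both`,
#'   `n_neither`, `n_unknown`.
#' @examples
#' g <- gen_clone_genotypes(22, 0.4, 0.5, allow_double = FALSE, seed = 1)
#' cooccurrence_count(g, "locus_a", "locus_b")$n_both  # 0 by construction
#' @export
cooccurrence_count <- function(table, locus_a, locus_b) {
  if (!all(c(locus_a, locus_b) %in% names(table))) {
    stop("locus columns not found in the genotype table")
  }
  a <- table[[locus_a]]
  b <- table[[locus_b]]
  unknown <- is.na(a) | is.na(b)
  list(
    n_clones = nrow(table),
    n_a_only = sum(!unknown & a == 1 & b == 0),
    n_b_only = sum(!unknown & a == 0 & b == 1),
    n_both = sum(!unknown & a == 1 & b == 1),
    n_neither = sum(!unknown & a == 0 & b == 0),
    n_unknown = sum(unknown)
  )
}

#' Exact independence test for mutual exclusivity (auxiliary)
#'
#' Fisher's exact test on the 2x2 carrier table of two loci.  This is an
#' auxiliary convenience — the core analysis reports the raw partition
#' counts from [cooccurrence_count()] — provided for users who want an
#' exact hypergeometric probability of the observed co-occurrence pattern.
#'
#' @inheritParams cooccurrence_count
#' @return The `htest` object from [stats::fisher.test()].
#' @export
cooccurrence_independence <- function(table, locus_a, locus_b) {
  cc <- cooccurrence_count(table, locus_a, locus_b)
  m <- matrix(c(cc$n_both, cc$n_b_only, cc$n_a_only, cc$n_neither),
              nrow = 2, dimnames = list(a = c("1", "0"), b = c("1", "0")))
  fisher.test(m)
}
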