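# Shared fixture builders.  All fixtures are constructed in code; nothing
# is read from disk unless a test writes it first.

# quick normalized/unnormalized selection estimate
est <- function(s, se = 0.01, normalized = TRUE) {
  selection_estimate(s, se, normalized = normalized)
}

# competition series with an exactly log-linear ln(mutant/reference):
# counts chosen so that ln(cm/cr) = intercept + slope * generations
exact_series <- function(slope, intercept = 0, generations = 0:10,
                         replicate = "r1", ref_count = 10000) {
  lnr <- intercept + slope * generations
  data.frame(
    replicate = replicate,
    hours = generations,           # placeholder time axis
    generations = generations,
    count_mutant = ref_count * exp(lnr),
    count_reference = ref_count,
    stringsAsFactors = FALSE
  )
}

# one-row variant record as a list
vrec <- function(pos, ref, counts, n = 0L, indels = "", coverage = NULL,
                 chrom = "chr1") {
  stopifnot(all(names(counts) %in% c("A", "C", "G", "T")))
  full <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  full[names(counts)] <- as.integer(counts)
  if (is.null(coverage)) coverage <- sum(full) + n + sum(parse_indels(indels))
  list(chrom = chrom, pos = pos, ref = ref, coverage = as.integer(coverage),
       A = full[["A"]], C = full[["C"]], G = full[["G"]], T = full[["T"]],
       N = as.integer(n), indels = indels)
}

# independent oracle for the nonsense-capacity scan: enumerate all nine
# single-base variants per codon and look their translation up in the
# standard genetic code
oracle_nonsense <- function(cds) {
  code <- Biostrings::GENETIC_CODE
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  n <- length(codons)
  if (n > 0 && code[[codons[n]]] == "*") codons <- codons[-n]
  codons <- codons[vapply(codons, function(cd) code[[cd]] != "*", TRUE)]
  reach <- vapply(codons, function(cd) {
    chars <- strsplit(cd, "")[[1]]
    for (i in 1:3) for (b in setdiff(c("A", "C", "G", "T"), chars[i])) {
      v <- chars; v[i] <- b
      if (code[[paste(v, collapse = "")]] == "*") return(TRUE)
    }
    FALSE
  }, TRUE)
  list(reachable = sum(reach), total_sense_codons = length(codons))
}

# independent geodesic path oracle: enumerate every permutation of the
# differing loci and keep the monotone ones
oracle_paths <- function(ls, start, end) {
  f <- ls$fitness
  s <- strsplit(start, "")[[1]]
  e <- strsplit(end, "")[[1]]
  diffs <- which(s != e)
  if (!length(diffs)) return(1L)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  n_ok <- 0L
  for (ord in perms(diffs)) {
    cur <- s
    ok <- TRUE
    prev <- f[start]
    for (i in ord) {
      cur[i] <- e[i]
      g <- paste(cur, collapse = "")
      if (f[g] <= prev) { ok <- FALSE; break }
      prev <- f[g]
    }
    if (ok) n_ok <- n_ok + 1L
  }
  n_ok
}
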