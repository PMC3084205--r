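# Heuristic post-caller filters deciding which candidate SNPs/indels in an
# evolved clone, relative to its ancestor, survive.  The filters operate on
# per-site allele-count records; they never touch reads or call external
# tools.  Conventions (recorded in the audit output): "non-reference bases"
# exclude N (N has its own rule, with total reads as denominator); the
# non-reference proportion uses non-N reads as denominator; indel
# proportions use total coverage.

#' Filtering thresholds
#'
#' The default values are the study-style heuristics: SNPs require an N
#' proportion < 0.1, the majority non-reference base to carry > 80% of
#' non-reference reads, and the non-reference proportion to be < 0.1 in one
#' strain and > 0.5 in the other; indels require coverage > 10, indel calls
#' > 50% of coverage, the two most frequent indel alleles to carry > 80% of
#' indel calls, reference matches < 50% of coverage, and a > 0.3 difference
#' in proportion for alleles shared between ancestor and evolved.
#'
#' @param snp_n_prop_max,snp_majority_nonref_min,snp_low_nonref_max,snp_high_nonref_min
#'   SNP rule thresholds.
#' @param indel_min_coverage,indel_prop_min,indel_top2_prop_min,indel_ref_match_max,indel_shared_diff_min
#'   Indel rule thresholds.
#' @return Object of class `variant_thresholds`.
#' @export
variant_thresholds <- function(snp_n_prop_max = 0.1,
                               snp_majority_nonref_min = 0.8,
                               snp_low_nonref_max = 0.1,
                               snp_high_nonref_min = 0.5,
                               indel_min_coverage = 10,
                               indel_prop_min = 0.5,
                               indel_top2_prop_min = 0.8,
                               indel_ref_match_max = 0.5,
                               indel_shared_diff_min = 0.3) {
  structure(as.list(environment()), class = "variant_thresholds")
}

#' Parse / format compact indel-count strings
#'
#' Indel observations are carried in TSV-friendly strings like
#' `"+A:30,-2:3"` (allele label, colon, read count, comma-separated; empty
#' string = no indel calls).
#'
#' @param x A single encoded string.
#' @return Named integer vector of counts per indel allele.
#' @export
parse_indels <- function(x) {
  if (is.na(x) || !nzchar(x)) return(setNames(integer(), character()))
  parts <- strsplit(x, ",", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  setNames(vapply(kv, function(p) as.integer(p[2L]), integer(1L)),
           vapply(kv, `[[`, character(1L), 1L))
}

#' @rdname parse_indels
#' @param counts Named integer vector of indel counts.
#' @export
format_indels <- function(counts) {
  if (!length(counts)) return("")
  paste0(names(counts), ":", counts, collapse = ",")
}

# normalize a one-row data frame / list into a variant record
as_variant_record <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- as.list(x)
  }
  needed <- c("chrom", "pos", "ref", "coverage", "A", "C", "G", "T", "N")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    stop("variant record lacks field(s): ", paste(missing, collapse = ", "))
  }
  x$base_counts <- c(A = as.integer(x$A), C = as.integer(x$C),
                     G = as.integer(x$G), T = as.integer(x$T))
  x$n_count <- as.integer(x$N)
  x$indel_counts <- if (is.character(x$indels %||% "")) {
    parse_indels(x$indels %||% "")
  } else {
    x$indels
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

consensus_base <- function(rec) {
  counts <- rec$base_counts
  if (sum(counts) == 0L) return(NA_character_)
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1L) "ambiguous" else top
}

nonref_stats <- function(rec) {
  counts <- rec$base_counts
  nonref <- counts[setdiff(names(counts), rec$ref)]
  non_n_reads <- sum(counts)          # N excluded from base_counts
  list(
    nonref_total = sum(nonref),
    nonref_prop = if (non_n_reads > 0) sum(nonref) / non_n_reads else NA_real_,
    majority_nonref_frac = if (sum(nonref) > 0) max(nonref) / sum(nonref)
                           else NA_real_
  )
}

audit_row <- function(rule, value, threshold, pass) {
  data.frame(rule = rule, value = value, threshold = threshold, pass = pass,
             stringsAsFactors = FALSE)
}

decision <- function(pass, reason, audit, anc, evo, type) {
  list(pass = pass, reason = reason, audit = audit,
       chrom = evo$chrom %||% anc$chrom, pos = evo$pos %||% anc$pos,
       type = type)
}

check_paired <- function(anc, evo) {
  if (!identical(as.character(anc$chrom), as.character(evo$chrom)) ||
      anc$pos != evo$pos) {
    stop("ancestor and evolved records refer to different positions")
  }
  if (!identical(toupper(anc$ref), toupper(evo$ref))) {
    stop("ancestor and evolved records disagree on the reference base")
  }
}

#' SNP filter for an ancestor/evolved record pair
#'
#' A candidate SNP passes when all of the following hold:
#' 1. the proportion of N bases covering the position is below
#'    `snp_n_prop_max` in both samples (value reported: the larger of the
#'    two);
#' 2. in the variant-carrying sample (the one with the higher non-reference
#'    proportion), the majority non-reference base carries more than
#'    `snp_majority_nonref_min` of all non-reference bases;
#' 3. the non-reference proportion is below `snp_low_nonref_max` in one
#'    sample and above `snp_high_nonref_min` in the other;
#' 4. the consensus genotypes of ancestor and evolved differ (sites where
#'    the two strains share their consensus are eliminated).
#'
#' Zero coverage in either sample fails with reason `"no coverage"` rather
#' than raising an error.
#'
#' @param anc,evo Variant records (one-row data frames or lists with fields
#'   `chrom`, `pos`, `ref`, `coverage`, `A`, `C`, `G`, `T`, `N`, `indels`)
#'   for the same position.
#' @param thresholds A [variant_thresholds()].
#' @return Decision list: `pass`, `reason`, per-rule `audit` data frame.
#' @export
filter_snps <- function(anc, evo, thresholds = variant_thresholds()) {
  anc <- as_variant_record(anc)
  evo <- as_variant_record(evo)
  check_paired(anc, evo)
  th <- thresholds
  if (anc$coverage == 0L || evo$coverage == 0L) {
    return(decision(FALSE, "no coverage",
                    audit_row("coverage", "0", "> 0", FALSE),
                    anc, evo, "snp"))
  }
  n_prop <- max(anc$n_count / anc$coverage, evo$n_count / evo$coverage)
  sa <- nonref_stats(anc)
  se <- nonref_stats(evo)
  carrier <- if (isTRUE(se$nonref_prop >= sa$nonref_prop)) se else sa
  maj <- carrier$majority_nonref_frac
  props <- sort(c(sa$nonref_prop, se$nonref_prop))
  r1 <- n_prop < th$snp_n_prop_max
  r2 <- !is.na(maj) && maj > th$snp_majority_nonref_min
  r3 <- !anyNA(props) && props[1L] < th$snp_low_nonref_max &&
    props[2L] > th$snp_high_nonref_min
  r4 <- {
    ca <- consensus_base(anc)
    ce <- consensus_base(evo)
    !is.na(ca) && !is.na(ce) && ca != ce
  }
  audit <- rbind(
    audit_row("N_proportion", sprintf("%.4f", n_prop),
              sprintf("< %s", th$snp_n_prop_max), r1),
    audit_row("majority_nonref_fraction",
              ifelse(is.na(maj), "NA", sprintf("%.4f", maj)),
              sprintf("> %s", th$snp_majority_nonref_min), r2),
    audit_row("nonref_prop_split",
              sprintf("anc=%.4f evo=%.4f", sa$nonref_prop, se$nonref_prop),
              sprintf("< %s in one and > %s in the other",
                      th$snp_low_nonref_max, th$snp_high_nonref_min), r3),
    audit_row("consensus_differs",
              sprintf("anc=%s evo=%s", consensus_base(anc),
                      consensus_base(evo)), "differ", r4)
  )
  pass <- r1 && r2 && r3 && r4
  reason <- if (pass) "PASS" else audit$rule[!audit$pass][1L]
  decision(pass, reason, audit, anc, evo, "snp")
}

#' Indel filter for an ancestor/evolved record pair
#'
#' A candidate indel passes when, in the evolved sample, all of: coverage
#' strictly above `indel_min_coverage`; indel calls above `indel_prop_min`
#' of coverage; the two most frequent indel alleles above
#' `indel_top2_prop_min` of all indel calls; reference matches below
#' `indel_ref_match_max` of coverage; and, for every indel allele observed
#' in both samples, the difference in proportion (of the respective
#' coverages) above `indel_shared_diff_min` (vacuously true when no allele
#' is shared).  An evolved record with no indel calls fails with reason
#' `"no indel evidence"`.
#'
#' @inheritParams filter_snps
#' @return Decision list as in [filter_snps()].
#' @export
filter_indels <- function(anc, evo, thresholds = variant_thresholds()) {
  anc <- as_variant_record(anc)
  evo <- as_variant_record(evo)
  check_paired(anc, evo)
  th <- thresholds
  if (anc$coverage == 0L || evo$coverage == 0L) {
    return(decision(FALSE, "no coverage",
                    audit_row("coverage", "0", "> 0", FALSE),
                    anc, evo, "indel"))
  }
  iev <- evo$indel_counts
  if (!length(iev) || sum(iev) == 0L) {
    return(decision(FALSE, "no indel evidence",
                    audit_row("indel_evidence", "0 indel calls", ">= 1", FALSE),
                    anc, evo, "indel"))
  }
  ian <- anc$indel_counts
  cov <- evo$coverage
  indel_total <- sum(iev)
  top2 <- sum(sort(iev, decreasing = TRUE)[seq_len(min(2L, length(iev)))])
  ref_matches <- evo$base_counts[[evo$ref]]
  shared <- intersect(names(iev), names(ian))
  shared_diffs <- if (length(shared)) {
    abs(iev[shared] / cov - ian[shared] / anc$coverage)
  } else {
    numeric()
  }
  r1 <- cov > th$indel_min_coverage
  r2 <- indel_total / cov > th$indel_prop_min
  r3 <- top2 / indel_total > th$indel_top2_prop_min
  r4 <- ref_matches / cov < th$indel_ref_match_max
  r5 <- !length(shared_diffs) || all(shared_diffs > th$indel_shared_diff_min)
  audit <- rbind(
    audit_row("coverage", as.character(cov),
              sprintf("> %s", th$indel_min_coverage), r1),
    audit_row("indel_proportion", sprintf("%.4f", indel_total / cov),
              sprintf("> %s", th$indel_prop_min), r2),
    audit_row("top2_indel_fraction", sprintf("%.4f", top2 / indel_total),
              sprintf("> %s", th$indel_top2_prop_min), r3),
    audit_row("ref_match_proportion", sprintf("%.4f", ref_matches / cov),
              sprintf("< %s", th$indel_ref_match_max), r4),
    audit_row("shared_allele_prop_diff",
              if (length(shared_diffs)) {
                paste(sprintf("%s=%.3f", names(shared_diffs), shared_diffs),
                      collapse = " ")
              } else "no shared alleles",
              sprintf("> %s (each shared allele)",
                      th$indel_shared_diff_min), r5)
  )
  pass <- r1 && r2 && r3 && r4 && r5
  reason <- if (pass) "PASS" else audit$rule[!audit$pass][1L]
  decision(pass, reason, audit, anc, evo, "indel")
}

#' Apply the SNP/indel filters to paired variant tables
#'
#' Batch driver: ancestor and evolved tables are outer-joined on
#' chromosome and position; every candidate position receives a decision
#' (indel filter when the evolved record carries indel calls, SNP filter
#' otherwise), positions present in only one table fail with reason
#' `"unpaired"`.  Tables must be sorted by chromosome then position.
#'
#' @param anc_table,evo_table Variant tables (as from
#'   [gen_variant_tables()]).
#' @param thresholds A [variant_thresholds()].
#' @return List with `survivors` (chrom, pos, type, reason) and `audit`
#'   (one row per position per rule).
#' @export
apply_filters <- function(anc_table, evo_table,
                          thresholds = variant_thresholds()) {
  check_sorted <- function(tab, label) {
    if (nrow(tab) < 2L) return(invisible())
    o <- order(tab$chrom, tab$pos)
    if (!identical(o, seq_len(nrow(tab)))) {
      first_bad <- which(o != seq_len(nrow(tab)))[1L]
      stop(sprintf("%s table is not sorted by chrom, pos (around %s:%d)",
                   label, tab$chrom[first_bad], tab$pos[first_bad]))
    }
  }
  check_sorted(anc_table, "ancestor")
  check_sorted(evo_table, "evolved")
  key <- function(tab) paste(tab$chrom, tab$pos, sep = ":")
  all_keys <- sort(unique(c(key(anc_table), key(evo_table))))
  if (!length(all_keys)) {
    empty <- data.frame(chrom = character(), pos = integer(),
                        type = character(), stringsAsFactors = FALSE)
    return(list(survivors = empty,
                decisions = cbind(empty, pass = logical(),
                                  reason = character()),
                audit = cbind(empty, audit_row(character(), character(),
                                               character(), logical()))))
  }
  anc_idx <- setNames(seq_len(nrow(anc_table)), key(anc_table))
  evo_idx <- setNames(seq_len(nrow(evo_table)), key(evo_table))
  decisions <- lapply(all_keys, function(k) {
    ia <- anc_idx[k]
    ie <- evo_idx[k]
    if (is.na(ia) || is.na(ie)) {
      present <- if (is.na(ia)) evo_table[ie, ] else anc_table[ia, ]
      return(decision(FALSE, "unpaired",
                      audit_row("paired", "present in one table only",
                                "both", FALSE),
                      as_variant_record(present), as_variant_record(present),
                      "unpaired"))
    }
    anc <- anc_table[ia, ]
    evo <- evo_table[ie, ]
    has_indel <- length(parse_indels(evo$indels %||% "")) > 0L
    if (has_indel) {
      filter_indels(anc, evo, thresholds)
    } else {
      filter_snps(anc, evo, thresholds)
    }
  })
  summary_df <- do.call(rbind, lapply(decisions, function(d) {
    data.frame(chrom = d$chrom, pos = d$pos, type = d$type,
               pass = d$pass, reason = d$reason, stringsAsFactors = FALSE)
  }))
  audit <- do.call(rbind, lapply(decisions, function(d) {
    cbind(data.frame(chrom = d$chrom, pos = d$pos, type = d$type,
                     stringsAsFactors = FALSE),
          d$audit)
  }))
  survivors <- summary_df[summary_df$pass, c("chrom", "pos", "type"),
                          drop = FALSE]
  rownames(survivors) <- NULL
  list(survivors = survivors, decisions = summary_df, audit = audit)
}
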