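# Plain-text interchange: tab-separated tables for competition series,
# variant and genotype tables; BedGraph-style TSV for depth profiles
# (0-based half-open externally, 1-based closed internally); JSON sidecars
# for true simulation parameters.

#' Read and write tab-separated tables
#'
#' Minimal TSV round-trip used for competition series, variant tables and
#' clone genotype tables.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return `read_table_tsv` returns a data frame.
#' @export
write_table_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = NA, comment.char = "", check.names = FALSE,
             na.strings = "NA", fill = FALSE)
}

#' Write / read a depth profile as BedGraph-style TSV
#'
#' External representation: columns `chrom`, `start`, `end`, `depth` with
#' 0-based half-open intervals, adjacent equal-depth bases run-length
#' merged.  Internal representation: per-base rows with 1-based `pos`.
#'
#' @param profile Data frame with columns `chrom`, `pos`, `depth`
#'   (contiguous 1-based positions per chromosome).
#' @param path File path.
#' @return `read_bedgraph` returns the per-base data frame.
#' @export
write_bedgraph <- function(profile, path) {
  stopifnot(all(c("chrom", "pos", "depth") %in% names(profile)))
  pieces <- lapply(split(profile, profile$chrom), function(p) {
    p <- p[order(p$pos), , drop = FALSE]
    if (any(diff(p$pos) != 1)) stop("positions must be contiguous")
    r <- rle(p$depth)
    ends <- cumsum(r$lengths)
    starts <- c(0L, head(ends, -1L))
    data.frame(chrom = p$chrom[1L],
               start = p$pos[1L] - 1L + starts,
               end = p$pos[1L] - 1L + ends,
               depth = r$values, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  bg <- read.table(path, header = FALSE, sep = "\t",
                   col.names = c("chrom", "start", "end", "depth"),
                   stringsAsFactors = FALSE)
  pieces <- lapply(seq_len(nrow(bg)), function(i) {
    data.frame(chrom = bg$chrom[i],
               pos = (bg$start[i] + 1L):bg$end[i],   # 0-based -> 1-based
               depth = bg$depth[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' JSON sidecar of true simulation parameters
#'
#' Every synthetic dataset can be written next to a small JSON file holding
#' the parameters that generated it, so downstream checks can compare
#' estimates to ground truth.
#'
#' @param params Named list of parameters.
#' @param path File path.
#' @return `read_params_json` returns the named list.
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
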