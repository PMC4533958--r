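# Length-distribution and base-composition signatures.
#
# The length histogram is computed over all reads (normalized counts),
# whereas signature fractions and positional profiles operate on unique
# sequences; the two denominators are deliberately different.

#' Read-length histogram
#'
#' Counts reads by length over a closed range. Reads outside the range are
#' excluded from the histogram but reported in the `excluded` attribute.
#'
#' @param reads character vector of sequences, a GRanges with a `seq`
#'   metadata column, or a list of either.
#' @param range integer vector of lengths to report (default 18-36 nt).
#' @param normalize if `TRUE`, add a `fraction` column normalized to the
#'   total read count inside the range.
#' @return data.frame with columns `length`, `count` (and `fraction`), with
#'   attribute `excluded` giving the number of out-of-range reads.
#' @export
length_histogram <- function(reads, range = 18:36, normalize = FALSE) {
  seqs <- read_sequences(reads)
  len <- nchar(seqs)
  inside <- len %in% range
  counts <- vapply(range, function(L) sum(len == L), numeric(1))
  out <- data.frame(length = as.integer(range), count = counts)
  if (normalize) {
    tot <- sum(counts)
    out$fraction <- if (tot > 0) counts / tot else rep(0, length(counts))
  }
  attr(out, "excluded") <- sum(!inside)
  out
}

#' Deduplicate read sequences
#'
#' Exact string deduplication after conversion to the canonical RNA
#' alphabet (T and U equivalent).
#'
#' @inheritParams length_histogram
#' @return character vector of distinct sequences.
#' @export
unique_sequences <- function(reads) {
  unique(as_rna(read_sequences(reads)))
}

#' 5'U / 5'G / position-10 A signature fractions
#'
#' Computes, per read length, the fraction of unique sequences with U at the
#' first position, G at the first position, and A at the tenth position
#' (1-based from the 5' end). Input reads are deduplicated internally, so the
#' result is invariant to read duplication. Lengths with no unique sequence
#' are reported as `NA` (undefined), not 0. Sequences containing symbols
#' outside A/C/G/T/U are skipped with a warning.
#'
#' @inheritParams length_histogram
#' @param lengths lengths (nt) to report; default 24-36.
#' @return data.frame with columns `length`, `n_unique`, `frac_5prime_u`,
#'   `frac_5prime_g`, `frac_10a`.
#' @export
signature_fractions <- function(reads, lengths = 24:36) {
  seqs <- unique_sequences(reads)
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    warning(sum(bad), " sequence(s) with non-ACGTU symbols skipped")
    seqs <- seqs[!bad]
  }
  len <- nchar(seqs)
  first <- substr(seqs, 1L, 1L)
  tenth <- ifelse(len >= 10L, substr(seqs, 10L, 10L), NA_character_)
  res <- lapply(lengths, function(L) {
    sel <- len == L
    n <- sum(sel)
    if (n == 0) {
      return(data.frame(length = L, n_unique = 0L, frac_5prime_u = NA_real_,
                        frac_5prime_g = NA_real_, frac_10a = NA_real_))
    }
    data.frame(length = L, n_unique = n,
               frac_5prime_u = mean(first[sel] == "U"),
               frac_5prime_g = mean(first[sel] == "G"),
               frac_10a = if (L >= 10) mean(tenth[sel] == "A") else NA_real_)
  })
  do.call(rbind, res)
}

#' Positional base-composition profile with information content
#'
#' Builds the 4 x L base-frequency matrix of the unique sequences of a given
#' length, together with the per-position Shannon entropy
#' H = -sum p log2 p (with 0 log2 0 = 0) and information content IC = 2 - H
#' in bits, as used for sequence logos.
#'
#' @inheritParams length_histogram
#' @param length read length L to profile; must lie in 18-36.
#' @return a `positional_profile` list with elements `freq` (4 x L matrix,
#'   rows A/C/G/U, columns summing to 1), `entropy`, `ic` (length-L numeric)
#'   and `n` (number of unique sequences used).
#' @export
positional_profile <- function(reads, length) {
  if (length < 18 || length > 36) {
    stop("length must be within 18-36 nt")
  }
  seqs <- unique_sequences(reads)
  seqs <- seqs[nchar(seqs) == length & !grepl("[^ACGU]", seqs)]
  if (length(seqs) == 0) {
    stop("no unique sequences of length ", length)
  }
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE)
  freq <- vapply(seq_len(ncol(mat)), function(j) {
    tab <- table(factor(mat[, j], levels = RNA_BASES))
    as.numeric(tab) / nrow(mat)
  }, numeric(4))
  rownames(freq) <- RNA_BASES
  colnames(freq) <- seq_len(ncol(freq))
  h <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  structure(list(freq = freq, entropy = h, ic = 2 - h, n = length(seqs)),
            class = "positional_profile")
}

#' Per-group signature tables for a set of samples
#'
#' Pools unique sequences per group and computes [signature_fractions()] for
#' each; a convenience wrapper mirroring per-group signature panels.
#'
#' @param samples named list of per-sample reads.
#' @param design design table with `sample_id` and `group`.
#' @param lengths lengths (nt) to report.
#' @return data.frame with a leading `group` column.
#' @export
group_signature_table <- function(samples, design, lengths = 24:36) {
  res <- lapply(unique(design$group), function(g) {
    ids <- design$sample_id[design$group == g]
    sf <- signature_fractions(samples[ids], lengths = lengths)
    cbind(group = g, sf)
  })
  do.call(rbind, res)
}
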