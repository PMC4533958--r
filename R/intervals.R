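# Strand-specific interval arithmetic: contig construction, intersection and
# overlap reporting. Interval work is delegated to GenomicRanges/IRanges;
# coordinates are half-open 0-based at BED I/O and 1-based closed inside R.

#' Parameters for small RNA contig construction
#'
#' Defaults follow the published procedure: reads of 24-36 nt are merged on
#' each strand allowing gaps of up to 100 bp, and contigs supported by fewer
#' than 100 alignments are discarded. A 24-35 nt window (the alternative
#' wording of the read-inclusion rule) can be requested via `max_read_len`.
#'
#' @param min_read_len,max_read_len read-length window (nt) for contributing
#'   alignments.
#' @param max_gap largest allowed gap (bp) between merged alignments;
#'   boundary inclusive (a gap of exactly `max_gap` still merges).
#' @param min_support minimum number of contributing alignment records.
#' @return a `contig_params` object.
#' @export
contig_params <- function(min_read_len = 24L, max_read_len = 36L,
                          max_gap = 100L, min_support = 100L) {
  if (min_read_len > max_read_len) stop("min_read_len must be <= max_read_len")
  if (max_gap < 0) stop("max_gap must be >= 0")
  if (min_support < 1) stop("min_support must be >= 1")
  structure(list(min_read_len = as.integer(min_read_len),
                 max_read_len = as.integer(max_read_len),
                 max_gap = as.integer(max_gap),
                 min_support = as.integer(min_support)),
            class = "contig_params")
}

#' Merge read alignments into strand-specific small RNA contigs
#'
#' Two alignments on the same strand join one contig iff the gap between
#' them (start2 - end1 in half-open coordinates) is at most `max_gap`. Only
#' alignments whose length lies in the configured window contribute, and
#' contigs supported by fewer than `min_support` alignment records are
#' discarded (multi-mapped reads contribute one unit per alignment record).
#'
#' @param alignments a GRanges of read alignments, or a (named) list of them
#'   which is pooled.
#' @param params a [contig_params()] object.
#' @return GRanges of contigs with metadata columns `contig_id` and
#'   `support`, and a `summary` attribute (data.frame with `n_contigs`,
#'   `mean_length`, `median_length`).
#' @export
build_contigs <- function(alignments, params = contig_params()) {
  stopifnot(inherits(params, "contig_params"))
  gr <- combine_alignments(alignments)
  keep <- width(gr) >= params$min_read_len & width(gr) <= params$max_read_len
  gr <- gr[keep]
  if (length(gr) == 0) {
    contigs <- GRanges()
    mcols(contigs)$contig_id <- character(0)
    mcols(contigs)$support <- integer(0)
    attr(contigs, "summary") <- data.frame(n_contigs = 0L,
                                           mean_length = NA_real_,
                                           median_length = NA_real_)
    return(contigs)
  }
  # reduce() merges ranges whose gap is < min.gapwidth, hence the +1 for a
  # boundary-inclusive "gap <= max_gap" rule; strands never merge together
  contigs <- GenomicRanges::reduce(gr, min.gapwidth = params$max_gap + 1L,
                                   ignore.strand = FALSE)
  support <- countOverlaps(contigs, gr, ignore.strand = FALSE)
  contigs <- contigs[support >= params$min_support]
  support <- support[support >= params$min_support]
  contigs <- sort(contigs, ignore.strand = TRUE)
  mcols(contigs)$contig_id <- sprintf("contig_%06d", seq_along(contigs))
  mcols(contigs)$support <- countOverlaps(contigs, gr, ignore.strand = FALSE)
  attr(contigs, "summary") <- data.frame(
    n_contigs = length(contigs),
    mean_length = if (length(contigs)) mean(width(contigs)) else NA_real_,
    median_length = if (length(contigs)) median(width(contigs)) else NA_real_
  )
  contigs
}

#' Contig set summary
#'
#' @param contigs a [build_contigs()] result.
#' @return data.frame with `n_contigs`, `mean_length`, `median_length`.
#' @export
contig_summary <- function(contigs) {
  s <- attr(contigs, "summary")
  if (!is.null(s)) return(s)
  data.frame(n_contigs = length(contigs),
             mean_length = if (length(contigs)) mean(width(contigs)) else NA_real_,
             median_length = if (length(contigs)) median(width(contigs)) else NA_real_)
}

#' Intersect two interval sets
#'
#' Half-open overlap semantics: two intervals overlap iff startA < endB and
#' startB < endA on the same chromosome, with the requested strand rule.
#'
#' @param query,subject GRanges.
#' @param strandedness `"ignore"` (default), `"same"` or `"opposite"`.
#' @return data.frame of overlapping pairs with columns `query_idx`,
#'   `subject_idx`, `overlap_width`; each pair reported once.
#' @export
intersect_intervals <- function(query, subject,
                                strandedness = c("ignore", "same", "opposite")) {
  strandedness <- match.arg(strandedness)
  hits <- findOverlaps(query, subject, ignore.strand = TRUE)
  qi <- queryHits(hits); si <- subjectHits(hits)
  if (strandedness != "ignore") {
    qs <- as.character(strand(query))[qi]
    ss <- as.character(strand(subject))[si]
    keep <- if (strandedness == "same") qs == ss else
      (qs == "+" & ss == "-") | (qs == "-" & ss == "+")
    qi <- qi[keep]; si <- si[keep]
  }
  ow <- pmin(end(query)[qi], end(subject)[si]) -
    pmax(start(query)[qi], start(subject)[si]) + 1L
  data.frame(query_idx = qi, subject_idx = si, overlap_width = ow)
}

#' Bidirectional overlap report against a reference interval set
#'
#' Reports the fraction and count of contigs overlapping at least one
#' reference record, and the fraction and count of reference records
#' overlapped by at least one contig (e.g. a piRNA reference resource).
#'
#' @param contigs,reference GRanges. Overlap is strand-ignorant.
#' @return one-row data.frame with counts and fractions for both directions
#'   plus an `undefined` flag (set when the reference is empty).
#' @export
overlap_report <- function(contigs, reference) {
  if (length(reference) == 0) {
    return(data.frame(n_contigs = length(contigs), n_contigs_overlapping = 0L,
                      frac_contigs = NA_real_, n_reference = 0L,
                      n_reference_overlapped = 0L, frac_reference = NA_real_,
                      undefined = TRUE))
  }
  co <- sum(overlapsAny(contigs, reference, ignore.strand = TRUE))
  ro <- sum(overlapsAny(reference, contigs, ignore.strand = TRUE))
  data.frame(
    n_contigs = length(contigs), n_contigs_overlapping = co,
    frac_contigs = if (length(contigs)) co / length(contigs) else NA_real_,
    n_reference = length(reference), n_reference_overlapped = ro,
    frac_reference = ro / length(reference),
    undefined = FALSE
  )
}
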