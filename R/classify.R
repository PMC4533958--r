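# Annotation-based read classification and tRNA-fragment typing.

#' Classification configuration
#'
#' @param precedence ordered annotation classes; when a read overlaps several
#'   tracks the earliest class in this order wins. The default puts the most
#'   specific annotations (miRNA, tRNA) first.
#' @param windows named list of closed length windows (nt); must be disjoint
#'   and cover 18-36. The defaults mirror the three observed length modes.
#' @param min_overlap minimum overlap (bp) for a read/track hit.
#' @param trf_max_len largest read length (nt) still typed as a tRF.
#' @param half_min_len smallest read length (nt) typed as a tRNA half;
#'   lengths strictly between the two bounds are `ambiguous`.
#' @param end_tolerance distance (nt) within which a read terminus is
#'   considered to coincide with a mature tRNA end.
#' @return a `class_config` object.
#' @export
class_config <- function(precedence = c("mirna", "trna", "pirna_cluster",
                                        "repeat", "exon"),
                         windows = list(short = c(18L, 24L),
                                        mid = c(25L, 31L),
                                        long = c(32L, 36L)),
                         min_overlap = 1L, trf_max_len = 24L,
                         half_min_len = 28L, end_tolerance = 2L) {
  if (anyDuplicated(precedence)) stop("precedence must be a total order")
  covered <- sort(unlist(lapply(windows, function(w) seq(w[1], w[2]))))
  if (!identical(as.integer(covered), 18:36)) {
    stop("length windows must be disjoint and cover 18-36 nt")
  }
  structure(list(precedence = precedence, windows = windows,
                 min_overlap = as.integer(min_overlap),
                 trf_max_len = as.integer(trf_max_len),
                 half_min_len = as.integer(half_min_len),
                 end_tolerance = as.integer(end_tolerance)),
            class = "class_config")
}

#' Assign each alignment to an annotation class
#'
#' Each alignment receives exactly one label: the highest-precedence class
#' among the tracks it overlaps, or `"unannotated"`. Lookup is strand-aware
#' for tRNA (fragment origin is strand-specific) and strand-ignorant for the
#' other tracks.
#'
#' @param alignments GRanges of read alignments.
#' @param tracks named list of annotation GRanges (names matching
#'   `config$precedence`).
#' @param config a [class_config()].
#' @return character vector of class labels, one per alignment record.
#' @export
classify_reads <- function(alignments, tracks, config = class_config()) {
  labels <- rep("unannotated", length(alignments))
  for (cl in rev(config$precedence)) {
    trk <- tracks[[cl]]
    if (is.null(trk) || length(trk) == 0) next
    hit <- overlapsAny(alignments, trk, minoverlap = config$min_overlap,
                       ignore.strand = cl != "trna")
    labels[hit] <- cl
  }
  labels
}

#' Assign length windows
#'
#' @param lengths integer read lengths (nt).
#' @param config a [class_config()].
#' @return character vector of window names (`NA` outside 18-36 nt).
#' @export
assign_window <- function(lengths, config = class_config()) {
  out <- rep(NA_character_, length(lengths))
  for (w in names(config$windows)) {
    rng <- config$windows[[w]]
    out[lengths >= rng[1] & lengths <= rng[2]] <- w
  }
  out
}

#' Class composition per length window and sample group
#'
#' Classifies every alignment of every sample and tabulates, per group and
#' length window, the fraction of alignments per annotation class (fractions
#' sum to 1 within each group x window) together with the average alignment
#' count per sample.
#'
#' @param samples named list of per-sample alignment GRanges.
#' @param design design table with `sample_id` and `group`.
#' @param tracks named list of annotation GRanges.
#' @param config a [class_config()].
#' @return data.frame with columns `group`, `window`, `class`, `n`,
#'   `fraction`, `mean_per_sample`.
#' @export
class_composition <- function(samples, design, tracks,
                              config = class_config()) {
  res <- list()
  for (g in unique(design$group)) {
    ids <- design$sample_id[design$group == g]
    gr <- combine_alignments(samples[ids])
    cls <- classify_reads(gr, tracks, config)
    win <- assign_window(width(gr), config)
    tab <- as.data.frame(table(window = win, class = cls),
                         stringsAsFactors = FALSE)
    names(tab)[3] <- "n"
    tab <- tab[tab$n > 0 | TRUE, ]
    tot <- tapply(tab$n, tab$window, sum)
    tab$fraction <- ifelse(tot[tab$window] > 0, tab$n / tot[tab$window],
                           NA_real_)
    tab$mean_per_sample <- tab$n / length(ids)
    res[[g]] <- cbind(group = g, tab)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Type tRNA-derived reads as tRFs or tRNA halves with end of origin
#'
#' Fragment type is determined solely by read length (<= `trf_max_len` nt:
#' tRF; >= `half_min_len` nt: tRNA half; in between: ambiguous). The end of
#' origin is called 5prime/3prime when the read's 5'/3' terminus lies within
#' `end_tolerance` nt of the corresponding mature tRNA end on the gene's
#' strand, and internal otherwise. Every read must overlap its tRNA gene.
#'
#' @param reads GRanges of reads overlapping tRNA genes.
#' @param trna_genes GRanges of tRNA genes (with optional `feature_id`
#'   metadata carried through as the tRNA label).
#' @param config a [class_config()].
#' @return data.frame with columns `fragment_type`, `origin_end`, `trna_id`.
#' @export
type_trna_fragment <- function(reads, trna_genes, config = class_config()) {
  hits <- findOverlaps(reads, trna_genes, ignore.strand = FALSE)
  first <- !duplicated(queryHits(hits))
  hits <- hits[first]
  if (length(hits) < length(reads)) {
    stop("every read must overlap a tRNA gene on the gene's strand")
  }
  gi <- subjectHits(hits)[order(queryHits(hits))]
  gene <- trna_genes[gi]
  len <- width(reads)
  fragment_type <- ifelse(len <= config$trf_max_len, "tRF",
                          ifelse(len >= config$half_min_len, "tRNA_half",
                                 "ambiguous"))
  plus <- as.character(strand(gene)) == "+"
  d5 <- ifelse(plus, start(reads) - start(gene), end(gene) - end(reads))
  d3 <- ifelse(plus, end(gene) - end(reads), start(reads) - start(gene))
  origin_end <- ifelse(abs(d5) <= config$end_tolerance, "5prime",
                       ifelse(abs(d3) <= config$end_tolerance, "3prime",
                              "internal"))
  ids <- mcols(gene)$feature_id
  if (is.null(ids)) ids <- as.character(gi)
  data.frame(fragment_type = fragment_type, origin_end = origin_end,
             trna_id = ids, stringsAsFactors = FALSE)
}
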