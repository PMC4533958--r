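`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(what, " must be a probability in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

#' Convert sequences to the canonical RNA alphabet
#'
#' Upper-cases and replaces T with U; sequencing output is DNA-alphabet while
#' analyses are reported on the RNA alphabet, and the two are treated as
#' equivalent on input.
#'
#' @param x character vector of sequences.
#' @return character vector over \{A, C, G, U\} (unvalidated).
#' @export
as_rna <- function(x) chartr("Tt", "UU", toupper(x))

# Extract read sequences from the accepted read representations: a character
# vector, a GRanges with a `seq` metadata column, or a list of either.
read_sequences <- function(reads) {
  if (is.character(reads)) return(reads)
  if (is(reads, "GRanges")) {
    s <- mcols(reads)$seq
    if (is.null(s)) stop("GRanges input must carry a 'seq' metadata column")
    return(as.character(s))
  }
  if (is.list(reads)) return(unlist(lapply(reads, read_sequences), use.names = FALSE))
  stop("unsupported read representation: ", class(reads)[1])
}

# Combine a list of alignment GRanges into one, tagging sample of origin.
combine_alignments <- function(alignments) {
  if (is(alignments, "GRanges")) return(alignments)
  stopifnot(is.list(alignments), length(alignments) > 0)
  grl <- lapply(names(alignments) %||% seq_along(alignments), function(nm) {
    g <- alignments[[nm]]
    mcols(g)$sample <- as.character(nm)
    g
  })
  do.call(c, unname(grl))
}

write_tsv <- function(df, file) {
  write.table(df, file = file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
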