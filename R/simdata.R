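# Synthetic small RNA-seq data generator.
#
# Emits a toy genome with non-overlapping annotation tracks and per-sample
# "already aligned" reads (coordinates + sequence); no aligner is simulated.
# Read sequences are generated with the positional base biases of the
# emulated populations (5'U / 10A for the piRNA population, 5'G for tRNA
# halves of 32-34 nt) rather than copied from the genome; outside forced
# positions the composition is uniform over A/C/G/U.

READ_CLASSES <- c("mirna", "pirna_cluster", "repeat", "trna_half", "trf",
                  "exon", "other")
FEATURE_CLASSES <- c("mirna", "pirna_cluster", "trna", "repeat", "exon")

#' Specification of a toy genome and its annotation tracks
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome in bases.
#' @param n_mirna_loci,n_pirna_clusters,n_trna_genes,n_repeat_elements,n_exons
#'   number of features per annotation class. Features are placed without
#'   overlap across classes.
#' @param feature_lengths named integer vector of per-class feature lengths
#'   (bases).
#' @param seed integer seed making [make_genome()] deterministic.
#' @return a `genome_spec` object.
#' @export
genome_spec <- function(n_chromosomes = 3L, chrom_length = 1e6L,
                        n_mirna_loci = 150L, n_pirna_clusters = 114L,
                        n_trna_genes = 600L, n_repeat_elements = 150L,
                        n_exons = 300L,
                        feature_lengths = c(mirna = 80L, pirna_cluster = 2000L,
                                            trna = 75L, `repeat` = 300L,
                                            exon = 500L),
                        seed = 1L) {
  counts <- c(mirna = n_mirna_loci, pirna_cluster = n_pirna_clusters,
              trna = n_trna_genes, `repeat` = n_repeat_elements, exon = n_exons)
  if (any(counts < 0)) stop("feature counts must be >= 0")
  feature_lengths <- unlist(feature_lengths)  # lists (e.g. from YAML) allowed
  if (n_chromosomes < 1 || chrom_length < max(feature_lengths)) {
    stop("chromosomes must exist and be long enough to hold every feature")
  }
  stopifnot(all(FEATURE_CLASSES %in% names(feature_lengths)))
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 feature_counts = counts,
                 feature_lengths = feature_lengths[FEATURE_CLASSES],
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a toy genome with annotation tracks
#'
#' Places the requested features uniformly at random without overlap across
#' classes (a feature that cannot be placed raises a placement error) and
#' draws random chromosome sequences. Deterministic for a fixed
#' `spec$seed`.
#'
#' @param spec a [genome_spec()].
#' @return a `toy_genome` list with elements `sequences`
#'   ([Biostrings::DNAStringSet]), `features` (one [GenomicRanges::GRanges]
#'   with `feature_id` and `class` metadata) and `tracks` (a named list of
#'   per-class GRanges, one BED-exportable track per annotation class).
#' @export
make_genome <- function(spec = genome_spec()) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(spec$seed, {
    chroms <- paste0("chr", seq_len(spec$n_chromosomes))
    sequences <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
      paste(sample(c("A", "C", "G", "T"), spec$chrom_length, replace = TRUE),
            collapse = "")
    }, character(1)))
    names(sequences) <- chroms

    occupied <- lapply(chroms, function(ch) logical(spec$chrom_length))
    n_total <- sum(spec$feature_counts)
    f_chrom <- character(n_total); f_start <- integer(n_total)
    f_len <- integer(n_total); f_class <- character(n_total)
    k <- 0L
    for (cl in FEATURE_CLASSES) {
      len <- spec$feature_lengths[[cl]]
      for (i in seq_len(spec$feature_counts[[cl]])) {
        placed <- FALSE
        for (try in seq_len(1000L)) {
          ci <- sample.int(length(chroms), 1L)
          st <- sample.int(spec$chrom_length - len + 1L, 1L)
          if (!any(occupied[[ci]][st:(st + len - 1L)])) {
            occupied[[ci]][st:(st + len - 1L)] <- TRUE
            k <- k + 1L
            f_chrom[k] <- chroms[ci]; f_start[k] <- st
            f_len[k] <- len; f_class[k] <- cl
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("placement error: could not place all '", cl,
               "' features without overlap")
        }
      }
    }
    features <- GRanges(
      seqnames = f_chrom,
      ranges = IRanges(start = f_start, width = f_len),
      strand = sample(c("+", "-"), n_total, replace = TRUE)
    )
    ids <- unlist(lapply(FEATURE_CLASSES, function(cl) {
      sprintf("%s_%04d", cl, seq_len(spec$feature_counts[[cl]]))
    }), use.names = FALSE)
    mcols(features)$feature_id <- ids
    mcols(features)$class <- f_class
    tracks <- lapply(setNames(FEATURE_CLASSES, FEATURE_CLASSES), function(cl) {
      features[mcols(features)$class == cl]
    })
    structure(list(spec = spec, sequences = sequences,
                   features = features, tracks = tracks),
              class = "toy_genome")
  })
}

#' Default per-class read-length distributions
#'
#' Discrete length models reproducing the three observed length modes:
#' miRNA-sized reads peak at 22 nt, the piRNA population (cluster- and
#' repeat-derived) at 30 nt, tRNA halves at 33 nt and tRFs at 20 nt. Exonic
#' degradation fragments are split between the short range and 35-36 nt.
#'
#' @return named list of named probability vectors (names are lengths in nt).
#' @export
default_length_models <- function() {
  lm <- list(
    mirna = setNames(c(.04, .07, .12, .22, .40, .15), 18:23),
    pirna_cluster = setNames(c(.02, .04, .06, .08, .12, .18, .35, .15), 24:31),
    trna_half = setNames(c(.18, .40, .22, .12, .08), 32:36),
    trf = setNames(c(.15, .25, .35, .15, .07, .03), 18:23),
    exon = setNames(c(rep(1 / 12, 6), .25, .25), c(18:23, 35:36)),
    other = setNames(rep(1 / 6, 6), 18:23)
  )
  lm[["repeat"]] <- lm$pirna_cluster
  lm[READ_CLASSES]
}

#' Per-group simulation parameters
#'
#' @param group_label free-text group name (e.g. "normal", "tumor", "cis").
#' @param class_weights mixture proportions over the read classes
#'   (must sum to 1). The weights describe the expected composition of a
#'   baseline (normal) sample; group effects below rescale individual
#'   classes without renormalizing the rest.
#' @param length_models per-class discrete length distributions, see
#'   [default_length_models()].
#' @param p_5prime_u probability that a piRNA-population read (cluster- or
#'   repeat-derived) starts with U; 0.25 corresponds to no bias.
#' @param p_10a probability of A at position 10 of a piRNA-population read.
#' @param p_5prime_g probability that a tRNA half of 32-34 nt starts with G.
#' @param pirna_log2fc log2 scale factor applied to the expected counts of
#'   every piRNA-population feature (clusters and repeats).
#' @param mirna_up_log2fc log2 scale factor applied to the designated
#'   up-regulated miRNA subset.
#' @param n_mirna_up number of designated up-regulated miRNA loci.
#' @param mirna_up_base_mean baseline (normal) expected reads per sample for
#'   each up-set miRNA locus; kept low so that the fold change is large while
#'   tumor counts stay moderate.
#' @param dispersion negative-binomial dispersion of per-feature counts
#'   (0 gives Poisson noise).
#' @param depth expected reads per baseline sample.
#' @param multimap_frac fraction of piRNA-population reads that receive
#'   additional alignment records.
#' @param multimap_kmax cap on alignment records per read (mirrors the
#'   usual "report up to 100 hits" alignment setting).
#' @param libsize_sdlog log-normal sd of the per-sample library-size factor.
#' @param trna_jitter maximum 5'-end offset (nt) of tRNA-derived reads from
#'   the annotated tRNA 5' end.
#' @return a `group_params` object.
#' @export
group_params <- function(group_label = "normal",
                         class_weights = c(mirna = 0.26, pirna_cluster = 0.18,
                                           `repeat` = 0.16, trna_half = 0.27,
                                           trf = 0.04, exon = 0.06,
                                           other = 0.03),
                         length_models = default_length_models(),
                         p_5prime_u = 0.70, p_10a = 0.35, p_5prime_g = 0.60,
                         pirna_log2fc = 0, mirna_up_log2fc = 0,
                         n_mirna_up = 23L, mirna_up_base_mean = 0.2,
                         dispersion = 0.05, depth = 1e5,
                         multimap_frac = 0.2, multimap_kmax = 100L,
                         libsize_sdlog = 0.1, trna_jitter = 2L) {
  stopifnot(setequal(names(class_weights), READ_CLASSES))
  if (abs(sum(class_weights) - 1) > 1e-8) stop("class_weights must sum to 1")
  if (any(class_weights < 0)) stop("class_weights must be non-negative")
  stop_if_not_prob(c(p_5prime_u, p_10a, p_5prime_g, multimap_frac),
                   "signature/multimap probabilities")
  if (depth <= 0) stop("depth must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  for (cl in READ_CLASSES) {
    pm <- length_models[[cl]]
    if (is.null(pm) || abs(sum(pm) - 1) > 1e-8) {
      stop("length model for class '", cl, "' must be a probability vector")
    }
  }
  structure(list(group_label = group_label,
                 class_weights = class_weights[READ_CLASSES],
                 length_models = length_models,
                 p_5prime_u = p_5prime_u, p_10a = p_10a,
                 p_5prime_g = p_5prime_g,
                 pirna_log2fc = pirna_log2fc,
                 mirna_up_log2fc = mirna_up_log2fc,
                 n_mirna_up = as.integer(n_mirna_up),
                 mirna_up_base_mean = mirna_up_base_mean,
                 dispersion = dispersion, depth = depth,
                 multimap_frac = multimap_frac,
                 multimap_kmax = as.integer(multimap_kmax),
                 libsize_sdlog = libsize_sdlog,
                 trna_jitter = as.integer(trna_jitter)),
            class = "group_params")
}

#' @rdname group_params
#' @param ... overrides passed on to [group_params()].
#' @export
normal_params <- function(...) group_params(group_label = "normal", ...)

#' Tumor-group parameters: global piRNA loss and miR-302/371-like upregulation
#'
#' Defaults inject a log2 fold change of -5 on the whole piRNA population,
#' +11 on the designated miRNA subset, and remove the 5'U/10A bias
#' (first/tenth base uniform at 0.25).
#'
#' @rdname group_params
#' @export
tumor_params <- function(...) {
  args <- list(...)
  defaults <- list(group_label = "tumor", p_5prime_u = 0.25, p_10a = 0.25,
                   pirna_log2fc = -5, mirna_up_log2fc = 11)
  do.call(group_params, utils::modifyList(defaults, args))
}

#' Carcinoma-in-situ parameters as a normal/tumor mixture
#'
#' CIS tissue mixes neoplastic and normal spermatogenic cells; its parameters
#' interpolate the normal and tumor settings at mixture fraction `mix`
#' (probabilities linearly, fold changes on the log2 scale).
#'
#' @param mix fraction of the tumor parameter set (0 = normal, 1 = tumor).
#' @rdname group_params
#' @export
cis_params <- function(mix = 0.5, ...) {
  np <- normal_params(); tp <- tumor_params()
  defaults <- list(
    group_label = "cis",
    p_5prime_u = (1 - mix) * np$p_5prime_u + mix * tp$p_5prime_u,
    p_10a = (1 - mix) * np$p_10a + mix * tp$p_10a,
    pirna_log2fc = mix * tp$pirna_log2fc,
    mirna_up_log2fc = mix * tp$mirna_up_log2fc
  )
  do.call(group_params, utils::modifyList(defaults, list(...)))
}

# Expected reads per sample for every (feature, read class) emission source.
# Returns a data.frame with feature coordinates and per-emission means.
emission_table <- function(genome, params) {
  stopifnot(inherits(genome, "toy_genome"), inherits(params, "group_params"))
  feats <- genome$features
  fd <- data.frame(feature_id = mcols(feats)$feature_id,
                   class = mcols(feats)$class,
                   chrom = as.character(seqnames(feats)),
                   start = start(feats), end = end(feats),
                   strand = as.character(strand(feats)),
                   stringsAsFactors = FALSE)
  w <- params$class_weights
  d <- params$depth
  n_of <- function(cl) sum(fd$class == cl)
  need <- c(mirna = unname(w["mirna"] > 0 || params$n_mirna_up > 0),
            pirna_cluster = unname(w["pirna_cluster"] > 0),
            trna = unname(w["trna_half"] > 0 || w["trf"] > 0),
            `repeat` = unname(w["repeat"] > 0),
            exon = unname(w["exon"] > 0))
  for (cl in names(need)) {
    if (need[[cl]] && n_of(cl) == 0) {
      stop("configuration error: class '", cl,
           "' has positive weight but an empty annotation track")
    }
  }
  rows <- list()
  add <- function(sub, read_class, mean) {
    if (nrow(sub) == 0) return()
    sub$read_class <- read_class
    sub$mean <- mean
    rows[[length(rows) + 1L]] <<- sub
  }
  mi <- fd[fd$class == "mirna", ]
  if (nrow(mi) > 0) {
    n_up <- min(params$n_mirna_up, nrow(mi))
    up <- seq_len(n_up)
    if (n_up < nrow(mi)) {
      add(mi[-up, ], "mirna", w[["mirna"]] * d / (nrow(mi) - n_up))
    }
    if (n_up > 0) {
      add(mi[up, ], "mirna",
          params$mirna_up_base_mean * 2^params$mirna_up_log2fc)
    }
  }
  pi_scale <- 2^params$pirna_log2fc
  pc <- fd[fd$class == "pirna_cluster", ]
  add(pc, "pirna_cluster", w[["pirna_cluster"]] * d / max(nrow(pc), 1) * pi_scale)
  rp <- fd[fd$class == "repeat", ]
  add(rp, "repeat", w[["repeat"]] * d / max(nrow(rp), 1) * pi_scale)
  tr <- fd[fd$class == "trna", ]
  add(tr, "trna_half", w[["trna_half"]] * d / max(nrow(tr), 1))
  add(tr, "trf", w[["trf"]] * d / max(nrow(tr), 1))
  ex <- fd[fd$class == "exon", ]
  add(ex, "exon", w[["exon"]] * d / max(nrow(ex), 1))
  if (w[["other"]] > 0) {
    bg <- data.frame(feature_id = "background", class = "other",
                     chrom = NA_character_, start = NA_integer_,
                     end = NA_integer_, strand = NA_character_,
                     read_class = "other", mean = w[["other"]] * d,
                     stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- bg
  }
  em <- do.call(rbind, rows)
  rownames(em) <- NULL
  em
}

# Generate sequences for unique read keys; forced base biases are applied at
# positions 1 and 10 (1-based from the 5' end), everything else uniform.
generate_key_sequences <- function(len, read_class, params) {
  n <- length(len)
  if (n == 0) return(character(0))
  total <- sum(len)
  idx <- sample.int(4L, total, replace = TRUE)
  starts <- cumsum(len) - len + 1L
  pir <- read_class %in% c("pirna_cluster", "repeat")
  if (any(pir)) {
    np <- sum(pir)
    forced <- runif(np) < params$p_5prime_u
    alt <- sample.int(3L, np, replace = TRUE)  # A, C, G
    idx[starts[pir]] <- ifelse(forced, 4L, alt)
    p10 <- pir & len >= 10L
    np10 <- sum(p10)
    if (np10 > 0) {
      forced10 <- runif(np10) < params$p_10a
      alt10 <- sample.int(3L, np10, replace = TRUE) + 1L  # C, G, U
      idx[starts[p10] + 9L] <- ifelse(forced10, 1L, alt10)
    }
  }
  gsel <- read_class == "trna_half" & len >= 32L & len <= 34L
  if (any(gsel)) {
    ng <- sum(gsel)
    forced <- runif(ng) < params$p_5prime_g
    alt <- c(1L, 2L, 4L)[sample.int(3L, ng, replace = TRUE)]  # A, C, U
    idx[starts[gsel]] <- ifelse(forced, 3L, alt)
  }
  big <- paste(RNA_BASES[idx], collapse = "")
  substring(big, starts, starts + len - 1L)
}

# Sample read start coordinates for one emission class.
read_starts <- function(fstart, fend, fstrand, len, read_class, params) {
  n <- length(len)
  st <- integer(n)
  anchored5 <- read_class %in% c("trna_half", "trf")
  canonical <- read_class == "mirna"
  uniform <- !anchored5 & !canonical
  if (any(uniform)) {
    lo <- fstart[uniform]
    hi <- fend[uniform] - len[uniform] + 1L
    hi <- pmax(hi, lo)  # reads longer than the feature start at the feature
    st[uniform] <- lo + floor(runif(sum(uniform)) * (hi - lo + 1L))
  }
  if (any(canonical)) st[canonical] <- fstart[canonical]
  if (any(anchored5)) {
    j <- sample.int(params$trna_jitter + 1L, sum(anchored5), replace = TRUE) - 1L
    plus <- fstrand[anchored5] == "+"
    sa <- integer(sum(anchored5))
    sa[plus] <- fstart[anchored5][plus] + j[plus]
    sa[!plus] <- fend[anchored5][!plus] - j[!plus] - len[anchored5][!plus] + 1L
    st[anchored5] <- sa
  }
  st
}

# Random background positions avoiding all annotated features.
draw_background <- function(n, genome, len) {
  if (n == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0)))
  }
  chroms <- names(genome$sequences)
  clen <- genome$spec$chrom_length
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(clen - max(len), n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  for (i in seq_len(25L)) {
    gr <- GRanges(chrom, IRanges(start, width = len), strand = strand)
    bad <- overlapsAny(gr, genome$features, ignore.strand = TRUE)
    if (!any(bad)) break
    nb <- sum(bad)
    chrom[bad] <- sample(chroms, nb, replace = TRUE)
    start[bad] <- sample.int(clen - max(len), nb, replace = TRUE)
  }
  data.frame(chrom = chrom, start = start, strand = strand,
             stringsAsFactors = FALSE)
}

#' Simulate the aligned reads of one small RNA-seq sample
#'
#' Per-feature read counts are drawn from a negative binomial around the
#' group's expected means (Poisson when `dispersion = 0`), read lengths from
#' the per-class length models, and positions according to the class rule
#' (miRNA reads at the canonical locus 5' end, tRNA-derived reads anchored at
#' the tRNA 5' end, cluster/repeat/exon reads uniform within the feature,
#' background reads outside every feature). A configurable fraction of
#' piRNA-population reads is emitted with multiple alignment records (one per
#' decoy locus of the same class, identical sequence).
#'
#' @param genome a [make_genome()] result.
#' @param params a [group_params()] object.
#' @param seed integer seed; the same genome/params/seed triple reproduces
#'   the sample exactly.
#' @return a [GenomicRanges::GRanges] of alignment records with metadata
#'   columns `read_id`, `seq`, `n_hits`, `true_class` and `true_feature`.
#' @export
simulate_sample <- function(genome, params, seed = 1L) {
  stopifnot(inherits(genome, "toy_genome"), inherits(params, "group_params"))
  withr::with_seed(as.integer(seed), {
    em <- emission_table(genome, params)
    libfac <- rlnorm(1, 0, params$libsize_sdlog)
    mu <- em$mean * libfac
    n <- if (params$dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / params$dispersion)
    } else {
      rpois(length(mu), mu)
    }
    rows <- rep(seq_along(n), n)
    if (length(rows) == 0) {
      return(GRanges(seqnames = character(0),
                     ranges = IRanges(integer(0), integer(0)),
                     strand = character(0),
                     read_id = character(0), seq = character(0),
                     n_hits = integer(0), true_class = character(0),
                     true_feature = character(0)))
    }
    rd <- em[rows, c("feature_id", "class", "chrom", "start", "end", "strand",
                     "read_class")]
    rownames(rd) <- NULL
    # lengths per read class
    rd$len <- NA_integer_
    for (cl in unique(rd$read_class)) {
      sel <- rd$read_class == cl
      pm <- params$length_models[[cl]]
      rd$len[sel] <- as.integer(sample(as.integer(names(pm)), sum(sel),
                                       replace = TRUE, prob = pm))
    }
    bg <- rd$read_class == "other"
    if (any(bg)) {
      pos <- draw_background(sum(bg), genome, rd$len[bg])
      rd$chrom[bg] <- pos$chrom
      rd$strand[bg] <- pos$strand
      rd$start[bg] <- pos$start
      rd$end[bg] <- pos$start  # placeholder; real end set below
      rd$rstart <- NA_integer_
      rd$rstart[bg] <- pos$start
    } else {
      rd$rstart <- NA_integer_
    }
    fb <- !bg
    rd$rstart[fb] <- read_starts(rd$start[fb], rd$end[fb], rd$strand[fb],
                                 rd$len[fb], rd$read_class[fb], params)
    rd$rend <- rd$rstart + rd$len - 1L

    # one sequence per distinct aligned molecule (same locus + length =>
    # identical read sequence)
    key <- paste(rd$chrom, rd$rstart, rd$len, rd$strand, sep = ":")
    first <- !duplicated(key)
    seqs_u <- generate_key_sequences(rd$len[first], rd$read_class[first],
                                     params)
    rd$seq <- seqs_u[match(key, key[first])]

    rd$read_id <- sprintf("r%07d", seq_len(nrow(rd)))
    rd$n_hits <- 1L

    # multi-mapping for part of the piRNA population: extra alignment
    # records at decoy loci of the same class, identical sequence
    pir <- which(rd$read_class %in% c("pirna_cluster", "repeat"))
    extra <- NULL
    if (length(pir) > 0 && params$multimap_frac > 0) {
      mm <- pir[runif(length(pir)) < params$multimap_frac]
      if (length(mm) > 0) {
        k_extra <- pmin(sample(1:4, length(mm), replace = TRUE),
                        params$multimap_kmax - 1L)
        rd$n_hits[mm] <- 1L + k_extra
        src <- rep(mm, k_extra)
        feats <- genome$features
        ex_rows <- rd[src, ]
        for (cl in unique(ex_rows$read_class)) {
          sel <- ex_rows$read_class == cl
          pool <- feats[mcols(feats)$class == cl]
          pick <- sample(length(pool), sum(sel), replace = TRUE)
          ex_rows$feature_id[sel] <- mcols(pool)$feature_id[pick]
          ex_rows$chrom[sel] <- as.character(seqnames(pool))[pick]
          ex_rows$strand[sel] <- as.character(strand(pool))[pick]
          lo <- start(pool)[pick]
          hi <- pmax(end(pool)[pick] - ex_rows$len[sel] + 1L, lo)
          ex_rows$rstart[sel] <- lo + floor(runif(sum(sel)) * (hi - lo + 1L))
          ex_rows$rend[sel] <- ex_rows$rstart[sel] + ex_rows$len[sel] - 1L
        }
        extra <- ex_rows
      }
    }
    all_rows <- if (is.null(extra)) rd else rbind(rd, extra)
    all_rows$n_hits <- rd$n_hits[match(all_rows$read_id, rd$read_id)]
    gr <- GRanges(seqnames = all_rows$chrom,
                  ranges = IRanges(all_rows$rstart, all_rows$rend),
                  strand = all_rows$strand)
    mcols(gr)$read_id <- all_rows$read_id
    mcols(gr)$seq <- all_rows$seq
    mcols(gr)$n_hits <- all_rows$n_hits
    mcols(gr)$true_class <- all_rows$read_class
    mcols(gr)$true_feature <- all_rows$feature_id
    gr
  })
}

#' Default study design
#'
#' A scaled version of the study structure: 12 normal control samples versus
#' 10 tumor case samples (optionally with carcinoma-in-situ samples grouped
#' with the cases).
#'
#' @param n_normal,n_tumor,n_cis samples per group.
#' @return data.frame with columns `sample_id`, `group`, `condition`.
#' @export
default_design <- function(n_normal = 12L, n_tumor = 10L, n_cis = 0L) {
  data.frame(
    sample_id = c(sprintf("N%02d", seq_len(n_normal)),
                  sprintf("C%02d", seq_len(n_cis)),
                  sprintf("T%02d", seq_len(n_tumor))),
    group = c(rep("normal", n_normal), rep("cis", n_cis),
              rep("tumor", n_tumor)),
    condition = c(rep("control", n_normal), rep("case", n_cis + n_tumor)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a whole small RNA-seq experiment with ground truth
#'
#' Simulates one aligned-read set per design row and assembles a ground-truth
#' table of per-feature true means and true tumor-vs-normal log2 fold
#' changes for parameter-recovery checks.
#'
#' @param design a design table, see [default_design()].
#' @param params named list of [group_params()] keyed by design group.
#' @param seed master seed; per-sample seeds are derived from it.
#' @param genome optional pre-built [make_genome()] result; built from `spec`
#'   otherwise.
#' @param spec [genome_spec()] used when `genome` is not supplied.
#' @return a `smallrna_experiment` list with `samples` (named list of
#'   alignment GRanges), `truth` (data.frame), `design`, `genome`, `params`.
#' @export
simulate_experiment <- function(design = default_design(),
                                params = list(normal = normal_params(),
                                              tumor = tumor_params(),
                                              cis = cis_params()),
                                seed = 1L, genome = NULL,
                                spec = genome_spec()) {
  stopifnot(all(c("sample_id", "group", "condition") %in% names(design)))
  if (any(table(design$condition) < 2)) {
    warning("a compared condition has fewer than 2 samples; ",
            "differential expression downstream will be underpowered")
  }
  if (is.null(genome)) genome <- make_genome(spec)
  groups <- unique(design$group)
  missing <- setdiff(groups, names(params))
  if (length(missing) > 0) {
    stop("no group_params supplied for group(s): ",
         paste(missing, collapse = ", "))
  }
  sample_seeds <- withr::with_seed(as.integer(seed), {
    sample.int(.Machine$integer.max - 1L, nrow(design))
  })
  samples <- lapply(seq_len(nrow(design)), function(i) {
    simulate_sample(genome, params[[design$group[i]]], sample_seeds[i])
  })
  names(samples) <- design$sample_id

  # truth table at library factor 1
  ems <- lapply(groups, function(g) {
    em <- emission_table(genome, params[[g]])
    agg <- aggregate(mean ~ feature_id + class, data = em, FUN = sum)
    names(agg)[3] <- paste0("mean_", g)
    agg
  })
  truth <- Reduce(function(a, b) merge(a, b, by = c("feature_id", "class"),
                                       all = TRUE), ems)
  if (all(c("mean_normal", "mean_tumor") %in% names(truth))) {
    truth$log2fc <- log2(truth$mean_tumor / truth$mean_normal)
  }
  structure(list(samples = samples, truth = truth, design = design,
                 genome = genome, params = params),
            class = "smallrna_experiment")
}
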