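# Negative-binomial differential expression: median-of-ratios size factors,
# pooled dispersion estimation with maximum sharing (parametric or local
# mean-dispersion fit), the exact conditioned NB test, fold changes with
# +/-Inf conventions, BH adjustment and a variance-stabilizing transform.
#
# The exact test compares the two condition count sums kA, kB of a feature
# conditioned on their total: with each sum modelled as NB with mean and
# variance implied by the pooled mean, the size factors and the shared
# dispersion, the p-value is the total probability of all splits (a, b),
# a + b = kA + kB, that are no more likely than the observed one.

#' Count alignments over a feature set
#'
#' Every alignment record overlapping a feature adds one to that feature's
#' count; an alignment overlapping k features adds one to each of them.
#' Under the default policy every alignment record of a multi-mapped read is
#' counted (so multi-locus piRNAs are retained); under `"unique"` only
#' alignment records overlapping exactly one feature contribute.
#'
#' @param features GRanges with a `feature_id` metadata column (or unnamed;
#'   indices are used).
#' @param alignments named list of per-sample alignment GRanges (or a single
#'   GRanges for a one-sample matrix).
#' @param multimap counting policy, `"all"` (default) or `"unique"`.
#' @param ignore_strand passed to the overlap test (default TRUE).
#' @return integer matrix, features x samples.
#' @export
count_reads <- function(features, alignments, multimap = c("all", "unique"),
                        ignore_strand = TRUE) {
  multimap <- match.arg(multimap)
  if (length(features) == 0) stop("feature set is empty")
  if (is(alignments, "GRanges")) alignments <- list(sample1 = alignments)
  ids <- mcols(features)$feature_id %||% mcols(features)$contig_id %||%
    as.character(seq_along(features))
  counts <- vapply(alignments, function(aln) {
    if (multimap == "all") {
      countOverlaps(features, aln, ignore.strand = ignore_strand)
    } else {
      hits <- findOverlaps(features, aln, ignore.strand = ignore_strand)
      n_feat <- table(subjectHits(hits))
      uniq <- names(n_feat)[n_feat == 1]
      keep <- as.character(subjectHits(hits)) %in% uniq
      tabulate(queryHits(hits)[keep], nbins = length(features))
    }
  }, numeric(length(features)))
  counts <- matrix(as.integer(counts), nrow = length(features),
                   dimnames = list(ids, names(alignments)))
  counts
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features (restricted
#' to features with a positive count in every sample) of the ratio of the
#' sample's count to the feature's geometric mean across samples.
#'
#' @param counts features x samples integer matrix.
#' @return named positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  loggeo <- rowMeans(log(counts))
  ok <- is.finite(loggeo)
  if (!any(ok)) {
    stop("no feature has a nonzero count in every sample; ",
         "filter the count matrix before normalization")
  }
  sf <- apply(counts, 2, function(x) {
    median(exp(log(x[ok]) - loggeo[ok]))
  })
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("degenerate size factor estimate; filter low-count features")
  }
  sf
}

#' Normalize counts by size factors
#'
#' @param counts features x samples matrix.
#' @param sf size factors from [size_factors()].
#' @return numeric matrix of normalized counts.
#' @export
normalized_counts <- function(counts, sf) {
  sweep(as.matrix(counts), 2, sf, "/")
}

# Iterated Gamma-GLM fit of dispersion ~ a0 + a1/mean, with outlier
# down-weighting by ratio trimming; falls back to a clamped least-squares
# fit if the GLM cannot be stabilized.
fit_parametric_dispersion <- function(means, disps) {
  coefs <- c(0.1, 1)
  ans <- try({
    for (iter in seq_len(20L)) {
      residual <- disps / (coefs[1] + coefs[2] / means)
      good <- which(residual > 1e-4 & residual < 15)
      if (length(good) < 2) stop("too few usable dispersion estimates")
      fit <- suppressWarnings(
        glm(disps[good] ~ I(1 / means[good]),
            family = Gamma(link = "identity"), start = coefs)
      )
      old <- coefs
      coefs <- unname(coefficients(fit))
      if (!all(is.finite(coefs)) || coefs[2] < 0) {
        stop("parametric dispersion fit failed")
      }
      coefs[1] <- max(coefs[1], 1e-12)
      if (sum(log(pmax(coefs, 1e-12) / pmax(old, 1e-12))^2) < 1e-6) break
    }
    coefs
  }, silent = TRUE)
  if (inherits(ans, "try-error")) {
    fit <- lm(disps ~ I(1 / means))
    ans <- pmax(unname(coefficients(fit)), c(1e-12, 0))
  }
  c(asympt_disp = ans[1], extra_pois = ans[2])
}

# Running-median trend of log dispersion versus log mean (window ~10 % of
# the features), evaluated by interpolation.
fit_local_dispersion <- function(means, disps, floor = 1e-8) {
  ord <- order(means)
  lm_ <- log(means[ord])
  ld <- log(pmax(disps[ord], floor))
  k <- max(5L, 2L * floor(0.05 * length(ld)) + 1L)
  if (k %% 2 == 0) k <- k + 1L
  if (k > length(ld)) k <- length(ld) - (1 - length(ld) %% 2)
  sm <- runmed(ld, k)
  keep <- !duplicated(lm_)
  fn <- approxfun(lm_[keep], sm[keep], rule = 2)
  list(fn = function(q) exp(fn(log(pmax(q, 1e-12)))),
       grid = data.frame(log_mean = lm_[keep], log_disp = sm[keep]))
}

#' Pooled dispersion estimation with maximum sharing
#'
#' Per-feature raw dispersions are obtained by the method of moments on
#' normalized counts, pooling the within-condition variability across all
#' conditions with replication: with pooled variance v, overall normalized
#' mean q and mean reciprocal size factor xi, the raw dispersion is
#' (v - xi q) / q^2, floored at 0. A mean-dispersion trend is then fitted,
#' either parametric (a0 + a1/q, Gamma GLM) or local (running-median trend
#' of log dispersion versus log mean), and under maximum sharing each
#' feature's final dispersion is the larger of its raw estimate and the
#' fitted value, floored at `min_disp`.
#'
#' @param counts features x samples matrix.
#' @param sf size factors.
#' @param conditions factor/character of per-sample conditions.
#' @param fit_type `"parametric"` or `"local"`.
#' @param min_disp dispersion floor.
#' @return a `dispersion_model` list with `raw`, `fitted`, `final`,
#'   `base_mean`, `fit_type`, and the fit (`coef` for parametric, `trend`
#'   for local).
#' @export
estimate_dispersions <- function(counts, sf, conditions,
                                 fit_type = c("parametric", "local"),
                                 min_disp = 1e-8) {
  fit_type <- match.arg(fit_type)
  counts <- as.matrix(counts)
  conditions <- as.factor(conditions)
  reps <- table(conditions)
  use_conds <- names(reps)[reps >= 2]
  if (length(use_conds) == 0) {
    stop("no condition has replicates; dispersion cannot be estimated")
  }
  norm <- normalized_counts(counts, sf)
  q <- rowMeans(norm)
  rss <- 0
  df_tot <- 0
  used_samples <- conditions %in% use_conds
  for (cn in use_conds) {
    sel <- conditions == cn
    m <- norm[, sel, drop = FALSE]
    rss <- rss + rowSums((m - rowMeans(m))^2)
    df_tot <- df_tot + sum(sel) - 1L
  }
  v <- rss / df_tot
  xi <- mean(1 / sf[used_samples])
  raw <- (v - xi * q) / q^2
  raw[q == 0] <- NA_real_
  raw <- pmax(raw, 0)

  usable <- which(q > 0 & raw > min_disp)
  if (length(usable) < 2) {
    # no feature shows extra-Poisson variability: the fitted trend is zero
    # and maximum sharing reduces to the raw estimates at the floor
    warning("no positive raw dispersion estimates; fitted trend set to zero")
    fitted <- ifelse(q > 0, 0, NA_real_)
    final <- pmax(pmax(raw, fitted), min_disp)
    final[q == 0] <- NA_real_
    return(structure(list(raw = raw, fitted = fitted, final = final,
                          base_mean = q, fit_type = fit_type,
                          coef = c(asympt_disp = min_disp, extra_pois = 0),
                          trend = list(fn = function(x) {
                            rep(min_disp, length(x))
                          }, grid = NULL),
                          min_disp = min_disp),
                     class = "dispersion_model"))
  }
  if (fit_type == "parametric") {
    cf <- fit_parametric_dispersion(q[usable], raw[usable])
    fitted <- rep(NA_real_, length(q))
    pos <- q > 0
    fitted[pos] <- cf[["asympt_disp"]] + cf[["extra_pois"]] / q[pos]
    trend <- NULL
  } else {
    loc <- fit_local_dispersion(q[usable], raw[usable], floor = min_disp)
    fitted <- rep(NA_real_, length(q))
    pos <- q > 0
    fitted[pos] <- loc$fn(q[pos])
    cf <- NULL
    trend <- loc
  }
  final <- pmax(pmax(raw, fitted), min_disp)
  final[q == 0] <- NA_real_
  structure(list(raw = raw, fitted = fitted, final = final, base_mean = q,
                 fit_type = fit_type, coef = cf, trend = trend,
                 min_disp = min_disp),
            class = "dispersion_model")
}

resolve_dispersions <- function(dispersions, n) {
  d <- if (inherits(dispersions, "dispersion_model")) dispersions$final
       else dispersions
  if (length(d) != n) stop("one dispersion per feature is required")
  d
}

#' Exact negative-binomial test for two conditions
#'
#' For each feature, the counts are summed within each condition (kA for the
#' first factor level, kB for the second). Conditioned on kA + kB, the
#' p-value is the probability of all splits (a, b) with a + b = kA + kB that
#' are at most as likely as the observed split, where a and b follow NB laws
#' with means q sA / q sB and variances q sA + alpha q^2 s2A (analogously
#' for B); q is the pooled mean of normalized counts, sA/sB the summed size
#' factors, s2A/s2B the summed squared size factors, alpha the feature's
#' shared dispersion. Features with zero counts in every sample get p = 1.
#'
#' @param counts features x samples matrix.
#' @param sf size factors.
#' @param dispersions a `dispersion_model` or a numeric vector of final
#'   per-feature dispersions.
#' @param conditions two-level factor (first level = baseline/control).
#' @return numeric vector of p-values.
#' @export
nbinom_test <- function(counts, sf, dispersions, conditions) {
  counts <- as.matrix(counts)
  conditions <- as.factor(conditions)
  if (nlevels(conditions) != 2) stop("exactly two conditions are required")
  disp <- resolve_dispersions(dispersions, nrow(counts))
  selA <- conditions == levels(conditions)[1]
  selB <- conditions == levels(conditions)[2]
  kA <- rowSums(counts[, selA, drop = FALSE])
  kB <- rowSums(counts[, selB, drop = FALSE])
  q <- rowMeans(normalized_counts(counts, sf))
  sA <- sum(sf[selA]); sB <- sum(sf[selB])
  s2A <- sum(sf[selA]^2); s2B <- sum(sf[selB]^2)
  muA <- q * sA; muB <- q * sB
  zero <- kA + kB == 0
  if (any(is.na(disp) & !zero)) {
    stop("dispersion missing for a tested feature")
  }
  fullVarA <- pmax(muA + disp * q^2 * s2A, muA * (1 + 1e-8))
  fullVarB <- pmax(muB + disp * q^2 * s2B, muB * (1 + 1e-8))
  sizeA <- muA^2 / (fullVarA - muA)
  sizeB <- muB^2 / (fullVarB - muB)
  pval <- rep(1, nrow(counts))
  for (i in which(!zero)) {
    ks <- 0:(kA[i] + kB[i])
    ps <- dnbinom(ks, mu = muA[i], size = sizeA[i]) *
      dnbinom(kA[i] + kB[i] - ks, mu = muB[i], size = sizeB[i])
    pobs <- ps[kA[i] + 1L]
    tot <- sum(ps)
    if (tot == 0) next
    pval[i] <- min(1, sum(ps[ps <= pobs * (1 + 1e-7)]) / tot)
  }
  pval
}

#' Fold changes and base means of normalized counts
#'
#' log2FoldChange is log2(case mean / control mean) of normalized counts;
#' a zero control mean with positive case mean gives +Inf, the reverse -Inf,
#' and 0/0 is reported as NA (undefined).
#'
#' @inheritParams nbinom_test
#' @return data.frame with `baseMean`, `baseMeanA` (control), `baseMeanB`
#'   (case) and `log2FoldChange`.
#' @export
fold_change <- function(counts, sf, conditions) {
  counts <- as.matrix(counts)
  conditions <- as.factor(conditions)
  norm <- normalized_counts(counts, sf)
  selA <- conditions == levels(conditions)[1]
  selB <- conditions == levels(conditions)[2]
  mA <- rowMeans(norm[, selA, drop = FALSE])
  mB <- rowMeans(norm[, selB, drop = FALSE])
  lfc <- ifelse(mA == 0 & mB == 0, NA_real_, log2(mB / mA))
  data.frame(baseMean = rowMeans(norm), baseMeanA = mA, baseMeanB = mB,
             log2FoldChange = lfc)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control; a thin validated front over the standard adjustment.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Full negative-binomial differential expression analysis
#'
#' Size factors, pooled maximum-sharing dispersions, exact NB test, fold
#' changes and BH adjustment in one call.
#'
#' @param counts features x samples matrix.
#' @param conditions two-level factor (first level = control).
#' @param fit_type dispersion fit type (`"parametric"` for compact feature
#'   sets such as miRNAs, `"local"` for large contig sets).
#' @param sf optional precomputed size factors.
#' @return data.frame with `id`, `baseMean`, `log2FoldChange`, `pvalue`,
#'   `padj`; the dispersion model and size factors are attached as
#'   attributes `dispersion_model` and `size_factors`.
#' @export
nbinom_de <- function(counts, conditions,
                      fit_type = c("parametric", "local"), sf = NULL) {
  fit_type <- match.arg(fit_type)
  counts <- as.matrix(counts)
  conditions <- as.factor(conditions)
  if (is.null(sf)) sf <- size_factors(counts)
  model <- estimate_dispersions(counts, sf, conditions, fit_type = fit_type)
  p <- nbinom_test(counts, sf, model, conditions)
  fc <- fold_change(counts, sf, conditions)
  res <- data.frame(id = rownames(counts) %||% seq_len(nrow(counts)),
                    baseMean = fc$baseMean,
                    log2FoldChange = fc$log2FoldChange,
                    pvalue = p, padj = bh_adjust(p),
                    stringsAsFactors = FALSE)
  attr(res, "dispersion_model") <- model
  attr(res, "size_factors") <- sf
  res
}

#' Select significant features
#'
#' Features with adjusted p strictly below the threshold, ordered by
#' adjusted p ascending and |log2FoldChange| descending.
#'
#' @param results a [nbinom_de()] result.
#' @param alpha significance threshold (strict inequality).
#' @param on `"padj"` (default) or `"pvalue"`.
#' @return subset of `results`, reordered.
#' @export
filter_significant <- function(results, alpha = 1e-6,
                               on = c("padj", "pvalue")) {
  on <- match.arg(on)
  sel <- !is.na(results[[on]]) & results[[on]] < alpha
  sub <- results[sel, , drop = FALSE]
  ab <- abs(sub$log2FoldChange)
  ab[is.na(ab)] <- -Inf
  sub[order(sub[[on]], -ab), , drop = FALSE]
}

#' Variance-stabilizing transformation
#'
#' Transforms normalized counts with the monotone map obtained by
#' integrating 1 / sqrt(q + a1 q + a0 q^2) under the fitted mean-dispersion
#' trend. For the parametric fit the integral has a closed form that
#' converges to log2 for large counts; for the local fit the integral is
#' evaluated by quadrature on a log-spaced grid and anchored to log2 at the
#' high-count end.
#'
#' @param counts features x samples count matrix.
#' @param model a `dispersion_model` from [estimate_dispersions()].
#' @param sf size factors (recomputed from `counts` when omitted).
#' @return matrix of variance-stabilized values on the log2-like scale.
#' @export
vst <- function(counts, model, sf = NULL) {
  if (!inherits(model, "dispersion_model")) {
    stop("a fitted dispersion_model is required")
  }
  counts <- as.matrix(counts)
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- normalized_counts(counts, sf)
  if (model$fit_type == "parametric") {
    a0 <- max(model$coef[["asympt_disp"]], 1e-12)
    a1 <- model$coef[["extra_pois"]]
    tr <- function(q) {
      log((1 + a1 + 2 * a0 * q +
             2 * sqrt(a0 * q * (1 + a1 + a0 * q))) / (4 * a0)) / log(2)
    }
    out <- tr(norm)
  } else {
    qmax <- max(norm, 1)
    grid <- exp(seq(log(1e-3), log(qmax * 1.05), length.out = 2048L))
    alpha <- model$trend$fn(grid)
    integrand <- 1 / sqrt(grid + alpha * grid^2)
    cum <- c(0, cumsum(diff(grid) * (head(integrand, -1) +
                                       integrand[-1]) / 2)) / log(2)
    f <- approxfun(grid, cum, rule = 2)
    offset <- log2(qmax) - f(qmax)
    out <- matrix(f(pmax(norm, min(grid))) + offset, nrow = nrow(norm))
  }
  dimnames(out) <- dimnames(norm)
  out
}
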