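# Delta-delta-CT relative quantification of qPCR validation assays.

#' Relative quantification by the 2^-ddCT method
#'
#' Replicate CT values are averaged arithmetically per (sample, assay).
#' Per sample, dCT = CT_target - CT_control (endogenous control assay);
#' ddCT = dCT_sample - dCT_reference (calibrator sample); RQ = 2^-ddCT, so
#' the reference sample always has RQ = 1 for every assay. A mean CT above
#' the cutoff is regarded as negative (no RQ); with
#' `cutoff_on = "replicate"` a single replicate above the cutoff already
#' marks the measurement negative.
#'
#' @param ct long-format table with columns `sample`, `assay`, `ct` (cycles)
#'   and optionally `replicate`.
#' @param reference_sample calibrator sample id (RQ = 1).
#' @param control_assay endogenous control assay id.
#' @param ct_cutoff CT value above which a measurement is negative.
#' @param cutoff_on apply the cutoff to the replicate `"mean"` (default) or
#'   to individual replicates.
#' @return data.frame with one row per (sample, target assay): `sample`,
#'   `assay`, `mean_ct`, `delta_ct`, `delta_delta_ct`, `rq`, `negative`.
#' @export
relative_quantification <- function(ct, reference_sample,
                                    control_assay = "RNU6B",
                                    ct_cutoff = 35,
                                    cutoff_on = c("mean", "replicate")) {
  cutoff_on <- match.arg(cutoff_on)
  stopifnot(all(c("sample", "assay", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("CT values must be positive")
  if (!reference_sample %in% ct$sample) {
    stop("reference sample '", reference_sample, "' not present in CT table")
  }
  if (!control_assay %in% ct$assay) {
    stop("endogenous control assay '", control_assay, "' not in CT table")
  }
  agg <- aggregate(ct ~ sample + assay, data = ct, FUN = mean)
  names(agg)[3] <- "mean_ct"
  over <- aggregate(ct ~ sample + assay, data = ct,
                    FUN = function(x) any(x > ct_cutoff))
  agg$negative <- if (cutoff_on == "mean") agg$mean_ct > ct_cutoff else
    over$ct[match(paste(agg$sample, agg$assay),
                  paste(over$sample, over$assay))]

  ctrl <- agg[agg$assay == control_assay, ]
  targets <- agg[agg$assay != control_assay, ]
  miss <- setdiff(unique(targets$sample), ctrl$sample)
  if (length(miss) > 0) {
    warning("no endogenous control measured for sample(s): ",
            paste(miss, collapse = ", "), "; their assays are undefined")
  }
  targets$delta_ct <- targets$mean_ct -
    ctrl$mean_ct[match(targets$sample, ctrl$sample)]
  ref <- targets[targets$sample == reference_sample, ]
  targets$delta_delta_ct <- targets$delta_ct -
    ref$delta_ct[match(targets$assay, ref$assay)]
  targets$rq <- 2^(-targets$delta_delta_ct)
  targets$rq[targets$negative] <- NA_real_
  targets$delta_delta_ct[targets$negative] <- NA_real_
  rownames(targets) <- NULL
  targets[, c("sample", "assay", "mean_ct", "delta_ct", "delta_delta_ct",
              "rq", "negative")]
}
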