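# End-to-end orchestration: simulate -> signatures -> contigs -> classify ->
# count -> differential expression -> report, as one reproducible run driven
# by a single config with a JSON manifest.

#' Default pipeline configuration
#'
#' All stage parameters in one nested list; round-trips losslessly through
#' YAML. Thresholds default to the published settings: significance at
#' adjusted p < 1e-6 and volcano flags at p < 1e-8 with |log2FC| > 5.
#'
#' @param outdir run directory.
#' @param seed master seed for every source of randomness in the run.
#' @param depth expected reads per sample.
#' @param n_normal,n_tumor,n_cis design sizes.
#' @param genome named list of [genome_spec()] overrides.
#' @param contigs named list of [contig_params()] overrides.
#' @param significance_alpha adjusted-p threshold for significance calls.
#' @param volcano_sig_padj,volcano_sig_lfc volcano flag thresholds.
#' @param top_n_contigs,top_n_mirna heatmap feature-set sizes.
#' @param simulate set to `FALSE` to skip simulation and start from
#'   user-supplied read files (`reads_dir` with `<sample_id>.tsv` files and a
#'   `design.tsv`).
#' @param reads_dir directory of pre-existing read files when
#'   `simulate = FALSE`.
#' @return nested configuration list.
#' @export
default_run_config <- function(outdir = "smallrna_run", seed = 1L,
                               depth = 1e5, n_normal = 12L, n_tumor = 10L,
                               n_cis = 0L, genome = list(),
                               contigs = list(),
                               significance_alpha = 1e-6,
                               volcano_sig_padj = 1e-8, volcano_sig_lfc = 5,
                               top_n_contigs = 2000L, top_n_mirna = 100L,
                               simulate = TRUE, reads_dir = NULL) {
  list(outdir = outdir, seed = as.integer(seed),
       simulate = simulate, reads_dir = reads_dir,
       design = list(n_normal = n_normal, n_tumor = n_tumor, n_cis = n_cis),
       depth = depth, genome = genome, contigs = contigs,
       thresholds = list(significance_alpha = significance_alpha,
                         volcano_sig_padj = volcano_sig_padj,
                         volcano_sig_lfc = volcano_sig_lfc),
       report = list(top_n_contigs = top_n_contigs,
                     top_n_mirna = top_n_mirna))
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @param config configuration list.
#' @return the configuration list / the path.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full small RNA analysis pipeline
#'
#' Executes simulation (or ingestion of user-supplied reads), signature
#' profiling, contig construction, classification, counting, differential
#' expression of contigs (local dispersion fit) and miRNAs (parametric fit),
#' clustering/volcano reporting and, when ground truth is available, a
#' truth-recovery report. All stage outputs are plain text in `outdir`; a
#' JSON manifest records parameters, seeds and file checksums, so a rerun
#' with the same config is byte-identical.
#'
#' @param config a configuration list from [default_run_config()] /
#'   [read_run_config()], or the path to a YAML config.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- simulate -----------------------------------------------------------
  if (isTRUE(config$simulate)) {
    exp_data <- stage("simulate", {
      spec <- do.call(genome_spec,
                      utils::modifyList(list(seed = config$seed),
                                        config$genome %||% list()))
      design <- default_design(config$design$n_normal, config$design$n_tumor,
                               config$design$n_cis %||% 0L)
      params <- list(normal = normal_params(depth = config$depth),
                     tumor = tumor_params(depth = config$depth),
                     cis = cis_params(depth = config$depth))
      simulate_experiment(design, params, seed = config$seed, spec = spec)
    })
    stage("write_inputs", {
      write_genome_fasta(exp_data$genome, file.path(out, "genome.fa"))
      write_tracks_bed(exp_data$genome, file.path(out, "tracks"))
      dir.create(file.path(out, "reads"), showWarnings = FALSE)
      for (id in names(exp_data$samples)) {
        write_alignments(exp_data$samples[[id]],
                         file.path(out, "reads", paste0(id, ".tsv")))
      }
      write_tsv(exp_data$truth, file.path(out, "truth.tsv"))
      write_tsv(exp_data$design, file.path(out, "design.tsv"))
    })
    samples <- exp_data$samples
    design <- exp_data$design
    tracks <- exp_data$genome$tracks
    truth <- exp_data$truth
  } else {
    if (is.null(config$reads_dir)) {
      stop("simulate = FALSE requires reads_dir")
    }
    design <- stage("load_design", {
      read.delim(file.path(config$reads_dir, "design.tsv"),
                 stringsAsFactors = FALSE)
    })
    samples <- stage("load_reads", {
      s <- lapply(design$sample_id, function(id) {
        read_alignments(file.path(config$reads_dir, "reads",
                                  paste0(id, ".tsv")))
      })
      names(s) <- design$sample_id
      s
    })
    tracks <- lapply(Sys.glob(file.path(config$reads_dir, "tracks", "*.bed")),
                     read_track_bed)
    names(tracks) <- sub("\\.bed$", "",
                         basename(Sys.glob(file.path(config$reads_dir,
                                                     "tracks", "*.bed"))))
    truth <- NULL
  }

  # --- signatures ---------------------------------------------------------
  stage("signatures", {
    hist_tab <- do.call(rbind, lapply(names(samples), function(id) {
      h <- length_histogram(samples[[id]], normalize = TRUE)
      cbind(sample = id, h)
    }))
    write_tsv(hist_tab, file.path(out, "length_histogram.tsv"))
    write_tsv(group_signature_table(samples, design),
              file.path(out, "signature_fractions.tsv"))
    logo <- do.call(rbind, lapply(c(30L, 33L), function(L) {
      pr <- try(positional_profile(samples[design$sample_id[
        design$group == design$group[1]]], L), silent = TRUE)
      if (inherits(pr, "try-error")) return(NULL)
      data.frame(length = L, position = seq_along(pr$entropy),
                 t(pr$freq), H = pr$entropy, IC = pr$ic)
    }))
    if (!is.null(logo)) write_tsv(logo, file.path(out, "logo_matrices.tsv"))
  })

  # --- contigs ------------------------------------------------------------
  cpar <- do.call(contig_params, config$contigs %||% list())
  contigs <- stage("contigs", build_contigs(samples, cpar))
  stage("write_contigs", {
    write_contigs_bed(contigs, file.path(out, "contigs.bed"))
    write_tsv(contig_summary(contigs), file.path(out, "contig_summary.tsv"))
    if (!is.null(tracks$pirna_cluster)) {
      write_tsv(overlap_report(contigs, tracks$pirna_cluster),
                file.path(out, "pirna_overlap_report.tsv"))
    }
  })

  # --- classification -----------------------------------------------------
  stage("classify", {
    write_tsv(class_composition(samples, design, tracks),
              file.path(out, "class_composition.tsv"))
  })

  # --- counting -----------------------------------------------------------
  counts_contig <- stage("count_contigs", {
    win <- lapply(samples, function(g) {
      g[width(g) >= cpar$min_read_len & width(g) <= cpar$max_read_len]
    })
    count_reads(contigs, win)
  })
  counts_mirna <- stage("count_mirna", {
    if (is.null(tracks$mirna) || length(tracks$mirna) == 0) NULL else
      count_reads(tracks$mirna, samples)
  })
  stage("write_counts", {
    write_count_matrix(counts_contig, file.path(out, "contig_counts.tsv"))
    if (!is.null(counts_mirna)) {
      write_count_matrix(counts_mirna, file.path(out, "mirna_counts.tsv"))
    }
  })

  # --- differential expression -------------------------------------------
  cond <- factor(design$condition, levels = c("control", "case"))
  alpha <- config$thresholds$significance_alpha
  de_contig <- stage("de_contigs", nbinom_de(counts_contig, cond,
                                             fit_type = "local"))
  de_mirna <- if (!is.null(counts_mirna)) {
    stage("de_mirna", nbinom_de(counts_mirna, cond, fit_type = "parametric"))
  }
  stage("write_de", {
    write_de_table(de_contig, file.path(out, "de_contigs.tsv"))
    if (!is.null(de_mirna)) {
      write_de_table(de_mirna, file.path(out, "de_mirna.tsv"))
    }
  })

  # --- reporting ----------------------------------------------------------
  stage("report", {
    vmat <- vst(counts_contig, attr(de_contig, "dispersion_model"),
                attr(de_contig, "size_factors"))
    topc <- top_n_features(vmat, min(config$report$top_n_contigs, nrow(vmat)))
    hc <- cluster_samples(vmat, topc)
    writeLines(dendrogram_newick(hc), file.path(out, "contig_dendrogram.nwk"))
    hm <- heatmap_data(vmat, topc, hc)
    write_count_matrix(round(hm, 6), file.path(out, "contig_vst_heatmap.tsv"))
    write_tsv(volcano_table(de_contig,
                            config$thresholds$volcano_sig_padj,
                            config$thresholds$volcano_sig_lfc),
              file.path(out, "contig_volcano.tsv"))
    if (!is.null(de_mirna)) {
      vmir <- vst(counts_mirna, attr(de_mirna, "dispersion_model"),
                  attr(de_mirna, "size_factors"))
      topm <- top_n_features(vmir, min(config$report$top_n_mirna, nrow(vmir)))
      hcm <- cluster_samples(vmir, topm)
      writeLines(dendrogram_newick(hcm),
                 file.path(out, "mirna_dendrogram.nwk"))
      write_tsv(volcano_table(de_mirna,
                              config$thresholds$volcano_sig_padj,
                              config$thresholds$volcano_sig_lfc),
                file.path(out, "mirna_volcano.tsv"))
    }
    if (!is.null(truth) && !is.null(de_mirna) &&
        "log2fc" %in% names(truth)) {
      write_tsv(truth_recovery(de_mirna, de_contig, contigs, truth,
                               tracks, alpha),
                file.path(out, "truth_recovery.tsv"))
    }
  })

  # --- manifest -----------------------------------------------------------
  files <- sort(setdiff(list.files(out, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    package = "smallRNAtlas",
    version = as.character(packageVersion("smallRNAtlas")),
    seed = config$seed,
    config = config,
    files = lapply(setNames(files, files), function(f) {
      unname(tools::md5sum(file.path(out, f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

write_de_table <- function(res, file) {
  out <- res
  out$log2FoldChange <- ifelse(
    is.infinite(out$log2FoldChange),
    ifelse(out$log2FoldChange > 0, "Inf", "-Inf"),
    format(out$log2FoldChange, digits = 8, trim = TRUE)
  )
  write_tsv(out, file)
}

# Sensitivity / false-discovery summary against the simulation ground truth.
truth_recovery <- function(de_mirna, de_contig, contigs, truth, tracks,
                           alpha = 1e-6) {
  sig_mir <- filter_significant(de_mirna, alpha)
  up_true <- truth$feature_id[truth$class == "mirna" &
                                is.finite(truth$log2fc) & truth$log2fc > 1]
  up_true <- union(up_true, truth$feature_id[truth$class == "mirna" &
                                               is.infinite(truth$log2fc) &
                                               truth$log2fc > 0])
  mir_tp <- sum(sig_mir$id %in% up_true)
  sig_con <- filter_significant(de_contig, alpha)
  affected <- tracks$pirna_cluster
  if (!is.null(tracks$`repeat`)) affected <- c(affected, tracks$`repeat`)
  con_sig_idx <- match(sig_con$id, mcols(contigs)$contig_id)
  con_tp <- sum(overlapsAny(contigs[con_sig_idx], affected,
                            ignore.strand = TRUE))
  data.frame(
    metric = c("mirna_true_up", "mirna_recovered", "mirna_false_positives",
               "contig_significant", "contig_significant_pirna_population"),
    value = c(length(up_true), mir_tp, nrow(sig_mir) - mir_tp,
              nrow(sig_con), con_tp)
  )
}
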