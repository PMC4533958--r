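simple_tracks <- function() {
  list(
    mirna = make_gr(data.frame(chrom = "chr1", start = 100, end = 180,
                               strand = "+")),
    trna = make_gr(data.frame(chrom = "chr1", start = 300, end = 374,
                              strand = "+")),
    pirna_cluster = make_gr(data.frame(chrom = "chr1", start = 500,
                                       end = 1500, strand = "+")),
    `repeat` = make_gr(data.frame(chrom = "chr1", start = c(1400, 2000),
                                  end = c(1700, 2300), strand = "+")),
    exon = make_gr(data.frame(chrom = "chr1", start = 3000, end = 3400,
                              strand = "+"))
  )
}

test_that("reads get the highest-precedence overlapping class, else unannotated", {
  tr <- simple_tracks()
  reads <- make_gr(data.frame(
    chrom = "chr1",
    start = c(110, 600, 1450, 5000, 3100),
    end = c(131, 629, 1479, 5021, 3121),
    strand = "+"
  ))
  lab <- classify_reads(reads, tr)
  expect_equal(lab, c("mirna", "pirna_cluster", "pirna_cluster",
                      "unannotated", "exon"))
  # flipping precedence flips only the dual-overlap read
  cfg <- class_config(precedence = c("mirna", "trna", "repeat",
                                     "pirna_cluster", "exon"))
  lab2 <- classify_reads(reads, tr, cfg)
  expect_equal(lab2[3], "repeat")
  expect_equal(lab2[-3], lab[-3])
})

test_that("precedence sensitivity is confined to multi-overlap reads", {
  tr <- simple_tracks()
  set.seed(4)
  st <- sample(50:3500, 200, replace = TRUE)
  reads <- make_gr(data.frame(chrom = "chr1", start = st, end = st + 27,
                              strand = "+"))
  a <- classify_reads(reads, tr)
  b <- classify_reads(reads, tr,
                      class_config(precedence = rev(c("mirna", "trna",
                                                      "pirna_cluster",
                                                      "repeat", "exon"))))
  differs <- a != b
  n_over <- sapply(names(tr), function(cl) {
    overlapsAny(reads, tr[[cl]], ignore.strand = cl != "trna")
  })
  multi <- rowSums(n_over) > 1
  expect_true(all(differs <= multi))  # label changes only on multi-overlaps
  expect_true(any(multi))
})

test_that("length windows are validated, disjoint and exhaustive", {
  cfg <- class_config()
  w <- assign_window(18:36, cfg)
  expect_false(any(is.na(w)))
  expect_equal(unname(table(w)[c("short", "mid", "long")]),
               c(7L, 7L, 5L), ignore_attr = TRUE)
  expect_true(is.na(assign_window(37, cfg)))
  expect_error(class_config(windows = list(short = c(18, 25),
                                           mid = c(25, 31),
                                           long = c(32, 36))),
               "disjoint")
})

test_that("class composition fractions sum to one per group and window", {
  g <- make_genome(tiny_spec(seed = 41))
  des <- default_design(2, 2)
  ex <- simulate_experiment(
    des, list(normal = normal_params(depth = 8000),
              tumor = tumor_params(depth = 8000)),
    seed = 42, genome = g
  )
  comp <- class_composition(ex$samples, ex$design, g$tracks)
  sums <- aggregate(fraction ~ group + window, data = comp, FUN = sum)
  expect_true(all(abs(sums$fraction - 1) < 1e-9))
})

test_that("tRNA reads dominate the long window and piRNA loss shows mid-window", {
  g <- make_genome(tiny_spec(seed = 43))
  des <- default_design(3, 3)
  ex <- simulate_experiment(
    des, list(normal = normal_params(depth = 3e4),
              tumor = tumor_params(depth = 3e4)),
    seed = 44, genome = g
  )
  comp <- class_composition(ex$samples, ex$design, g$tracks)
  long_trna <- comp$fraction[comp$group == "normal" & comp$window == "long" &
                               comp$class == "trna"]
  expect_lt(abs(long_trna - 0.9), 0.05)

  # the piRNA loss shows as a drop in the average mid-window read count per
  # sample (the generator keeps window composition fixed, so the loss is in
  # absolute abundance rather than in the within-window fractions)
  mid_pir <- function(grp) {
    sum(comp$mean_per_sample[comp$group == grp & comp$window == "mid" &
                               comp$class %in% c("pirna_cluster", "repeat")])
  }
  expect_gt(mid_pir("normal"), 8 * mid_pir("tumor"))
})

test_that("class labels agree with the simulation ground truth", {
  g <- make_genome(tiny_spec(seed = 45))
  s <- simulate_sample(g, normal_params(depth = 2e4), seed = 46)
  lab <- classify_reads(s, g$tracks)
  truth <- mcols(s)$true_class
  truth[truth %in% c("trna_half", "trf")] <- "trna"
  truth[truth == "other"] <- "unannotated"
  expect_gte(mean(lab == truth), 0.99)
})

test_that("tRNA fragments are typed by length and end of origin", {
  gene <- make_gr(data.frame(chrom = "chr1", start = 1001, end = 1075,
                             strand = "+"))
  mcols(gene)$feature_id <- "trna_0001"
  rd <- function(start, len) {
    make_gr(data.frame(chrom = "chr1", start = start,
                       end = start + len - 1, strand = "+"))
  }
  expect_equal(type_trna_fragment(rd(1001, 20), gene)$fragment_type, "tRF")
  expect_equal(type_trna_fragment(rd(1001, 20), gene)$origin_end, "5prime")
  t33 <- type_trna_fragment(rd(1001, 33), gene)
  expect_equal(t33$fragment_type, "tRNA_half")
  expect_equal(t33$origin_end, "5prime")
  expect_equal(type_trna_fragment(rd(1001, 26), gene)$fragment_type,
               "ambiguous")
  # within the 2 nt tolerance still a 5' call; 3 nt away no longer
  expect_equal(type_trna_fragment(rd(1003, 20), gene)$origin_end, "5prime")
  expect_equal(type_trna_fragment(rd(1004, 20), gene)$origin_end, "internal")
  # a read ending at the gene 3' end
  expect_equal(type_trna_fragment(rd(1056, 20), gene)$origin_end, "3prime")

  # minus-strand gene: the 5' end is the right-hand boundary
  gene_m <- make_gr(data.frame(chrom = "chr1", start = 1001, end = 1075,
                               strand = "-"))
  mcols(gene_m)$feature_id <- "trna_0002"
  r5m <- make_gr(data.frame(chrom = "chr1", start = 1056, end = 1075,
                            strand = "-"))
  expect_equal(type_trna_fragment(r5m, gene_m)$origin_end, "5prime")

  expect_error(type_trna_fragment(rd(5000, 20), gene), "must overlap")
})

test_that("simulated tRNA-derived reads are 5'-end derived halves and tRFs", {
  g <- make_genome(tiny_spec(seed = 47))
  s <- simulate_sample(g, normal_params(depth = 2e4), seed = 48)
  tr <- s[mcols(s)$true_class %in% c("trna_half", "trf")]
  ty <- type_trna_fragment(tr, g$tracks$trna)
  expect_true(all(ty$origin_end == "5prime"))
  half <- mcols(tr)$true_class == "trna_half"
  expect_true(all(ty$fragment_type[half] == "tRNA_half"))
  expect_true(all(ty$fragment_type[!half] %in% c("tRF", "ambiguous")))
})
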