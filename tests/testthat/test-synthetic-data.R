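test_that("hairpin precursors are palindromic stems with controlled bulges", {
  mat <- "ACGUACGUACGUACGUACGU"
  p <- make_hairpin_precursor(mat, loop_len = 6, n_bulges = 0, seed = 1)
  expect_equal(nchar(p), 46)
  arm5 <- substr(p, 1, 20)
  arm3 <- substr(p, 27, 46)
  expect_identical(arm5, mat)
  expect_identical(arm3, revcomp(mat))

  p2 <- make_hairpin_precursor(mat, loop_len = 6, n_bulges = 2, seed = 1)
  arm3b <- strsplit(substr(p2, 27, 46), "")[[1]]
  expect_equal(sum(arm3b != strsplit(revcomp(mat), "")[[1]]), 2)

  expect_error(make_hairpin_precursor(mat, loop_len = 2), "invalid loop")
})

test_that("a bulge-free precursor refolds into a full-length stem", {
  set.seed(5)
  for (i in 1:3) {
    mat <- random_rna(20)
    p <- make_hairpin_precursor(mat, loop_len = 6, n_bulges = 0)
    expect_equal(fold_nussinov(p)$pair_count, nchar(mat))
  }
})

test_that("make_genome embeds every planted precursor at its truth locus", {
  cfg <- tiny_config(seed = 103L)
  sim <- make_genome(cfg)
  tm <- sim$truth$mirnas
  expect_equal(nrow(tm), cfg$n_known_mirnas + cfg$n_novel_mirnas)
  for (i in seq_len(nrow(tm))) {
    seg <- substr(sim$genome[[tm$chrom[i]]], tm$start[i], tm$end[i])
    if (tm$strand[i] == "-") seg <- revcomp(seg)
    expect_identical(dna_to_rna(seg), tm$precursor_seq[i])
    ## mature is an exact substring of the precursor on its strand
    expect_true(grepl(tm$mature_seq[i], dna_to_rna(seg), fixed = TRUE))
  }
  ## truth loci do not overlap each other or the decoy masks
  gr <- GenomicRanges::GRanges(tm$chrom,
                               IRanges::IRanges(tm$start, tm$end))
  mk <- GenomicRanges::GRanges(sim$mask$chrom,
                               IRanges::IRanges(sim$mask$start,
                                                sim$mask$end))
  expect_equal(sum(GenomicRanges::countOverlaps(gr, gr)), nrow(tm))
  expect_equal(sum(GenomicRanges::countOverlaps(gr, mk)), 0)
})

test_that("identical configs give byte-identical outputs", {
  cfg <- tiny_config(seed = 104L)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_all(cfg, d1)
  simulate_all(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("a genome too small for the planted features is rejected", {
  expect_error(make_genome(tiny_config(seed = 1L, chrom_length = 500L)),
               "capacity")
})

test_that("each sample FASTQ holds exactly `depth` reads", {
  run <- tiny_noise_run()
  for (fq in run$sim$files$fastq) {
    expect_equal(length(readLines(fq)) / 4L, 800)
  }
})

test_that("with zero background every clean read comes from a truth locus", {
  run <- tiny_zn_run()
  matures <- rna_to_dna(run$sim$truth$mirnas$mature_seq)
  cat <- run$run$catalog
  expect_true(all(cat$tags$seq %in% matures))
})

test_that("planted tissue fold-changes appear in the read counts", {
  cfg <- zero_noise_config(tiny_config(seed = 105L, depth = 20000L))
  sim <- make_genome(cfg)
  reads <- simulate_reads(cfg, sim)
  tm <- sim$truth$mirnas
  de <- tm[!is.na(tm$de_tissue) & tm$de_tissue == "TW", ][1, ]
  n_tw <- sum(substr(reads[["TW1"]]$seq, 1, nchar(de$mature_seq)) ==
                rna_to_dna(de$mature_seq))
  n_nw <- sum(substr(reads[["NW1"]]$seq, 1, nchar(de$mature_seq)) ==
                rna_to_dna(de$mature_seq))
  expect_gt(n_tw / n_nw, 4 * 0.75)
  expect_lt(n_tw / n_nw, 4 * 1.25)
})

test_that("noiseless expression is exactly anti-correlated with abundance", {
  cfg <- zero_noise_config(tiny_config(seed = 106L))
  sim <- simulate_expression(cfg, make_genome(cfg))
  tg <- sim$truth$targets
  for (i in seq_len(nrow(tg))) {
    r <- cor(sim$expr[tg$gene_id[i], ], sim$truth$abund[tg$mirna_id[i], ])
    expect_equal(r, -1, tolerance = 1e-12)
  }
})

test_that("default noise keeps planted pairs below the r <= -0.8 line", {
  ## the generator's noise scale is tuned so planted pairs survive the
  ## anti-correlation filter in at least 90% of cases
  emp <- unlist(lapply(301:305, function(s) {
    cfg <- tiny_config(seed = s)
    sim <- simulate_expression(cfg, make_genome(cfg))
    sim$truth$targets$empirical_r
  }))
  expect_gte(mean(emp <= -0.8), 0.9)
})

test_that("the planted pathway is enriched among network genes", {
  run <- tiny_zn_run()
  sim <- run$sim
  net_genes <- unique(c(sim$truth$targets$gene_id, sim$truth$tf_edges$gene))
  enr <- enrich_pathways(net_genes, rownames(sim$expr), sim$pathway_map)
  expect_identical(enr$pathway_id[1], sim$truth$enriched_pathway)
  expect_lt(enr$p_value[1], 0.05)
  ## cross-check against the enumeration oracle
  row <- enr[enr$pathway_id == sim$truth$enriched_pathway, ]
  expect_equal(row$p_value,
               oracle_hyper_p(row$k, row$K, row$n, row$N),
               tolerance = 1e-12)
})

test_that("Ct tables invert to planted fold-changes at zero noise", {
  run <- tiny_zn_run()
  sim <- run$sim
  ct <- sim$ct_table
  tm <- sim$truth$mirnas
  de <- tm[!is.na(tm$de_tissue) & tm$de_tissue == "TW", ][1, ]
  g <- ct[ct$gene_id == de$mirna_id & ct$replicate == 1, ]
  ref <- ct[ct$is_reference & ct$replicate == 1, ]
  rel <- delta_delta_ct(g$ct[g$sample_id == "TW1"],
                        ref$ct[ref$sample_id == "TW1"],
                        g$ct[g$sample_id == "NW1"],
                        ref$ct[ref$sample_id == "NW1"])
  expect_equal(rel, 4, tolerance = 1e-9)
})
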