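mk_readset <- function(seqs, quals = NULL, sample_id = "s1") {
  if (is.null(quals)) {
    quals <- vapply(nchar(seqs),
                    function(n) paste(rep("I", n), collapse = ""),
                    character(1))  # Phred 40
  }
  rs <- data.frame(read_id = paste0("r", seq_along(seqs)), seq = seqs,
                   qual = quals, stringsAsFactors = FALSE)
  attr(rs, "sample_id") <- sample_id
  rs
}

adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("phred transform matches its definition", {
  expect_equal(phred_q(0.01), 20)
  expect_equal(phred_q(1), 0)
  expect_equal(phred_q(0.001), 30)
  expect_error(phred_q(0), "error_ratio")
  expect_error(phred_q(-0.1), "error_ratio")
})

test_that("read cleaning applies the trim, length, N and tail-Q rules", {
  insert20 <- strrep("AC", 10)
  insert17 <- substr(insert20, 1, 17)
  with_n <- paste0("NNN", substr(insert20, 4, 20))      # 3 N in 20 (15%)
  raw <- mk_readset(paste0(c(insert20, insert17, with_n), adapter))
  out <- clean_reads(raw, adapter)
  expect_identical(out$reads$seq, insert20)  # 17-nt and N-rich discarded
  expect_equal(out$stats$raw_reads, 3)
  expect_equal(out$stats$clean_reads, 2)     # N filter hits 'clean' too
  expect_equal(out$stats$total_srna, 1)      # length filter

  ## low 3'-tail quality discards an otherwise good read
  lowq <- paste0(strrep("I", 17), "(((")     # last 3 bases Q7
  raw2 <- mk_readset(insert20, quals = lowq)
  out2 <- clean_reads(raw2, adapter)
  expect_equal(out2$stats$clean_reads, 0)
  expect_error(clean_reads(raw2, "XYZ"), "adapter")
})

test_that("cleaning accounting is exact: clean + discarded = raw", {
  run <- tiny_noise_run()
  st <- run$run$stats
  expect_true(all(st$clean_reads <= st$raw_reads))
  expect_true(all(st$total_srna <= st$clean_reads))
  expect_true(all(st$mapped_srna <= st$total_srna))
  ## stored percentage reproduces the recomputed one
  expect_equal(st$mapping_ratio,
               round(st$mapped_srna / st$total_srna * 100, 2))
})

test_that("exact mapper agrees with naive substring search", {
  set.seed(42)
  genome <- c(chrA = random_dna(5000), chrB = random_dna(5000))
  tags <- c(vapply(1:30, function(i) random_dna(20), character(1)),
            substr(genome[["chrA"]], 101, 121),     # planted forward
            revcomp(substr(genome[["chrB"]], 201, 222)))  # planted reverse
  cleaned <- mk_readset(tags)
  cat <- collapse_and_map(cleaned, genome)
  for (i in seq_len(nrow(cat$tags))) {
    got <- cat$loci[cat$loci$tag_id == cat$tags$tag_id[i],
                    c("chrom", "start", "end", "strand")]
    rownames(got) <- NULL
    want <- oracle_locate(cat$tags$seq[i], genome)
    rownames(want) <- NULL
    expect_equal(got, want, info = cat$tags$seq[i])
  }
  ## unmapped tag flagged with zero loci
  novel <- strrep("ACGT", 5)
  cat2 <- collapse_and_map(mk_readset(novel), genome)
  expect_true(cat2$tags$unmapped[cat2$tags$seq == novel])
  expect_error(collapse_and_map(cleaned, character(0)), "empty genome")
})

test_that("masking removes fully-annotated tags and is idempotent", {
  run <- tiny_zn_run()
  sim <- run$sim
  genome <- sim$genome
  ## construct tags: one inside a decoy tRNA, one mature (unmasked)
  decoy <- sim$mask[sim$mask$type == "tRNA", ][1, ]
  t_in <- substr(genome[[decoy$chrom]], decoy$start + 10,
                 decoy$start + 30)
  t_out <- rna_to_dna(sim$truth$mirnas$mature_seq[1])
  cat <- collapse_and_map(mk_readset(c(t_in, t_out)), genome)
  mask <- read_mask(sim$files$annotation,
                    types = c("rRNA", "tRNA", "snoRNA"))
  masked <- mask_annotated(cat, mask)
  expect_false(t_in %in% masked$tags$seq)
  expect_true(t_out %in% masked$tags$seq)
  ## idempotent
  again <- mask_annotated(masked, mask)
  expect_identical(again$tags, masked$tags)
  ## empty mask is the identity
  expect_identical(mask_annotated(cat, NULL)$tags, cat$tags)
})

test_that("a tag with one masked and one unmasked locus is retained", {
  ## same 20-mer planted inside a masked interval and in open sequence
  set.seed(7)
  tag <- random_dna(20)
  genome <- c(chr1 = paste0(random_dna(100), tag, random_dna(100),
                            tag, random_dna(100)))
  cat <- collapse_and_map(mk_readset(tag), genome)
  expect_equal(nrow(cat$loci), 2)
  mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(90, 130))
  masked <- mask_annotated(cat, mask)
  expect_true(tag %in% masked$tags$seq)
  expect_equal(nrow(masked$loci), 1)   # masked locus dropped
})

test_that("length and first-base profiles are proper distributions", {
  run <- tiny_noise_run()
  cat <- run$run$catalog
  lp <- length_profile(cat)
  expect_equal(sum(lp), 1, tolerance = 1e-12)
  ## generator centers mature lengths on 21 nt
  expect_equal(names(which.max(lp)), "21")

  fb <- first_base_profile(cat)
  rs <- rowSums(fb)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
  expect_identical(colnames(fb), c("A", "C", "G", "U"))

  only21 <- mk_readset(c(paste0("T", strrep("AG", 10)),
                         paste0("T", strrep("GC", 10))))
  cat21 <- collapse_and_map(only21, c(chr1 = random_dna(500)))
  expect_equal(unname(length_profile(cat21)["21"]), 1)
  expect_equal(unname(first_base_profile(cat21)["21", "U"]), 1)
})

test_that("simulated miRNAs start with U at the configured frequency", {
  cfg <- tiny_config(seed = 301L, n_novel_mirnas = 30L, n_known_mirnas = 0L,
                     chrom_length = 120000L,
                     targets_per_mirna = rep(1L, 30L), n_tfs = 3L)
  sim <- make_genome(cfg)
  frac_u <- mean(substr(sim$truth$mirnas$mature_seq, 1, 1) == "U")
  expect_gt(frac_u, 0.45)   # binomial spread around 0.7 at n = 30
  expect_lt(frac_u, 0.95)
})
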