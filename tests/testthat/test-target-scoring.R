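test_that("expectation scoring matches hand-evaluated cases", {
  mk_aln <- function(mirna, target) {
    a <- strsplit(mirna, "")[[1]]; b <- strsplit(target, "")[[1]]
    code <- mapply(function(x, y) {
      p <- paste0(x, y)
      if (p %in% c("AU", "UA", "GC", "CG")) "match"
      else if (p %in% c("GU", "UG")) "GU" else "mismatch"
    }, a, b)
    data.frame(mirna_pos = seq_along(a), mirna_base = a, target_base = b,
               code = unname(code), stringsAsFactors = FALSE)
  }
  m <- "UGACAGAAGAGAGUGAGCAC"
  perfect <- mk_aln(m, chartr("ACGU", "UGCA", m))  # column-wise complement
  expect_equal(expectation_score(perfect), 0)

  ## single mismatch at position 5 (seed region): 1.0 doubled
  mm5 <- perfect
  mm5$target_base[5] <- setdiff(c("A", "C", "G", "U"),
                                c(mm5$target_base[5],
                                  chartr("ACGU", "UGCA", mm5$mirna_base[5]),
                                  if (mm5$mirna_base[5] %in% c("G", "U"))
                                    chartr("GU", "UG", mm5$mirna_base[5])))[1]
  mm5$code[5] <- "mismatch"
  expect_equal(expectation_score(mm5), 2.0)

  ## G:U at position 20 + mismatch at position 1 (both outside the seed)
  gu <- perfect
  gu$mirna_base[20] <- "G"; gu$target_base[20] <- "U"; gu$code[20] <- "GU"
  gu$mirna_base[1] <- "A"; gu$target_base[1] <- "C"; gu$code[1] <- "mismatch"
  expect_equal(expectation_score(gu), 1.5)

  bad <- perfect; bad$code[3] <- "mismatch"
  expect_error(expectation_score(bad), "inconsistent")
})

test_that("a perfect complementary site scores zero with the right cut", {
  set.seed(31)
  m <- random_rna(21)
  site <- rna_to_dna(revcomp(m))
  tx <- paste0(random_dna(150), site, random_dna(150))
  hits <- scan_transcript(m, tx, cutoff = 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$expectation, 0)
  expect_equal(hits$site_start, 151)
  ## cut between the bases opposite miRNA positions 10 and 11
  expect_equal(hits$cleavage_pos, 151 + 21 - 10)
  ## cutoff 0 admits only perfect complements
  expect_true(all(scan_transcript(m, tx, cutoff = 0)$expectation == 0))
})

test_that("transcript scanning equals the brute-force site oracle", {
  set.seed(32)
  for (rep in 1:4) {
    m <- random_rna(21)
    tx <- random_dna(400)
    got <- scan_transcript(m, tx, cutoff = 6)
    want <- oracle_scan(m, tx, cutoff = 6)
    got <- got[order(got$site_start), c("site_start", "expectation",
                                        "n_gaps")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("the reported alignment reproduces the reported score", {
  set.seed(33)
  m <- random_rna(21)
  site <- rna_to_dna(revcomp(m))
  mut <- function(s, pos) {
    substr(s, pos, pos) <- c(A = "C", C = "A", G = "A",
                             T = "C")[substr(s, pos, pos)]
    s
  }
  tx <- paste0(random_dna(100), site, random_dna(50),
               mut(mut(site, 3), 17), random_dna(100))
  hits <- scan_transcript(m, tx, cutoff = 8)
  expect_gt(nrow(hits), 1)
  for (i in seq_len(min(nrow(hits), 10))) {
    aln <- hit_alignment(m, tx, hits[i, ])
    expect_equal(expectation_score(aln), hits$expectation[i],
                 info = paste("hit", i))
  }
})

test_that("scores are monotone in added penalties", {
  m <- "UGACAGAAGAGAGUGAGCAC"
  base <- data.frame(mirna_pos = 1:20,
                     mirna_base = strsplit(m, "")[[1]],
                     target_base = strsplit(chartr("ACGU", "UGCA", m),
                                            "")[[1]],
                     code = "match", stringsAsFactors = FALSE)
  sc <- expectation_score(base)
  for (pos in c(1, 5, 13, 20)) {
    worse <- base
    worse$code[pos] <- "mismatch"
    worse$target_base[pos] <- "X"
    ## bypass validation with consistent sequences instead
    worse$target_base[pos] <- setdiff(
      c("A", "C", "G", "U"),
      c(chartr("ACGU", "UGCA", worse$mirna_base[pos]),
        if (worse$mirna_base[pos] %in% c("G", "U"))
          chartr("GU", "UG", worse$mirna_base[pos])))[1]
    expect_gt(expectation_score(worse), sc)
  }
})

test_that("planted target sites are all recovered, and only they", {
  run <- tiny_zn_run()
  sim <- run$sim
  tg <- sim$truth$targets
  novel <- run$run$novel$records
  hits <- run$run$hits[run$run$hits$best, ]
  planted <- paste(tg$mirna_id, tg$gene_id)
  found <- paste(hits$mirna_id, hits$transcript_id)
  expect_true(all(planted %in% found))
  ## perfect sites score 0 at the recorded position
  ph <- merge(hits, tg, by.x = c("mirna_id", "transcript_id"),
              by.y = c("mirna_id", "gene_id"))
  expect_true(all(ph$expectation == 0))
  expect_equal(ph$site_start.x, ph$site_start.y)

  ## invariance under transcript order permutation
  m <- setNames(novel$mature_seq, novel$mirna_id)[1:2]
  tx <- sim$transcripts
  h1 <- predict_targets(m, tx, cutoff = 3)
  h2 <- predict_targets(m, rev(tx), cutoff = 3)
  key <- function(h) {
    h <- h[order(h$mirna_id, h$transcript_id, h$site_start), ]
    rownames(h) <- NULL
    h
  }
  expect_equal(key(h1), key(h2))
  expect_error(predict_targets(m, c(tx, tx[1])), "duplicate")
})
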