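## Synthetic study generator.
##
## Emulates a 3-tissue (normal wood NW, tension wood TW, opposite wood OW),
## 3-replicate small-RNA study: a toy genome with planted miRNA hairpin
## precursors, per-sample FASTQ reads with adapters, an mRNA expression
## matrix with planted miRNA-target anti-correlation and TF co-expression
## structure, pathway labels with one enriched pathway, and qPCR Ct tables.
## Every planted fact is recorded in a machine-readable truth object so the
## pipeline's calls can be scored against ground truth.

#' Configuration for the synthetic study generator
#'
#' Defaults mirror the study design the package targets: 3 tissues
#' (NW/TW/OW) x 3 replicates, 12 novel miRNAs carrying 39 planted target
#' pairs of which 21 target genes encode transcription factors, planted
#' differential abundance at 4-fold, and planted miRNA-target
#' anti-correlation across the 9 samples. The planted correlation
#' magnitude defaults to 0.95, tuned (by Monte-Carlo at design time) so
#' that at n = 9 at least 90% of planted pairs show empirical r <= -0.8.
#'
#' @param seed integer seed; identical configs give byte-identical outputs
#' @param n_chrom,chrom_length toy genome shape
#' @param n_known_mirnas,n_novel_mirnas planted miRNA counts
#' @param n_genes,n_tfs gene pool size and number of TF-annotated target
#'   genes (the TF fraction of planted targets)
#' @param n_samples_per_tissue replicates per tissue
#' @param tissues tissue labels
#' @param depth reads per sample FASTQ
#' @param de_fold planted fold-change for tissue-differential miRNAs (>= 2)
#' @param noise_sd replicate-level lognormal noise (0 = noiseless)
#' @param planted_r magnitude of the planted miRNA-target and TF-gene
#'   correlations (1 = exact affine relation)
#' @param adapter_seq 3' adapter appended to every simulated read
#' @param background_frac fraction of reads drawn from masked decoy loci and
#'   random genome positions rather than planted matures
#' @param qual_fail_frac fraction of reads given a degraded 3' quality tail
#' @param targets_per_mirna integer vector, planted targets per novel miRNA
#'   (defaults sum to 39 across 12 miRNAs)
#' @param mature_len_range inclusive mature length range (centered on 21)
#' @param u_start_frac probability a planted mature starts with U
#' @param loop_len hairpin loop length (>= 3)
#' @param n_coexpr downstream co-expressed genes per TF
#' @param n_pathways number of pathway labels; "path01" is planted enriched
#' @param transcript_len length of synthetic transcripts
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(seed = 1L,
                             n_chrom = 2L, chrom_length = 60000L,
                             n_known_mirnas = 5L, n_novel_mirnas = 12L,
                             n_genes = 120L, n_tfs = 21L,
                             n_samples_per_tissue = 3L,
                             tissues = c("NW", "TW", "OW"),
                             depth = 10000L,
                             de_fold = 4,
                             noise_sd = 0.15,
                             planted_r = 0.95,
                             adapter_seq = "TGGAATTCTCGGGTGCCAAGG",
                             background_frac = 0.10,
                             qual_fail_frac = 0.02,
                             targets_per_mirna = NULL,
                             mature_len_range = c(20L, 22L),
                             u_start_frac = 0.7,
                             loop_len = 8L,
                             n_coexpr = 2L,
                             n_pathways = 10L,
                             transcript_len = 500L) {
  if (is.null(targets_per_mirna)) {
    ## 3 x 4 targets + 9 x 3 targets = 39 pairs over 12 miRNAs
    targets_per_mirna <- rep_len(c(4L, rep(3L, 3L)), n_novel_mirnas)
  }
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_length = as.integer(chrom_length),
              n_known_mirnas = as.integer(n_known_mirnas),
              n_novel_mirnas = as.integer(n_novel_mirnas),
              n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
              n_samples_per_tissue = as.integer(n_samples_per_tissue),
              tissues = tissues, depth = as.integer(depth),
              de_fold = de_fold, noise_sd = noise_sd,
              planted_r = planted_r, adapter_seq = toupper(adapter_seq),
              background_frac = background_frac,
              qual_fail_frac = qual_fail_frac,
              targets_per_mirna = as.integer(targets_per_mirna),
              mature_len_range = as.integer(mature_len_range),
              u_start_frac = u_start_frac, loop_len = as.integer(loop_len),
              n_coexpr = as.integer(n_coexpr),
              n_pathways = as.integer(n_pathways),
              transcript_len = as.integer(transcript_len))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$depth > 0, cfg$de_fold >= 2, cfg$noise_sd >= 0,
            cfg$loop_len >= 3, cfg$background_frac >= 0,
            cfg$background_frac < 1,
            length(cfg$targets_per_mirna) == cfg$n_novel_mirnas,
            cfg$n_tfs <= sum(cfg$targets_per_mirna),
            grepl("^[ACGT]+$", cfg$adapter_seq))
  invisible(cfg)
}

#' Zero-noise variant of a synthetic configuration
#'
#' Sets replicate noise, correlation noise, background reads and quality
#' degradation to zero so the pipeline should recover the planted truth
#' exactly.
#' @param cfg a `synthetic_config`
#' @return modified `synthetic_config`
#' @export
zero_noise_config <- function(cfg) {
  cfg$noise_sd <- 0
  cfg$planted_r <- 1
  cfg$background_frac <- 0
  cfg$qual_fail_frac <- 0
  cfg
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

largest_remainder <- function(weights, total) {
  k <- length(weights)
  if (total == 0 || sum(weights) == 0) return(integer(k))
  exact <- weights / sum(weights) * total
  base <- floor(exact)
  rem <- as.integer(round(total - sum(base)))
  if (rem > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Build a hairpin precursor around a mature miRNA
#'
#' Constructs mature arm + loop + reverse-complement star arm, with
#' `n_bulges` controlled mispairings introduced in the star arm. The loop is
#' drawn from {A, C} only, so it cannot base-pair internally and the
#' returned sequence folds into a single stem-loop whose stem contains the
#' mature arm.
#'
#' @param mature RNA string, 18-24 nt
#' @param loop_len loop length in nt (>= 3)
#' @param n_bulges number of star-arm positions mutated so they cannot pair
#' @param seed optional integer seed; NULL uses the current RNG stream
#' @return precursor RNA string of length 2*nchar(mature) + loop_len
#' @examples
#' make_hairpin_precursor("ACGUACGUACGUACGUACGU", loop_len = 6, seed = 1)
#' @export
make_hairpin_precursor <- function(mature, loop_len = 8L, n_bulges = 0L,
                                   seed = NULL) {
  mature <- toupper(mature)
  if (!grepl("^[ACGU]+$", mature)) stop("mature must be an RNA string")
  lm <- nchar(mature)
  if (lm < 18 || lm > 24) stop("mature length must be 18-24 nt")
  if (loop_len < 3) stop("invalid loop: loop_len must be >= 3")
  if (!is.null(seed)) set.seed(as.integer(seed))
  loop <- random_seq(loop_len, alphabet = c("A", "C"))
  star <- split_chars(revcomp(mature))
  if (n_bulges > 0) {
    if (n_bulges > lm - 4) stop("too many bulges for this mature length")
    ## spread bulges over the interior of the star arm
    pos <- unique(round(seq(3, lm - 2, length.out = n_bulges)))
    pos <- pos[seq_len(min(n_bulges, length(pos)))]
    mat <- split_chars(mature)
    for (p in pos) {
      partner <- mat[lm - p + 1]          # mature base paired with star[p]
      star[p] <- switch(partner, G = "A", A = "C", U = "C", C = "A")
    }
  }
  paste0(mature, loop, paste(star, collapse = ""))
}

## Reference-style naming for the planted known miRNAs.
.known_families <- c("miR156", "miR166", "miR396", "miR408", "miR482",
                     "miR159", "miR160", "miR164", "miR167", "miR171")

#' Generate the toy genome with planted precursors
#'
#' Plants `n_known_mirnas + n_novel_mirnas` hairpin precursors at
#' non-overlapping loci (some on the minus strand), adds decoy rRNA/tRNA/
#' snoRNA intervals for masking, assigns per-tissue expected abundances with
#' planted `de_fold` tissue effects on the novel miRNAs, and draws the
#' per-sample abundance used by both the read and the expression
#' simulators.
#'
#' @param cfg a `synthetic_config`
#' @return list with `genome` (named character vector of chromosome
#'   sequences), `truth` (see Details), and `mask` (data.frame of decoy
#'   features)
#' @details `truth$mirnas` has one row per planted miRNA (id, status,
#'   mature/precursor sequence, locus, tissue means); `truth$abund` is the
#'   expected miRNA x sample abundance matrix; target/TF/pathway truth is
#'   appended by [simulate_expression()].
#' @export
make_genome <- function(cfg) {
  validate_synthetic_config(cfg)
  set.seed(derive_seed(cfg$seed, 1L))
  n_mir <- cfg$n_known_mirnas + cfg$n_novel_mirnas
  lens <- sample(seq(cfg$mature_len_range[1], cfg$mature_len_range[2]),
                 n_mir, replace = TRUE,
                 prob = c(0.2, 0.6, 0.2)[seq_len(diff(cfg$mature_len_range) + 1)])
  prec_len <- 2L * max(lens) + cfg$loop_len
  per_chrom <- ceiling(n_mir / cfg$n_chrom)
  n_mask_per_chrom <- 3L
  slot <- cfg$chrom_length %/% (per_chrom + n_mask_per_chrom + 1L)
  if (slot < prec_len + 400L) {
    stop("capacity error: precursors + masks do not fit chrom_length")
  }

  genome <- stats::setNames(
    vapply(seq_len(cfg$n_chrom), function(i) random_seq(cfg$chrom_length),
           character(1)),
    paste0("chr", seq_len(cfg$n_chrom)))

  ## draw matures (first base U with prob u_start_frac) and precursors
  mature <- character(n_mir)
  precursor <- character(n_mir)
  for (i in seq_len(n_mir)) {
    first <- if (stats::runif(1) < cfg$u_start_frac) "U" else
      sample(c("A", "C", "G"), 1)
    mature[i] <- paste0(first, random_seq(lens[i] - 1L,
                                          alphabet = c("A", "C", "G", "U")))
    precursor[i] <- make_hairpin_precursor(mature[i], cfg$loop_len, 0L)
  }

  ## place precursors and decoy masks, non-overlapping, round-robin chroms
  chrom <- paste0("chr", ((seq_len(n_mir) - 1L) %% cfg$n_chrom) + 1L)
  slot_idx <- ((seq_len(n_mir) - 1L) %/% cfg$n_chrom)
  start <- (slot_idx + 1L) * slot
  end <- start + nchar(precursor) - 1L
  strand <- ifelse(seq_len(n_mir) %% 4L == 0L, "-", "+")

  for (i in seq_len(n_mir)) {
    emb <- rna_to_dna(precursor[i])
    if (strand[i] == "-") emb <- revcomp(emb)
    s <- genome[[chrom[i]]]
    genome[[chrom[i]]] <- paste0(substr(s, 1, start[i] - 1L), emb,
                                 substr(s, end[i] + 1L, nchar(s)))
  }

  ## decoy masked features at the tail of each chromosome
  mask_types <- c("rRNA", "tRNA", "snoRNA")
  mask <- do.call(rbind, lapply(seq_len(cfg$n_chrom), function(ci) {
    ms <- (per_chrom + seq_len(n_mask_per_chrom)) * slot + slot %/% 2L
    data.frame(chrom = paste0("chr", ci), start = ms, end = ms + 199L,
               strand = "+", type = mask_types,
               stringsAsFactors = FALSE)
  }))

  ## status and ids: first n_known are known; novels named in genome order
  status <- rep(c("known", "novel"),
                c(cfg$n_known_mirnas, cfg$n_novel_mirnas))
  fam <- rep_len(.known_families, cfg$n_known_mirnas)
  known_ids <- paste0("hbr-", fam, letters[stats::ave(seq_along(fam), fam,
                                                      FUN = seq_along)])
  mirna_id <- character(n_mir)
  mirna_id[status == "known"] <- known_ids
  nov <- which(status == "novel")
  ord <- nov[order(chrom[nov], start[nov])]
  mirna_id[ord] <- paste0("novel_", seq_along(ord))

  ## abundance: lognormal base, de_fold tissue effect cycling over novels
  base_abund <- exp(stats::rnorm(n_mir, log(200), 0.7))
  de_tissue <- rep(NA_character_, n_mir)
  de_tissue[nov] <- rep_len(cfg$tissues, length(nov))
  tiss_ab <- sapply(cfg$tissues, function(t) {
    base_abund * ifelse(!is.na(de_tissue) & de_tissue == t, cfg$de_fold, 1)
  })
  rownames(tiss_ab) <- mirna_id

  samples <- paste0(rep(cfg$tissues, each = cfg$n_samples_per_tissue),
                    seq_len(cfg$n_samples_per_tissue))
  abund <- sapply(seq_along(samples), function(s) {
    t <- rep(cfg$tissues, each = cfg$n_samples_per_tissue)[s]
    tiss_ab[, t] * exp(stats::rnorm(n_mir, 0, cfg$noise_sd))
  })
  dimnames(abund) <- list(mirna_id, samples)

  mirnas <- data.frame(mirna_id = mirna_id, status = status,
                       family = c(fam, rep(NA_character_,
                                           cfg$n_novel_mirnas)),
                       mature_seq = mature, precursor_seq = precursor,
                       chrom = chrom, start = start, end = end,
                       strand = strand, de_tissue = de_tissue,
                       base_abund = base_abund, stringsAsFactors = FALSE)

  truth <- list(mirnas = mirnas, tissue_abund = tiss_ab, abund = abund,
                samples = samples,
                tissue_of_sample = stats::setNames(
                  rep(cfg$tissues, each = cfg$n_samples_per_tissue),
                  samples))
  list(genome = genome, truth = truth, mask = mask)
}

sample_quality <- function(len, degraded, high_q = 38L, low_q = 8L,
                           degrade_from = 16L) {
  q <- rep(high_q, len)
  if (degraded && len >= degrade_from) {
    q[degrade_from:len] <- low_q
  }
  q
}

#' Simulate per-sample small-RNA FASTQ reads
#'
#' Each sample gets exactly `cfg$depth` reads: planted matures sampled
#' proportionally to the per-sample abundance (largest-remainder
#' allocation, so zero-noise configs are exactly proportional), plus
#' background reads drawn from the decoy masked regions and random genome
#' loci. The 3' adapter is appended to every read; a `qual_fail_frac`
#' fraction of reads gets a degraded 3' quality tail so the Q20 filter is
#' always exercised.
#'
#' @param cfg a `synthetic_config`
#' @param sim output of [make_genome()]
#' @return named list of per-sample data.frames (read_id, seq, qual)
#' @export
simulate_reads <- function(cfg, sim) {
  force(sim)   # evaluate now: lazy evaluation after set.seed would let
               # make_genome() clobber this stage's RNG stream
  set.seed(derive_seed(cfg$seed, 2L))
  truth <- sim$truth
  genome <- sim$genome
  n_bg <- as.integer(round(cfg$depth * cfg$background_frac))
  n_mr <- cfg$depth - n_bg
  out <- list()
  for (s in truth$samples) {
    counts <- largest_remainder(truth$abund[, s], n_mr)
    seqs <- rep(rna_to_dna(truth$mirnas$mature_seq), counts)
    if (n_bg > 0) {
      n_decoy <- n_bg %/% 2L
      bg <- character(n_bg)
      for (k in seq_len(n_bg)) {
        len <- sample(18:30, 1)
        if (k <= n_decoy) {
          m <- sim$mask[sample(nrow(sim$mask), 1), ]
          p <- sample(seq(m$start, m$end - len + 1L), 1)
          bg[k] <- substr(genome[[m$chrom]], p, p + len - 1L)
        } else {
          ci <- sample(names(genome), 1)
          p <- sample(nchar(genome[[ci]]) - len, 1)
          bg[k] <- substr(genome[[ci]], p, p + len - 1L)
        }
      }
      seqs <- c(seqs, bg)
    }
    seqs <- sample(seqs)                       # shuffle read order
    full <- substr(paste0(seqs, cfg$adapter_seq), 1, 50)
    degraded <- stats::runif(length(full)) < cfg$qual_fail_frac
    qual <- vapply(seq_along(full), function(i) {
      paste(phred_to_chars(sample_quality(nchar(full[i]), degraded[i])),
            collapse = "")
    }, character(1))
    out[[s]] <- data.frame(
      read_id = sprintf("%s_read%06d", s, seq_along(full)),
      seq = full, qual = qual, stringsAsFactors = FALSE)
  }
  out
}

#' Simulate the expression side: mRNA matrix, TF table, pathways, qPCR Ct
#'
#' For each planted (miRNA, target) pair, gene expression across the 9
#' samples is a decreasing affine function of the miRNA's per-sample
#' abundance plus Gaussian noise scaled so the expected Pearson r equals
#' `-planted_r`; TF target genes get `n_coexpr` downstream genes
#' co-expressed the same way with positive sign. One pathway ("path01") is
#' over-represented among network genes. Ct values follow
#' Ct = 35 - log2(expression), so the ddCt method recovers planted
#' fold-changes exactly at zero noise.
#'
#' @param cfg a `synthetic_config`
#' @param sim output of [make_genome()]; its `truth` is extended
#' @return `sim` with `expr` (gene x sample matrix), `transcripts` (named
#'   character vector), `tf_table`, `pathway_map`, `ct_table` and an
#'   extended `truth` (targets, tf_edges, enriched_pathway, warnings)
#' @export
simulate_expression <- function(cfg, sim) {
  force(sim)   # see simulate_reads: argument must be evaluated before
               # this stage's seed is set
  set.seed(derive_seed(cfg$seed, 3L))
  truth <- sim$truth
  samples <- truth$samples
  genes <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  baseline <- exp(stats::rnorm(cfg$n_genes, log(150), 0.5))
  names(baseline) <- genes

  n_targets <- sum(cfg$targets_per_mirna)
  target_gene <- sample(genes, n_targets)
  novel <- truth$mirnas$mirna_id[truth$mirnas$status == "novel"]
  tgt_mirna <- rep(novel, cfg$targets_per_mirna)

  ## 21 of 39 planted targets are TF genes, spread across miRNAs
  is_tf <- rep(FALSE, n_targets)
  is_tf[seq(1, n_targets, length.out = cfg$n_tfs)] <- TRUE
  stopifnot(sum(is_tf) == cfg$n_tfs)

  remaining <- setdiff(genes, target_gene)
  down_gene <- sample(remaining, sum(is_tf) * cfg$n_coexpr)

  expr <- matrix(rep(baseline, length(samples)) *
                   exp(stats::rnorm(cfg$n_genes * length(samples), 0,
                                    cfg$noise_sd)),
                 nrow = cfg$n_genes, dimnames = list(genes, samples))

  signal <- matrix(0, cfg$n_genes, length(samples),
                   dimnames = dimnames(expr))  # deterministic components
  plant_affine <- function(base, driver, sign) {
    z <- as.numeric(scale(driver))
    sig <- base * (1 + sign * 0.35 * z)
    sigma <- if (cfg$planted_r >= 1) 0 else
      base * 0.35 * sqrt(1 / cfg$planted_r^2 - 1)
    list(value = pmax(sig + stats::rnorm(length(z), 0, sigma), 0.01),
         signal = sig)
  }

  emp_r <- numeric(n_targets)
  for (k in seq_len(n_targets)) {
    drv <- truth$abund[tgt_mirna[k], ]
    pl <- plant_affine(baseline[target_gene[k]], drv, -1)
    expr[target_gene[k], ] <- pl$value
    signal[target_gene[k], ] <- pl$signal
    emp_r[k] <- stats::cor(expr[target_gene[k], ], drv)
  }
  tf_genes <- target_gene[is_tf]
  tf_edges <- data.frame(tf = rep(tf_genes, each = cfg$n_coexpr),
                         gene = down_gene, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(tf_edges))) {
    drv <- expr[tf_edges$tf[k], ]
    pl <- plant_affine(baseline[tf_edges$gene[k]], drv, +1)
    expr[tf_edges$gene[k], ] <- pl$value
    signal[tf_edges$gene[k], ] <- pl$signal
    tf_edges$empirical_r[k] <- stats::cor(expr[tf_edges$gene[k], ], drv)
  }

  targets <- data.frame(mirna_id = tgt_mirna, gene_id = target_gene,
                        planted_r = -cfg$planted_r, empirical_r = emp_r,
                        is_tf = is_tf, stringsAsFactors = FALSE)
  warnings <- character(0)
  if (any(targets$empirical_r > -0.8)) {
    warnings <- sprintf(
      "noise too large: %d planted pairs have empirical r > -0.8",
      sum(targets$empirical_r > -0.8))
  }

  ## pathway labels: uniform background, planted enrichment among network
  ## genes (targets + TF downstream genes)
  pathways <- sprintf("path%02d", seq_len(cfg$n_pathways))
  pathway_map <- data.frame(
    gene_id = genes,
    pathway_id = sample(pathways, cfg$n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  network_genes <- unique(c(target_gene, down_gene))
  planted_in_path <- network_genes[seq_len(ceiling(length(network_genes) / 2))]
  pathway_map$pathway_id[pathway_map$gene_id %in% planted_in_path] <- "path01"

  ## transcripts with a perfect complementary site planted per target pair
  transcripts <- stats::setNames(
    vapply(genes, function(g) random_seq(cfg$transcript_len), character(1)),
    genes)
  site_start <- integer(n_targets)
  for (k in seq_len(n_targets)) {
    site <- revcomp(rna_to_dna(
      truth$mirnas$mature_seq[truth$mirnas$mirna_id == tgt_mirna[k]]))
    pos <- 100L + 7L * k %% 50L
    tx <- transcripts[[target_gene[k]]]
    transcripts[[target_gene[k]]] <-
      paste0(substr(tx, 1, pos - 1L), site,
             substr(tx, pos + nchar(site), nchar(tx)))
    site_start[k] <- pos
  }
  targets$site_start <- site_start

  ## qPCR Ct tables: Ct = 35 - log2(expr), reference gene UBQ constant
  ct_genes <- unique(c(novel, target_gene[match(novel, tgt_mirna)]))
  ct_rows <- list()
  for (g in ct_genes) {
    val <- if (g %in% rownames(truth$abund)) truth$abund[g, ] else expr[g, ]
    for (r in 1:3) {
      ct_rows[[length(ct_rows) + 1L]] <- data.frame(
        sample_id = samples, gene_id = g, replicate = r,
        ct = 35 - log2(val) + stats::rnorm(length(val), 0,
                                           0.3 * cfg$noise_sd),
        is_reference = FALSE, stringsAsFactors = FALSE)
    }
  }
  for (r in 1:3) {
    ct_rows[[length(ct_rows) + 1L]] <- data.frame(
      sample_id = samples, gene_id = "UBQ", replicate = r,
      ct = 35 - log2(1024) + stats::rnorm(length(samples), 0,
                                          0.3 * cfg$noise_sd),
      is_reference = TRUE, stringsAsFactors = FALSE)
  }
  ct_table <- do.call(rbind, ct_rows)
  rownames(ct_table) <- NULL

  tf_families <- rep_len(c("MYB", "bZIP", "C3H", "FAR1"), length(tf_genes))
  sim$expr <- expr
  sim$signal <- signal
  sim$transcripts <- transcripts
  sim$tf_table <- data.frame(gene_id = tf_genes, family = tf_families,
                             stringsAsFactors = FALSE)
  sim$pathway_map <- pathway_map
  sim$ct_table <- ct_table
  truth$targets <- targets
  truth$tf_edges <- tf_edges
  truth$enriched_pathway <- "path01"
  truth$warnings <- warnings
  sim$truth <- truth
  sim
}

#' Run the full synthetic generator and write all files
#'
#' @param cfg a `synthetic_config`
#' @param outdir output directory (created if absent)
#' @return invisibly, the in-memory `sim` object with a `files` element
#'   naming every written path
#' @export
simulate_all <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- make_genome(cfg)
  reads <- simulate_reads(cfg, sim)
  sim <- simulate_expression(cfg, sim)
  truth <- sim$truth

  files <- list()
  files$genome <- file.path(outdir, "genome.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome),
                              files$genome)
  files$transcriptome <- file.path(outdir, "transcriptome.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$transcripts),
                              files$transcriptome)

  ## known-miRNA reference: mature + precursor entries
  known <- truth$mirnas[truth$mirnas$status == "known", ]
  ref <- c(stats::setNames(rna_to_dna(known$mature_seq), known$mirna_id),
           stats::setNames(rna_to_dna(known$precursor_seq),
                           paste0(known$mirna_id, "-precursor")))
  files$reference <- file.path(outdir, "mirna_reference.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref),
                              files$reference)

  files$annotation <- file.path(outdir, "annotation.gff3")
  write_mask_gff3(sim$mask, truth$mirnas, files$annotation)

  files$fastq <- stats::setNames(
    file.path(outdir, paste0(truth$samples, ".fastq")), truth$samples)
  for (s in truth$samples) {
    rec <- reads[[s]]
    writeLines(as.vector(rbind(paste0("@", rec$read_id), rec$seq, "+",
                               rec$qual)),
               files$fastq[[s]])
  }

  files$expression <- file.path(outdir, "expression.tsv")
  write_tsv(data.frame(gene_id = rownames(sim$expr), sim$expr,
                       check.names = FALSE), files$expression)
  files$tf_table <- file.path(outdir, "tf_table.tsv")
  write_tsv(sim$tf_table, files$tf_table)
  files$pathway_map <- file.path(outdir, "pathway_map.tsv")
  write_tsv(sim$pathway_map, files$pathway_map)
  files$ct_table <- file.path(outdir, "ct_table.tsv")
  write_tsv(sim$ct_table, files$ct_table)

  files$truth <- file.path(outdir, "truth.json")
  jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", dataframe = "columns")

  sim$reads <- reads
  sim$files <- files
  invisible(sim)
}

#' Ground-truth TF co-expression edge set, including induced edges
#'
#' Tissue-driven abundance patterns necessarily correlate a TF gene not
#' only with its explicitly planted downstream genes but also with every
#' gene driven by a same-pattern miRNA. The generator therefore defines
#' the true TF-layer edge set from the deterministic signal components:
#' an edge (TF, gene) is true when the correlation of the two noiseless
#' signals reaches `r_min` in absolute value. Genes without planted
#' structure have constant signal and induce no edges.
#'
#' @param sim output of [simulate_expression()]
#' @param r_min absolute-correlation threshold (match the TF-layer
#'   threshold)
#' @return data.frame (tf, gene, signal_r)
#' @export
induced_tf_truth <- function(sim, r_min = 0.8) {
  sig <- sim$signal
  tfs <- sim$tf_table$gene_id
  rows <- list()
  varying <- rownames(sig)[apply(sig, 1, stats::var) > 0]
  for (tf in intersect(tfs, varying)) {
    others <- setdiff(varying, tf)
    r <- as.numeric(stats::cor(sig[tf, ], t(sig[others, , drop = FALSE])))
    keep <- abs(r) >= r_min
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, gene = others[keep], signal_r = r[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(tf = character(0), gene = character(0),
                      signal_r = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_mask_gff3 <- function(mask, mirnas, path) {
  lines <- c("##gff-version 3")
  rows <- c(
    sprintf("%s\tmirwoodnet\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
            mask$chrom, mask$type, mask$start, mask$end, mask$strand,
            paste0("decoy_", seq_len(nrow(mask)))),
    sprintf("%s\tmirwoodnet\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s",
            mirnas$chrom, mirnas$start, mirnas$end, mirnas$strand,
            mirnas$mirna_id))
  writeLines(c(lines, rows), path)
  invisible(path)
}
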