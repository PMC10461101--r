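## Known-miRNA assignment, novel miRNA calling by hairpin folding, family
## assignment and per-tissue miRNA sets.

#' Fold an RNA sequence by base-pair maximization
#'
#' Nussinov-style dynamic program over {AU, GC, GU} pairs with a minimum
#' hairpin loop size, followed by a deterministic traceback: at each
#' subproblem the 5'-most position is paired whenever pairing it achieves
#' the optimum, with the 5'-most admissible partner. Base-pair maximization
#' stands in for an energy model; the structure is used only for the
#' hairpin acceptance rules, which do not need free energies.
#'
#' @param seq RNA string (T is normalized to U); length >= 10
#' @param min_loop minimum number of unpaired bases in a hairpin loop
#' @return list with `structure` (dot-bracket), `pair_count`, and `pairs`
#'   (integer vector of partner positions, 0 = unpaired)
#' @examples
#' fold_nussinov("GGGAAACCC")$pair_count # 3
#' @export
fold_nussinov <- function(seq, min_loop = 3L) {
  s <- dna_to_rna(toupper(seq))
  if (!grepl("^[ACGU]+$", s)) stop("alphabet error: non-RNA characters")
  x <- split_chars(s)
  n <- length(x)
  if (n < min_loop + 2L) stop("sequence too short to fold")
  pairmat <- outer(x, x, FUN = function(a, b) can_pair(a, b))

  dp <- matrix(0L, n, n)
  for (span in seq(min_loop + 1L, n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- dp[i + 1L, j]
      ks <- seq(i + min_loop + 1L, j)
      ok <- pairmat[i, ks]
      if (any(ok)) {
        kk <- ks[ok]
        right <- integer(length(kk))
        inb <- kk < j
        if (any(inb)) right[inb] <- dp[cbind(kk[inb] + 1L, j)]
        v <- 1L + dp[cbind(i + 1L, kk - 1L)] + right
        best <- max(best, max(v))
      }
      dp[i, j] <- best
    }
  }

  pairs <- integer(n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    while (i < j && dp[i, j] > 0L) {
      target <- dp[i, j]
      paired_at <- 0L
      if (i + min_loop + 1L <= j) {
        for (k in seq(i + min_loop + 1L, j)) {
          if (pairmat[i, k]) {
            v <- 1L + dp[i + 1L, k - 1L] +
              (if (k < j) dp[k + 1L, j] else 0L)
            if (v == target) { paired_at <- k; break }
          }
        }
      }
      if (paired_at > 0L) {
        pairs[i] <- paired_at
        pairs[paired_at] <- i
        if (paired_at < j) stack[[length(stack) + 1L]] <-
            c(paired_at + 1L, j)
        j <- paired_at - 1L
        i <- i + 1L
      } else {
        i <- i + 1L
      }
    }
  }

  structure_str <- rep(".", n)
  structure_str[pairs > seq_len(n)] <- "("
  structure_str[pairs > 0L & pairs < seq_len(n)] <- ")"
  list(structure = paste(structure_str, collapse = ""),
       pair_count = sum(pairs > 0L) %/% 2L,
       pairs = pairs)
}

#' Read a mature + precursor miRNA reference FASTA
#'
#' Entries whose names end in "-precursor" (or contain "MIR") are treated
#' as precursors; the rest as mature sequences.
#' @param path FASTA file
#' @return list with `mature` and `precursor` named RNA character vectors
#' @export
read_mirna_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm)) stop("duplicate reference IDs")
  seqs <- dna_to_rna(toupper(as.character(x)))
  is_prec <- grepl("-precursor$|MIR", nm)
  list(mature = stats::setNames(seqs[!is_prec], nm[!is_prec]),
       precursor = stats::setNames(seqs[is_prec], nm[is_prec]))
}

## Does `a` equal `b` after at most `max_trim` total end-trims (5' or 3',
## on either sequence)? No internal mismatch allowed.
terminal_trim_match <- function(a, b, max_trim = 2L) {
  na <- nchar(a); nb <- nchar(b)
  for (a5 in 0:max_trim) for (a3 in 0:(max_trim - a5)) {
    rem <- max_trim - a5 - a3
    for (b5 in 0:rem) for (b3 in 0:(rem - b5)) {
      if (na - a5 - a3 == nb - b5 - b3 && na - a5 - a3 > 0 &&
          substr(a, 1 + a5, na - a3) == substr(b, 1 + b5, nb - b3)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

mirna_family <- function(id) {
  m <- regmatches(id, regexpr("miR-?[0-9]+", id, ignore.case = TRUE))
  if (length(m) == 0) NA_character_ else sub("mir", "miR", m,
                                             ignore.case = TRUE)
}

#' Assign tags to known miRNAs from a reference
#'
#' A tag is a known miRNA when its sequence equals a reference mature
#' sequence exactly or differs only by at most 2 nt of terminal trimming
#' (no internal mismatches). Tags matching the same reference entry are
#' aggregated; families are parsed from reference naming.
#'
#' @param catalog TagCatalog (after masking)
#' @param reference list from [read_mirna_reference()] or path to the FASTA
#' @return MirnaRecord data.frame (mirna_id, status = "known", family,
#'   mature_seq, chrom, start, end, strand, per-sample counts) with
#'   attribute `explained_tags` (tag_ids absorbed by known miRNAs)
#' @export
match_known <- function(catalog, reference) {
  if (is.character(reference)) reference <- read_mirna_reference(reference)
  if (length(reference$mature) == 0) stop("reference has no mature entries")
  smp <- catalog_samples(catalog)
  tags <- catalog$tags[!catalog$tags$unmapped, , drop = FALSE]
  tag_rna <- dna_to_rna(tags$seq)

  rec <- list(); explained <- integer(0)
  for (ri in seq_along(reference$mature)) {
    ref_id <- names(reference$mature)[ri]
    ref_seq <- reference$mature[[ri]]
    hit <- which(vapply(tag_rna, terminal_trim_match, logical(1),
                        b = ref_seq))
    if (length(hit) == 0) next
    explained <- c(explained, tags$tag_id[hit])
    counts <- colSums(tags[hit, smp, drop = FALSE])
    top <- hit[which.max(rowSums(tags[hit, smp, drop = FALSE]))]
    loc <- catalog$loci[catalog$loci$tag_id == tags$tag_id[top], ,
                        drop = FALSE]
    loc <- if (nrow(loc)) loc[1, ] else
      data.frame(chrom = NA, start = NA, end = NA, strand = NA)
    rec[[length(rec) + 1L]] <- cbind(
      data.frame(mirna_id = ref_id, status = "known",
                 family = mirna_family(ref_id),
                 mature_seq = tag_rna[top], chrom = loc$chrom,
                 start = loc$start, end = loc$end, strand = loc$strand,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(counts), check.names = FALSE))
  }
  out <- if (length(rec)) do.call(rbind, rec) else
    empty_mirna_records(smp)
  rownames(out) <- NULL
  attr(out, "explained_tags") <- unique(explained)
  out
}

empty_mirna_records <- function(samples) {
  base <- data.frame(mirna_id = character(0), status = character(0),
                     family = character(0), mature_seq = character(0),
                     chrom = character(0), start = integer(0),
                     end = integer(0), strand = character(0),
                     stringsAsFactors = FALSE)
  for (s in samples) base[[s]] <- integer(0)
  base
}

## Hairpin acceptance rules for a folded precursor window. The mature must
## sit on one arm of a single-stemmed hairpin:
##   (i)   >= min_stem_pairs mature bases in one antiparallel duplex run
##         (partners strictly decreasing, bulges bounded on both sides)
##   (ii)  >= min_paired_frac of mature bases paired at all
##   (iii) that run's partners all lie on one side of the mature — the
##         mature arm's path to its pairing partner has no multiloop
##         branch (base-pair-maximal structures have ties that can dot
##         small hairpins into the loop, so the literal structure string
##         is not trusted for this; the duplex chain is)
##   (iv)  the unpaired span between the mature arm and its partner
##         region (the terminal loop plus frayed ends) is compact
hairpin_verdict <- function(fold, mature_start, mature_len,
                            min_stem_pairs = 14L, min_paired_frac = 0.6,
                            max_bulge = 3L, max_loop_span = 50L) {
  p <- fold$pairs
  m_idx <- seq(mature_start, mature_start + mature_len - 1L)
  partners <- p[m_idx]
  frac_paired <- mean(partners > 0L)
  if (frac_paired < min_paired_frac) {
    return(list(accepted = FALSE, reason = "low mature pairing fraction"))
  }
  ## longest antiparallel chain over mature positions with partners
  ## outside the mature region
  outside <- which(partners > 0L &
                     (partners < mature_start |
                        partners > mature_start + mature_len - 1L))
  if (length(outside) == 0) {
    return(list(accepted = FALSE, reason = "insufficient stem pairing"))
  }
  run_len <- 0L; prev_q <- Inf; prev_i <- -10L
  best_len <- 0L; run_idx <- integer(0); best_idx <- integer(0)
  for (i in outside) {
    q <- partners[i]
    if (q < prev_q && prev_q - q <= max_bulge + 1L &&
        i - prev_i <= max_bulge %/% 2L + 1L) {
      run_len <- run_len + 1L
      run_idx <- c(run_idx, i)
    } else {
      run_len <- 1L
      run_idx <- i
    }
    prev_q <- q; prev_i <- i
    if (run_len > best_len) {
      best_len <- run_len
      best_idx <- run_idx
    }
  }
  if (best_len < min(min_stem_pairs, mature_len - 4L)) {
    return(list(accepted = FALSE, reason = "insufficient stem pairing"))
  }
  qs <- partners[best_idx]
  m_abs <- m_idx[best_idx]
  above <- all(qs > max(m_idx)); below <- all(qs < min(m_idx))
  if (!above && !below) {
    return(list(accepted = FALSE, reason = "mature pairs both arms"))
  }
  loop_span <- if (above) min(qs) - max(m_abs) - 1L else
    min(m_abs) - max(qs) - 1L
  if (loop_span > max_loop_span) {
    return(list(accepted = FALSE, reason = "no compact stem-loop"))
  }
  list(accepted = TRUE, reason = "ok", stem_pairs = best_len)
}

#' Call novel miRNAs from unexplained tags by precursor folding
#'
#' For every mapped tag not explained by a known miRNA, two candidate
#' precursor windows are extracted on the tag's strand (mature at the 5'
#' end plus `flank` nt downstream, and mature at the 3' end plus `flank` nt
#' upstream), folded with [fold_nussinov()], and tested against the hairpin
#' acceptance rules. Overlapping accepted candidates are merged; novel IDs
#' are assigned in genome coordinate order (novel_1, novel_2, ...).
#'
#' @param catalog TagCatalog (after masking)
#' @param genome named character vector from [read_genome()]
#' @param known MirnaRecord data.frame from [match_known()] (its explained
#'   tags are skipped: known takes precedence over novel)
#' @param flank window extension in nt
#' @param min_count minimum total read count for a tag to be considered
#'   (read-support evidence; keeps stray background tags from being
#'   folded)
#' @return list with `records` (MirnaRecord data.frame, status = "novel")
#'   and `candidates` (per-window HairpinCandidate table incl. rejected
#'   windows with reasons)
#' @export
call_novel <- function(catalog, genome, known, flank = 80L,
                       min_count = 5L) {
  smp <- catalog_samples(catalog)
  explained <- attr(known, "explained_tags") %||% integer(0)
  tags <- catalog$tags[!catalog$tags$unmapped &
                         !(catalog$tags$tag_id %in% explained), ,
                       drop = FALSE]
  tags <- tags[rowSums(tags[, smp, drop = FALSE]) >= min_count, ,
               drop = FALSE]

  cand <- list()
  for (i in seq_len(nrow(tags))) {
    ti <- tags$tag_id[i]
    loci <- catalog$loci[catalog$loci$tag_id == ti, , drop = FALSE]
    for (li in seq_len(nrow(loci))) {
      lc <- loci[li, ]
      clen <- nchar(genome[[lc$chrom]])
      for (side in c("mature5", "mature3")) {
        if (lc$strand == "+") {
          ws <- if (side == "mature5") lc$start else
            max(1L, lc$start - flank)
          we <- if (side == "mature5") min(clen, lc$end + flank) else
            lc$end
          wseq <- substr(genome[[lc$chrom]], ws, we)
          moff <- if (side == "mature5") 1L else lc$start - ws + 1L
        } else {
          ws <- if (side == "mature5") max(1L, lc$start - flank) else
            lc$start
          we <- if (side == "mature5") lc$end else
            min(clen, lc$end + flank)
          wseq <- revcomp(substr(genome[[lc$chrom]], ws, we))
          moff <- if (side == "mature5") 1L else we - lc$end + 1L
        }
        mlen <- lc$end - lc$start + 1L
        if (nchar(wseq) < mlen + 10L) next
        fold <- fold_nussinov(wseq)
        v <- hairpin_verdict(fold, moff, mlen)
        cand[[length(cand) + 1L]] <- data.frame(
          tag_id = ti, seq = tags$seq[i], chrom = lc$chrom,
          win_start = ws, win_end = we, strand = lc$strand, side = side,
          mature_offset = moff, structure = fold$structure,
          pair_count = fold$pair_count, accepted = v$accepted,
          reason = v$reason,
          total_count = sum(tags[i, smp, drop = FALSE]),
          stringsAsFactors = FALSE)
      }
    }
  }
  cand <- if (length(cand)) do.call(rbind, cand) else
    data.frame(tag_id = integer(0), seq = character(0),
               chrom = character(0), win_start = integer(0),
               win_end = integer(0), strand = character(0),
               side = character(0), mature_offset = integer(0),
               structure = character(0), pair_count = integer(0),
               accepted = logical(0), reason = character(0),
               total_count = numeric(0), stringsAsFactors = FALSE)

  acc <- cand[cand$accepted, , drop = FALSE]
  ## merge overlapping accepted windows on a chromosome into one miRNA;
  ## strand is ignored on purpose: a mature read exact-matches both its
  ## own arm and the star arm (opposite strand) of the same precursor
  records <- empty_mirna_records(smp)
  if (nrow(acc) > 0) {
    acc <- acc[order(acc$chrom, acc$win_start, -acc$total_count), ,
               drop = FALSE]
    groups <- integer(nrow(acc)); g <- 0L
    last_chrom <- ""; last_end <- -1L
    for (i in seq_len(nrow(acc))) {
      if (acc$chrom[i] != last_chrom || acc$win_start[i] > last_end) {
        g <- g + 1L
        last_chrom <- acc$chrom[i]
        last_end <- acc$win_end[i]
      } else {
        last_end <- max(last_end, acc$win_end[i])
      }
      groups[i] <- g
    }
    rec <- lapply(split(seq_len(nrow(acc)), groups), function(idx) {
      sub <- acc[idx, , drop = FALSE]
      top <- sub[which.max(sub$total_count), ]
      tag_rows <- catalog$tags$tag_id %in% unique(sub$tag_id)
      counts <- colSums(catalog$tags[tag_rows, smp, drop = FALSE])
      cbind(data.frame(mirna_id = NA_character_, status = "novel",
                       family = NA_character_,
                       mature_seq = dna_to_rna(top$seq),
                       chrom = top$chrom, start = top$win_start,
                       end = top$win_end, strand = top$strand,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(counts), check.names = FALSE))
    })
    records <- do.call(rbind, rec)
    records <- records[order(records$chrom, records$start), , drop = FALSE]
    records$mirna_id <- paste0("novel_", seq_len(nrow(records)))
    rownames(records) <- NULL
  }
  list(records = records, candidates = cand)
}

#' Assign a family to novel miRNAs by edit distance to reference matures
#'
#' The family of the closest reference mature (Levenshtein distance) is
#' assigned when the distance is at most `max_distance`; ties go to the
#' lexicographically smallest family.
#'
#' @param novel MirnaRecord data.frame (status "novel")
#' @param reference list from [read_mirna_reference()]
#' @param max_distance maximum edit distance for a family call
#' @return `novel` with the `family` column filled (NA when no family is
#'   within range)
#' @export
assign_family <- function(novel, reference, max_distance = 3L) {
  if (nrow(novel) == 0 || length(reference$mature) == 0) return(novel)
  fams <- vapply(names(reference$mature), mirna_family, character(1))
  d <- utils::adist(novel$mature_seq, reference$mature)
  for (i in seq_len(nrow(novel))) {
    dmin <- min(d[i, ])
    if (dmin <= max_distance) {
      cand <- sort(unique(fams[which(d[i, ] == dmin)]))
      novel$family[i] <- cand[1]
    }
  }
  novel
}

#' Per-tissue miRNA sets and their Venn partition
#'
#' A miRNA belongs to a tissue when its replicate-summed count reaches
#' `min_count`.
#'
#' @param records MirnaRecord data.frame with per-sample count columns
#' @param tissue_of_sample named character vector mapping sample -> tissue
#' @param min_count minimum summed count for tissue membership
#' @return list with `sets` (per-tissue id vectors), `shared` (ids present
#'   in every tissue), and `partition` (named counts per membership
#'   signature, e.g. "NW&TW")
#' @export
tissue_mirna_sets <- function(records, tissue_of_sample, min_count = 1L) {
  tissues <- unique(unname(tissue_of_sample))
  sets <- lapply(tissues, function(t) {
    s <- names(tissue_of_sample)[tissue_of_sample == t]
    tot <- rowSums(records[, s, drop = FALSE])
    records$mirna_id[tot >= min_count]
  })
  names(sets) <- tissues
  universe <- unique(unlist(sets))
  sig <- vapply(universe, function(id) {
    paste(tissues[vapply(sets, function(s) id %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  partition <- table(sig)
  shared <- universe[sig == paste(tissues, collapse = "&")]
  list(sets = sets, shared = shared,
       partition = stats::setNames(as.integer(partition),
                                   names(partition)))
}
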