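## Plant-style miRNA target prediction: reverse-complement scanning with a
## position-weighted expectation score (mismatch 1, G:U 0.5, gap 2;
## penalties doubled over miRNA positions 2-13) and a nominal cleavage
## coordinate opposite miRNA positions 10/11.

.default_penalties <- list(mismatch = 1.0, gu = 0.5, gap = 2.0,
                           seed_range = c(2L, 13L), seed_multiplier = 2)

## penalty lookup: rows = miRNA base, cols = target base (RNA alphabet).
## 0 for a Watson-Crick pair, `gu` for a wobble, `mismatch` otherwise.
penalty_matrix <- function(pen = .default_penalties) {
  b <- c("A", "C", "G", "U")
  P <- matrix(pen$mismatch, 4, 4, dimnames = list(b, b))
  P["A", "U"] <- P["U", "A"] <- P["G", "C"] <- P["C", "G"] <- 0
  P["G", "U"] <- P["U", "G"] <- pen$gu
  P
}

#' Expectation score of a miRNA-target duplex alignment
#'
#' Sums mispairing penalties over the alignment: mismatch 1.0, G:U wobble
#' 0.5, gap (single-nucleotide bulge) 2.0, with every penalty doubled when
#' it falls at miRNA positions 2-13 (the extended seed). A perfect
#' complement scores 0; lower is a better target.
#'
#' @param alignment data.frame with columns `mirna_pos` (1-based, 5'->3' on
#'   the miRNA; for a gap row, the position of the next miRNA base),
#'   `mirna_base` ("-" for a gap), `target_base`, and `code` in
#'   {"match", "GU", "mismatch", "gap"}
#' @param penalties list like `.default_penalties` (config-exposed scoring
#'   constants)
#' @return numeric expectation score in penalty units
#' @examples
#' aln <- data.frame(mirna_pos = 1:3, mirna_base = c("A", "C", "G"),
#'                   target_base = c("U", "G", "C"),
#'                   code = c("match", "match", "match"))
#' expectation_score(aln) # 0
#' @export
expectation_score <- function(alignment, penalties = .default_penalties) {
  if (!all(alignment$code %in% c("match", "GU", "mismatch", "gap"))) {
    stop("invalid pairing codes")
  }
  ## validate codes against the sequences where both bases are present
  both <- alignment$code != "gap"
  if (any(both)) {
    a <- toupper(dna_to_rna(alignment$mirna_base[both]))
    b <- toupper(dna_to_rna(alignment$target_base[both]))
    expect <- ifelse(is_wc_pair(a, b), "match",
                     ifelse(is_gu_pair(a, b), "GU", "mismatch"))
    if (!all(expect == alignment$code[both])) {
      stop("pairing code inconsistent with sequences")
    }
  }
  base_pen <- c(match = 0, GU = penalties$gu, mismatch = penalties$mismatch,
                gap = penalties$gap)[alignment$code]
  in_seed <- alignment$mirna_pos >= penalties$seed_range[1] &
    alignment$mirna_pos <= penalties$seed_range[2]
  sum(base_pen * ifelse(in_seed, penalties$seed_multiplier, 1))
}

#' Scan a transcript for miRNA target sites
#'
#' Slides the miRNA antiparallel along the transcript (miRNA 5' end pairs
#' the site's 3' end) scoring every gapless site and every single-bulge
#' variant (one extra transcript base between adjacent miRNA positions,
#' never between positions 10 and 11). All sites scoring at or below
#' `cutoff` are returned best-first. The nominal cleavage position is the
#' transcript base paired with miRNA position 10 (the cut lies between the
#' bases opposite miRNA positions 10 and 11).
#'
#' @param mirna RNA (or DNA) string, 5'->3'
#' @param transcript RNA (or DNA) string, 5'->3' sense strand
#' @param cutoff maximum expectation score reported
#' @param penalties scoring constants (see [expectation_score()])
#' @param max_bulges 0 or 1 single-nucleotide bulges per site
#' @return TargetHit data.frame (site_start, site_end, expectation, n_gaps,
#'   gap_after (miRNA position 5' of the bulge, NA if none), cleavage_pos)
#' @export
scan_transcript <- function(mirna, transcript, cutoff = 3.0,
                            penalties = .default_penalties,
                            max_bulges = 1L) {
  m <- split_chars(toupper(dna_to_rna(mirna)))
  tchr <- split_chars(toupper(dna_to_rna(transcript)))
  L <- length(m); n <- length(tchr)
  if (n < L) stop("transcript shorter than miRNA")
  bases <- c("A", "C", "G", "U")
  mi <- match(m, bases); ti <- match(tchr, bases)
  P <- penalty_matrix(penalties)
  w <- ifelse(seq_len(L) >= penalties$seed_range[1] &
                seq_len(L) <= penalties$seed_range[2],
              penalties$seed_multiplier, 1)

  hits <- list()
  ## gapless: miRNA pos i pairs transcript pos s + L - i
  S0 <- n - L + 1L
  score0 <- numeric(S0)
  term0 <- matrix(0, L, S0)
  for (i in seq_len(L)) {
    idx <- ti[seq(L - i + 1L, n - i + 1L)]
    term0[i, ] <- w[i] * P[cbind(mi[i], idx)]
  }
  score0 <- colSums(term0)
  sel <- which(score0 <= cutoff)
  if (length(sel)) {
    hits[[1]] <- data.frame(site_start = sel, site_end = sel + L - 1L,
                            expectation = score0[sel], n_gaps = 0L,
                            gap_after = NA_integer_,
                            cleavage_pos = sel + L - 10L,
                            stringsAsFactors = FALSE)
  }

  if (max_bulges >= 1L && n >= L + 1L) {
    ## bulged site of length L+1 starting at s: miRNA pos i pairs
    ## s + L + 1 - i for i <= g, and s + L - i for i > g
    S1 <- n - L
    term1 <- matrix(0, L, S1)
    for (i in seq_len(L)) {
      idx <- ti[seq(L - i + 2L, n - i + 1L)]
      term1[i, ] <- w[i] * P[cbind(mi[i], idx)]
    }
    A <- apply(term1, 2, cumsum)                    # A[g, s]
    B <- apply(term0[, seq_len(S1), drop = FALSE], 2,
               function(col) rev(cumsum(rev(col)))) # B[g, s] = sum i>=g
    gs <- setdiff(seq_len(L - 1L), 10L)
    best_g <- rep(NA_integer_, S1)
    best_sc <- rep(Inf, S1)
    for (g in gs) {
      gap_w <- penalties$gap *
        if ((g + 1L) >= penalties$seed_range[1] &&
            (g + 1L) <= penalties$seed_range[2])
          penalties$seed_multiplier else 1
      sc <- A[g, ] + (if (g + 1L <= L) B[g + 1L, ] else 0) + gap_w
      better <- sc < best_sc
      best_sc[better] <- sc[better]
      best_g[better] <- g
    }
    sel <- which(best_sc <= cutoff)
    if (length(sel)) {
      g <- best_g[sel]
      cleave <- ifelse(g >= 10L, sel + L + 1L - 10L, sel + L - 10L)
      hits[[length(hits) + 1L]] <- data.frame(
        site_start = sel, site_end = sel + L, expectation = best_sc[sel],
        n_gaps = 1L, gap_after = g, cleavage_pos = cleave,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(site_start = integer(0), site_end = integer(0),
                      expectation = numeric(0), n_gaps = integer(0),
                      gap_after = integer(0), cleavage_pos = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  ## a bulged variant never beats a gapless site at the same start;
  ## drop the worse duplicate per start position
  out <- out[order(out$site_start, out$expectation, out$n_gaps), ,
             drop = FALSE]
  out <- out[!duplicated(out$site_start), , drop = FALSE]
  out <- out[order(out$expectation, out$site_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reconstruct the duplex alignment of a reported target site
#'
#' @param mirna,transcript sequences given to [scan_transcript()]
#' @param hit one row of its output
#' @return DuplexAlignment data.frame accepted by [expectation_score()]
#' @export
hit_alignment <- function(mirna, transcript, hit) {
  m <- split_chars(toupper(dna_to_rna(mirna)))
  tchr <- split_chars(toupper(dna_to_rna(transcript)))
  L <- length(m); s <- hit$site_start
  rows <- list()
  if (hit$n_gaps == 0L) {
    tpos <- s + L - seq_len(L)
  } else {
    g <- hit$gap_after
    tpos <- ifelse(seq_len(L) <= g, s + L + 1L - seq_len(L),
                   s + L - seq_len(L))
    rows$gap <- data.frame(mirna_pos = g + 1L, mirna_base = "-",
                           target_base = tchr[s + L - g], code = "gap",
                           stringsAsFactors = FALSE)
  }
  a <- m; b <- tchr[tpos]
  code <- ifelse(is_wc_pair(a, b), "match",
                 ifelse(is_gu_pair(a, b), "GU", "mismatch"))
  aln <- data.frame(mirna_pos = seq_len(L), mirna_base = a,
                    target_base = b, code = code, stringsAsFactors = FALSE)
  if (!is.null(rows$gap)) aln <- rbind(aln, rows$gap)
  aln[order(aln$mirna_pos, aln$mirna_base == "-"), ]
}

#' Predict targets for a set of miRNAs over a transcriptome
#'
#' @param mirnas named RNA character vector (or MirnaRecord data.frame with
#'   `mirna_id` and `mature_seq`)
#' @param transcripts named character vector of transcript sequences, or a
#'   FASTA path
#' @param cutoff maximum expectation score
#' @param penalties scoring constants
#' @return TargetHit data.frame (mirna_id, transcript_id, expectation,
#'   site_start, site_end, n_gaps, cleavage_pos, best: one best hit per
#'   miRNA-transcript pair flagged for network use)
#' @export
predict_targets <- function(mirnas, transcripts, cutoff = 3.0,
                            penalties = .default_penalties) {
  if (is.data.frame(mirnas)) {
    mirnas <- stats::setNames(mirnas$mature_seq, mirnas$mirna_id)
  }
  if (is.character(transcripts) && length(transcripts) == 1 &&
      file.exists(transcripts)) {
    transcripts <- read_genome(transcripts)
  }
  if (anyDuplicated(names(transcripts))) stop("duplicate transcript IDs")
  rows <- list()
  for (mid in names(mirnas)) {
    for (tid in names(transcripts)) {
      h <- scan_transcript(mirnas[[mid]], transcripts[[tid]], cutoff,
                           penalties)
      if (nrow(h) == 0) next
      h$best <- seq_len(nrow(h)) == 1L
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(mirna_id = mid, transcript_id = tid,
                   stringsAsFactors = FALSE), h)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      expectation = numeric(0), n_gaps = integer(0),
                      gap_after = integer(0), cleavage_pos = integer(0),
                      best = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
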