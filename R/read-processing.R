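## Read cleaning, exact mapping, annotation masking and composition
## profiles for small-RNA libraries.

#' Read a FASTQ file into a ReadSet
#'
#' @param path FASTQ file (Phred+33, uncompressed)
#' @param sample_id label attached to the set; defaults to the file stem
#' @return a `ReadSet`: data.frame (read_id, seq, qual) with attribute
#'   `sample_id`
#' @export
read_fastq <- function(path, sample_id = NULL) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  rs <- data.frame(read_id = names(x), seq = as.character(x),
                   qual = as.character(S4Vectors::mcols(x)$qualities),
                   stringsAsFactors = FALSE)
  rownames(rs) <- NULL
  attr(rs, "sample_id") <- if (is.null(sample_id))
    sub("\\.(fastq|fq)$", "", basename(path)) else sample_id
  rs
}

#' Clean raw small-RNA reads
#'
#' Trims the 3' adapter at its first occurrence (exact match of at least
#' `min_adapter_match` nt of the adapter prefix), then discards reads that
#' fail the quality filters: N fraction above `max_n_frac` or any of the
#' final `tail_window` bases with Phred quality below `min_tail_q`. Reads
#' surviving those filters are the "clean reads"; the subset whose trimmed
#' length lies in `[min_len, max_len]` is the "total sRNA" set returned for
#' mapping (clean reads >= total sRNA, matching the conventional read-
#' accounting table layout).
#'
#' @param raw ReadSet (see [read_fastq()])
#' @param adapter 3' adapter DNA string
#' @param min_len,max_len retained trimmed-length range (nt)
#' @param max_n_frac maximum tolerated fraction of N bases
#' @param min_tail_q minimum Phred quality required over the 3' tail
#' @param tail_window number of 3'-terminal bases checked against
#'   `min_tail_q`
#' @param min_adapter_match minimum adapter prefix length for a trim
#' @return list with `reads` (the total-sRNA ReadSet) and `stats` (a
#'   CleanStats row: raw_reads, clean_reads, total_srna; mapped counts are
#'   filled in by [collapse_and_map()])
#' @export
clean_reads <- function(raw, adapter, min_len = 18L, max_len = 30L,
                        max_n_frac = 0.10, min_tail_q = 20L,
                        tail_window = 3L, min_adapter_match = 8L) {
  if (nrow(raw) == 0) stop("empty ReadSet")
  adapter <- toupper(adapter)
  if (!grepl("^[ACGT]+$", adapter)) stop("adapter must be a DNA string")
  probe <- substr(adapter, 1, min_adapter_match)

  hit <- regexpr(probe, raw$seq, fixed = TRUE)
  trim_to <- ifelse(hit > 0, hit - 1L, nchar(raw$seq))
  seq <- substr(raw$seq, 1L, trim_to)
  qual <- substr(raw$qual, 1L, trim_to)
  len <- nchar(seq)

  n_frac <- ifelse(len > 0,
                   (nchar(seq) - nchar(gsub("N", "", seq, fixed = TRUE))) /
                     pmax(len, 1L), 1)
  tail_ok <- vapply(seq_along(seq), function(i) {
    if (len[i] == 0) return(FALSE)
    w <- min(tail_window, len[i])
    q <- utf8ToInt(substr(qual[i], len[i] - w + 1L, len[i])) - 33L
    all(q >= min_tail_q)
  }, logical(1))

  is_clean <- len > 0 & n_frac <= max_n_frac & tail_ok
  in_range <- is_clean & len >= min_len & len <= max_len

  reads <- data.frame(read_id = raw$read_id[in_range], seq = seq[in_range],
                      qual = qual[in_range], stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  attr(reads, "sample_id") <- attr(raw, "sample_id")
  stats <- data.frame(sample = attr(raw, "sample_id") %||% NA_character_,
                      raw_reads = nrow(raw), clean_reads = sum(is_clean),
                      total_srna = sum(in_range),
                      mapped_srna = NA_integer_,
                      mapping_ratio = NA_real_, stringsAsFactors = FALSE)
  list(reads = reads, stats = stats)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mapping ratio as printed in read-accounting tables
#'
#' @param mapped,total mapped and total small-RNA read counts
#' @return mapped / total * 100, rounded to 2 decimals
#' @examples
#' mapping_ratio(7378835, 8002438) # 92.21
#' @export
mapping_ratio <- function(mapped, total) {
  round(mapped / total * 100, 2)
}

#' Load a genome FASTA as a named character vector
#' @param path FASTA file
#' @return named character vector of chromosome sequences (uppercase DNA)
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)),
                  sub("\\s.*$", "", names(x)))
}

#' Collapse cleaned reads to unique tags and map them exactly
#'
#' Unique sequences are counted per sample and placed on the genome by
#' exact matching on both strands (no mismatches). Each tag's count is
#' assigned once, regardless of how many loci it matches; tags with no
#' locus are flagged unmapped. Per-sample mapped totals (reads whose tag
#' has at least one locus) complete the CleanStats table.
#'
#' @param cleaned named list of per-sample cleaned ReadSets (or a single
#'   ReadSet)
#' @param genome named character vector from [read_genome()]
#' @param stats optional CleanStats data.frame to complete
#' @return a `TagCatalog`: list with `tags` (tag_id, seq, length, n_loci,
#'   unmapped, one count column per sample), `loci` (tag_id, chrom, start,
#'   end, strand) and `stats`
#' @export
collapse_and_map <- function(cleaned, genome, stats = NULL) {
  if (length(genome) == 0 || all(!nzchar(genome))) stop("empty genome")
  if (is.data.frame(cleaned)) {
    cleaned <- stats::setNames(list(cleaned),
                               attr(cleaned, "sample_id") %||% "sample1")
  }
  samples <- names(cleaned)
  all_seqs <- sort(unique(unlist(lapply(cleaned, `[[`, "seq"),
                                 use.names = FALSE)))
  counts <- sapply(cleaned, function(rs) {
    tab <- table(factor(rs$seq, levels = all_seqs))
    as.integer(tab)
  })
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = length(samples))
  colnames(counts) <- samples

  loci <- exact_match_loci(all_seqs, genome)
  n_loci <- integer(length(all_seqs))
  if (nrow(loci) > 0) {
    tb <- table(factor(loci$tag_id, levels = seq_along(all_seqs)))
    n_loci <- as.integer(tb)
  }
  tags <- data.frame(tag_id = seq_along(all_seqs), seq = all_seqs,
                     length = nchar(all_seqs), n_loci = n_loci,
                     unmapped = n_loci == 0L, stringsAsFactors = FALSE)
  tags <- cbind(tags, as.data.frame(counts, check.names = FALSE))

  if (!is.null(stats)) {
    for (i in seq_len(nrow(stats))) {
      s <- stats$sample[i]
      if (s %in% samples) {
        stats$mapped_srna[i] <- sum(counts[!tags$unmapped, s])
        stats$mapping_ratio[i] <- mapping_ratio(stats$mapped_srna[i],
                                                stats$total_srna[i])
      }
    }
  }
  structure(list(tags = tags, loci = loci, stats = stats),
            class = "TagCatalog")
}

## Exact placement of tags on both strands via Biostrings pattern matching.
exact_match_loci <- function(seqs, genome) {
  rows <- list()
  subjects <- lapply(genome, Biostrings::DNAString)
  for (ti in seq_along(seqs)) {
    pat <- seqs[ti]
    rc <- revcomp(pat)
    for (chrom in names(genome)) {
      fwd <- Biostrings::matchPattern(pat, subjects[[chrom]])
      if (length(fwd)) {
        rows[[length(rows) + 1L]] <- data.frame(
          tag_id = ti, chrom = chrom,
          start = BiocGenerics::start(fwd), end = BiocGenerics::end(fwd),
          strand = "+", stringsAsFactors = FALSE)
      }
      rev <- Biostrings::matchPattern(rc, subjects[[chrom]])
      if (length(rev)) {
        rows[[length(rows) + 1L]] <- data.frame(
          tag_id = ti, chrom = chrom,
          start = BiocGenerics::start(rev), end = BiocGenerics::end(rev),
          strand = "-", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(tag_id = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$tag_id, out$chrom, out$start, out$strand), , drop = FALSE]
}

#' Read masking annotations from a GFF3 or BED file
#'
#' BED input (0-based half-open) is converted to 1-based inclusive
#' coordinates on read. Feature types can be restricted with `types`.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or BED file
#' @param types optional character vector of feature types to keep (GFF3
#'   only)
#' @return GRanges of masked intervals
#' @export
read_mask <- function(path, types = c("rRNA", "tRNA", "snRNA", "snoRNA",
                                      "repeat", "protein_coding")) {
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "BED" else "GFF3"
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "GFF3" && !is.null(gr$type) && !is.null(types)) {
    gr <- gr[as.character(gr$type) %in% types]
  }
  if (any(BiocGenerics::end(gr) < BiocGenerics::start(gr))) {
    stop("malformed interval: end < start")
  }
  gr
}

#' Remove tags explained by annotated non-miRNA classes
#'
#' A mapped tag is removed only when *every* locus overlaps a masked
#' feature; tags with at least one unmasked locus are retained (masked loci
#' are dropped from their locus list). Unmapped tags are untouched. The
#' operation is idempotent.
#'
#' @param catalog TagCatalog from [collapse_and_map()]
#' @param mask GRanges of masked intervals (e.g. [read_mask()]); NULL or
#'   empty leaves the catalog unchanged
#' @return filtered TagCatalog
#' @export
mask_annotated <- function(catalog, mask) {
  if (is.null(mask) || length(mask) == 0 || nrow(catalog$loci) == 0) {
    return(catalog)
  }
  loci_gr <- GenomicRanges::GRanges(
    catalog$loci$chrom,
    IRanges::IRanges(catalog$loci$start, catalog$loci$end))
  hits <- GenomicRanges::findOverlaps(loci_gr, mask, ignore.strand = TRUE)
  masked_locus <- seq_len(nrow(catalog$loci)) %in%
    S4Vectors::queryHits(hits)
  all_masked <- tapply(masked_locus, catalog$loci$tag_id, all)
  fully_masked_ids <- as.integer(names(all_masked))[unlist(all_masked)]
  keep_tag <- !(catalog$tags$tag_id %in% fully_masked_ids)
  catalog$tags <- catalog$tags[keep_tag, , drop = FALSE]
  catalog$loci <- catalog$loci[!masked_locus &
                                 catalog$loci$tag_id %in%
                                 catalog$tags$tag_id, , drop = FALSE]
  rownames(catalog$tags) <- rownames(catalog$loci) <- NULL
  catalog
}

catalog_samples <- function(catalog) {
  setdiff(colnames(catalog$tags),
          c("tag_id", "seq", "length", "n_loci", "unmapped"))
}

#' Read-weighted length distribution of a tag catalog
#'
#' @param catalog TagCatalog
#' @param lengths lengths to report (default 18-30 nt)
#' @return named numeric vector of fractions summing to 1
#' @export
length_profile <- function(catalog, lengths = 18:30) {
  if (nrow(catalog$tags) == 0) stop("empty catalog")
  smp <- catalog_samples(catalog)
  w <- rowSums(catalog$tags[, smp, drop = FALSE])
  keep <- catalog$tags$length %in% lengths
  tab <- tapply(w[keep], factor(catalog$tags$length[keep],
                                levels = lengths), sum)
  tab[is.na(tab)] <- 0
  tab / sum(tab)
}

#' First-nucleotide composition by tag length
#'
#' Read-weighted fraction of each first base (RNA alphabet) at each tag
#' length; rows (lengths with any reads) sum to 1.
#'
#' @param catalog TagCatalog
#' @param lengths lengths to report (default 18-30 nt)
#' @return matrix length x base (A, C, G, U)
#' @export
first_base_profile <- function(catalog, lengths = 18:30) {
  if (nrow(catalog$tags) == 0) stop("empty catalog")
  smp <- catalog_samples(catalog)
  w <- rowSums(catalog$tags[, smp, drop = FALSE])
  first <- dna_to_rna(substr(catalog$tags$seq, 1, 1))
  keep <- catalog$tags$length %in% lengths & first %in% c("A", "C", "G", "U")
  m <- tapply(w[keep],
              list(factor(catalog$tags$length[keep], levels = lengths),
                   factor(first[keep], levels = c("A", "C", "G", "U"))),
              sum)
  m[is.na(m)] <- 0
  rs <- rowSums(m)
  m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
  m
}
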