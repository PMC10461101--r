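## Independent brute-force oracles. These deliberately share no code with
## the package implementations they check.

## Exhaustive enumeration of non-crossing structures, returning the
## maximum number of {AU, GC, GU} pairs with hairpin loops >= min_loop.
enum_max_pairs <- function(seq, min_loop = 3L) {
  x <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  ok <- c("AU", "UA", "GC", "CG", "GU", "UG")
  rec <- function(idx) {
    if (length(idx) < 2) return(0L)
    i <- idx[1]
    best <- rec(idx[-1])
    for (j in idx[-1]) {
      if (j - i > min_loop && paste0(x[i], x[j]) %in% ok) {
        best <- max(best, 1L + rec(idx[idx > i & idx < j]) +
                      rec(idx[idx > j]))
      }
    }
    best
  }
  rec(seq_along(x))
}

## Naive substring mapper (both strands) using fixed-string gregexpr.
oracle_locate <- function(tag, genome) {
  rows <- list()
  for (chrom in names(genome)) {
    for (v in list(list(tag, "+"), list(revcomp(tag), "-"))) {
      hit <- gregexpr(v[[1]], genome[[chrom]], fixed = TRUE)[[1]]
      if (hit[1] != -1) {
        for (h in as.integer(hit)) {
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, start = h, end = h + nchar(tag) - 1L,
            strand = v[[2]], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

## Position-by-position target-site scan: per start, the better of the
## gapless score and the best single-bulge variant (bulge never between
## miRNA positions 10 and 11).
oracle_scan <- function(mirna, transcript, cutoff = 3, max_bulges = 1L) {
  pen1 <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% c("AU", "UA", "GC", "CG")) 0
    else if (p %in% c("GU", "UG")) 0.5
    else 1
  }
  wt <- function(i) if (i >= 2 && i <= 13) 2 else 1
  m <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  tc <- strsplit(chartr("T", "U", toupper(transcript)), "")[[1]]
  L <- length(m); n <- length(tc)
  rows <- list()
  for (s in seq_len(n - L + 1L)) {
    sc <- 0
    for (i in seq_len(L)) sc <- sc + wt(i) * pen1(m[i], tc[s + L - i])
    best <- c(sc = sc, gaps = 0)
    if (max_bulges >= 1L && s <= n - L) {
      for (g in setdiff(seq_len(L - 1L), 10L)) {
        sg <- 2 * (if (g + 1L >= 2 && g + 1L <= 13) 2 else 1)
        for (i in seq_len(L)) {
          b <- if (i <= g) tc[s + L + 1L - i] else tc[s + L - i]
          sg <- sg + wt(i) * pen1(m[i], b)
        }
        if (sg < best["sc"]) best <- c(sc = sg, gaps = 1)
      }
    }
    if (best["sc"] <= cutoff) {
      rows[[length(rows) + 1L]] <- data.frame(
        site_start = s, expectation = unname(best["sc"]),
        n_gaps = as.integer(best["gaps"]))
    }
  }
  if (length(rows) == 0) {
    return(data.frame(site_start = integer(0), expectation = numeric(0),
                      n_gaps = integer(0)))
  }
  do.call(rbind, rows)
}

## Hypergeometric upper tail by direct enumeration of draw compositions.
oracle_hyper_p <- function(k, K, n, N) {
  js <- seq(max(0, k), min(K, n))
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
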