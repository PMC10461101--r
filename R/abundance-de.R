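## Reads-per-million normalization and differential abundance calling.

#' Normalize miRNA counts to reads per million
#'
#' Normalized abundance = mapped read count / total reads * 1,000,000,
#' applied exactly with no pseudocount.
#'
#' @param counts miRNA x sample integer matrix
#' @param totals named per-sample totals (mapped read counts)
#' @return an `AbundanceMatrix`: list with `values` (normalized matrix) and
#'   `totals`
#' @examples
#' normalize_abundance(matrix(500, 1, 1, dimnames = list("m", "s")),
#'                     c(s = 1e6))$values # 500
#' @export
normalize_abundance <- function(counts, totals) {
  counts <- as.matrix(counts)
  if (is.null(names(totals))) names(totals) <- colnames(counts)
  totals <- totals[colnames(counts)]
  if (any(is.na(totals)) || any(totals <= 0)) {
    bad <- colnames(counts)[is.na(totals) | totals <= 0]
    stop("zero or missing total for sample(s): ",
         paste(bad, collapse = ", "))
  }
  values <- sweep(counts, 2, totals, "/") * 1e6
  structure(list(values = values, totals = totals),
            class = "AbundanceMatrix")
}

#' Welch test for differential abundance between two replicate groups
#'
#' Fold change is computed on pseudocounted group means,
#' (mean(a)+pc)/(mean(b)+pc); the p-value comes from a two-sided Welch
#' t-test on log2(abundance + pc). When both groups have zero within-group
#' variance the test degenerates: p = 0 if the constants differ, p = 1 if
#' they are equal.
#'
#' @param a,b normalized replicate abundances (>= 2 each)
#' @param pseudocount stability constant on the normalized scale
#' @param fc_min,p_max significance thresholds (|FC| >= fc_min, p <= p_max)
#' @return one-row DEResult data.frame (log2_fc, p_value, direction,
#'   significant)
#' @export
de_test <- function(a, b, pseudocount = 1.0, fc_min = 2, p_max = 0.05) {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 replicates per group")
  fc <- (mean(a) + pseudocount) / (mean(b) + pseudocount)
  log2_fc <- log2(fc)
  la <- log2(a + pseudocount); lb <- log2(b + pseudocount)
  if (stats::var(la) == 0 && stats::var(lb) == 0) {
    p <- if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0
  } else {
    p <- tryCatch(stats::t.test(la, lb)$p.value, error = function(e) 1)
  }
  significant <- (fc >= fc_min || fc <= 1 / fc_min) && p <= p_max
  data.frame(log2_fc = log2_fc, p_value = p,
             direction = ifelse(log2_fc >= 0, "up-in-A", "up-in-B"),
             significant = significant, stringsAsFactors = FALSE)
}

#' Differential abundance over a set of tissue contrasts
#'
#' @param abund AbundanceMatrix from [normalize_abundance()]
#' @param tissue_of_sample named character vector mapping sample -> tissue
#' @param contrasts list of c(tissueA, tissueB) pairs; default all ordered
#'   tissue pairs in order of appearance
#' @param pseudocount,fc_min,p_max passed to [de_test()]
#' @return DEResult data.frame (mirna_id, contrast, log2_fc, p_value,
#'   q_value (BH within contrast), direction, significant)
#' @export
de_table <- function(abund, tissue_of_sample, contrasts = NULL,
                     pseudocount = 1.0, fc_min = 2, p_max = 0.05) {
  values <- abund$values
  tissues <- unique(unname(tissue_of_sample))
  if (is.null(contrasts)) {
    contrasts <- utils::combn(tissues, 2, simplify = FALSE)
  }
  out <- list()
  for (ct in contrasts) {
    sa <- names(tissue_of_sample)[tissue_of_sample == ct[1]]
    sb <- names(tissue_of_sample)[tissue_of_sample == ct[2]]
    res <- do.call(rbind, lapply(rownames(values), function(m) {
      r <- de_test(values[m, sa], values[m, sb], pseudocount, fc_min,
                   p_max)
      cbind(data.frame(mirna_id = m,
                       contrast = paste(ct, collapse = ":"),
                       stringsAsFactors = FALSE), r)
    }))
    res$direction <- ifelse(res$log2_fc >= 0, paste0("up-in-", ct[1]),
                            paste0("up-in-", ct[2]))
    res$q_value <- stats::p.adjust(res$p_value, method = "BH")
    out[[length(out) + 1L]] <- res
  }
  out <- do.call(rbind, out)
  out[, c("mirna_id", "contrast", "log2_fc", "p_value", "q_value",
          "direction", "significant")]
}

#' Summarize significant miRNAs per contrast and direction
#'
#' @param de DEResult data.frame from [de_table()]
#' @return data.frame (contrast, n_significant, one count per direction)
#' @export
de_summary <- function(de) {
  out <- lapply(split(de, de$contrast), function(d) {
    sig <- d[d$significant, , drop = FALSE]
    dirs <- table(sig$direction)
    df <- data.frame(contrast = d$contrast[1], n_significant = nrow(sig),
                     stringsAsFactors = FALSE)
    for (nm in names(dirs)) df[[nm]] <- as.integer(dirs[[nm]])
    df
  })
  nms <- unique(unlist(lapply(out, names)))
  out <- lapply(out, function(d) {
    d[setdiff(nms, names(d))] <- 0L
    d[nms]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
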