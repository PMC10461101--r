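## Relative expression from qPCR cycle thresholds by the 2^-ddCt method.

#' Relative expression by the 2^-ddCt method
#'
#' Computes 2^-((target_ct - ref_ct) - (calib_target_ct - calib_ref_ct)),
#' i.e. double normalization to a reference gene and a calibrator sample,
#' assuming amplification efficiency 2.0. An efficiency-corrected variant
#' replaces the base 2 with the supplied efficiency.
#'
#' @param target_ct,ref_ct Ct of the gene of interest and the reference
#'   gene in the test sample
#' @param calib_target_ct,calib_ref_ct the same two Cts in the calibrator
#'   sample
#' @param efficiency amplification efficiency (fold per cycle; default 2)
#' @return relative expression (1.0 when test equals calibrator)
#' @examples
#' delta_delta_ct(20, 15, 18, 15) # 0.25
#' @export
delta_delta_ct <- function(target_ct, ref_ct, calib_target_ct,
                           calib_ref_ct, efficiency = 2) {
  cts <- c(target_ct, ref_ct, calib_target_ct, calib_ref_ct)
  if (any(!is.finite(cts))) stop("all Ct values must be finite")
  ddct <- (target_ct - ref_ct) - (calib_target_ct - calib_ref_ct)
  efficiency^(-ddct)
}

#' Relative expression for a full Ct table against a calibrator condition
#'
#' Each sample's target Ct is normalized to that sample's reference-gene
#' Ct (replicates of the reference averaged), then calibrated to the mean
#' delta-Ct of the calibrator condition. Technical replicates are averaged
#' on the linear 2^-ddCt scale.
#'
#' @param ct data.frame (sample_id, gene_id, replicate, ct, is_reference)
#' @param condition_of_sample named character vector mapping sample ->
#'   condition (e.g. tissue)
#' @param calibrator condition used as calibrator
#' @param efficiency amplification efficiency
#' @return data.frame (gene_id, sample_id, condition, rel_expr) of
#'   per-sample relative expression (replicate-averaged)
#' @export
relative_expression <- function(ct, condition_of_sample, calibrator,
                                efficiency = 2) {
  stopifnot(all(c("sample_id", "gene_id", "replicate", "ct",
                  "is_reference") %in% names(ct)))
  if (!calibrator %in% condition_of_sample) {
    stop("calibrator condition not present")
  }
  ref <- ct[ct$is_reference, , drop = FALSE]
  if (nrow(ref) == 0) stop("no reference gene in Ct table")
  if (length(unique(ref$gene_id)) != 1) {
    stop("exactly one reference gene expected")
  }
  ref_ct <- tapply(ref$ct, ref$sample_id, mean)

  tgt <- ct[!ct$is_reference, , drop = FALSE]
  tgt$dct <- tgt$ct - ref_ct[tgt$sample_id]
  calib_samples <- names(condition_of_sample)[
    condition_of_sample == calibrator]
  rows <- lapply(split(tgt, tgt$gene_id), function(d) {
    calib_dct <- mean(d$dct[d$sample_id %in% calib_samples])
    rel <- efficiency^(-(d$dct - calib_dct))
    agg <- tapply(rel, d$sample_id, mean)   # technical reps, linear scale
    data.frame(gene_id = d$gene_id[1], sample_id = names(agg),
               condition = unname(condition_of_sample[names(agg)]),
               rel_expr = as.numeric(agg), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize relative expression per gene and condition
#'
#' @param rel output of [relative_expression()]
#' @param calibrator condition whose mean defines the fold-change baseline
#' @return data.frame (gene_id, condition, mean, se, log2_fc, n); `se` is
#'   NA (flagged) for single-replicate conditions
#' @export
summarize_qpcr <- function(rel, calibrator) {
  rows <- lapply(split(rel, list(rel$gene_id, rel$condition), drop = TRUE),
                 function(d) {
    m <- mean(d$rel_expr)
    se <- if (nrow(d) >= 2) stats::sd(d$rel_expr) / sqrt(nrow(d)) else
      NA_real_
    data.frame(gene_id = d$gene_id[1], condition = d$condition[1],
               mean = m, se = se, n = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  base <- stats::setNames(out$mean[out$condition == calibrator],
                          out$gene_id[out$condition == calibrator])
  out$log2_fc <- log2(out$mean / base[out$gene_id])
  rownames(out) <- NULL
  out[order(out$gene_id, out$condition), ]
}
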