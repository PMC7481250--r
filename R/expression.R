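#' Relative expression by the 2^-ddCt method
#'
#' Fold change of a target gene in a sample relative to a calibrator,
#' normalised by a reference gene:
#' \deqn{2^{-[(Ct_{target,s} - Ct_{ref,s}) - (Ct_{target,c} - Ct_{ref,c})]}.}
#'
#' @param ct_target_s,ct_ref_s Target and reference-gene Ct in the sample.
#' @param ct_target_c,ct_ref_c Target and reference-gene Ct in the
#'   calibrator.
#' @return Fold change. Vectorised.
#' @export
#' @examples
#' delta_delta_ct(24, 20, 26, 20)  # 4
delta_delta_ct <- function(ct_target_s, ct_ref_s, ct_target_c, ct_ref_c) {
  .check_ct(c(ct_target_s, ct_ref_s, ct_target_c, ct_ref_c))
  2^(-((ct_target_s - ct_ref_s) - (ct_target_c - ct_ref_c)))
}

.check_ct <- function(ct) {
  if (any(!is.finite(ct)) || any(ct <= 0) || any(ct >= 45))
    stop("Ct values must lie in (0, 45)")
  invisible(NULL)
}

#' Per-gene relative expression table from qPCR wells
#'
#' For each gene and sample group, computes replicate-wise delta-Ct against
#' the group's mean reference-gene Ct, then delta-delta-Ct against the
#' calibrator group's mean delta-Ct, and reports mean and SD of the 2^-ddCt
#' fold changes over replicates. The calibrator group's mean fold change is
#' 1 by construction for every gene.
#'
#' @param wells Data frame with columns `gene`, `group`, `replicate`, `ct`.
#' @param ref_gene Reference (internal control) gene, e.g. the actin gene;
#'   must be present in every group.
#' @param calibrator_group Group against which fold changes are expressed.
#' @return Data frame with `gene`, `group`, `mean_fold_change`,
#'   `sd_fold_change`, `n`.
#' @export
relative_expression_table <- function(wells, ref_gene = "OsActin1",
                                      calibrator_group) {
  stopifnot(all(c("gene", "group", "replicate", "ct") %in% names(wells)))
  .check_ct(wells$ct)
  groups <- unique(wells$group)
  if (!calibrator_group %in% groups) stop("calibrator group absent from wells")
  ref_mean <- vapply(groups, function(g) {
    ct <- wells$ct[wells$group == g & wells$gene == ref_gene]
    if (length(ct) == 0)
      stop(sprintf("reference gene '%s' missing in group '%s'", ref_gene, g))
    mean(ct)
  }, numeric(1))
  names(ref_mean) <- groups

  targets <- setdiff(unique(wells$gene), ref_gene)
  rows <- list()
  for (gene in targets) {
    # calibrator mean delta-Ct for this gene
    cal <- wells[wells$gene == gene & wells$group == calibrator_group, ]
    if (nrow(cal) == 0)
      stop(sprintf("gene '%s' missing in calibrator group", gene))
    dct_cal <- mean(cal$ct) - ref_mean[[calibrator_group]]
    for (g in groups) {
      w <- wells[wells$gene == gene & wells$group == g, ]
      if (nrow(w) == 0) next
      fc <- 2^(-((w$ct - ref_mean[[g]]) - dct_cal))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, group = g, mean_fold_change = mean(fc),
        sd_fold_change = if (nrow(w) > 1) stats::sd(fc) else NA_real_,
        n = nrow(w))
    }
  }
  do.call(rbind, rows)
}

#' Filter a DEG table for nitrogen-metabolism genes
#'
#' Keeps differentially expressed genes (adjusted p below `alpha`) whose GO
#' annotation matches any of the nitrogen-metabolism keywords by
#' case-insensitive substring. Input order is preserved; the filter is
#' idempotent and monotone in `alpha`.
#'
#' @param degs Data frame with columns `gene_id`, `log2fc`, `padj` and
#'   `go_terms` (either a list column of character vectors or
#'   semicolon-joined strings).
#' @param alpha Adjusted-p threshold for calling a gene differentially
#'   expressed.
#' @param keywords Character vector of GO keywords.
#' @return The qualifying subset of `degs`, original order.
#' @export
filter_nitrogen_degs <- function(degs, alpha = 0.05,
                                 keywords = c("nitrogen", "nitrate",
                                              "ammonia")) {
  stopifnot(all(c("gene_id", "log2fc", "padj", "go_terms") %in% names(degs)))
  if (any(degs$padj < 0 | degs$padj > 1, na.rm = TRUE))
    stop("padj must lie in [0, 1]")
  if (length(keywords) == 0) return(degs[0, , drop = FALSE])
  terms <- degs$go_terms
  if (!is.list(terms)) terms <- strsplit(as.character(terms), ";", fixed = TRUE)
  hit <- vapply(terms, function(tt) {
    any(vapply(keywords, function(k) any(grepl(k, tt, ignore.case = TRUE)),
               logical(1)))
  }, logical(1))
  keep <- !is.na(degs$padj) & degs$padj < alpha & hit
  degs[keep, , drop = FALSE]
}
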