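# Relative qPCR expression by the comparative delta-Cq method with a
# reference (housekeeping) gene, reported as fold change against the
# control-group mean.

#' Relative expression from Cq records
#'
#' Per sample and gene, replicate Cq values are averaged arithmetically;
#' `delta Cq = mean Cq(target) - mean Cq(reference)` within each sample;
#' relative expression is `2^(-delta Cq)`; fold change divides each
#' sample's relative expression by the mean relative expression of the
#' control group for that gene (so the control-group mean fold change is 1
#' by construction).  Amplification efficiency is fixed at 2; no
#' efficiency correction is applied.
#'
#' Samples missing the reference gene are excluded with a warning.
#'
#' @param records data.frame with columns `sample`, `group`, `gene`, `cq`
#'   (replicate rows allowed).
#' @param reference_gene Name of the internal-control gene (default
#'   `"GAPDH"`).
#' @param control_group Name of the control group (default `"control"`).
#' @return data.frame with one row per sample x target gene: `sample`,
#'   `group`, `gene`, `delta_cq`, `rel_expr`, `fold_change`.
#' @export
relative_expression <- function(records, reference_gene = "GAPDH",
                                control_group = "control") {
  stopifnot(all(c("sample", "group", "gene", "cq") %in% names(records)))
  if (any(records$cq <= 0)) stop("Cq values must be positive", call. = FALSE)
  if (!reference_gene %in% records$gene) {
    stop(sprintf("reference gene '%s' absent from records", reference_gene),
         call. = FALSE)
  }
  agg <- stats::aggregate(list(cq = records$cq),
                          by = list(sample = records$sample,
                                    group = records$group,
                                    gene = records$gene),
                          FUN = mean)
  ref <- agg[agg$gene == reference_gene, c("sample", "cq")]
  names(ref)[2] <- "cq_ref"
  tgt <- agg[agg$gene != reference_gene, , drop = FALSE]
  no_ref <- setdiff(unique(tgt$sample), ref$sample)
  if (length(no_ref)) {
    warning("excluding sample(s) without reference gene: ",
            paste(no_ref, collapse = ", "), call. = FALSE)
    tgt <- tgt[!tgt$sample %in% no_ref, , drop = FALSE]
  }
  out <- merge(tgt, ref, by = "sample", sort = FALSE)
  out$delta_cq <- out$cq - out$cq_ref
  out$rel_expr <- 2^(-out$delta_cq)
  if (!control_group %in% out$group) {
    stop(sprintf("control group '%s' absent", control_group), call. = FALSE)
  }
  ctrl_mean <- stats::aggregate(
    list(ctrl = out$rel_expr[out$group == control_group]),
    by = list(gene = out$gene[out$group == control_group]),
    FUN = mean)
  out <- merge(out, ctrl_mean, by = "gene", sort = FALSE)
  out$fold_change <- out$rel_expr / out$ctrl
  out <- out[order(out$gene, out$group, out$sample),
             c("sample", "group", "gene", "delta_cq", "rel_expr",
               "fold_change")]
  rownames(out) <- NULL
  out
}
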