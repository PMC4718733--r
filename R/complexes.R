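#' Stoichiometry loss of a protein complex
#'
#' Loss of within-complex stoichiometry at a time point is the
#' interquartile range (IQR) of the member log2 fold changes: 0 means the
#' members changed in perfect coordination. Quantiles use linear
#' interpolation between order statistics by default.
#'
#' @param member_fold_changes numeric vector of member log2 fold changes
#'   (at least 2 finite values).
#' @param quantile_type quantile convention passed to [stats::quantile()]
#'   (7 = linear interpolation, the common default).
#' @return non-negative IQR value.
#' @examples
#' stoichiometry_loss(c(1, 2, 3, 4)) # 1.5
#' @export
stoichiometry_loss <- function(member_fold_changes, quantile_type = 7) {
  x <- member_fold_changes[is.finite(member_fold_changes)]
  if (length(x) < 2) stop("need at least 2 finite member fold changes")
  q <- stats::quantile(x, c(0.25, 0.75), type = quantile_type, names = FALSE)
  q[2] - q[1]
}

#' Stoichiometry-loss trajectories for a complex catalog
#'
#' Scores every complex with at least `min_members` quantified members at
#' every time point, and summarizes the population of complexes by the
#' mean across complexes per time point.
#'
#' @param fc genes x times log2 fold-change matrix.
#' @param catalog named list of member gene identifier vectors (e.g. from
#'   [read_gmt()]).
#' @param times column time points.
#' @param min_members minimum quantified members for a complex to be
#'   scored.
#' @param quantile_type passed to [stoichiometry_loss()].
#' @return list with `iqr` (complexes x times matrix), `mean_iqr`
#'   (data.frame per time), and `skipped` complexes (with the number of
#'   quantified members).
#' @export
complex_trajectories <- function(fc, catalog, times, min_members = 2,
                                 quantile_type = 7) {
  present <- lapply(catalog, function(g) intersect(unique(g), rownames(fc)))
  n_present <- lengths(present)
  if (all(n_present == 0)) {
    stop("no catalog members found in the data; missing complexes: ",
         paste(utils::head(names(catalog), 5), collapse = ", "))
  }
  score <- n_present >= min_members
  iqr <- t(vapply(present[score], function(g) {
    apply(fc[g, , drop = FALSE], 2, stoichiometry_loss,
          quantile_type = quantile_type)
  }, numeric(ncol(fc))))
  colnames(iqr) <- sprintf("t_%g", times)
  list(iqr = iqr,
       mean_iqr = data.frame(time_h = times, mean_iqr = colMeans(iqr)),
       skipped = n_present[!score])
}

#' Compare stoichiometry loss between two populations or levels
#'
#' Restricts both fold-change tables to their shared genes (as done when
#' comparing the proteome with the transcriptome), scores the shared
#' complexes in both, and reports paired per-time mean IQRs.
#'
#' @param fc_a,fc_b genes x times log2 fold-change matrices (e.g. mother
#'   vs daughter, or proteome vs transcriptome).
#' @param catalog named list of complex member vectors.
#' @param times column time points.
#' @param labels names of the two datasets in the output.
#' @param restrict_shared_genes restrict scoring to genes present in both
#'   tables.
#' @inheritParams complex_trajectories
#' @return data.frame with `time_h` and one mean-IQR column per dataset,
#'   plus the per-complex matrices as attributes `iqr_a` and `iqr_b`.
#' @export
compare_stoichiometry <- function(fc_a, fc_b, catalog, times,
                                  labels = c("a", "b"), min_members = 2,
                                  restrict_shared_genes = TRUE,
                                  quantile_type = 7) {
  if (restrict_shared_genes) {
    genes <- intersect(rownames(fc_a), rownames(fc_b))
    fc_a <- fc_a[genes, , drop = FALSE]
    fc_b <- fc_b[genes, , drop = FALSE]
  }
  ta <- complex_trajectories(fc_a, catalog, times, min_members,
                             quantile_type)
  tb <- complex_trajectories(fc_b, catalog, times, min_members,
                             quantile_type)
  shared <- intersect(rownames(ta$iqr), rownames(tb$iqr))
  out <- data.frame(time_h = times,
                    a = colMeans(ta$iqr[shared, , drop = FALSE]),
                    b = colMeans(tb$iqr[shared, , drop = FALSE]))
  names(out)[2:3] <- paste0("mean_iqr_", labels)
  attr(out, "iqr_a") <- ta$iqr[shared, , drop = FALSE]
  attr(out, "iqr_b") <- tb$iqr[shared, , drop = FALSE]
  out
}
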