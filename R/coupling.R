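#' Divergence from the young state
#'
#' Rank correlation between each time point's abundance (or fold-change)
#' vector and the young reference vector, over shared genes.
#'
#' @param m genes x times matrix.
#' @param times column time points.
#' @param reference_time_h reference time (must be a column).
#' @param method correlation method (default Spearman).
#' @return data.frame with `time_h` and `correlation`.
#' @export
divergence_from_young <- function(m, times, reference_time_h = times[1],
                                  method = "spearman") {
  jref <- which(abs(times - reference_time_h) < 1e-9)
  if (length(jref) != 1) stop("reference time must be present exactly once")
  if (nrow(m) < 3) stop("need at least 3 shared genes")
  ref <- m[, jref]
  data.frame(time_h = times,
             correlation = apply(m, 2, stats::cor, y = ref,
                                 method = method))
}

#' Proteome-transcriptome correlation over time
#'
#' One correlation per time point per method over the genes shared between
#' the two tables. `pearson_raw` correlates raw values, `pearson_log2`
#' log2-transformed values; `spearman` and `kendall` are rank-based (on raw
#' values; ranks are log-invariant).
#'
#' @param proteome,transcriptome genes x times matrices over the same
#'   time points.
#' @param times column time points.
#' @param methods subset of `c("spearman", "pearson_raw", "pearson_log2",
#'   "kendall")`.
#' @return data.frame with `time_h` and one column per method; a method is
#'   `NA` at a time point where it is undefined (constant vector).
#' @export
crosslevel_correlation <- function(proteome, transcriptome, times,
                                   methods = c("spearman", "pearson_raw",
                                               "pearson_log2", "kendall")) {
  methods <- match.arg(methods, several.ok = TRUE)
  genes <- intersect(rownames(proteome), rownames(transcriptome))
  if (length(genes) == 0) stop("no shared genes")
  p <- proteome[genes, , drop = FALSE]
  t2 <- transcriptome[genes, , drop = FALSE]
  one <- function(x, y, method) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    switch(method,
           spearman = stats::cor(x, y, method = "spearman"),
           kendall = stats::cor(x, y, method = "kendall"),
           pearson_raw = stats::cor(x, y),
           pearson_log2 = {
             ok <- x > 0 & y > 0
             stats::cor(log2(x[ok]), log2(y[ok]))
           })
  }
  out <- data.frame(time_h = times)
  for (mth in methods) {
    out[[mth]] <- vapply(seq_along(times),
                         function(j) one(p[, j], t2[, j], mth), numeric(1))
  }
  out
}

#' Co-expression quadrant assignment
#'
#' Classifies each gene by the signs of its protein and transcript log2
#' fold changes: Q1 both up (coupled), Q2 protein up / transcript down
#' (uncoupled protein overabundance), Q3 both down (coupled), Q4 protein
#' down / transcript up (uncoupled). Genes with an exactly zero fold change
#' sit on an axis and are excluded from the quadrant fractions.
#'
#' @param protein_fc,transcript_fc named log2 fold-change vectors; gene
#'   sets are intersected.
#' @return list with `assignment` (data.frame: gene, protein_fc,
#'   transcript_fc, quadrant), `fractions` over Q1-Q4 (denominator excludes
#'   axis genes) and the `n_axis` count.
#' @export
quadrant_map <- function(protein_fc, transcript_fc) {
  genes <- intersect(names(protein_fc), names(transcript_fc))
  p <- protein_fc[genes]; t2 <- transcript_fc[genes]
  if (any(!is.finite(p)) || any(!is.finite(t2))) {
    stop("fold changes must be finite")
  }
  quad <- ifelse(p > 0 & t2 > 0, "Q1",
          ifelse(p > 0 & t2 < 0, "Q2",
          ifelse(p < 0 & t2 < 0, "Q3",
          ifelse(p < 0 & t2 > 0, "Q4", "axis"))))
  assignment <- data.frame(gene = genes, protein_fc = unname(p),
                           transcript_fc = unname(t2), quadrant = quad,
                           stringsAsFactors = FALSE)
  inq <- quad != "axis"
  fractions <- if (any(inq)) {
    tab <- table(factor(quad[inq], levels = c("Q1", "Q2", "Q3", "Q4")))
    as.numeric(tab) / sum(inq)
  } else rep(NA_real_, 4)
  names(fractions) <- c("Q1", "Q2", "Q3", "Q4")
  list(assignment = assignment, fractions = fractions,
       n_axis = sum(!inq))
}

#' Relative protein overabundance over time
#'
#' Overabundance of a gene at a time point is its protein log2 fold change
#' minus its transcript log2 fold change. Per-quadrant sums use the
#' final-time quadrant assignment; the total sum over all genes is also
#' reported per time point.
#'
#' @param protein_fc,transcript_fc genes x times log2 fold-change matrices
#'   over the same time points; gene sets are intersected.
#' @param times column time points.
#' @return list with `overabundance` (genes x times), `by_quadrant`
#'   (data.frame of per-quadrant sums per time), `total` (per-time sums)
#'   and the final-time `quadrants`.
#' @export
overabundance_series <- function(protein_fc, transcript_fc, times) {
  genes <- intersect(rownames(protein_fc), rownames(transcript_fc))
  p <- protein_fc[genes, , drop = FALSE]
  t2 <- transcript_fc[genes, , drop = FALSE]
  over <- p - t2
  last <- ncol(p)
  qm <- quadrant_map(stats::setNames(p[, last], genes),
                     stats::setNames(t2[, last], genes))
  quad <- stats::setNames(qm$assignment$quadrant, qm$assignment$gene)
  by_q <- do.call(rbind, lapply(c("Q1", "Q2", "Q3", "Q4", "axis"),
    function(q) {
      sel <- names(quad)[quad == q]
      data.frame(quadrant = q, time_h = times,
                 sum_overabundance = if (length(sel))
                   colSums(over[sel, , drop = FALSE]) else
                   rep(0, length(times)))
    }))
  list(overabundance = over,
       by_quadrant = by_q,
       total = data.frame(time_h = times, sum_overabundance = colSums(over)),
       quadrants = quad)
}

#' Census of fold changes crossing a threshold per time point
#'
#' A gene counts as "up" at a time point if its log2 fold change versus the
#' young reference reaches `log2(threshold)`, "down" if it reaches the
#' negative threshold; a change is "new" if no earlier time point crossed
#' in the same direction. The summary fraction is the share of final-time
#' changers that had already crossed (same direction) at an earlier time.
#'
#' @param fc genes x times log2 fold-change matrix versus the reference.
#' @param times column time points.
#' @param threshold linear fold-change threshold (2 = twofold).
#' @return list with `census` (per-time counts of new/previous changers by
#'   direction), `fraction_presaged` (`NA` when no final-time changer
#'   exists), and the final-time changer counts.
#' @export
foldchange_census <- function(fc, times, threshold = 2) {
  th <- log2(threshold)
  up <- fc >= th
  down <- fc <= -th
  earlier_up <- t(apply(up, 1, function(x) c(FALSE, cumsum(x)[-length(x)] > 0)))
  earlier_down <- t(apply(down, 1, function(x) c(FALSE, cumsum(x)[-length(x)] > 0)))
  census <- data.frame(
    time_h = times,
    new_up = colSums(up & !earlier_up),
    new_down = colSums(down & !earlier_down),
    previous_up = colSums(up & earlier_up),
    previous_down = colSums(down & earlier_down))
  census$total_changed <- census$new_up + census$new_down +
    census$previous_up + census$previous_down
  last <- ncol(fc)
  final_changers <- sum(up[, last]) + sum(down[, last])
  presaged <- sum(up[, last] & earlier_up[, last]) +
    sum(down[, last] & earlier_down[, last])
  list(census = census,
       fraction_presaged = if (final_changers > 0)
         presaged / final_changers else NA_real_,
       final_changers = final_changers, presaged = presaged)
}
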