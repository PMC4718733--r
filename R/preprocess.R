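#' Pipeline configuration
#'
#' Central container for the tunable processing parameters.
#'
#' @param loess_span span of the local polynomial regression used to fuse
#'   replicates (fraction of points in each local fit).
#' @param cv_cutoff replicate coefficient-of-variation cutoff; genes with
#'   CV strictly below the cutoff are retained.
#' @param reference_time_h young reference time point (hours).
#' @param normalization_total per-time-point total abundance.
#' @param fold_change_threshold linear fold-change threshold of the census.
#' @param log_space_fit fit replicate profiles in log2 space instead of
#'   linear abundance space.
#' @param negative_fit_action what to do with genes whose fitted profile
#'   goes negative: `"remove"` (default) or `"clamp"` to a small positive
#'   floor.
#' @param seed integer seed recorded for stochastic stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(loess_span = 0.75, cv_cutoff = 0.3,
                            reference_time_h = 7.8,
                            normalization_total = 1e6,
                            fold_change_threshold = 2,
                            log_space_fit = FALSE,
                            negative_fit_action = c("remove", "clamp"),
                            seed = 1L) {
  if (loess_span <= 0 || loess_span > 1) stop("loess_span must be in (0, 1]")
  if (cv_cutoff <= 0) stop("cv_cutoff must be positive")
  structure(list(loess_span = loess_span, cv_cutoff = cv_cutoff,
                 reference_time_h = reference_time_h,
                 normalization_total = normalization_total,
                 fold_change_threshold = fold_change_threshold,
                 log_space_fit = log_space_fit,
                 negative_fit_action = match.arg(negative_fit_action),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Per-protein bead-effect correction factors
#'
#' The magnetic beads cause a reproducible, protein-specific signal loss.
#' The correction factor of a protein is the ratio of its mean abundance
#' without beads to its mean abundance with beads (ratio of replicate
#' means); multiplying bead-containing measurements by the factor undoes
#' the loss.
#'
#' @param with_beads,without_beads genes x replicates matrices (or vectors)
#'   of the same protein set measured with and without beads.
#' @return data.frame with `protein_id`, `factor`, `n_replicates`, and a
#'   logical `flagged` column marking proteins with zero with-beads mean
#'   (factor undefined, set `NA`).
#' @export
bead_correction_factors <- function(with_beads, without_beads) {
  wb <- as.matrix(with_beads); nb <- as.matrix(without_beads)
  if (nrow(wb) != nrow(nb)) stop("protein sets must match")
  if (!is.null(rownames(wb)) && !is.null(rownames(nb)) &&
      !identical(rownames(wb), rownames(nb))) {
    stop("protein sets must match (same identifiers, same order)")
  }
  mw <- rowMeans(wb); mn <- rowMeans(nb)
  flagged <- mw == 0
  fac <- ifelse(flagged, NA_real_, mn / mw)
  data.frame(protein_id = if (is.null(rownames(wb)))
               sprintf("p%05d", seq_len(nrow(wb))) else rownames(wb),
             factor = fac, n_replicates = ncol(wb), flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Apply bead correction factors to an abundance table
#'
#' Multiplies the protein channels of bead-containing samples by the
#' per-protein factors. Re-applying to an already corrected table is
#' refused (the correction is not idempotent).
#'
#' @param table an `abundance_table` of proteins.
#' @param factors data.frame from [bead_correction_factors()].
#' @return corrected `abundance_table` carrying a `bead_corrected`
#'   attribute.
#' @export
apply_bead_correction <- function(table, factors) {
  if (isTRUE(attr(table, "bead_corrected"))) {
    stop("table is already bead-corrected; refusing to correct twice")
  }
  fac <- factors$factor[match(rownames(table$abundance),
                              factors$protein_id)]
  if (anyNA(fac)) {
    stop("missing or flagged correction factor for some proteins")
  }
  bead_cols <- table$samples$has_beads
  table$abundance[, bead_cols] <- table$abundance[, bead_cols] * fac
  attr(table, "bead_corrected") <- TRUE
  table
}

#' Standardize a series to the young reference time point
#'
#' Converts abundances to log2 fold changes versus the reference harvest.
#' The per-gene log2 offset between the reference sample and an unprocessed
#' sample (never biotinylated or bead-labeled) is computed and stored as
#' metadata, so processing-induced level shifts are not mistaken for aging;
#' only times at or after the reference enter downstream analyses.
#'
#' @param series an `unmixed_series` or genes x times matrix.
#' @param times time points of the columns (taken from the series if
#'   omitted).
#' @param reference_time_h reference time (must be present).
#' @param unprocessed optional named abundance vector of an unprocessed
#'   sample, used for the processing offset.
#' @return list of class `fc_table`: `fc` (genes x retained times log2
#'   fold changes), `times`, `reference_time_h`, `processing_offset`
#'   (per-gene log2, `NA` if no unprocessed sample given) and `flagged`
#'   genes with non-positive reference abundance.
#' @export
standardize_reference <- function(series, times = NULL,
                                  reference_time_h = 7.8,
                                  unprocessed = NULL) {
  m <- if (inherits(series, "unmixed_series")) series$abundance else series
  if (is.null(times)) {
    if (!inherits(series, "unmixed_series")) stop("times is required")
    times <- series$times
  }
  jref <- which(abs(times - reference_time_h) < 1e-9)
  if (length(jref) != 1) stop("reference time must be present exactly once")
  ref <- m[, jref]
  flagged <- !is.finite(ref) | ref <= 0
  keep <- times >= reference_time_h - 1e-9
  fc <- log2(sweep(m[!flagged, keep, drop = FALSE], 1, ref[!flagged], "/"))
  offset <- rep(NA_real_, sum(!flagged))
  names(offset) <- rownames(m)[!flagged]
  if (!is.null(unprocessed)) {
    u <- unprocessed[rownames(fc)]
    offset <- log2(ref[!flagged] / u)
  }
  structure(list(fc = fc, times = times[keep],
                 reference_time_h = reference_time_h,
                 processing_offset = offset,
                 flagged = rownames(m)[flagged]),
            class = "fc_table")
}

loess_fit_one <- function(y, t, span, eval_times) {
  fit <- stats::loess(y ~ t, span = span, degree = 2,
                      control = stats::loess.control(surface = "direct"))
  stats::predict(fit, data.frame(t = eval_times))
}

#' Fuse two replicate series by local polynomial regression
#'
#' Pools the time points of both replicates per gene, fits a LOESS curve
#' (standard span 0.75), and resamples the fit at the experimental harvest
#' times. Deterministic given its inputs and invariant to the order of the
#' replicates.
#'
#' @param rep1,rep2 `unmixed_series` (or genes x times matrices with a
#'   `times` attribute) of the two replicates; gene sets are intersected.
#' @param config a `pipeline_config` (provides the span, fitting space and
#'   negative-value rule).
#' @param eval_times times at which the fit is evaluated; defaults to the
#'   union of replicate times.
#' @return list with `fitted` (genes x eval_times matrix), `times`,
#'   `unfittable` (genes with < 4 pooled points) and `negative` (genes
#'   whose fit crossed zero; removed or clamped per the config).
#' @export
fit_profiles <- function(rep1, rep2, config = pipeline_config(),
                         eval_times = NULL) {
  get <- function(r) {
    if (inherits(r, "unmixed_series")) list(m = r$abundance, t = r$times)
    else list(m = r, t = attr(r, "times"))
  }
  a <- get(rep1); b <- get(rep2)
  genes <- intersect(rownames(a$m), rownames(b$m))
  if (is.null(eval_times)) eval_times <- sort(union(a$t, b$t))
  fitted <- matrix(NA_real_, length(genes), length(eval_times),
                   dimnames = list(genes, sprintf("t_%g", eval_times)))
  unfittable <- character(0)
  for (g in genes) {
    t_all <- c(a$t, b$t)
    y_all <- c(a$m[g, ], b$m[g, ])
    ok <- is.finite(y_all)
    if (sum(ok) < 4) { unfittable <- c(unfittable, g); next }
    y <- y_all[ok]
    if (config$log_space_fit) y <- log2(pmax(y, .Machine$double.xmin))
    f <- loess_fit_one(y, t_all[ok], config$loess_span, eval_times)
    if (config$log_space_fit) f <- 2^f
    fitted[g, ] <- f
  }
  fitted <- fitted[!(rownames(fitted) %in% unfittable), , drop = FALSE]
  neg <- rownames(fitted)[apply(fitted, 1, function(x) any(x <= 0))]
  if (length(neg) && !config$log_space_fit) {
    if (config$negative_fit_action == "remove") {
      fitted <- fitted[setdiff(rownames(fitted), neg), , drop = FALSE]
    } else {
      floor_val <- 1e-6 * stats::median(fitted[fitted > 0])
      fitted[fitted <= 0] <- floor_val
    }
  }
  list(fitted = fitted, times = eval_times, unfittable = unfittable,
       negative = neg)
}

#' Replicate reproducibility filter on the coefficient of variation
#'
#' Per gene, the CV across replicates (sample SD with the n-1 denominator,
#' divided by the mean) is computed at every shared time point and averaged
#' over time; genes with mean CV strictly below the cutoff are retained.
#' Time points with zero mean are excluded from that gene's CV.
#'
#' @param rep1,rep2 `unmixed_series` or genes x times matrices over the
#'   same time points; gene sets are intersected.
#' @param config a `pipeline_config` (provides `cv_cutoff`).
#' @return list with per-gene `cv`, the `retained` gene set and the
#'   `retained_fraction`.
#' @export
cv_filter <- function(rep1, rep2, config = pipeline_config()) {
  m1 <- if (inherits(rep1, "unmixed_series")) rep1$abundance else rep1
  m2 <- if (inherits(rep2, "unmixed_series")) rep2$abundance else rep2
  genes <- intersect(rownames(m1), rownames(m2))
  shared <- intersect(colnames(m1), colnames(m2))
  m1 <- m1[genes, shared, drop = FALSE]
  m2 <- m2[genes, shared, drop = FALSE]
  mu <- (m1 + m2) / 2
  sdv <- abs(m1 - m2) / sqrt(2)       # two-replicate sample SD
  cvmat <- sdv / mu
  cvmat[!is.finite(cvmat) | mu == 0] <- NA
  cv <- rowMeans(cvmat, na.rm = TRUE)
  retained <- genes[!is.na(cv) & cv < config$cv_cutoff]
  list(cv = cv, retained = retained,
       retained_fraction = length(retained) / length(genes))
}
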