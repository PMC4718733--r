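#' Mathematical un-mixing of one time point
#'
#' Solves, per gene, the square linear system `W a = a_mix`, where the rows
#' of `W` are the measured cell-type fractions of the mixed samples and
#' `a_mix` the measured mixed abundances. The solve is exact (no
#' non-negativity constraint); physically impossible negative components
#' are flagged unsolvable instead, and an ill-conditioned `W` flags the
#' whole time point.
#'
#' @param mix_abundances genes x mixes matrix (or vector for one gene) of
#'   finite, non-negative measured abundances.
#' @param W mixes x cell-types composition matrix; must be square with as
#'   many rows as there are mix columns in `mix_abundances`.
#' @param condition_max condition-number threshold above which `W` is
#'   treated as singular.
#' @return list with `values` (genes x cell-types solved abundances) and
#'   `solvable` (logical matrix; `FALSE` where the solved component is
#'   negative or `W` is ill-conditioned), plus the condition number.
#' @examples
#' W <- rbind(c(0.8, 0.15, 0.05), c(0.3, 0.6, 0.1), c(0.05, 0.9, 0.05))
#' unmix_timepoint(c(84, 41, 16.5), W)$values # 100 10 50
#' @export
unmix_timepoint <- function(mix_abundances, W, condition_max = 1e8) {
  if (is.vector(mix_abundances)) {
    mix_abundances <- matrix(mix_abundances, nrow = 1)
  }
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) {
    stop("W must be square (as many mixes as cell types solved)")
  }
  if (ncol(mix_abundances) != nrow(W)) {
    stop("mix abundance columns must match the rows of W")
  }
  if (any(!is.finite(mix_abundances)) || any(mix_abundances < 0)) {
    stop("mix abundances must be finite and non-negative")
  }
  cond <- kappa(W, exact = TRUE)
  n_types <- ncol(W)
  types <- colnames(W)
  if (is.null(types)) types <- paste0("type", seq_len(n_types))
  if (!is.finite(cond) || cond > condition_max) {
    values <- matrix(NA_real_, nrow(mix_abundances), n_types,
                     dimnames = list(rownames(mix_abundances), types))
    return(list(values = values,
                solvable = matrix(FALSE, nrow(mix_abundances), n_types,
                                  dimnames = dimnames(values)),
                condition = cond))
  }
  values <- t(solve(W, t(mix_abundances)))
  dimnames(values) <- list(rownames(mix_abundances), types)
  list(values = values, solvable = values >= 0, condition = cond)
}

#' Un-mix a replicate series of mixed samples into pure cell-type series
#'
#' Applies [unmix_timepoint()] at every harvest. Time points whose measured
#' dead fraction is negligible in every mix are solved as a two-unknown
#' (mother, daughter) system using the most mother-enriched and most
#' daughter-enriched mixes, with those two composition rows re-normalized
#' over the live cell types; the dead series is marked unsolvable there.
#'
#' @param table an `abundance_table` of one molecule kind and replicate.
#' @param compositions long composition data.frame (measured fractions).
#' @param two_type_dead_max maximum dead fraction (in every mix) for a time
#'   point to be treated as free of dead cells (exact zeros up to rounding).
#' @param condition_max passed to [unmix_timepoint()].
#' @return named list of `unmixed_series` objects (`mother`, `daughter`,
#'   `dead`), each with an `abundance` genes x times matrix, a `status`
#'   character matrix (`"solved"` / `"unsolvable"`), and the time points.
#' @export
unmix_series <- function(table, compositions, two_type_dead_max = 1e-6,
                         condition_max = 1e8) {
  meta <- table$samples
  times <- sort(unique(meta$time_h))
  genes <- rownames(table$abundance)
  types <- c("mother", "daughter", "dead")
  empty <- function() matrix(NA_real_, length(genes), length(times),
                             dimnames = list(genes, sprintf("t_%g", times)))
  ab <- stats::setNames(lapply(types, function(x) empty()), types)
  st <- stats::setNames(lapply(types, function(x) {
    m <- empty(); m[] <- "unsolvable"; m
  }), types)

  for (j in seq_along(times)) {
    W <- composition_matrix(compositions, times[j])
    cols <- meta$sample_id[abs(meta$time_h - times[j]) < 1e-9]
    mix_ids <- meta$mix[match(cols, meta$sample_id)]
    A <- table$abundance[, cols, drop = FALSE]
    colnames(A) <- mix_ids
    A <- A[, rownames(W), drop = FALSE]
    if (max(W[, "dead"]) <= two_type_dead_max) {
      pick <- c(rownames(W)[which.max(W[, "mother"])],
                rownames(W)[which.max(W[, "daughter"])])
      W2 <- W[pick, c("mother", "daughter")]
      W2 <- W2 / rowSums(W2)
      res <- unmix_timepoint(A[, pick, drop = FALSE], W2, condition_max)
      solve_types <- c("mother", "daughter")
    } else {
      res <- unmix_timepoint(A, W, condition_max)
      solve_types <- types
    }
    for (ty in solve_types) {
      ab[[ty]][, j] <- res$values[, ty]
      st[[ty]][res$solvable[, ty], j] <- "solved"
    }
  }
  lapply(stats::setNames(types, types), function(ty) {
    structure(list(abundance = ab[[ty]], status = st[[ty]], times = times,
                   cell_type = ty), class = "unmixed_series")
  })
}

#' @export
print.unmixed_series <- function(x, ...) {
  cat(sprintf("unmixed_series (%s): %d genes x %d times; %.1f%% solved\n",
              x$cell_type, nrow(x$abundance), length(x$times),
              100 * mean(x$status == "solved")))
  invisible(x)
}

#' Finalize an un-mixed series: drop sparse genes, interpolate gaps
#'
#' Genes with fewer than `min_solved` solved time points are dropped.
#' Remaining unsolvable entries are linearly interpolated in time from the
#' nearest solved neighbours; boundary gaps take the nearest solved value.
#' The finalized series contains no negative abundances.
#'
#' @param raw an `unmixed_series` with per-entry status flags.
#' @param min_solved minimum number of solved time points per retained gene.
#' @return an `unmixed_series` whose status entries are `"solved"` or
#'   `"interpolated"`, plus a `dropped` attribute listing removed genes.
#' @export
finalize_series <- function(raw, min_solved = 5) {
  solved <- raw$status == "solved"
  keep <- rowSums(solved) >= min_solved
  ab <- raw$abundance[keep, , drop = FALSE]
  st <- raw$status[keep, , drop = FALSE]
  sv <- solved[keep, , drop = FALSE]
  for (i in seq_len(nrow(ab))) {
    gaps <- !sv[i, ]
    if (any(gaps)) {
      fill <- stats::approx(x = raw$times[sv[i, ]], y = ab[i, sv[i, ]],
                            xout = raw$times[gaps], method = "linear",
                            rule = 2)$y
      ab[i, gaps] <- fill
      st[i, gaps] <- "interpolated"
    }
  }
  structure(list(abundance = ab, status = st, times = raw$times,
                 cell_type = raw$cell_type,
                 dropped = rownames(raw$abundance)[!keep]),
            class = "unmixed_series")
}

#' Normalize each time point to a fixed total abundance
#'
#' @param series an `unmixed_series`, or a plain genes x times matrix.
#' @param total target column sum (1e6 by default, as for the shotgun
#'   proteomes and transcriptomes).
#' @return object of the same shape with every column scaled to `total`.
#' @export
normalize_total <- function(series, total = 1e6) {
  m <- if (inherits(series, "unmixed_series")) series$abundance else series
  sums <- colSums(m)
  if (any(sums <= 0)) stop("every time point needs a positive total")
  m <- sweep(m, 2, total / sums, "*")
  if (inherits(series, "unmixed_series")) {
    series$abundance <- m
    series
  } else m
}

#' Quantify un-mixing recovery against ground truth
#'
#' @param recovered named list of genes x times matrices (or
#'   `unmixed_series`) per cell type.
#' @param truth matching named list of true abundance matrices.
#' @return list with `per_gene` relative errors (averaged over entries),
#'   overall `average_error`, per-cell-type `log2_correlation`, and the
#'   number of excluded zero-truth entries.
#' @export
validate_unmixing <- function(recovered, truth) {
  types <- names(recovered)
  all_err <- c(); per_gene <- list(); log2_cor <- c(); excluded <- 0L
  for (ty in types) {
    rec <- recovered[[ty]]
    if (inherits(rec, "unmixed_series")) rec <- rec$abundance
    tru <- truth[[ty]]
    if (inherits(tru, "unmixed_series")) tru <- tru$abundance
    tru <- tru[rownames(rec), , drop = FALSE]
    if (!all(dim(rec) == dim(tru))) stop("gene/time sets must align")
    ok <- is.finite(rec) & is.finite(tru) & tru > 0
    excluded <- excluded + sum(!ok)
    err <- abs(rec - tru) / tru
    err[!ok] <- NA
    per_gene[[ty]] <- rowMeans(err, na.rm = TRUE)
    all_err <- c(all_err, err[ok])
    pos <- ok & rec > 0
    log2_cor[ty] <- stats::cor(log2(rec[pos]), log2(tru[pos]))
  }
  list(per_gene = per_gene, average_error = mean(all_err),
       log2_correlation = log2_cor, excluded_zero_truth = excluded)
}

#' Write an un-mixed series with its status sidecar
#' @param series an `unmixed_series`.
#' @param path abundance TSV path; flags go to `<path>.status.tsv`.
#' @export
write_series_tsv <- function(series, path) {
  write_matrix_tsv(series$abundance, series$times, path)
  long <- data.frame(
    gene = rep(rownames(series$status), times = ncol(series$status)),
    time_h = rep(series$times, each = nrow(series$status)),
    status = as.vector(series$status))
  if (!is.null(attr(series, "dropped")) || !is.null(series$dropped)) {
    dropped <- series$dropped
    if (length(dropped)) {
      long <- rbind(long, data.frame(gene = dropped, time_h = NA,
                                     status = "dropped"))
    }
  }
  write_tsv(long, paste0(path, ".status.tsv"))
  invisible(path)
}
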