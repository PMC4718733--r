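#' Gene-by-sample abundance table with sample metadata
#'
#' @param abundance numeric matrix, genes x samples, non-negative.
#' @param samples data.frame with columns `sample_id`, `time_h`,
#'   `replicate`, `mix`, `has_beads`, `molecule_kind`, one row per column
#'   of `abundance`.
#' @param genes gene identifiers (rownames of `abundance` if missing).
#' @return object of class `abundance_table`.
#' @export
abundance_table <- function(abundance, samples, genes = rownames(abundance)) {
  abundance <- as.matrix(abundance)
  if (is.null(genes)) stop("gene identifiers are required")
  need <- c("sample_id", "time_h", "replicate", "mix", "has_beads",
            "molecule_kind")
  if (!all(need %in% names(samples))) {
    stop("samples must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(samples) != ncol(abundance)) {
    stop("one metadata row per sample column is required")
  }
  if (any(!is.finite(abundance)) || any(abundance < 0)) {
    stop("abundances must be finite and non-negative")
  }
  rownames(abundance) <- genes
  colnames(abundance) <- samples$sample_id
  structure(list(abundance = abundance, samples = samples),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d genes x %d samples (%s)\n",
              nrow(x$abundance), ncol(x$abundance),
              paste(unique(x$samples$molecule_kind), collapse = "+")))
  invisible(x)
}

#' Write / read an abundance table as TSV (matrix + metadata sidecar)
#'
#' @param x an `abundance_table`.
#' @param path path of the abundance TSV; the sample metadata is written
#'   next to it as `<path>.samples.tsv`.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(x, path) {
  df <- data.frame(gene = rownames(x$abundance), x$abundance,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  utils::write.table(x$samples, paste0(path, ".samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  samples <- utils::read.delim(paste0(path, ".samples.tsv"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  abundance_table(m, samples)
}

#' Write / read a composition table as TSV
#'
#' Long format: one row per time point and mix, with fractional columns
#' `frac_mother`, `frac_daughter`, `frac_dead`.
#' @param comp data.frame as produced by [compose_mixed_samples()].
#' @param path TSV path.
#' @export
write_composition_tsv <- function(comp, path) {
  utils::write.table(comp, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_composition_tsv
#' @export
read_composition_tsv <- function(path) utils::read.delim(path)

#' Composition matrix W for one time point
#'
#' @param comp long composition data.frame.
#' @param time time point (hours).
#' @return mixes x cell-types matrix with rows on the simplex.
#' @export
composition_matrix <- function(comp, time) {
  rows <- comp[abs(comp$time_h - time) < 1e-9, , drop = FALSE]
  if (nrow(rows) == 0) stop("no compositions recorded at time ", time)
  W <- as.matrix(rows[, c("frac_mother", "frac_daughter", "frac_dead")])
  dimnames(W) <- list(rows$mix, c("mother", "daughter", "dead"))
  W
}

#' Read / write GMT-format gene-set catalogs
#'
#' One set per line: name, description, then member gene identifiers,
#' tab-separated.
#' @param path GMT file path.
#' @return named list of character vectors (members per complex).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(ln, 1, 40))
    out[[parts[1]]] <- unique(parts[-(1:2)])
  }
  out
}

#' @rdname read_gmt
#' @param catalog named list of member vectors.
#' @param descriptions optional per-set description strings.
#' @export
write_gmt <- function(catalog, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(catalog))
  lines <- vapply(seq_along(catalog), function(i) {
    paste(c(names(catalog)[i], descriptions[i], catalog[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a generic data.frame as TSV (single header row, NA for missing)
#' @param df data.frame.
#' @param path TSV path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) utils::read.delim(path, check.names = FALSE)

#' Write a genes-x-times matrix as TSV with a `gene` key column
#' @param m matrix with rownames (genes); columns are time points.
#' @param times time values used as column headers.
#' @param path TSV path.
#' @export
write_matrix_tsv <- function(m, times, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  names(df)[-1] <- sprintf("t_%g", times)
  write_tsv(df, path)
}
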