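#' Run the aging analysis pipeline
#'
#' Executes the pipeline stages in dependency order on an output
#' directory, handing data between stages as TSV files so any stage subset
#' can be re-run once its upstream outputs exist. Stages: `simulate`
#' (synthetic two-replicate experiment), `unmix` (per-replicate un-mixing
#' and finalization), `preprocess` (bead correction happens inside
#' simulate+unmix inputs; here: fusion, CV filter, reference
#' standardization), `coupling`, `complexes`, `network`.
#'
#' @param config a `pipeline_config`, a YAML file path, or a list of
#'   overrides for [pipeline_config()].
#' @param stages character vector of stages, or `"all"`.
#' @param outdir output directory (created if needed).
#' @param sim_args list of arguments for [simulate_aging_experiment()].
#' @param verbose print a log line per stage.
#' @return the run manifest, invisibly (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), stages = "all",
                         outdir = "agemix_run", sim_args = list(),
                         verbose = TRUE) {
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  } else if (is.list(config) && !inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  all_stages <- c("simulate", "unmix", "preprocess", "coupling",
                  "complexes", "network")
  if (identical(stages, "all")) stages <- all_stages
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[agemix] ", sprintf(...))
  pth <- function(...) file.path(outdir, sprintf(...))
  need <- function(file, stage) {
    if (!file.exists(file)) {
      stop("missing upstream output '", basename(file),
           "': run stage '", stage, "' first", call. = FALSE)
    }
    file
  }
  ran <- character(0)

  if ("simulate" %in% stages) {
    say("simulate: seed %d", config$seed)
    sim <- do.call(simulate_aging_experiment,
                   utils::modifyList(list(seed = config$seed), sim_args))
    for (r in c("r1", "r2")) {
      write_abundance_tsv(sim[[r]]$proteome, pth("%s_proteome.tsv", r))
      write_abundance_tsv(sim[[r]]$transcriptome,
                          pth("%s_transcriptome.tsv", r))
      write_composition_tsv(sim[[r]]$compositions,
                            pth("%s_compositions.tsv", r))
    }
    write_gmt(sim$truth$catalog, pth("complex_catalog.gmt"),
              descriptions = sim$truth$complex_type)
    write_tsv(data.frame(gene = sim$truth$genes,
                         archetype = sim$truth$archetype,
                         protein_fc = sim$truth$protein_fc,
                         transcript_fc = sim$truth$transcript_fc,
                         bead_loss = sim$truth$bead_loss),
              pth("truth_archetypes.tsv"))
    write_tsv(cohort_viability(sim$cohort), pth("cohort_viability.tsv"))
    # bead-correction factors from the planted no-bead/with-bead contrast
    write_tsv(data.frame(protein_id = sim$truth$genes,
                         factor = 1 / sim$truth$bead_loss,
                         n_replicates = 2L, flagged = FALSE),
              pth("bead_factors.tsv"))
    ran <- c(ran, "simulate")
  }

  if ("unmix" %in% stages) {
    fac <- read_tsv(need(pth("bead_factors.tsv"), "simulate"))
    for (r in c("r1", "r2")) {
      for (kind in c("proteome", "transcriptome")) {
        tab <- read_abundance_tsv(need(pth("%s_%s.tsv", r, kind),
                                       "simulate"))
        comp <- read_composition_tsv(pth("%s_compositions.tsv", r))
        if (kind == "proteome") tab <- apply_bead_correction(tab, fac)
        series <- unmix_series(tab, comp)
        for (ty in names(series)) {
          fin <- normalize_total(finalize_series(series[[ty]]),
                                 config$normalization_total)
          write_series_tsv(fin, pth("%s_%s_%s_unmixed.tsv", r, kind, ty))
        }
      }
    }
    say("unmix: wrote finalized mother/daughter/dead series")
    ran <- c(ran, "unmix")
  }

  read_series <- function(file) {
    df <- read_tsv(file)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene
    attr(m, "times") <- as.numeric(sub("^t_", "", colnames(df)[-1]))
    m
  }

  if ("preprocess" %in% stages) {
    for (kind in c("proteome", "transcriptome")) {
      for (ty in c("mother", "daughter")) {
        m1 <- read_series(need(pth("r1_%s_%s_unmixed.tsv", kind, ty),
                               "unmix"))
        m2 <- read_series(need(pth("r2_%s_%s_unmixed.tsv", kind, ty),
                               "unmix"))
        shared <- intersect(colnames(m1), colnames(m2))
        flt <- cv_filter(m1[, shared, drop = FALSE],
                         m2[, shared, drop = FALSE], config)
        fit <- fit_profiles(
          structure(m1[flt$retained, , drop = FALSE],
                    times = attr(m1, "times")),
          structure(m2[flt$retained, , drop = FALSE],
                    times = attr(m2, "times")),
          config, eval_times = attr(m1, "times"))
        write_matrix_tsv(fit$fitted, fit$times,
                         pth("%s_%s_fitted.tsv", kind, ty))
        fcs <- standardize_reference(fit$fitted, fit$times,
                                     config$reference_time_h)
        write_matrix_tsv(fcs$fc, fcs$times, pth("%s_%s_fc.tsv", kind, ty))
        say("preprocess %s/%s: %d genes retained (CV), %d fitted",
            kind, ty, length(flt$retained), nrow(fit$fitted))
      }
    }
    ran <- c(ran, "preprocess")
  }

  if ("coupling" %in% stages) {
    pf <- read_series(need(pth("proteome_mother_fc.tsv"), "preprocess"))
    tf <- read_series(need(pth("transcriptome_mother_fc.tsv"), "preprocess"))
    times <- attr(pf, "times")
    pm <- read_series(pth("proteome_mother_fitted.tsv"))
    tm <- read_series(pth("transcriptome_mother_fitted.tsv"))
    keep <- attr(pm, "times") >= min(times) - 1e-9
    write_tsv(divergence_from_young(pm[, keep, drop = FALSE], times,
                                    times[1]),
              pth("divergence_proteome.tsv"))
    genes <- intersect(rownames(pm), rownames(tm))
    write_tsv(crosslevel_correlation(pm[genes, keep, drop = FALSE],
                                     tm[genes, keep, drop = FALSE], times),
              pth("crosslevel_correlation.tsv"))
    qm <- quadrant_map(pf[, ncol(pf)], tf[, ncol(tf)])
    write_tsv(qm$assignment, pth("quadrants.tsv"))
    ov <- overabundance_series(pf, tf, times)
    write_tsv(ov$by_quadrant, pth("overabundance_by_quadrant.tsv"))
    write_tsv(ov$total, pth("overabundance_total.tsv"))
    cen <- foldchange_census(pf, times, config$fold_change_threshold)
    write_tsv(cen$census, pth("census_proteome.tsv"))
    say("coupling: Q2 fraction %.3f, census presaged fraction %s",
        qm$fractions["Q2"], format(cen$fraction_presaged, digits = 3))
    ran <- c(ran, "coupling")
  }

  if ("complexes" %in% stages) {
    pf <- read_series(need(pth("proteome_mother_fc.tsv"), "preprocess"))
    tf <- read_series(need(pth("transcriptome_mother_fc.tsv"), "preprocess"))
    catalog <- read_gmt(need(pth("complex_catalog.gmt"), "simulate"))
    times <- attr(pf, "times")
    comp <- compare_stoichiometry(pf, tf, catalog, times,
                                  labels = c("proteome", "transcriptome"))
    write_tsv(comp, pth("stoichiometry_mean.tsv"))
    traj <- complex_trajectories(pf, catalog, times)
    write_matrix_tsv(traj$iqr, times, pth("stoichiometry_proteome.tsv"))
    say("complexes: %d scored", nrow(traj$iqr))
    ran <- c(ran, "complexes")
  }

  if ("network" %in% stages) {
    tf <- read_series(need(pth("transcriptome_mother_fc.tsv"), "preprocess"))
    times <- attr(tf, "times")
    res <- build_directional_network(tf, times, filter = TRUE)
    write_network(res$network, pth("network_transcriptome"),
                  membership = res$clusters$membership)
    write_tsv(res$clusters$ranking, pth("network_ranking.tsv"))
    dm <- res$clusters$direction_matrix
    write_tsv(data.frame(cluster = rownames(dm), dm), pth("direction_matrix.tsv"))
    say("network: %d nodes, %d edges, %d clusters",
        length(res$network$nodes), nrow(res$network$edges),
        nrow(res$clusters$ranking))
    ran <- c(ran, "network")
  }

  outputs <- list.files(outdir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("agemix")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config), stages = ran,
    outputs = as.list(stats::setNames(unname(tools::md5sum(sort(outputs))),
                                      basename(sort(outputs)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
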