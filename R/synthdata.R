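#' Simulate a replicatively aging cohort of mother cells
#'
#' Each founder cell divides according to a homogeneous Poisson process with
#' a per-cell division rate. Cell-to-cell variability in division rate is
#' modelled by drawing each cell's rate from a gamma distribution with mean
#' `mean_rate` and coefficient of variation `rate_cv` (`rate_cv = 0` gives
#' every cell the same rate, i.e. a pure Poisson event process). Death is an
#' age-dependent hazard on the division count: each cell draws a replicative
#' lifespan limit from a logistic distribution and dies (division count
#' frozen) once its divisions reach that limit.
#'
#' @param n_cells number of founder mother cells.
#' @param mean_rate mean division rate in events per hour.
#' @param duration total simulated time in hours.
#' @param times times (hours) at which the cohort state is recorded;
#'   defaults to 12 exponentially spaced harvests over `duration`.
#' @param seed integer random seed (mandatory, for reproducibility).
#' @param rate_cv coefficient of variation of the per-cell division rate.
#' @param death logical; if `FALSE` cells never die.
#' @param death_midpoint replicative age (divisions) at which the death
#'   hazard is centred.
#' @param death_scale scale of the logistic lifespan distribution, in
#'   divisions.
#' @return an object of class `cohort_sim`: list with `times`, integer
#'   matrix `divisions` (cells x times), logical matrix `alive`, per-cell
#'   `rates`, and the call parameters.
#' @export
simulate_cohort <- function(n_cells = 1000, mean_rate = 0.5, duration = 72,
                            times = NULL, seed = 1L, rate_cv = 0.2,
                            death = TRUE, death_midpoint = 34,
                            death_scale = 4) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (mean_rate <= 0) stop("mean_rate must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (is.null(times)) times <- harvest_schedule(duration / 10, duration, 12L,
                                               "exponential")
  times <- sort(times)
  if (any(times < 0) || any(times > duration)) {
    stop("times must lie within [0, duration]")
  }
  set.seed(seed)
  rates <- if (rate_cv > 0) {
    shape <- 1 / rate_cv^2
    stats::rgamma(n_cells, shape = shape, rate = shape / mean_rate)
  } else rep(mean_rate, n_cells)
  limit <- if (death) {
    pmax(1, stats::rlogis(n_cells, location = death_midpoint,
                          scale = death_scale))
  } else rep(Inf, n_cells)

  k <- length(times)
  divisions <- matrix(0L, n_cells, k)
  alive <- matrix(TRUE, n_cells, k)
  div <- rep(0L, n_cells)
  liv <- rep(TRUE, n_cells)
  t_prev <- 0
  for (j in seq_len(k)) {
    dt <- times[j] - t_prev
    if (dt > 0 && any(liv)) {
      inc <- stats::rpois(sum(liv), rates[liv] * dt)
      div[liv] <- div[liv] + inc
    }
    dying <- liv & (div >= limit)
    # a dying cell's count is frozen at its lifespan limit
    div[dying] <- as.integer(ceiling(limit[dying]))
    liv[dying] <- FALSE
    divisions[, j] <- div
    alive[, j] <- liv
    t_prev <- times[j]
  }
  structure(list(times = times, divisions = divisions, alive = alive,
                 rates = rates,
                 params = list(n_cells = n_cells, mean_rate = mean_rate,
                               duration = duration, seed = seed,
                               rate_cv = rate_cv, death = death,
                               death_midpoint = death_midpoint,
                               death_scale = death_scale)),
            class = "cohort_sim")
}

#' Division-count distribution of the living cohort at a recorded time
#'
#' @param cohort a `cohort_sim` object.
#' @param time one of the recorded times.
#' @param alive_only restrict to cells still alive at `time`.
#' @return integer vector of division counts.
#' @export
division_counts <- function(cohort, time, alive_only = TRUE) {
  j <- match(time, cohort$times)
  if (is.na(j)) stop("time was not recorded in this simulation")
  keep <- if (alive_only) cohort$alive[, j] else rep(TRUE, nrow(cohort$divisions))
  cohort$divisions[keep, j]
}

#' Population viability of a cohort over time
#'
#' @param cohort a `cohort_sim` object.
#' @return data.frame with `time_h` and `viability` (fraction alive).
#' @export
cohort_viability <- function(cohort) {
  data.frame(time_h = cohort$times, viability = colMeans(cohort$alive))
}

#' Harvest schedule over the lifespan
#'
#' Exponential spacing (a geometric progression) keeps the information
#' overlap between neighbouring samples low when age distributions widen
#' with time; linear spacing is an arithmetic progression.
#'
#' @param t_start,t_end first and last harvest times in hours, `0 < t_start
#'   < t_end`.
#' @param n_points number of harvests (>= 2).
#' @param mode `"exponential"` or `"linear"`.
#' @return strictly increasing numeric vector of length `n_points` from
#'   `t_start` to `t_end` inclusive.
#' @examples
#' harvest_schedule(8, 64, 4, "exponential") # 8 16 32 64
#' @export
harvest_schedule <- function(t_start, t_end, n_points,
                             mode = c("exponential", "linear")) {
  mode <- match.arg(mode)
  if (n_points < 2) stop("n_points must be >= 2")
  if (!(t_end > t_start && t_start > 0)) stop("need t_end > t_start > 0")
  if (mode == "exponential") {
    exp(seq(log(t_start), log(t_end), length.out = n_points))
  } else {
    seq(t_start, t_end, length.out = n_points)
  }
}

#' Default harvest times of the aging experiment emulation
#'
#' Twelve exponentially spaced harvests from 7.8 h to 72 h.
#' @return numeric vector of length 12.
#' @export
default_harvest_times <- function() harvest_schedule(7.8, 72, 12L, "exponential")

archetype_levels <- c("coupled_up", "coupled_down", "uncoupled_protein_up",
                      "uncoupled_protein_down", "flat")

# deterministic integer allocation of n items to fractions (largest remainder)
allocate_counts <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(left)]] <- counts[order_rem[seq_len(left)]] + 1
  }
  as.integer(counts)
}

#' Generate ground-truth molecular trajectories
#'
#' Plants per-gene protein and transcript trajectories for mother, daughter
#' and dead cells over the harvest times. Mother trajectories follow smooth
#' monotone log2 trends whose terminal fold change and sign are set by the
#' gene's archetype; daughter trajectories are attenuated copies of the
#' mother trends (partial rejuvenation); dead-cell profiles are a fixed,
#' time-constant signature. Archetypes mirror the co-expression quadrants:
#' `coupled_up` (Q1: protein and transcript up), `coupled_down` (Q3: both
#' down), `uncoupled_protein_up` (Q2: protein up, transcript down),
#' `uncoupled_protein_down` (Q4: protein down, transcript up) and `flat`.
#' Protein complexes are planted as `coordinated` (identical member slopes)
#' or `drifting` (a heterogeneous fan of member slopes).
#'
#' @param n_genes number of genes.
#' @param archetype_fractions named fractions over the five archetypes,
#'   summing to 1.
#' @param n_complexes number of planted protein complexes.
#' @param complex_size_range integer range of complex sizes.
#' @param times harvest times (hours).
#' @param seed integer random seed.
#' @param fc_range range of planted terminal |log2 fold changes| for
#'   non-flat genes.
#' @param daughter_attenuation multiplier on mother log2 trends for
#'   daughters (partial rejuvenation; 0 = fully rejuvenated).
#' @param bead_loss_range range of per-protein bead retention factors in
#'   (0, 1]; 1 means no loss.
#' @param frac_coordinated fraction of complexes planted as coordinated.
#' @param baseline_cor correlation of per-gene log protein and log
#'   transcript baseline abundances (the young-state coupling).
#' @param baseline_sdlog log-scale spread of the baseline abundances.
#' @return an object of class `molecular_truth`.
#' @export
generate_molecular_truth <- function(n_genes = 2000,
                                     archetype_fractions = c(
                                       coupled_up = 0.20, coupled_down = 0.20,
                                       uncoupled_protein_up = 0.25,
                                       uncoupled_protein_down = 0.10,
                                       flat = 0.25),
                                     n_complexes = 30,
                                     complex_size_range = c(4L, 12L),
                                     times = default_harvest_times(),
                                     seed = 1L,
                                     fc_range = c(0.5, 2.5),
                                     daughter_attenuation = 0.5,
                                     bead_loss_range = c(0.5, 1),
                                     frac_coordinated = 0.5,
                                     baseline_cor = 0.75,
                                     baseline_sdlog = 1.5) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (is.null(names(archetype_fractions)) ||
      !all(names(archetype_fractions) %in% archetype_levels)) {
    stop("archetype_fractions must be named with the five archetypes")
  }
  fr <- archetype_fractions[archetype_levels]
  fr[is.na(fr)] <- 0
  names(fr) <- archetype_levels
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop("archetype fractions must be non-negative and sum to 1")
  }
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  counts <- allocate_counts(n_genes, fr)
  archetype <- rep(archetype_levels, counts)
  archetype <- sample(archetype)  # shuffle positions

  mag_p <- stats::runif(n_genes, fc_range[1], fc_range[2])
  mag_t <- stats::runif(n_genes, fc_range[1], fc_range[2])
  sign_p <- ifelse(archetype %in% c("coupled_up", "uncoupled_protein_up"), 1,
            ifelse(archetype %in% c("coupled_down", "uncoupled_protein_down"),
                   -1, 0))
  sign_t <- ifelse(archetype %in% c("coupled_up", "uncoupled_protein_down"), 1,
            ifelse(archetype %in% c("coupled_down", "uncoupled_protein_up"),
                   -1, 0))
  protein_fc <- sign_p * mag_p
  transcript_fc <- sign_t * mag_t
  # coupled genes track their transcript magnitude at the protein level
  coupled <- archetype %in% c("coupled_up", "coupled_down")
  protein_fc[coupled] <- transcript_fc[coupled]

  # complexes: members' protein slopes are overridden, labels recomputed
  catalog <- list()
  complex_type <- character(0)
  complex_slopes <- list()
  if (n_complexes > 0) {
    sizes <- sample(seq(complex_size_range[1], complex_size_range[2]),
                    n_complexes, replace = TRUE)
    if (sum(sizes) > n_genes) stop("complexes require more genes than available")
    pool <- sample(genes, sum(sizes))
    type <- rep(c("coordinated", "drifting"),
                allocate_counts(n_complexes, c(frac_coordinated,
                                               1 - frac_coordinated)))
    at <- 1L
    for (i in seq_len(n_complexes)) {
      members <- pool[seq(at, at + sizes[i] - 1L)]
      at <- at + sizes[i]
      idx <- match(members, genes)
      if (type[i] == "coordinated") {
        slopes <- rep(stats::runif(1, 0.5, 1.5), sizes[i])
      } else {
        slopes <- seq(0, stats::runif(1, 1.5, 2.5), length.out = sizes[i])
      }
      protein_fc[idx] <- slopes
      transcript_fc[idx] <- slopes  # complex members transcribed coherently
      name <- sprintf("CPX%03d", i)
      catalog[[name]] <- members
      complex_type[name] <- type[i]
      complex_slopes[[name]] <- stats::setNames(slopes, members)
    }
    # keep archetype labels consistent with the planted signs
    archetype <- ifelse(protein_fc > 0 & transcript_fc > 0, "coupled_up",
                 ifelse(protein_fc < 0 & transcript_fc < 0, "coupled_down",
                 ifelse(protein_fc > 0 & transcript_fc < 0, "uncoupled_protein_up",
                 ifelse(protein_fc < 0 & transcript_fc > 0, "uncoupled_protein_down",
                        "flat"))))
  }

  s <- (times - times[1]) / (times[length(times)] - times[1])
  # protein and transcript baselines are correlated on the log scale
  # (young-cell proteome-transcriptome rank correlation ~0.75)
  z_t <- stats::rnorm(n_genes)
  z_p <- baseline_cor * z_t + sqrt(1 - baseline_cor^2) * stats::rnorm(n_genes)
  base_t <- exp(log(50) + baseline_sdlog * z_t)
  base_p <- exp(log(5e4) + baseline_sdlog * z_p)
  dead_factor_p <- stats::rlnorm(n_genes, 0, 0.5)
  dead_factor_t <- stats::rlnorm(n_genes, 0, 0.5)
  traj <- function(base, fc, atten = 1) base * 2^(outer(fc * atten, s))
  dimn <- list(genes, sprintf("t%02d", seq_along(times)))
  mk <- function(m) { dimnames(m) <- dimn; m }

  structure(list(
    genes = genes, times = times, archetype = archetype,
    protein = list(mother = mk(traj(base_p, protein_fc)),
                   daughter = mk(traj(base_p, protein_fc,
                                      daughter_attenuation)),
                   dead = mk(matrix(base_p * dead_factor_p, n_genes,
                                    length(times)))),
    transcript = list(mother = mk(traj(base_t, transcript_fc)),
                      daughter = mk(traj(base_t, transcript_fc,
                                         daughter_attenuation)),
                      dead = mk(matrix(base_t * dead_factor_t, n_genes,
                                       length(times)))),
    protein_fc = stats::setNames(protein_fc, genes),
    transcript_fc = stats::setNames(transcript_fc, genes),
    bead_loss = stats::setNames(stats::runif(n_genes, bead_loss_range[1],
                                             bead_loss_range[2]), genes),
    catalog = catalog, complex_type = complex_type,
    complex_slopes = complex_slopes,
    params = list(seed = seed, archetype_fractions = fr,
                  daughter_attenuation = daughter_attenuation)),
    class = "molecular_truth")
}

#' Default mixed-sample design emulating the aging experiment
#'
#' Three mixed samples per harvest: a mother-enriched fraction (80-99%
#' mothers, bead-containing), a wash fraction of intermediate composition
#' (bead-containing), and the column effluent (mainly daughters, bead-free).
#' Dead cells are absent from the earliest harvests and accumulate with
#' time; the dead:mother ratio differs between mixes (detached dead cells
#' enrich in the wash, dead daughters appear in the effluent), which keeps
#' the three-unknown system solvable at late time points.
#'
#' @param times harvest times.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise on mixed abundances.
#' @param comp_concentration Dirichlet concentration of the composition
#'   measurement error (`Inf` = compositions measured exactly).
#' @param dead_onset fraction of the (normalized) time axis before which no
#'   dead cells are present.
#' @return an object of class `mix_design` with one compositions matrix
#'   (mixes x cell types, rows on the simplex) per time point.
#' @export
default_mix_design <- function(times = default_harvest_times(),
                               noise_cv = 0.10, comp_concentration = Inf,
                               dead_onset = 0.12) {
  s <- (times - times[1]) / (times[length(times)] - times[1])
  u <- pmax(0, (s - dead_onset) / (1 - dead_onset))
  comp <- lapply(seq_along(times), function(j) {
    d2 <- 0.30 * u[j]; m2 <- 0.99 + (0.60 - 0.99) * s[j]
    d1 <- 0.35 * u[j]; m1 <- 0.55 + (0.25 - 0.55) * s[j]
    d3 <- 0.10 * u[j]; m3 <- 0.05
    W <- rbind(mix2 = c(m2, 1 - m2 - d2, d2),
               mix1 = c(m1, 1 - m1 - d1, d1),
               mix3 = c(m3, 1 - m3 - d3, d3))
    colnames(W) <- c("mother", "daughter", "dead")
    W[c("mix1", "mix2", "mix3"), ]
  })
  names(comp) <- sprintf("t%02d", seq_along(times))
  structure(list(times = times, compositions = comp,
                 has_beads = c(mix1 = TRUE, mix2 = TRUE, mix3 = FALSE),
                 noise_cv = noise_cv,
                 comp_concentration = comp_concentration),
            class = "mix_design")
}

#' Lognormal noise factors with a given coefficient of variation and mean 1
#' @noRd
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

#' Compose measured mixed-cell samples from ground truth
#'
#' Measured mix abundance = composition-weighted sum of the pure cell-type
#' abundances, multiplied by lognormal measurement noise; protein channels
#' of bead-containing mixes are additionally multiplied by the planted
#' per-protein bead retention factors. Measured compositions are a
#' Dirichlet perturbation of the true compositions (re-normalized to the
#' simplex).
#'
#' @param truth a `molecular_truth` object covering `design$times`.
#' @param design a `mix_design`.
#' @param seed integer random seed.
#' @param replicate replicate label stored in sample metadata.
#' @param time_subset optional indices of `design$times` to harvest (for
#'   partially overlapping replicate series).
#' @return list with `proteome` and `transcriptome` abundance tables
#'   (class `abundance_table`), the measured `compositions` (long
#'   data.frame, one row per time x mix) and the true compositions.
#' @export
compose_mixed_samples <- function(truth, design, seed = 1L,
                                  replicate = "R1", time_subset = NULL) {
  if (!identical(truth$times, design$times)) {
    stop("truth and design must cover the same harvest times")
  }
  set.seed(seed)
  idx <- if (is.null(time_subset)) seq_along(design$times) else time_subset
  mixes <- rownames(design$compositions[[1]])
  n_genes <- length(truth$genes)

  build <- function(kind) {
    pure <- truth[[kind]]
    cols <- list(); meta <- list()
    for (j in idx) {
      W <- design$compositions[[j]]
      P <- cbind(pure$mother[, j], pure$daughter[, j], pure$dead[, j])
      mixed <- P %*% t(W)  # genes x mixes
      for (m in seq_along(mixes)) {
        a <- mixed[, m] * lognormal_noise(n_genes, design$noise_cv)
        if (kind == "protein" && design$has_beads[mixes[m]]) {
          a <- a * truth$bead_loss
        }
        sid <- sprintf("%s_t%02d_%s_%s", replicate, j, mixes[m],
                       if (kind == "protein") "prot" else "rna")
        cols[[sid]] <- a
        meta[[sid]] <- data.frame(
          sample_id = sid, time_h = design$times[j], replicate = replicate,
          mix = mixes[m], has_beads = unname(design$has_beads[mixes[m]]),
          molecule_kind = if (kind == "protein") "protein" else "transcript",
          stringsAsFactors = FALSE)
      }
    }
    abundance_table(do.call(cbind, cols), do.call(rbind, meta),
                    genes = truth$genes)
  }

  comp_measured <- list(); comp_true <- list()
  for (j in idx) {
    W <- design$compositions[[j]]
    Wm <- W
    if (is.finite(design$comp_concentration)) {
      for (m in seq_len(nrow(W))) {
        pos <- W[m, ] > 0
        Wm[m, pos] <- rdirichlet1(design$comp_concentration * W[m, pos])
      }
    }
    tm <- design$times[j]
    comp_true[[length(comp_true) + 1]] <- data.frame(
      time_h = tm, mix = rownames(W), frac_mother = W[, "mother"],
      frac_daughter = W[, "daughter"], frac_dead = W[, "dead"],
      row.names = NULL)
    comp_measured[[length(comp_measured) + 1]] <- data.frame(
      time_h = tm, mix = rownames(Wm), frac_mother = Wm[, "mother"],
      frac_daughter = Wm[, "daughter"], frac_dead = Wm[, "dead"],
      row.names = NULL)
  }

  list(proteome = build("protein"), transcriptome = build("transcript"),
       compositions = do.call(rbind, comp_measured),
       compositions_true = do.call(rbind, comp_true))
}

#' Count-weighted population viability
#'
#' Combines per-mix viability fractions into a population viability,
#' weighting each mix by the number of cells it contains.
#'
#' @param viability_per_mix viability fractions in \[0, 1\].
#' @param cell_counts_per_mix cell counts (>= 0, not all zero).
#' @return weighted mean viability in \[0, 1\].
#' @examples
#' weighted_viability(c(1, 0), c(3, 1)) # 0.75
#' @export
weighted_viability <- function(viability_per_mix, cell_counts_per_mix) {
  if (length(viability_per_mix) != length(cell_counts_per_mix)) {
    stop("viability and count vectors must have equal length")
  }
  if (any(cell_counts_per_mix < 0)) stop("cell counts must be >= 0")
  if (sum(cell_counts_per_mix) == 0) stop("all-zero cell counts: undefined")
  if (any(viability_per_mix < 0 | viability_per_mix > 1)) {
    stop("viabilities must lie in [0, 1]")
  }
  sum(viability_per_mix * cell_counts_per_mix) / sum(cell_counts_per_mix)
}

#' Simulate a full two-replicate aging experiment
#'
#' Convenience wrapper: cohort, ground truth, mix design, and two partially
#' overlapping replicate series of measured mixed samples (replicate 1
#' covers all harvests, replicate 2 a trailing subset, mirroring the two
#' experimental campaigns).
#'
#' @param n_genes,archetype_fractions,n_complexes passed to
#'   [generate_molecular_truth()].
#' @param times harvest times.
#' @param noise_cv,comp_concentration passed to [default_mix_design()].
#' @param seed integer random seed.
#' @param r2_from index of the first harvest covered by replicate 2.
#' @param ... further arguments for [generate_molecular_truth()].
#' @return list with `truth`, `design`, `cohort`, and per-replicate sample
#'   sets `r1`, `r2` (as returned by [compose_mixed_samples()]).
#' @export
simulate_aging_experiment <- function(n_genes = 1000,
                                      archetype_fractions = c(
                                        coupled_up = 0.20, coupled_down = 0.20,
                                        uncoupled_protein_up = 0.25,
                                        uncoupled_protein_down = 0.10,
                                        flat = 0.25),
                                      n_complexes = 20,
                                      times = default_harvest_times(),
                                      noise_cv = 0.10,
                                      comp_concentration = Inf,
                                      seed = 1L, r2_from = 4L, ...) {
  truth <- generate_molecular_truth(n_genes = n_genes,
                                    archetype_fractions = archetype_fractions,
                                    n_complexes = n_complexes, times = times,
                                    seed = seed, ...)
  design <- default_mix_design(times, noise_cv = noise_cv,
                               comp_concentration = comp_concentration)
  cohort <- simulate_cohort(times = times, duration = max(times),
                            seed = seed + 1L)
  r1 <- compose_mixed_samples(truth, design, seed = seed + 2L,
                              replicate = "R1")
  r2 <- compose_mixed_samples(truth, design, seed = seed + 3L,
                              replicate = "R2",
                              time_subset = seq(r2_from, length(times)))
  list(truth = truth, design = design, cohort = cohort, r1 = r1, r2 = r2)
}

#' Generate a two-block driver/responder system for network inference
#'
#' Drivers are smooth, independent temporal profiles (samples from a
#' squared-exponential Gaussian process over the harvest times); each
#' responder is a sparse linear map of drivers plus smooth private noise.
#' Only a fraction of each driver's variance is transmitted to its
#' responders (`activity_transmission`): a regulator's measured profile
#' carries variation that its targets do not inherit. This is what makes
#' the causal asymmetry detectable — responders are nearly fully explained
#' by their parents, while drivers retain unexplained (non-transmitted)
#' variance and therefore a high standardized partial variance.
#'
#' @param n_drivers,n_responders block sizes.
#' @param times time points of the profiles.
#' @param seed integer random seed.
#' @param n_parents number of drivers mixed into each responder.
#' @param noise_sd responder private-noise standard deviation relative to
#'   the responder signal standard deviation (the private noise is itself
#'   smooth, as profiles entering the network analysis are smoothed fits).
#' @param activity_transmission fraction of driver variance transmitted to
#'   responders, in (0, 1].
#' @param lengthscale_frac GP length scale as a fraction of the time range.
#' @return list with `profiles` (genes x times), `role` (named
#'   "driver"/"responder"), and the parent sets.
#' @export
generate_driver_responder <- function(n_drivers = 50, n_responders = 150,
                                      times = default_harvest_times(),
                                      seed = 1L, n_parents = 1,
                                      noise_sd = 0.2,
                                      activity_transmission = 0.5,
                                      lengthscale_frac = 0.08) {
  set.seed(seed)
  k <- length(times)
  ls <- lengthscale_frac * diff(range(times))
  K <- exp(-outer(times, times, "-")^2 / (2 * ls^2)) + diag(1e-8, k)
  L <- chol(K)
  gp <- function(n) matrix(rnorm(n * k), n, k) %*% L
  activity <- gp(n_drivers)
  private <- gp(n_drivers)
  drivers <- sqrt(activity_transmission) * activity +
    sqrt(1 - activity_transmission) * private
  rownames(drivers) <- rownames(activity) <-
    sprintf("drv%03d", seq_len(n_drivers))
  parents <- list()
  responders <- matrix(0, n_responders, k)
  rownames(responders) <- sprintf("rsp%03d", seq_len(n_responders))
  for (j in seq_len(n_responders)) {
    pa <- sample(n_drivers, n_parents)
    w <- stats::runif(n_parents, 0.5, 1.5) *
      sample(c(-1, 1), n_parents, replace = TRUE)
    sig <- colSums(activity[pa, , drop = FALSE] * w)
    priv <- as.vector(rnorm(k) %*% L)
    responders[j, ] <- sig + noise_sd * stats::sd(sig) / stats::sd(priv) * priv
    parents[[rownames(responders)[j]]] <- rownames(drivers)[pa]
  }
  profiles <- rbind(drivers, responders)
  role <- stats::setNames(rep(c("driver", "responder"),
                              c(n_drivers, n_responders)),
                          rownames(profiles))
  list(profiles = profiles, role = role, parents = parents,
       times = times)
}
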