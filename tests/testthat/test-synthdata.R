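test_that("cohort division counts follow the Poisson process", {
  co <- simulate_cohort(n_cells = 1000, mean_rate = 0.5, duration = 72,
                        times = c(10, 20, 40, 70), seed = 3, rate_cv = 0,
                        death = FALSE)
  d <- division_counts(co, 20)
  # Poisson process: mean = var = rate * t = 10
  expect_equal(mean(d), 10, tolerance = 0.05)
  expect_equal(stats::var(d), 10, tolerance = 0.15)

  # near-zero duration: P(no event in 0.01 h) = exp(-0.005) > 0.99
  co0 <- simulate_cohort(n_cells = 1000, mean_rate = 0.5, duration = 0.01,
                         times = 0.01, seed = 4, rate_cv = 0, death = FALSE)
  expect_gte(mean(division_counts(co0, 0.01) == 0), 0.99)

  expect_error(simulate_cohort(mean_rate = -1), "positive")
  expect_error(simulate_cohort(duration = 0), "positive")
})

test_that("age distributions widen and counts never decrease", {
  co <- simulate_cohort(n_cells = 1000, mean_rate = 0.5, duration = 72,
                        times = c(10, 30, 50, 70), seed = 3)
  sds <- vapply(co$times, function(t) stats::sd(division_counts(co, t)),
                numeric(1))
  expect_true(all(diff(sds) > 0))
  # divisions are non-decreasing per cell; dead cells stay frozen
  expect_true(all(apply(co$divisions, 1, function(x) all(diff(x) >= 0))))
  died_mid <- !co$alive[, 2]
  expect_true(all(co$divisions[died_mid, 2] == co$divisions[died_mid, 4]))
  # viability declines once deaths start
  v <- cohort_viability(co)$viability
  expect_true(all(diff(v) <= 0))
})

test_that("harvest schedules are geometric or arithmetic progressions", {
  expect_equal(harvest_schedule(7.8, 72, 2, "exponential"), c(7.8, 72))
  expect_equal(harvest_schedule(8, 64, 4, "exponential"), c(8, 16, 32, 64))
  expect_equal(harvest_schedule(10, 70, 4, "linear"), c(10, 30, 50, 70))
  expect_error(harvest_schedule(10, 70, 1), "n_points")
  expect_error(harvest_schedule(70, 10, 4), "t_end")
  expect_length(default_harvest_times(), 12)
  expect_true(all(diff(default_harvest_times()) > 0))
})

test_that("molecular truth plants archetypes consistently", {
  flat <- generate_molecular_truth(n_genes = 50, archetype_fractions =
    c(flat = 1), n_complexes = 0, seed = 1)
  expect_true(all(flat$protein_fc == 0))
  expect_true(all(flat$transcript_fc == 0))

  tr <- generate_molecular_truth(n_genes = 400, n_complexes = 10, seed = 2)
  # all abundances strictly positive
  for (kind in c("protein", "transcript")) {
    for (ty in c("mother", "daughter", "dead")) {
      expect_true(all(tr[[kind]][[ty]] > 0))
    }
  }
  # archetype labels match the planted terminal fold-change signs
  expect_true(all(tr$archetype[tr$protein_fc > 0 & tr$transcript_fc < 0] ==
                    "uncoupled_protein_up"))
  expect_true(all(tr$archetype[tr$protein_fc < 0 & tr$transcript_fc > 0] ==
                    "uncoupled_protein_down"))
  expect_true(all(tr$protein_fc[tr$archetype == "flat"] == 0))
  # coordinated complexes have identical member slopes
  coord <- names(tr$complex_type)[tr$complex_type == "coordinated"]
  for (cx in coord) {
    expect_equal(length(unique(tr$complex_slopes[[cx]])), 1L)
  }
  drift <- names(tr$complex_type)[tr$complex_type == "drifting"]
  for (cx in drift) {
    expect_gt(length(unique(tr$complex_slopes[[cx]])), 1L)
  }

  expect_error(generate_molecular_truth(archetype_fractions = c(flat = 0.5)),
               "sum to 1")
})

test_that("quadrant archetypes are planted in the requested proportions", {
  fr <- c(coupled_up = 0.25, coupled_down = 0.25,
          uncoupled_protein_up = 0.25, uncoupled_protein_down = 0.25,
          flat = 0)
  tr <- generate_molecular_truth(n_genes = 100, archetype_fractions = fr,
                                 n_complexes = 0, seed = 2)
  # noise-free quadrant assignment recovers exactly 25 genes per quadrant
  k <- length(tr$times)
  qm <- quadrant_map(log2(tr$protein$mother[, k] / tr$protein$mother[, 1]),
                     log2(tr$transcript$mother[, k] / tr$transcript$mother[, 1]))
  expect_equal(unname(table(qm$assignment$quadrant)[c("Q1", "Q2", "Q3", "Q4")]),
               rep(25L, 4), ignore_attr = TRUE)
  expect_true(all(qm$assignment$quadrant ==
                    archetype_quadrant[tr$archetype[match(qm$assignment$gene,
                                                          tr$genes)]]))
})

test_that("mixed samples compose as composition-weighted sums", {
  # identity mixing: zero noise and composition (1, 0, 0)
  tr <- generate_molecular_truth(n_genes = 30, n_complexes = 0, seed = 5,
                                 bead_loss_range = c(1, 1))
  design <- default_mix_design(tr$times, noise_cv = 0)
  for (j in seq_along(tr$times)) {
    design$compositions[[j]]["mix2", ] <- c(1, 0, 0)
  }
  out <- compose_mixed_samples(tr, design, seed = 1)
  m2 <- out$transcriptome$samples$mix == "mix2"
  for (j in seq_along(tr$times)) {
    cols <- m2 & abs(out$transcriptome$samples$time_h - tr$times[j]) < 1e-9
    expect_equal(unname(out$transcriptome$abundance[, cols]),
                 unname(tr$transcript$mother[, j]))
  }

  # hand-computed weighted sum: (100, 10, 50) x (0.8, 0.15, 0.05) -> 84
  W <- rbind(c(0.8, 0.15, 0.05))
  expect_equal(drop(cbind(100, 10, 50) %*% t(W)), 84)

  # composition rows stay on the simplex, measured and true
  d2 <- default_mix_design(tr$times, comp_concentration = 200)
  out2 <- compose_mixed_samples(tr, d2, seed = 2)
  sums <- rowSums(out2$compositions[, c("frac_mother", "frac_daughter",
                                        "frac_dead")])
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("lognormal measurement noise has the designed CV", {
  tr <- generate_molecular_truth(n_genes = 1000, n_complexes = 0, seed = 6,
                                 bead_loss_range = c(1, 1))
  design <- default_mix_design(tr$times, noise_cv = 0.1)
  out <- compose_mixed_samples(tr, design, seed = 7)
  # reconstruct the noise-free mix for the first time point, first mix
  W <- composition_matrix(out$compositions_true, tr$times[1])
  pure <- cbind(tr$transcript$mother[, 1], tr$transcript$daughter[, 1],
                tr$transcript$dead[, 1])
  clean <- drop(pure %*% W["mix1", ])
  cols <- out$transcriptome$samples$mix == "mix1" &
    abs(out$transcriptome$samples$time_h - tr$times[1]) < 1e-9
  ratio <- out$transcriptome$abundance[, cols] / clean
  cv <- stats::sd(ratio) / mean(ratio)
  expect_gte(cv, 0.08)
  expect_lte(cv, 0.12)
})

test_that("bead losses hit only protein channels of bead mixes", {
  tr <- generate_molecular_truth(n_genes = 50, n_complexes = 0, seed = 8,
                                 bead_loss_range = c(0.4, 0.8))
  design <- default_mix_design(tr$times, noise_cv = 0)
  out <- compose_mixed_samples(tr, design, seed = 1)
  meta_p <- out$proteome$samples
  j <- 1
  W <- composition_matrix(out$compositions_true, tr$times[j])
  pure <- cbind(tr$protein$mother[, j], tr$protein$daughter[, j],
                tr$protein$dead[, j])
  for (mx in c("mix1", "mix3")) {
    cols <- meta_p$mix == mx & abs(meta_p$time_h - tr$times[j]) < 1e-9
    clean <- drop(pure %*% W[mx, ])
    fac <- out$proteome$abundance[, cols] / clean
    if (mx == "mix1") {
      expect_equal(unname(fac), unname(tr$bead_loss))
    } else {
      expect_equal(unname(fac), rep(1, 50))
    }
  }
})

test_that("population viability is the count-weighted mean", {
  expect_equal(weighted_viability(0.8, 5e6), 0.8)
  expect_equal(weighted_viability(c(0.9, 0.5), c(1e6, 1e6)), 0.7)
  expect_equal(weighted_viability(c(1, 0), c(3, 1)), 0.75)
  expect_error(weighted_viability(c(1, 0), c(0, 0)), "all-zero")
  expect_error(weighted_viability(c(1.2), c(1)), "\\[0, 1\\]")
  expect_error(weighted_viability(c(0.5, 0.5), 1), "equal length")
})

test_that("driver/responder systems have the declared block structure", {
  sys <- generate_driver_responder(n_drivers = 10, n_responders = 30,
                                   seed = 2)
  expect_equal(sum(sys$role == "driver"), 10)
  expect_equal(sum(sys$role == "responder"), 30)
  expect_true(all(lengths(sys$parents) == 1))
  expect_true(all(unlist(sys$parents) %in% names(sys$role)[sys$role == "driver"]))
  # responders correlate with their parent's transmitted activity
  cors <- vapply(names(sys$parents), function(r) {
    stats::cor(sys$profiles[r, ], sys$profiles[sys$parents[[r]], ])
  }, numeric(1))
  expect_gt(mean(abs(cors)), 0.5)
})
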