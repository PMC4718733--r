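test_that("bead correction factors are ratios of replicate means", {
  wb <- rbind(p1 = c(50, 51), p2 = c(10, 10))
  nb <- rbind(p1 = c(100, 102), p2 = c(10, 10))
  fac <- bead_correction_factors(wb, nb)
  expect_equal(fac$factor, c(2, 1), tolerance = 1e-12)
  expect_false(any(fac$flagged))
  # zero with-beads mean is flagged, factor undefined
  wb0 <- rbind(p1 = c(0, 0), p2 = c(10, 10))
  fac0 <- bead_correction_factors(wb0, nb)
  expect_true(fac0$flagged[1])
  expect_true(is.na(fac0$factor[1]))
  expect_error(bead_correction_factors(wb, nb[1, , drop = FALSE]), "match")
})

test_that("applying bead correction is guarded against double application", {
  tab <- abundance_table(
    matrix(c(50, 10, 100, 20), 2, 2,
           dimnames = list(c("p1", "p2"), NULL)),
    data.frame(sample_id = c("s1", "s2"), time_h = c(8, 8),
               replicate = "R1", mix = c("mix2", "mix3"),
               has_beads = c(TRUE, FALSE), molecule_kind = "protein"))
  fac <- data.frame(protein_id = c("p1", "p2"), factor = c(2, 1))
  cor1 <- apply_bead_correction(tab, fac)
  expect_equal(unname(cor1$abundance[, 1]), c(100, 10))  # bead sample scaled
  expect_equal(unname(cor1$abundance[, 2]), c(100, 20))  # bead-free untouched
  expect_error(apply_bead_correction(cor1, fac), "twice")
})

test_that("bead correction removes the planted losses entirely", {
  tr <- generate_molecular_truth(n_genes = 60, n_complexes = 0, seed = 31,
                                 bead_loss_range = c(0.4, 0.9))
  out <- compose_mixed_samples(tr, default_mix_design(tr$times, noise_cv = 0),
                               seed = 1)
  fac <- data.frame(protein_id = tr$genes, factor = 1 / tr$bead_loss)
  corrected <- apply_bead_correction(out$proteome, fac)
  fin <- finalize_series(unmix_series(corrected, out$compositions)$mother)
  err <- validate_unmixing(list(m = fin),
                           list(m = tr$protein$mother))$average_error
  expect_lt(err, 1e-9)
  # without correction the planted artifact corrupts recovery
  fin_raw <- finalize_series(unmix_series(out$proteome,
                                          out$compositions)$mother)
  err_raw <- validate_unmixing(list(m = fin_raw),
                               list(m = tr$protein$mother))$average_error
  expect_gt(err_raw, 0.05)
})

test_that("standardize_reference produces log2 fold changes vs the young state", {
  times <- c(7.8, 20, 40)
  m <- rbind(g1 = c(100, 200, 400), g2 = c(10, 10, 10))
  fc <- standardize_reference(m, times, 7.8)
  expect_equal(unname(fc$fc["g1", ]), c(0, 1, 2))
  expect_equal(unname(fc$fc["g2", ]), c(0, 0, 0))
  # reference equal to the unprocessed sample: zero processing offset
  fc2 <- standardize_reference(m, times, 7.8,
                               unprocessed = c(g1 = 100, g2 = 10))
  expect_equal(unname(fc2$processing_offset), c(0, 0))
  # zero reference abundance flags the gene
  m0 <- rbind(g1 = c(0, 1, 2), g2 = c(1, 2, 4))
  fc3 <- standardize_reference(m0, times, 7.8)
  expect_equal(fc3$flagged, "g1")
  expect_error(standardize_reference(m, times, 12), "reference time")
})

test_that("fit_profiles reproduces exact signals and averages replicates", {
  times <- seq(4, 72, length.out = 12)
  mk <- function(f) {
    m <- rbind(g1 = f(times))
    attr(m, "times") <- times
    m
  }
  cfg <- pipeline_config()
  # both replicates constant at 5 -> fitted 5 everywhere
  f0 <- fit_profiles(mk(function(t) rep(5, length(t))),
                     mk(function(t) rep(5, length(t))), cfg)
  expect_equal(unname(f0$fitted["g1", ]), rep(5, 12))
  # exact line is reproduced at interior points
  f1 <- fit_profiles(mk(function(t) 2 * t), mk(function(t) 2 * t), cfg)
  expect_equal(unname(f1$fitted["g1", 2:11]), 2 * times[2:11],
               tolerance = 1e-6)
  # constant replicates at 5 and 7: fit strictly between them
  f2 <- fit_profiles(mk(function(t) rep(5, length(t))),
                     mk(function(t) rep(7, length(t))), cfg)
  expect_true(all(f2$fitted > 5 & f2$fitted < 7))
  # invariant to replicate order
  set.seed(5)
  ra <- mk(function(t) 10 + t + rnorm(length(t)))
  rb <- mk(function(t) 12 + t + rnorm(length(t)))
  expect_equal(fit_profiles(ra, rb, cfg)$fitted,
               fit_profiles(rb, ra, cfg)$fitted)
})

test_that("fit_profiles flags unfittable genes and removes negative fits", {
  times <- seq(4, 72, length.out = 12)
  m1 <- rbind(ok = 5 + times, bad = c(1, 2, NA, rep(NA, 9)))
  m2 <- rbind(ok = 5 + times, bad = c(1, NA, rep(NA, 10)))
  attr(m1, "times") <- times; attr(m2, "times") <- times
  f <- fit_profiles(m1, m2, pipeline_config())
  expect_equal(f$unfittable, "bad")
  # a profile fitted through zero-crossing values is removed by default
  m3 <- rbind(neg = seq(5, -1, length.out = 12))
  m4 <- rbind(neg = seq(5, -1, length.out = 12))
  attr(m3, "times") <- times; attr(m4, "times") <- times
  f2 <- fit_profiles(m3, m4, pipeline_config())
  expect_equal(f2$negative, "neg")
  expect_equal(nrow(f2$fitted), 0)
  f3 <- fit_profiles(m3, m4, pipeline_config(negative_fit_action = "clamp"))
  expect_equal(nrow(f3$fitted), 1)
  expect_true(all(f3$fitted > 0))
})

test_that("cv_filter applies the replicate reproducibility rule", {
  times <- 1:6
  m1 <- rbind(same = rep(10, 6), far = rep(10, 6), edge = rep(1, 6))
  m2 <- rbind(same = rep(10, 6), far = rep(20, 6), edge = rep(1, 6))
  colnames(m1) <- colnames(m2) <- sprintf("t_%d", times)
  # gene "edge" engineered to sit exactly at the cutoff
  cut <- 0.3
  b <- (2 + cut * sqrt(2)) / (2 - cut * sqrt(2))
  m2["edge", ] <- b
  flt <- cv_filter(m1, m2, pipeline_config(cv_cutoff = cut))
  expect_true("same" %in% flt$retained)         # CV 0
  expect_false("far" %in% flt$retained)         # CV ~0.4714 > 0.3
  expect_equal(unname(flt$cv["far"]), (10 / sqrt(2)) / 15, tolerance = 1e-12)
  expect_false("edge" %in% flt$retained)        # boundary: strict less-than
  expect_equal(unname(flt$cv["edge"]), cut, tolerance = 1e-12)
  expect_equal(flt$retained_fraction, 1 / 3)
})

test_that("retention is monotone in the CV cutoff", {
  set.seed(41)
  times <- 1:8
  m1 <- matrix(stats::rlnorm(160, 3, 0.5), 20, 8,
               dimnames = list(sprintf("g%02d", 1:20), sprintf("t_%d", times)))
  m2 <- m1 * stats::rlnorm(160, 0, 0.3)
  counts <- vapply(c(0.1, 0.2, 0.3, 0.5, 1),
                   function(ct) length(cv_filter(m1, m2,
                     pipeline_config(cv_cutoff = ct))$retained), numeric(1))
  expect_true(all(diff(counts) >= 0))
})
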