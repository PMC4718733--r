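times12 <- default_harvest_times()

test_that("the evidence filter removes flat and noisy profiles", {
  expect_equal(profile_signal_score(rep(5, 12), times12), -Inf)
  # strong monotone trend with 1% noise is retained with a large score
  set.seed(71)
  trend <- seq(0, 3, length.out = 12) + 0.03 * rnorm(12)
  expect_gt(profile_signal_score(trend, times12), 5)
  # >= 95% of white-noise profiles are removed at the default threshold
  nulls <- matrix(rnorm(1000 * 12), 1000, 12,
                  dimnames = list(sprintf("n%04d", 1:1000), NULL))
  flt <- profile_signal_filter(nulls, times12)
  expect_lte(length(flt$retained), 50)
  expect_error(profile_signal_filter(nulls[, 1:3], times12[1:3]),
               "4 time points")
})

test_that("shrinkage correlation estimates are well-behaved", {
  # orthogonal profiles give the identity
  m <- rbind(a = c(2, 0, 2, 0), b = c(1, 1, -1, -1))
  sh <- shrink_correlation(m)
  expect_equal(unname(sh$R), diag(2))
  # n >> p: intensity vanishes and the sample correlation is recovered
  set.seed(72)
  big <- matrix(rnorm(3 * 3000), 3, 3000)
  big[2, ] <- big[1, ] * 0.7 + 0.3 * big[2, ]
  sh2 <- shrink_correlation(big)
  expect_lt(sh2$lambda, 0.01)
  expect_equal(sh2$R[1, 2], stats::cor(big[1, ], big[2, ]),
               tolerance = 0.01)
  # duplicated profile: shrinkage keeps the matrix positive definite
  dup <- rbind(a = rnorm(8), c = rnorm(8))
  dup <- rbind(dup, b = dup["a", ])
  sh3 <- shrink_correlation(dup)
  expect_lt(sh3$R["a", "b"], 1)
  expect_equal(unname(which.max(sh3$R["a", c("b", "c")])), 1L)
  expect_true(all(eigen(sh3$R, only.values = TRUE)$values > 0))
  # zero-variance genes are excluded with a report
  z <- rbind(a = rnorm(6), flat = rep(2, 6))
  expect_equal(shrink_correlation(z)$excluded, "flat")
})

test_that("partial correlations match the closed form on 3 variables", {
  # fork: y and z both driven by x with r_xy = r_xz = 0.9, r_yz = 0.81
  R <- rbind(c(1, 0.9, 0.9), c(0.9, 1, 0.81), c(0.9, 0.81, 1))
  dimnames(R) <- list(c("x", "y", "z"), c("x", "y", "z"))
  pc <- partial_correlations(R)
  closed <- function(ryz, ryx, rzx) {
    (ryz - ryx * rzx) / sqrt((1 - ryx^2) * (1 - rzx^2))
  }
  expect_equal(pc["y", "z"], closed(0.81, 0.9, 0.9), tolerance = 1e-12)
  expect_equal(pc["y", "z"], 0, tolerance = 1e-12)
  # edges survive only where direct dependence exists
  net <- partial_correlation_network(R, 0.1)
  ek <- paste(net$edges$source, net$edges$target)
  expect_setequal(ek, c("x y", "x z"))
  # identity correlation: no edges; cutoff 0: complete graph
  expect_equal(nrow(partial_correlation_network(diag(3), 0.1)$edges), 0)
  expect_equal(nrow(partial_correlation_network(R, 0)$edges), 3)
})

test_that("precision-based SPV equals explicit neighbour regression", {
  set.seed(73)
  x <- rnorm(40)
  y <- 0.8 * x + 0.3 * rnorm(40)
  z <- 0.7 * x + 0.4 * rnorm(40)
  prof <- rbind(x = x, y = y, z = z)
  R <- stats::cor(t(prof))
  spv_p <- standardized_partial_variance(R)
  for (v in c("x", "y", "z")) {
    reg <- spv_regression(prof, v, setdiff(c("x", "y", "z"), v))
    expect_equal(unname(spv_p[v]), reg$spv, tolerance = 1e-10)
    expect_false(reg$regularized)
  }
  expect_true(all(spv_p > 0 & spv_p <= 1))
  # degenerate case: as many neighbours as observations -> ridge, flagged
  short <- prof[, 1:2]
  expect_true(spv_regression(short, "x", c("y", "z"))$regularized)
})

test_that("edges are oriented from high to low SPV, antisymmetrically", {
  net <- structure(list(
    nodes = c("m", "n"),
    edges = data.frame(source = "m", target = "n", pcor = 0.8),
    spv = c(m = 0.9, n = 0.3)), class = "pcor_network")
  d1 <- orient_edges(net)
  expect_equal(d1$edges$source, "m")
  expect_true(d1$edges$directed)
  # swapping the stored orientation never changes the arrow
  net2 <- net
  net2$edges <- data.frame(source = "n", target = "m", pcor = 0.8)
  d2 <- orient_edges(net2)
  expect_equal(d2$edges$source, "m")
  expect_equal(d2$edges$target, "n")
  # tied SPV leaves the edge undirected
  net$spv <- c(m = 0.5, n = 0.5)
  expect_false(orient_edges(net)$edges$directed)
})

test_that("a planted chain is oriented driver -> responder", {
  set.seed(74)
  # driver with non-transmitted variance, two noisy responders
  act <- rnorm(12)
  drv <- sqrt(0.5) * act + sqrt(0.5) * rnorm(12)
  prof <- rbind(drv = drv,
                r1 = act + 0.3 * rnorm(12),
                r2 = act + 0.3 * rnorm(12))
  sh <- shrink_correlation(prof)
  net <- orient_edges(partial_correlation_network(sh, 0.1), prof)
  e <- net$edges
  chain <- e[e$source == "drv" | e$target == "drv", ]
  expect_true(all(chain$source == "drv"))
  expect_gt(net$spv["drv"], max(net$spv[c("r1", "r2")]))
})

test_that("clusters and causal ranking follow the direction matrix", {
  # two 4-cliques joined by 5 arrows A -> B and 1 arrow B -> A
  cliq <- function(nodes) t(combn(nodes, 2))
  a <- paste0("a", 1:4); b <- paste0("b", 1:4)
  intra <- rbind(cliq(a), cliq(b))
  inter <- cbind(c(a[1], a[1], a[3], a[3], a[4], b[2]),
                 c(b[1], b[3], b[3], b[4], b[1], a[2]))
  edges <- data.frame(source = c(intra[, 1], inter[, 1]),
                      target = c(intra[, 2], inter[, 2]),
                      pcor = 0.5)
  spv <- stats::setNames(c(rep(0.9, 4), rep(0.3, 4)), c(a, b))
  spv["b2"] <- 0.95  # forces the single reverse arrow b2 -> a2
  spv["a2"] <- 0.1
  net <- structure(list(nodes = sort(c(a, b)), edges = edges, spv = spv),
                   class = "pcor_network")
  dnet <- orient_edges(net)
  cl <- cluster_and_rank(dnet)
  expect_equal(nrow(cl$ranking), 2)
  ca <- cl$membership["a1"]; cb <- cl$membership["b1"]
  expect_true(all(cl$membership[a] == ca) && all(cl$membership[b] == cb))
  inter_counts <- cl$direction_matrix
  expect_equal(unname(inter_counts[ca, cb]), 5L)
  expect_equal(unname(inter_counts[cb, ca]), 1L)
  rk <- cl$ranking
  expect_equal(rk$causal_ratio[rk$cluster == paste0("C", ca)], 5)
  expect_equal(rk$causal_ratio[rk$cluster == paste0("C", cb)], 0.2)
  expect_equal(rk$rank[rk$cluster == paste0("C", ca)], 1L)
  # out/in totals sum to twice the inter-cluster directed edges
  off <- inter_counts; diag(off) <- 0L
  expect_equal(sum(rk$outgoing) + sum(rk$incoming), 2L * sum(off))
})

test_that("small-graph clustering attains the brute-force modularity", {
  set.seed(75)
  for (i in 1:12) {
    n <- sample(5:8, 1)
    g <- igraph::sample_gnp(n, 0.5)
    if (igraph::ecount(g) == 0) next
    igraph::V(g)$name <- paste0("v", seq_len(n))
    df <- igraph::as_data_frame(g)
    net <- structure(list(
      nodes = igraph::V(g)$name,
      edges = data.frame(source = df$from, target = df$to, pcor = 0.5,
                         directed = FALSE),
      spv = stats::setNames(rep(0.5, n), igraph::V(g)$name)),
      class = c("directional_network", "pcor_network"))
    cl <- cluster_and_rank(net)
    expect_equal(cl$modularity, oracle_best_modularity(g), tolerance = 1e-10)
  }
  # two disconnected triangles split into exactly two clusters
  tri <- data.frame(source = c("a1", "a2", "a3", "b1", "b2", "b3"),
                    target = c("a2", "a3", "a1", "b2", "b3", "b1"),
                    pcor = 0.5, directed = FALSE)
  net2 <- structure(list(nodes = sort(unique(c(tri$source, tri$target))),
                         edges = tri,
                         spv = stats::setNames(rep(0.5, 6),
                                               sort(unique(c(tri$source,
                                                             tri$target))))),
                    class = c("directional_network", "pcor_network"))
  cl2 <- cluster_and_rank(net2)
  expect_equal(nrow(cl2$ranking), 2)
  expect_true(cl2$unranked)              # no inter-cluster arrows at all
  expect_true(all(is.na(cl2$ranking$rank)))
})

test_that("the sensitivity sweep is monotone and stable where expected", {
  sys <- generate_driver_responder(n_drivers = 15, n_responders = 45,
                                   seed = 76)
  sw <- sensitivity_sweep(sys$profiles,
                          cutoff_quantiles = c(0.85, 0.90, 0.95))
  expect_true(all(diff(sw$table$edges) <= 0))
  expect_true(all(diff(sw$table$nodes) <= 0))
  # a repeated cutoff gives identical rows and perfect stability
  co <- sw$table$cutoff[2]
  sw2 <- sensitivity_sweep(sys$profiles, cutoffs = c(co, co))
  expect_equal(sw2$table[1, -1], sw2$table[2, -1], ignore_attr = TRUE)
  expect_equal(sw2$stability, 1)
})
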