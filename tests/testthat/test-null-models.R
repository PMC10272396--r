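# Randomized-genome null models, closed-form oracles, normality summaries.

# Enumeration oracle: exact mean count of genes at SSc = 1 over all
# placements of k genes among n slots.
enum_adjacent_mean <- function(n, k, topo) {
  sets <- utils::combn(n, k)
  mean(vapply(seq_len(ncol(sets)), function(j) {
    ssc <- brute_ssc(n, sets[, j], topo)
    sum(ssc == 1L, na.rm = TRUE)
  }, numeric(1)))
}

test_that("randomize_placement is uniform-without-replacement and seeded", {
  p <- randomize_placement(100, 10, rng_seed = 5)
  expect_equal(p, sort(p))
  expect_equal(length(unique(p)), 10L)
  expect_identical(p, randomize_placement(100, 10, rng_seed = 5))
  expect_equal(randomize_placement(7, 7, rng_seed = 1), 1:7)
  expect_error(randomize_placement(5, 6), "exceeds")
})

test_that("closed-form adjacent-gene expectation matches enumeration", {
  for (topo in c("circular", "linear")) {
    for (cond in list(c(5, 2), c(6, 3), c(7, 3), c(8, 4))) {
      expect_equal(expected_adjacent_count(cond[1], cond[2], topo),
                   enum_adjacent_mean(cond[1], cond[2], topo),
                   tolerance = 1e-12,
                   info = sprintf("%s n=%d k=%d", topo, cond[1], cond[2]))
    }
  }
  expect_equal(expected_adjacent_count(5, 2, "circular"), 1.0)
  expect_equal(expected_adjacent_count(5, 2, "linear"), 0.8)
  # the "about 35" expectation for 5,000 PEGs and 300 GH genes
  expect_equal(expected_adjacent_count(5000, 300, "circular"), 34.82,
               tolerance = 1e-3)
  expect_error(expected_adjacent_count(10, 1), "n_gh")
})

test_that("simulated means agree with the closed form within 4 SE", {
  for (cond in list(c(50, 5), c(200, 20), c(1000, 50))) {
    nd <- simulate_null(null_spec(cond[1], cond[2], iterations = 2000,
                                  seed = 17))
    mu <- nd$summaries["mean", "n_ssc_1"]
    se <- nd$summaries["sd", "n_ssc_1"] / sqrt(nrow(nd$values))
    expect_lt(abs(mu - expected_adjacent_count(cond[1], cond[2])), 4 * se)
  }
})

test_that("simulation converges to the exhaustive average on tiny genomes", {
  nd <- simulate_null(null_spec(5, 2, iterations = 4000, seed = 3))
  expect_equal(nd$summaries["mean", "n_ssc_1"], 1.0, tolerance = 0.05)
  # all slots occupied: every gene adjacent, clustered fraction 1 always
  nd2 <- simulate_null(null_spec(6, 6, iterations = 50, seed = 3,
                                 thresholds = 5L))
  expect_true(all(nd2$values[, "f_clustered_5"] == 1))
})

test_that("identical null specs give bit-identical draws", {
  s <- null_spec(300, 30, iterations = 100, seed = 123)
  expect_identical(simulate_null(s)$values, simulate_null(s)$values)
})

test_that("matched nulls preserve the replicon partition and bracket
           observed clustering correctly", {
  # uniformly placed genes sit inside the null's 95% band almost always:
  # over 30 genomes at least 80% must be inside (the miss rate is 5%)
  inside <- vapply(1:30, function(i) {
    g <- generate_genome(synth_spec(n_pegs = 2000, n_gh = 100,
                                    cluster_count = 0, seed = 300 + i))
    nd <- matched_null(g, iterations = 200, seed = 400 + i,
                       thresholds = 5L)
    obs <- clustered_fraction(g, 5)
    obs >= nd$summaries["q2.5", "f_clustered_5"] &&
      obs <= nd$summaries["q97.5", "f_clustered_5"]
  }, logical(1))
  expect_gte(mean(inside), 0.8)
  g <- generate_genome(synth_spec(n_pegs = 2000, n_gh = 100,
                                  cluster_count = 0, seed = 8))

  # fully contiguous genes exceed the 97.5% quantile
  gc <- mk_genome(2000, gh = 1:100)
  ndc <- matched_null(gc, iterations = 400, seed = 9)
  expect_gt(clustered_fraction(gc, 5),
            ndc$summaries["q97.5", "f_clustered_5"])

  # single-iteration distribution: quantiles equal the sole value
  nd1 <- matched_null(g, iterations = 1, seed = 2)
  expect_equal(nd1$summaries["q2.5", "f_clustered_5"],
               nd1$summaries["q97.5", "f_clustered_5"])

  expect_error(matched_null(mk_genome(50, gh = c(3, 10)), iterations = 10),
               NA)
  expect_error(matched_null(mk_genome(50, gh = 7), iterations = 10),
               "at least 2")
})

test_that("multi-replicon matched nulls keep per-replicon GH counts", {
  g <- mk_genome2(100, c(2, 3, 7, 50), 60, c(10, 20))
  nd <- matched_null(g, iterations = 50, seed = 4)
  expect_equal(nd$spec$n_pegs, 160L)
  expect_equal(nd$spec$n_gh, 6L)
  # every replicate has 6 genes' worth of SSc values pooled
  expect_true(all(rowSums(nd$values[, paste0("n_ssc_", 1:20)]) <= 6))
})

test_that("empirical p uses the add-one rule", {
  vals <- 1:10 / 100
  expect_equal(empirical_p(0.5, vals, "greater"), 1 / 11)
  expect_equal(empirical_p(0.001, vals, "greater"), 1)
  expect_equal(empirical_p(0.001, vals, "less"), 1 / 11)
  expect_equal(empirical_p(0.05, vals, "greater"), (1 + 6) / 11)
  expect_error(empirical_p(1, numeric(0), "greater"), "empty")
})

test_that("normality summary separates normal from exponential samples", {
  set.seed(31)
  norm <- stats::rnorm(5000)
  expo <- stats::rexp(5000)
  expect_gte(normality_summary(norm)$W, 0.99)
  expect_lt(normality_summary(expo)$W, 0.98)
  expect_error(normality_summary(rep(1, 10)), "zero variance")
  # oversized samples are subsampled to the test's limit
  big <- normality_summary(stats::rnorm(8000), seed = 2)
  expect_equal(big$n, 5000L)
})
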