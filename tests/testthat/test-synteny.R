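# Synteny scores, clusters and clustered fractions.

test_that("SSc follows the shortest-distance definition on both topologies", {
  g <- mk_genome(10, gh = c(2, 3, 7))
  expect_equal(synteny_scores(g)$scores$ssc, c(1L, 1L, 4L))

  lin <- mk_genome(10, gh = c(1, 10), topo = "linear")
  expect_equal(synteny_scores(lin)$scores$ssc, c(9L, 9L))
  circ <- mk_genome(10, gh = c(1, 10))
  expect_equal(synteny_scores(circ)$scores$ssc, c(1L, 1L))

  single <- mk_genome(10, gh = 4)
  expect_true(is.na(synteny_scores(single)$scores$ssc))
})

test_that("SSc histogram accounts for every class gene", {
  g <- mk_genome(60, gh = c(1, 2, 10, 33, 59))
  prof <- synteny_scores(g, s_max = 20L)
  ssc <- prof$scores$ssc
  over <- sum(!is.na(ssc) & ssc > prof$s_max)
  expect_equal(sum(prof$n_ssc) + over + sum(is.na(ssc)), prof$n_class)
  expect_true(all(prof$f_ssc >= 0 & prof$f_ssc <= 1))
  expect_equal(sum(prof$f_ssc) * prof$n_class, sum(prof$n_ssc))
})

test_that("distances never cross replicons", {
  g <- mk_genome2(20, c(1, 20), 15, 8)
  prof <- synteny_scores(g)
  ssc <- stats::setNames(prof$scores$ssc, prof$scores$gene_id)
  expect_equal(unname(ssc[c("a1", "a20")]), c(1L, 1L))  # wrap on chr
  expect_true(is.na(ssc["b8"]))                          # alone on plasmid
})

test_that("clusters chain through gaps up to the threshold, wrap-aware", {
  g <- mk_genome(10, gh = c(2, 3, 7))
  cl3 <- find_clusters(g, 3)
  expect_true(setequal_partitions(cluster_partition(cl3),
                                  list(c(2, 3), 7)))
  cl5 <- find_clusters(g, 5)    # wrap gap 7->2 is 5, chains everything
  expect_true(setequal_partitions(cluster_partition(cl5),
                                  list(c(2, 3, 7))))
  expect_equal(nrow(find_clusters(mk_genome(10), 5)), 0L)
  expect_error(find_clusters(g, 0), "threshold")
})

test_that("wrap-spanning clusters keep chain order and correct gaps", {
  g <- mk_genome(12, gh = c(1, 2, 10, 11))
  cl <- find_clusters(g, 3)
  expect_equal(nrow(cl), 1L)
  ords <- cl$ordinals[[1]]
  # chain starts after the largest break (gap 10 -> ... -> 2 or 2 -> 10)
  expect_true(identical(ords, c(10L, 11L, 1L, 2L)))
  expect_equal(cl$gaps[[1]], c(1L, 2L, 1L))
  expect_equal(cl$span[1], 5L)
})

test_that("clustered_fraction matches its definition and handles edge cases", {
  g <- mk_genome(10, gh = c(2, 3, 7))
  expect_equal(clustered_fraction(g, 5), 1)
  expect_equal(clustered_fraction(g, 1), 2 / 3)
  expect_equal(clustered_fraction(mk_genome(10, gh = 4), 5), 0)  # undefined SSc
  expect_error(clustered_fraction(mk_genome(10), 5), "no GH genes")
})

test_that("SSc and clusters match exhaustive enumeration on small replicons", {
  for (topo in c("circular", "linear")) {
    for (n in 3:8) {
      for (k in 1:3) {
        sets <- utils::combn(n, k)
        for (j in seq_len(ncol(sets))) {
          members <- sets[, j]
          g <- mk_genome(n, gh = members, topo = topo)
          got <- synteny_scores(g)$scores$ssc
          expect_equal(got, brute_ssc(n, members, topo),
                       info = sprintf("ssc %s n=%d {%s}", topo, n,
                                      paste(members, collapse = ",")))
          for (thr in 1:3) {
            cl <- find_clusters(g, thr)
            expect_true(
              setequal_partitions(
                cluster_partition(cl),
                brute_cluster_partition(n, members, topo, thr)),
              info = sprintf("clusters %s n=%d thr=%d {%s}", topo, n, thr,
                             paste(members, collapse = ",")))
          }
        }
      }
    }
  }
})

test_that("rotation and reversal leave SSc multiset and clusters unchanged", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    k <- sample(2:6, 1)
    members <- sort(sample.int(n, k))
    g <- mk_genome(n, gh = members)
    base_ssc <- sort(synteny_scores(g)$scores$ssc)
    base_part <- cluster_partition(find_clusters(g, 3))

    rot <- sample.int(n, 1)
    rot_members <- sort(((members - 1 + rot) %% n) + 1)
    gr <- mk_genome(n, gh = rot_members)
    expect_equal(sort(synteny_scores(gr)$scores$ssc), base_ssc)
    rot_part <- lapply(cluster_partition(find_clusters(gr, 3)),
                       function(p) sort(((p - 1 - rot) %% n) + 1))
    expect_true(setequal_partitions(rot_part, base_part))

    rev_members <- sort(n + 1 - members)
    gv <- mk_genome(n, gh = rev_members)
    expect_equal(sort(synteny_scores(gv)$scores$ssc), base_ssc)
  }
})

test_that("clustered_fraction is non-decreasing in the threshold", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(30:100, 1)
    g <- mk_genome(n, gh = sort(sample.int(n, sample(3:10, 1))),
                   topo = sample(c("circular", "linear"), 1))
    fr <- vapply(1:15, function(t) clustered_fraction(g, t), numeric(1))
    expect_true(all(diff(fr) >= 0))
  }
})

test_that("synteny_table joins scores with cluster membership", {
  g <- mk_genome(10, gh = c(2, 3, 7))
  tab <- synteny_table(g, threshold = 3)
  expect_equal(tab$cluster_size[tab$gene_id == "g2"], 2L)
  expect_equal(tab$cluster_size[tab$gene_id == "g7"], 1L)
  expect_equal(tab$ssc, c(1L, 1L, 4L))
})
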