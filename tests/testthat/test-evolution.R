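small_cfg <- function(...) {
  evo_config(random_linlog(m = 2, r = 4, seed = 3), pop_size = 50,
             generations = 5, n_loci = 40, seed = 99, ...)
}

test_that("initial genome places markers and targets correctly", {
  cfg <- small_cfg()
  arr <- initial_genome(cfg, seed = 1)
  expect_identical(length(arr), 40L)
  expect_identical(arr[1], -1L)
  expect_identical(which(arr == -2L), 21L)
  expect_identical(sort(arr[arr > 0]), 1:4)
})

test_that("rearrangements conserve the locus multiset and never move ori", {
  cfg <- small_cfg()
  arr <- initial_genome(cfg, seed = 2)
  set.seed(8)
  cur <- arr
  for (i in 1:200) {
    cur <- if (i %% 2) apply_inversion(cur, cfg) else apply_translocation(cur, cfg)
    expect_identical(sort(cur), sort(arr))
    expect_identical(cur[1], -1L)
  }
  # inversion is an involution; single-locus inversion is the identity
  blk <- 5:9
  expect_identical(apply_inversion(apply_inversion(arr, cfg, blk), cfg, blk), arr)
  expect_identical(apply_inversion(arr, cfg, block = 7L), arr)
  # translocation back to the original position is the identity
  expect_identical(apply_translocation(arr, cfg, block = 5:6, insert_after = 4L), arr)
})

test_that("target positions map both replichores onto [0, 1]", {
  cfg <- small_cfg()
  arr <- rep(0L, 40); arr[1] <- -1L; arr[21] <- -2L
  arr[c(2, 20, 22, 40)] <- 1:4
  p <- target_positions(arr)
  # slots 2 and 40 are one step from ori on either arm; 20 and 22 one step from ter
  expect_equal(as.numeric(p), c(1 / 20, 19 / 20, 19 / 20, 1 / 20))
  expect_error(target_positions(rep(0L, 10)), "invalid genome")
})

test_that("fitness rewards co-location and punishes ori-ter shrinkage", {
  cfg <- small_cfg()
  # contiguous targets adjacent to one another
  clustered <- rep(0L, 40); clustered[1] <- -1L; clustered[21] <- -2L
  clustered[10:13] <- 1:4
  f_clustered <- as.numeric(genome_fitness(clustered, cfg))
  # identical genomes get identical fitness
  expect_identical(f_clustered, as.numeric(genome_fitness(clustered, cfg)))
  # clustered beats the bulk of random arrangements
  set.seed(31)
  f_rand <- replicate(50, {
    as.numeric(genome_fitness(initial_genome(cfg), cfg))
  })
  expect_gt(f_clustered, stats::quantile(f_rand, 0.95))
  # a genome with ter dragged to 50% of the original arc is inviable
  squeezed <- rep(0L, 40); squeezed[1] <- -1L; squeezed[11] <- -2L
  squeezed[30:33] <- 1:4
  fs <- genome_fitness(squeezed, cfg)
  expect_false(attr(fs, "viable"))
  expect_equal(as.numeric(fs), 1 / cfg$obj_cfg$sentinel)
})

test_that("cluster detector matches definitions and the brute-force scanner", {
  # T,T,N,T: one pure cluster of 2 and one mixed cluster spanning 4 loci
  arr <- make_arrangement(c(TRUE, TRUE, FALSE, TRUE))
  cl <- detect_clusters(arr)
  expect_identical(cl$n_pure, 1L)
  expect_identical(cl$max_pure_size, 2L)
  expect_identical(cl$n_mixed, 1L)
  expect_identical(cl$max_mixed_span, 4L)
  # T,N,N,T,N,N,N,T,T: one mixed (gap 2) and one pure (T,T)
  arr2 <- make_arrangement(c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
  cl2 <- detect_clusters(arr2)
  expect_identical(cl2$n_pure, 1L)
  expect_identical(cl2$n_mixed, 1L)
  expect_identical(cl2$max_mixed_span, 4L)
  # scattered targets with >= 3 neutral loci between any two: nothing
  arr3 <- make_arrangement(c(TRUE, rep(FALSE, 3), TRUE, rep(FALSE, 4), TRUE))
  cl3 <- detect_clusters(arr3)
  expect_identical(cl3$n_pure + cl3$n_mixed, 0L)
  # run of three targets
  arr4 <- make_arrangement(c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(detect_clusters(arr4)$max_pure_size, 3L)
  # randomized patterns against the oracle
  set.seed(14)
  for (i in 1:25) {
    pattern <- runif(30) < 0.3
    cl <- detect_clusters(make_arrangement(pattern))
    # oracle works on the sequence after ori excluding nothing; ter is the
    # final non-target locus in make_arrangement's layout
    oracle <- scan_clusters_oracle(c(pattern, FALSE))
    expect_identical(cl$n_pure, length(oracle$pure))
    expect_identical(cl$n_mixed, length(oracle$mixed))
    if (length(oracle$pure)) {
      expect_identical(cl$max_pure_size, max(lengths(oracle$pure)))
    }
    if (length(oracle$mixed)) {
      expect_identical(cl$max_mixed_span, max(lengths(oracle$mixed)))
    }
  }
})

test_that("evolution is deterministic, conserves loci and respects the median filter", {
  cfg <- small_cfg()
  res1 <- evolve(cfg)
  res2 <- evolve(cfg)
  expect_identical(res1$trajectory, res2$trajectory)
  expect_identical(res1$best_genome, res2$best_genome)
  expect_identical(sort(res1$best_genome), sort(res1$initial_genome))
  # zero mutation rates: population and fitness constant forever
  cfg0 <- evo_config(random_linlog(m = 2, r = 4, seed = 3), pop_size = 50,
                     generations = 5, n_loci = 40, p_inv = 0, p_transl = 0,
                     seed = 99)
  res0 <- evolve(cfg0)
  expect_true(all(res0$trajectory$best_fitness == res0$trajectory$best_fitness[1]))
  expect_true(all(res0$trajectory$n_variants == 1L))
})

test_that("selection enriches gene clustering across seeds (scaled-down run)", {
  mod <- random_linlog(m = 3, r = 6, seed = 5)
  deltas <- sapply(1:10, function(s) {
    cfg <- evo_config(mod, pop_size = 150, generations = 120, n_loci = 80,
                      p_inv = 0.02, seed = 1000 + s)
    res <- evolve(cfg, record_every = 120)
    tr <- res$trajectory
    c(fit_gain = tr$best_fitness[nrow(tr)] - tr$best_fitness[1],
      cluster_gain = (tr$n_pure + tr$n_mixed)[nrow(tr)] -
                     (tr$n_pure + tr$n_mixed)[1])
  })
  # fitness of the fittest strain grows in most runs and on average
  expect_gt(mean(deltas["fit_gain", ]), 0)
  # one-sided evidence of cluster enrichment
  expect_gt(mean(deltas["cluster_gain", ]), 0)
})
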