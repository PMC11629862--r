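toy_annotation <- function(positions, genome_length = 1e6, gene_length = 100,
                           modules = list(M1 = paste0("g", seq_along(positions)))) {
  genes <- data.frame(id = paste0("g", seq_along(positions)),
                      start = positions, end = positions + gene_length,
                      strand = "+", stringsAsFactors = FALSE)
  genome_annotation(genome_length, genes, modules)
}

test_that("proximity score is -log2 of the pooled first-quartile distance", {
  # four genes, midpoint gaps 1024 apart in one module: all pairwise
  # distances multiples of 1024, Q1 determined by the quantile dialect
  pos <- c(0, 1024, 2048, 4096)
  ann <- toy_annotation(pos)
  ps <- proximity_score(ann)
  d <- as.numeric(dist(pos + 50))
  expect_equal(attr(ps, "q1"), unname(quantile(d, 0.25)))
  expect_equal(as.numeric(ps), -log2(unname(quantile(d, 0.25))))
  # two genes with midpoints 1024 apart: PS = -10
  ps2 <- proximity_score(toy_annotation(c(0, 1024)))
  expect_equal(as.numeric(ps2), -10)
  # adjacent identical midpoints are floored at 1 nt: PS = 0, not Inf
  ann0 <- toy_annotation(c(5000, 5000 - 1), gene_length = 3)
  expect_lte(as.numeric(proximity_score(ann0)), 0)
  expect_error(proximity_score(toy_annotation(1, modules = list(M1 = "g1"))),
               "undefined")
})

test_that("proximity score respects circular topology, rotation and strand", {
  # genes at the two ends of a circular genome are close, not far
  ann <- toy_annotation(c(100, 1e6 - 300))
  expect_equal(attr(proximity_score(ann), "q1"),
               1e6 - (1e6 - 300 + 50) + 150)
  # rotation invariance
  shift <- 123456
  pos <- c(1000, 5000, 250000, 600000)
  ann1 <- toy_annotation(pos)
  ann2 <- toy_annotation((pos + shift) %% 1e6)
  expect_equal(as.numeric(proximity_score(ann1)), as.numeric(proximity_score(ann2)))
  # strand flips do not matter
  ann3 <- toy_annotation(pos)
  ann3$genes$strand <- c("-", "+", "-", "-")
  expect_equal(as.numeric(proximity_score(ann3)), as.numeric(proximity_score(ann1)))
})

test_that("moving a module pair apart cannot raise the score", {
  base <- c(10000, 12000)
  ps_seq <- sapply(c(0, 5e3, 5e4, 2e5, 4e5), function(extra) {
    as.numeric(proximity_score(toy_annotation(c(base[1], base[2] + extra))))
  })
  expect_true(all(diff(ps_seq) <= 0))
})

test_that("log2 PTR estimation from coverage windows", {
  mkcov <- function(do, dt) {
    coverage_profile(data.frame(position = 1:100, depth = do),
                     data.frame(position = 1:100, depth = dt))
  }
  expect_equal(ptr_from_coverage(mkcov(rep(100, 100), rep(100, 100))), 0)
  expect_equal(ptr_from_coverage(mkcov(rep(200, 100), rep(100, 100))), 1.0)
  expect_error(ptr_from_coverage(mkcov(rep(1, 100), rep(0, 100))), "positive")
})

test_that("replication-activity tests classify simulated species correctly", {
  # constant zeros fail both one-sided tests
  r0 <- ptr_tests(rep(0, 10))
  expect_false(r0$mero_oligoploid)
  expect_gte(r0$p_gt0, 1)
  # strong replication: passes both
  set.seed(77)
  r1 <- ptr_tests(rnorm(10, mean = 1.5, sd = 0.1))
  expect_lte(r1$p_gt0, 0.01)
  expect_lte(r1$p_gt1, 0.01)
  expect_true(r1$mero_oligoploid)
  # moderate replication: passes > 0, fails > 1
  r2 <- ptr_tests(rnorm(10, mean = 0.5, sd = 0.1))
  expect_lte(r2$p_gt0, 0.01)
  expect_gt(r2$p_gt1, 0.5)
  expect_false(r2$mero_oligoploid)
  # too few libraries: excluded with a reason
  r3 <- ptr_tests(c(0.5, 0.7))
  expect_true(r3$excluded)
  expect_match(r3$reason, "libraries")
})

test_that("PS ~ PTR regression recovers planted relations", {
  # exact linear relation: perfect fit
  tab <- data.frame(species = paste0("s", 1:10), ps = seq(-12, -3),
                    log2ptr = 0.3 + 0.1 * seq(-12, -3))
  # summary.lm warns about the noiseless fit being "essentially perfect"
  rep1 <- suppressWarnings(ps_ptr_association(tab))
  expect_equal(rep1$slope, 0.1, tolerance = 1e-10)
  expect_equal(rep1$adj_r2, 1, tolerance = 1e-10)
  # planted slope with noise is recovered within its confidence interval
  set.seed(21)
  hits <- replicate(20, {
    ps <- runif(40, -14, -4)
    tab <- data.frame(species = seq_len(40), ps = ps,
                      log2ptr = 0.5 + 0.12 * ps + rnorm(40, 0, 0.1))
    fit <- ps_ptr_association(tab)
    ci <- confint(fit$fit)[2, ]
    ci[1] <= 0.12 && 0.12 <= ci[2]
  })
  expect_gte(mean(hits), 0.8)
  # permuted predictor: p-values roughly uniform under the null
  set.seed(22)
  ps <- runif(30, -14, -4)
  y <- rnorm(30)
  pvals <- replicate(200, {
    ps_ptr_association(data.frame(species = 1:30, ps = sample(ps), log2ptr = y))$slope_p
  })
  expect_gt(mean(pvals > 0.5), 0.3)
  expect_lt(mean(pvals <= 0.05), 0.15)
  # genus-level averaging and group test
  set.seed(23)
  ps40 <- runif(40, -14, -4)
  tab <- data.frame(species = seq_len(40), ps = ps40,
                    log2ptr = 0.5 + 0.12 * ps40 + rnorm(40, 0, 0.1),
                    genus = rep(letters[1:10], each = 4))
  tab$mero_oligoploid <- tab$log2ptr > 0.5 + 0.12 * median(tab$ps)
  repg <- ps_ptr_association(tab, level = "genus")
  expect_identical(repg$n, 10L)
  reps <- ps_ptr_association(tab)
  expect_s3_class(reps$group_test, "htest")
  expect_error(ps_ptr_association(data.frame(ps = rep(1, 5), log2ptr = rnorm(5))),
               "degenerate")
})

test_that("annotation IO round-trips through BED-like files", {
  ann <- generate_annotated_genome(genome_length = 2e5, n_genes = 60,
                                   gene_length = 500, n_modules = 5,
                                   genes_per_module = 4, theta = 1, seed = 3)
  bed <- tempfile(fileext = ".bed"); mods <- tempfile(fileext = ".tsv")
  write_genome_annotation(ann, bed, mods)
  back <- read_genome_annotation(bed, mods, genome_length = 2e5)
  expect_equal(back$genes$start, ann$genes$start)
  expect_equal(sort(names(back$modules)), sort(names(ann$modules)))
  expect_equal(as.numeric(proximity_score(back)), as.numeric(proximity_score(ann)))
})
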