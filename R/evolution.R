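#' Configuration of the gene-order evolution simulation
#'
#' A population of circular genomes with `n_loci` equally spaced loci
#' (spacing 10 kb), carrying the origin at a fixed locus, the terminus
#' initially antipodal, and one locus per enzyme of the metabolic model;
#' all other loci are neutral. Each generation every genome can undergo at
#' most one rearrangement: an inversion with probability `p_inv` (block
#' length `max(1, round(N(5, var 9)))`) or a translocation with probability
#' `p_transl = p_inv / 2` (block length `max(1, round(N(3, var 9)))`).
#' Fitness is `1 / F` with `F` the homeostasis objective of the implied gene
#' layout; genomes whose minimum ori-ter arc shrinks below
#' `min_oriter_frac` of its initial value get a sentinel minimal fitness.
#' Selection removes variants strictly below the median fitness, then
#' resamples the population proportionally to fitness.
#'
#' @param model a [linlog_model()] providing the target enzymes.
#' @param pop_size population size (default 1e5; scale down for desk runs).
#' @param generations number of generations to simulate.
#' @param p_inv per-genome per-generation inversion probability (the two
#'   scenarios studied are 0.005 and 0.0025).
#' @param p_transl translocation probability; defaults to `p_inv / 2`.
#' @param n_loci number of loci on the circular genome (default 600).
#' @param spacing inter-locus distance in nucleotides (default 10000).
#' @param taus,C,D passed to [objective_config()].
#' @param min_oriter_frac viability threshold on the minimum ori-ter arc,
#'   as a fraction of its initial value (default 0.75).
#' @param inv_block_mean,inv_block_sd,transl_block_mean,transl_block_sd
#'   block-length distribution parameters (normal, rounded, floored at 1).
#' @param seed RNG seed; the whole trajectory is reproducible from it.
#' @return An object of class `evo_config`.
#' @export
evo_config <- function(model, pop_size = 1e5, generations = 1000,
                       p_inv = 0.005, p_transl = p_inv / 2,
                       n_loci = 600, spacing = 1e4,
                       taus = c(20, 30, 40, 50, 70, 90, 120), C = 40, D = 20,
                       min_oriter_frac = 0.75,
                       inv_block_mean = 5, inv_block_sd = 3,
                       transl_block_mean = 3, transl_block_sd = 3,
                       seed = NULL) {
  stopifnot(inherits(model, "linlog_model"))
  if (pop_size < 2) stop("`pop_size` must be >= 2", call. = FALSE)
  if (p_inv < 0 || p_inv > 1 || p_transl < 0 || p_transl > 1 ||
      p_inv + p_transl > 1) {
    stop("mutation probabilities must lie in [0, 1] and sum to <= 1", call. = FALSE)
  }
  n_targets <- length(model$reactions)
  if (n_loci < n_targets + 2L) stop("`n_loci` too small for targets + ori + ter", call. = FALSE)
  structure(list(model = model, obj_cfg = objective_config(model, taus = taus, C = C, D = D),
                 pop_size = as.integer(pop_size), generations = as.integer(generations),
                 p_inv = p_inv, p_transl = p_transl,
                 n_loci = as.integer(n_loci), spacing = spacing,
                 n_targets = n_targets, min_oriter_frac = min_oriter_frac,
                 inv_block_mean = inv_block_mean, inv_block_sd = inv_block_sd,
                 transl_block_mean = transl_block_mean, transl_block_sd = transl_block_sd,
                 seed = seed),
            class = "evo_config")
}

# Genome encoding: integer vector of length n_loci over the circular order.
# Slot 1 always holds the ori marker (-1); the ter marker is -2; target
# genes are 1..n_targets; neutral loci are 0. Rearranged blocks never
# contain ori or ter, so ori stays at slot 1 while ter can drift.
ORI_CODE <- -1L
TER_CODE <- -2L

#' Build the ancestral genome
#'
#' Places ori at slot 1, ter antipodal, and the target genes at random
#' neutral slots (uniform without replacement).
#'
#' @param cfg an [evo_config()].
#' @param seed optional RNG seed for the placement.
#' @return Integer arrangement vector (see package internals).
#' @export
initial_genome <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "evo_config"))
  n <- cfg$n_loci
  ter_slot <- n %/% 2L + 1L
  with_seed(seed, {
    arr <- rep(0L, n)
    arr[1L] <- ORI_CODE
    arr[ter_slot] <- TER_CODE
    free <- setdiff(seq_len(n), c(1L, ter_slot))
    arr[sample(free, cfg$n_targets)] <- seq_len(cfg$n_targets)
    arr
  })
}

# sample a contiguous block of `len` slots (non-wrapping, slots 2..n) that
# avoids the ter marker; resample until valid
sample_block <- function(arr, len) {
  n <- length(arr)
  len <- min(len, n - 3L)  # must leave room for ori and ter outside
  repeat {
    start <- sample.int(n - 1L, 1L) + 1L           # in 2..n
    if (start + len - 1L > n) next                  # no wrap past ori
    block <- start:(start + len - 1L)
    if (!any(arr[block] == TER_CODE)) return(block)
  }
}

block_length <- function(mean, sd) {
  max(1L, as.integer(round(stats::rnorm(1L, mean, sd))))
}

#' Invert a contiguous block of loci
#'
#' Reverses a randomly chosen block (length `max(1, round(N(mean, sd^2)))`)
#' that contains neither the ori nor the ter marker. Conserves the locus
#' multiset; inverting the same block twice restores the genome.
#'
#' @param arr integer arrangement vector.
#' @param cfg an [evo_config()] (block-length parameters).
#' @param block optional explicit slot indices, for testing.
#' @return The rearranged arrangement vector.
#' @export
apply_inversion <- function(arr, cfg, block = NULL) {
  if (is.null(block)) {
    block <- sample_block(arr, block_length(cfg$inv_block_mean, cfg$inv_block_sd))
  }
  arr[block] <- arr[rev(block)]
  arr
}

#' Translocate a contiguous block of loci
#'
#' Excises a randomly chosen block (length `max(1, round(N(mean, sd^2)))`,
#' never containing ori or ter) and reinserts it at a uniformly chosen
#' position in the remaining sequence (never before ori, so ori stays at
#' slot 1). Conserves the locus multiset.
#'
#' @inheritParams apply_inversion
#' @param insert_after optional position (in the excised sequence) after
#'   which to reinsert, for testing; 1 keeps slot 2 as the first possible
#'   insertion point.
#' @return The rearranged arrangement vector.
#' @export
apply_translocation <- function(arr, cfg, block = NULL, insert_after = NULL) {
  if (is.null(block)) {
    block <- sample_block(arr, block_length(cfg$transl_block_mean, cfg$transl_block_sd))
  }
  excised <- arr[block]
  rest <- arr[-block]
  if (is.null(insert_after)) {
    insert_after <- sample.int(length(rest), 1L)   # after position i (>=1: never before ori)
  }
  append(rest, excised, after = insert_after)
}

#' Fractional ori-ter positions of the target genes
#'
#' Maps each target locus to its replichore-fractional position: the arc
#' distance from ori (in loci) divided by the ori-ter arc length on that
#' side of the chromosome.
#'
#' @param arr integer arrangement vector.
#' @return Numeric vector of positions, ordered by target gene id, plus
#'   attributes `arm_lengths` (clockwise/counterclockwise ori-ter arcs, in
#'   loci).
#' @export
target_positions <- function(arr) {
  n <- length(arr)
  ter <- which(arr == TER_CODE)
  if (arr[1L] != ORI_CODE || length(ter) != 1L) {
    stop("invalid genome: ori must sit at slot 1 and exactly one ter marker must exist",
         call. = FALSE)
  }
  arm_cw <- ter - 1L           # slots 1 -> ter clockwise
  arm_ccw <- n - ter + 1L      # slots ter -> 1 the other way
  idx <- which(arr > 0L)
  p <- ifelse(idx <= ter, (idx - 1L) / arm_cw, (n + 1L - idx) / arm_ccw)
  structure(p[order(arr[idx])], arm_lengths = c(cw = arm_cw, ccw = arm_ccw))
}

#' Fitness of a genome arrangement
#'
#' `1 / F` with `F` the homeostasis objective of the implied gene layout.
#' Genomes violating the ori-ter arc constraint, or whose layout yields a
#' singular steady state, receive the sentinel minimal fitness.
#'
#' @param arr integer arrangement vector.
#' @param cfg an [evo_config()].
#' @return Scalar fitness (attribute `F` carries the objective value).
#' @export
genome_fitness <- function(arr, cfg) {
  stopifnot(inherits(cfg, "evo_config"))
  p <- target_positions(arr)
  arms <- attr(p, "arm_lengths")
  init_min_arm <- min((cfg$n_loci %/% 2L), cfg$n_loci - (cfg$n_loci %/% 2L))
  if (min(arms) < cfg$min_oriter_frac * init_min_arm) {
    return(structure(1 / cfg$obj_cfg$sentinel, F = cfg$obj_cfg$sentinel,
                     viable = FALSE))
  }
  F <- objective_F(as.numeric(p), cfg$obj_cfg)
  structure(1 / as.numeric(F), F = as.numeric(F), viable = !attr(F, "singular"))
}

#' Detect pure and mixed gene clusters on a genome
#'
#' Working on the circular order cut at the origin (a cluster may not span
#' ori; the ter marker counts as an ordinary non-target locus), finds
#' \emph{pure clusters} - maximal runs of >= 2 consecutive target genes -
#' and \emph{mixed clusters} - maximal stretches with target genes at both
#' extremities, at least one internal non-target locus, and every internal
#' non-target run of length <= 2.
#'
#' @param arr integer arrangement vector.
#' @return A list with `n_pure`, `max_pure_size` (target genes in the
#'   largest pure run), `n_mixed`, `max_mixed_span` (loci spanned by the
#'   largest mixed cluster), and the cluster member lists `pure` / `mixed`
#'   (slot indices).
#' @export
detect_clusters <- function(arr) {
  n <- length(arr)
  seq_lin <- arr[-1L]                       # cut the circle at ori
  is_t <- seq_lin > 0L
  # pure clusters: maximal runs of targets with length >= 2
  rl <- rle(is_t)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  pure_idx <- which(rl$values & rl$lengths >= 2L)
  pure <- lapply(pure_idx, function(i) (starts[i]:ends[i]) + 1L)  # back to slots
  # mixed clusters: group targets whose successive gaps are <= 2 non-targets
  tpos <- which(is_t)
  mixed <- list()
  if (length(tpos) >= 2L) {
    gap_ok <- diff(tpos) <= 3L              # <= 2 non-targets between them
    grp <- cumsum(c(TRUE, !gap_ok))
    for (g in split(tpos, grp)) {
      if (length(g) < 2L) next
      span <- g[1L]:g[length(g)]
      if (any(!is_t[span])) {               # needs an internal non-target
        mixed[[length(mixed) + 1L]] <- span + 1L
      }
    }
  }
  list(
    n_pure = length(pure),
    max_pure_size = if (length(pure)) max(lengths(pure)) else 0L,
    n_mixed = length(mixed),
    max_mixed_span = if (length(mixed)) max(lengths(mixed)) else 0L,
    pure = pure, mixed = mixed)
}

#' Simulate gene-order evolution under the homeostasis objective
#'
#' Population simulation at the level of unique structural variants: each
#' generation (1) every genome mutates with probabilities `p_inv` /
#' `p_transl` (at most one event per genome); (2) fitness is computed only
#' for never-seen arrangements (cached by arrangement key - numerically
#' identical to recomputation); (3) variants with fitness strictly below
#' the population median are removed (ties at the median survive, so
#' selection can never empty the population); (4) the population is
#' resampled to `pop_size` with probabilities proportional to
#' `count x fitness`; (5) cluster statistics of the fittest variant and
#' population means are recorded. The whole trajectory is a deterministic
#' function of `cfg$seed`.
#'
#' @param cfg an [evo_config()].
#' @param record_every record trajectory rows every this many generations
#'   (generation 0 and the final generation are always recorded).
#' @return A list of class `evo_result`: `trajectory` (data frame with
#'   `generation`, `best_fitness`, `mean_fitness`, `n_pure`,
#'   `max_pure_size`, `n_mixed`, `max_mixed_span`, `n_variants`),
#'   `best_genome` (fittest final arrangement), `initial_genome`, and `cfg`.
#' @export
evolve <- function(cfg, record_every = 1L) {
  stopifnot(inherits(cfg, "evo_config"))
  with_seed(cfg$seed, evolve_impl(cfg, record_every))
}

evolve_impl <- function(cfg, record_every) {
  key_of <- function(arr) paste(arr, collapse = ".")
  fitness_cache <- new.env(parent = emptyenv())
  fitness_of <- function(arr, key) {
    if (!is.null(f <- fitness_cache[[key]])) return(f)
    f <- as.numeric(genome_fitness(arr, cfg))
    fitness_cache[[key]] <- f
    f
  }
  anc <- initial_genome(cfg)
  anc_key <- key_of(anc)
  variants <- list()                  # key -> arrangement
  variants[[anc_key]] <- anc
  counts <- stats::setNames(cfg$pop_size, anc_key)
  fit <- stats::setNames(fitness_of(anc, anc_key), anc_key)

  record <- function(gen) {
    best <- which.max(fit)
    cl <- detect_clusters(variants[[names(fit)[best]]])
    data.frame(generation = gen,
               best_fitness = unname(fit[best]),
               mean_fitness = sum(fit[names(counts)] * counts) / sum(counts),
               n_pure = cl$n_pure, max_pure_size = cl$max_pure_size,
               n_mixed = cl$n_mixed, max_mixed_span = cl$max_mixed_span,
               n_variants = length(counts))
  }
  traj <- list(record(0L))

  for (gen in seq_len(cfg$generations)) {
    if (cfg$p_inv + cfg$p_transl > 0) {
      new_counts <- counts
      for (key in names(counts)) {
        k <- counts[[key]]
        ev <- stats::rmultinom(1L, k, c(cfg$p_inv, cfg$p_transl,
                                        1 - cfg$p_inv - cfg$p_transl))
        n_mut <- ev[1L] + ev[2L]
        if (n_mut == 0L) next
        parent <- variants[[key]]
        for (j in seq_len(n_mut)) {
          child <- if (j <= ev[1L]) apply_inversion(parent, cfg)
                   else apply_translocation(parent, cfg)
          ck <- key_of(child)
          if (is.null(variants[[ck]])) {
            variants[[ck]] <- child
            fit[ck] <- fitness_of(child, ck)
          }
          new_counts[ck] <- (if (ck %in% names(new_counts)) new_counts[[ck]] else 0L) + 1L
          new_counts[key] <- new_counts[[key]] - 1L
        }
      }
      counts <- new_counts[new_counts > 0L]
    }
    # selection: drop variants strictly below the individual-level median
    fvec <- fit[names(counts)]
    med <- weighted_median(fvec, counts)
    keep <- fvec >= med
    counts <- counts[keep]
    fvec <- fvec[keep]
    # fitness-proportional resampling back to pop_size
    w <- as.numeric(counts) * fvec
    counts <- stats::setNames(
      as.integer(stats::rmultinom(1L, cfg$pop_size, w / sum(w))), names(counts))
    counts <- counts[counts > 0L]
    # prune arrangements no longer alive (fitness cache is kept)
    variants <- variants[names(counts)]
    fit <- fit[names(counts)]
    if (gen %% record_every == 0L || gen == cfg$generations) {
      traj[[length(traj) + 1L]] <- record(gen)
    }
  }
  trajectory <- do.call(rbind, traj)
  best <- names(fit)[which.max(fit)]
  structure(list(trajectory = trajectory, best_genome = variants[[best]],
                 initial_genome = anc, cfg = cfg),
            class = "evo_result")
}

# median over individuals when values come with integer multiplicities
weighted_median <- function(values, weights) {
  o <- order(values)
  v <- values[o]; w <- as.numeric(weights[o])
  cw <- cumsum(w)
  total <- cw[length(cw)]
  i <- which(cw >= total / 2)[1L]
  if (cw[i] == total / 2 && i < length(v)) (v[i] + v[i + 1L]) / 2 else v[i]
}
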