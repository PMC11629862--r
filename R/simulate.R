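#' Simulate sequencing-coverage windows around ori and ter
#'
#' Generates the two 50-kb coverage windows consumed by
#' [ptr_from_coverage()]. Expected depth follows the replication dosage
#' model: relative to the terminus depth, a locus at fractional position `p`
#' is covered `2^(((1 - p) C + D) / tau) / 2^(D / tau)`-fold. Within each
#' 50-kb window the dosage gradient is second order (the window is ~1% of a
#' replichore) and is neglected: the ori window is generated flat at the
#' `p = 0` level and the ter window at the `p = 1` level, which makes the
#' noiseless mean-ratio estimator recover `C / tau` exactly. Counts are
#' drawn per position from the chosen noise model.
#'
#' @param params a [replication_params()].
#' @param depth_ter expected depth at the terminus (reads per position).
#' @param genome_length genome length in nucleotides (default 4.6e6); with
#'   ori at 0, ter sits at `genome_length / 2` on the circle.
#' @param window_length window length in nucleotides (default 50000).
#' @param noise `"poisson"` (default), `"nb"` (negative binomial, for
#'   overdispersed real-world coverage) or `"none"`.
#' @param dispersion negative-binomial size parameter (only for `noise = "nb"`).
#' @param spacing sample one position every `spacing` nt within the window
#'   (default 1: every position).
#' @param seed RNG seed.
#' @return A [coverage_profile()].
#' @export
simulate_coverage <- function(params, depth_ter = 100, genome_length = 4.6e6,
                              window_length = 5e4,
                              noise = c("poisson", "nb", "none"),
                              dispersion = 10, spacing = 1L, seed = NULL) {
  stopifnot(inherits(params, "replication_params"))
  noise <- match.arg(noise)
  stopifnot_scalar_pos(depth_ter, "depth_ter")
  half <- window_length / 2
  offs <- seq(-half, half - spacing, by = spacing)
  ter_center <- genome_length / 2
  mu_ori <- depth_ter * 2^(params$C / params$tau)  # p = 0 level
  mu_ter <- depth_ter                               # p = 1 level
  draw <- function(mu, n) {
    switch(noise,
           none = rep(mu, n),
           poisson = stats::rpois(n, mu),
           nb = stats::rnbinom(n, mu = mu, size = dispersion))
  }
  with_seed(seed, {
    ori <- data.frame(position = (offs %% genome_length),
                      depth = draw(mu_ori, length(offs)))
    ter <- data.frame(position = ter_center + offs,
                      depth = draw(mu_ter, length(offs)))
    coverage_profile(ori, ter, window_length = window_length)
  })
}

#' Generate an annotated circular genome with planted gene modules
#'
#' Places `n_modules` functional modules of `genes_per_module` genes each on
#' a circular genome; with probability `theta` a module is planted as a
#' contiguous block of gene slots, otherwise its genes are scattered
#' uniformly. Filler genes occupy a share of the remaining slots. `theta = 1`
#' gives maximal clustering (highest proximity score for the configuration),
#' `theta = 0` a fully scattered genome.
#'
#' @param genome_length genome length in nucleotides (default 4.6e6).
#' @param n_genes total number of genes including fillers (default 3000).
#' @param gene_length gene length in nucleotides (default 900).
#' @param n_modules number of functional modules (default 50).
#' @param genes_per_module module size (default 6).
#' @param theta clustering degree in [0, 1].
#' @param seed RNG seed.
#' @return A [genome_annotation()].
#' @export
generate_annotated_genome <- function(genome_length = 4.6e6, n_genes = 3000,
                                      gene_length = 900, n_modules = 50,
                                      genes_per_module = 6, theta = 0.5,
                                      seed = NULL) {
  if (theta < 0 || theta > 1) stop("`theta` must lie in [0, 1]", call. = FALSE)
  slot_size <- round(gene_length * 1.3)
  n_slots <- floor(genome_length / slot_size)
  n_module_genes <- n_modules * genes_per_module
  if (n_genes < n_module_genes) stop("`n_genes` smaller than the module genes", call. = FALSE)
  if (n_slots < n_genes) {
    stop(sprintf("cannot pack %d non-overlapping genes of length %d into %g nt",
                 n_genes, gene_length, genome_length), call. = FALSE)
  }
  with_seed(seed, {
    free <- rep(TRUE, n_slots)
    slot_of <- integer(0)
    module_of <- character(0)
    for (mi in seq_len(n_modules)) {
      clustered <- stats::runif(1) < theta
      if (clustered) {
        # uniform choice among starts of fully free runs (circular)
        ok <- vapply(seq_len(n_slots), function(s) {
          idx <- ((s - 1L + 0:(genes_per_module - 1L)) %% n_slots) + 1L
          all(free[idx])
        }, logical(1))
        if (!any(ok)) stop("infeasible packing: no free run for a clustered module", call. = FALSE)
        s <- sample(which(ok), 1L)
        idx <- ((s - 1L + 0:(genes_per_module - 1L)) %% n_slots) + 1L
      } else {
        idx <- sample(which(free), genes_per_module)
      }
      free[idx] <- FALSE
      slot_of <- c(slot_of, idx)
      module_of <- c(module_of, rep(sprintf("M%03d", mi), genes_per_module))
    }
    n_fill <- n_genes - n_module_genes
    fill_idx <- if (n_fill > 0) sample(which(free), n_fill) else integer(0)
    slots <- c(slot_of, fill_idx)
    ids <- sprintf("g%05d", seq_along(slots))
    genes <- data.frame(
      id = ids,
      start = (slots - 1L) * slot_size,
      end = (slots - 1L) * slot_size + gene_length,
      strand = sample(c("+", "-"), length(slots), replace = TRUE),
      stringsAsFactors = FALSE)
    modules <- split(ids[seq_len(n_module_genes)], module_of)
    genome_annotation(genome_length, genes, modules, circular = TRUE)
  })
}

#' Random valid linlog model
#'
#' Builds a connected chain-with-branches network: `m` variable metabolites
#' in a linear chain from an external substrate to an external product
#' (`m + 1` chain reactions), plus `r - m - 1` parallel bypass reactions
#' that split the flux of randomly chosen chain steps, so a strictly
#' positive `J0` in the null space of `N` exists by construction. Reference
#' levels are normalized (`E0 = x0 = c0 = 1`); elasticities are +1 for
#' substrates and -1 for products with small multiplicative jitter. Models
#' whose steady-state matrix is singular at the reference are resampled.
#'
#' @param m number of variable metabolites (>= 1).
#' @param r number of reactions (>= m + 1).
#' @param seed RNG seed.
#' @param jitter sd of the log-normal jitter on elasticities (default 0.1).
#' @param max_attempts resampling budget for singular constructions.
#' @return A [linlog_model()] whose last chain reaction (the sink) is the
#'   output reaction.
#' @export
random_linlog <- function(m, r, seed = NULL, jitter = 0.1, max_attempts = 20L) {
  if (m < 1L) stop("`m` must be >= 1", call. = FALSE)
  if (r < m + 1L) stop("need `r >= m + 1` for a source-to-sink chain", call. = FALSE)
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      mets <- paste0("x", seq_len(m))
      exts <- c("s_in", "s_out")
      n_extra <- r - (m + 1L)
      # chain edge e goes from node e-1 to node e (node 0 = external in,
      # node m+1 = external out)
      edge_from <- 0:m
      edge_to <- 1:(m + 1L)
      flux <- rep(1, m + 1L)
      extra_edge <- if (n_extra > 0) sample(m + 1L, n_extra, replace = TRUE) else integer(0)
      rxn_from <- c(edge_from, edge_from[extra_edge])
      rxn_to <- c(edge_to, edge_to[extra_edge])
      flux <- c(flux, numeric(n_extra))
      for (k in seq_along(extra_edge)) {
        u <- stats::runif(1, 0.2, 0.8) * flux[extra_edge[k]]
        flux[extra_edge[k]] <- flux[extra_edge[k]] - u
        flux[m + 1L + k] <- u
      }
      rxns <- paste0("v", seq_len(r))
      N <- matrix(0, m, r, dimnames = list(mets, rxns))
      Bx <- matrix(0, r, m, dimnames = list(rxns, mets))
      Bc <- matrix(0, r, 2, dimnames = list(rxns, exts))
      jit <- function(n) exp(stats::rnorm(n, 0, jitter))
      for (i in seq_len(r)) {
        f <- rxn_from[i]; t <- rxn_to[i]
        if (f == 0) Bc[i, "s_in"] <- jit(1) else {
          N[f, i] <- -1; Bx[i, f] <- jit(1)
        }
        if (t == m + 1L) Bc[i, "s_out"] <- -jit(1) else {
          N[t, i] <- 1; Bx[i, t] <- -jit(1)
        }
      }
      model <- linlog_model(N, E0 = rep(1, r), J0 = flux, x0 = rep(1, m),
                            c0 = stats::setNames(c(1, 1), exts), Bx = Bx, Bc = Bc,
                            output_reaction = rxns[m + 1L])
      ok <- tryCatch({
        x <- linlog_steady_state(model, check = TRUE)
        max(abs(x - model$x0)) < 1e-8
      }, error = function(e) FALSE)
      if (ok) return(model)
    }
    stop("failed to build a nonsingular random linlog model", call. = FALSE)
  })
}
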