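#' Homeostasis-objective configuration
#'
#' Bundles everything needed to score a gene layout (or a promoter-strength
#' vector) for metabolite homeostasis: the linlog model whose enzymes the
#' genes encode, the replication parameters, and the set of division times
#' across which the coefficient of variation is computed.
#'
#' @param model a [linlog_model()].
#' @param taus division times in minutes; default
#'   `c(20, 30, 40, 50, 70, 90, 120)`, spanning fast to slow growth for an
#'   E. coli-like organism.
#' @param C,D replication period and division delay in minutes (defaults 40
#'   and 20).
#' @param sentinel objective value assigned to layouts whose steady state is
#'   singular (treated as an invalid/lethal phenotype); default `1e6`.
#' @return An object of class `objective_config`.
#' @export
objective_config <- function(model, taus = c(20, 30, 40, 50, 70, 90, 120),
                             C = 40, D = 20, sentinel = 1e6) {
  stopifnot(inherits(model, "linlog_model"))
  if (length(taus) < 1L || any(taus <= 0)) stop("`taus` must be nonempty and positive", call. = FALSE)
  params <- derive_parameters(model)
  structure(list(model = model, params = params,
                 taus = as.numeric(taus), C = C, D = D, sentinel = sentinel,
                 # precomputed pieces of the steady-state system (hot path)
                 N = unname(model$N),
                 Bp = unname(params$Bp),
                 a_eff = unname(params$Ap + as.numeric(params$Cp %*% log(model$c0))),
                 E0 = unname(model$E0)),
            class = "objective_config")
}

#' Enzyme abundances implied by gene positions at one division time
#'
#' Copy numbers act multiplicatively on expression: at division time `tau`
#' the enzyme encoded at position `p_i` is present at
#' `E_i = E0_i * n(p_i; C, D, tau)` (positions mode) or
#' `E_i = k_i * n(p_i; C, D, tau)` (promoter mode, fixed positions).
#'
#' @param positions fractional ori-ter positions, one per reaction.
#' @param cfg an [objective_config()].
#' @param tau division time in minutes.
#' @param k optional promoter-strength multipliers replacing `E0`.
#' @return Enzyme abundance vector aligned with the model's reactions.
#' @export
enzymes_from_positions <- function(positions, cfg, tau, k = NULL) {
  stopifnot(inherits(cfg, "objective_config"))
  r <- length(cfg$model$reactions)
  if (length(positions) != r) stop("one position per reaction is required", call. = FALSE)
  base <- if (is.null(k)) cfg$model$E0 else k
  if (any(base <= 0)) stop("enzyme multipliers must be > 0", call. = FALSE)
  rp <- replication_params(cfg$C, cfg$D, tau)
  base * average_copy_number(rp, positions)
}

#' Average coefficient of variation of metabolite concentrations
#'
#' The homeostasis objective: for each division time in `cfg$taus` the gene
#' layout is converted to enzyme abundances, the linlog steady state is
#' solved and every metabolite concentration collected;
#' `F = mean_i(sd_i / mean_i)` across division times (sample standard
#' deviation). `F = 0` iff the metabolite vector is identical at every
#' division time, which happens exactly when all enzymes scale uniformly -
#' e.g. when all genes share one position. The fitness proxy used by the
#' evolutionary modules is `1 / F`. Layouts with a singular steady state at
#' any division time receive the sentinel value, flagged via the
#' `"singular"` attribute.
#'
#' @param positions fractional positions (positions mode) - or, in promoter
#'   mode, the fixed positions with `k` the decision vector.
#' @param cfg an [objective_config()].
#' @param k promoter strengths (promoter mode only).
#' @return The objective value `F` (>= 0), with attribute `singular`.
#' @export
objective_F <- function(positions, cfg, k = NULL) {
  stopifnot(inherits(cfg, "objective_config"))
  base <- if (is.null(k)) cfg$E0 else k
  if (length(positions) != length(cfg$E0) || length(base) != length(cfg$E0)) {
    stop("one position (and one multiplier) per reaction is required", call. = FALSE)
  }
  if (any(base <= 0) || any(positions < 0) || any(positions > 1)) {
    return(structure(cfg$sentinel, singular = TRUE))
  }
  m <- nrow(cfg$N)
  nt <- length(cfg$taus)
  # copy numbers for all genes x division times in one shot
  logcop <- outer(((1 - positions) * cfg$C + cfg$D) * log(2), 1 / cfg$taus)
  Ecop <- base * exp(logcop)
  X <- matrix(NA_real_, m, nt)
  for (t in seq_len(nt)) {
    E <- Ecop[, t]
    logx <- tryCatch(-solve(cfg$N %*% (cfg$Bp * E), cfg$N %*% (E * cfg$a_eff)),
                     error = function(e) NULL)
    if (is.null(logx) || anyNA(logx) || any(!is.finite(logx))) {
      return(structure(cfg$sentinel, singular = TRUE))
    }
    X[, t] <- exp(logx)
  }
  if (nt == 1L) return(structure(0, singular = FALSE))
  mu <- rowMeans(X)
  sdev <- sqrt(rowSums((X - mu)^2) / (nt - 1))
  structure(mean(sdev / mu), singular = FALSE)
}

#' Default optimizer control settings
#'
#' The box-constrained quasi-Newton setup used for the homeostasis
#' objective: `abs.tol = 1e-15`, `xf.tol = 1e-12`, `x.tol = 1e-12`,
#' `iter.max = 1e6`, `eval.max = 1e6`, `step.min = 1e-6`, `step.max = 1`.
#' Pass `iter.max`/`eval.max` overrides for bounded-effort scans (the
#' promoter objective has a flat direction - uniform scaling of all
#' multipliers leaves `F` unchanged - along which full convergence to the
#' tight tolerances can take very long without changing the outcome).
#'
#' @param ... named overrides of individual control entries.
#' @return A list suitable for [stats::nlminb()]'s `control` argument.
#' @export
nlminb_control <- function(...) {
  ctl <- list(abs.tol = 1e-15, xf.tol = 1e-12, x.tol = 1e-12,
              iter.max = 1e6, eval.max = 1e6, step.min = 1e-6, step.max = 1)
  utils::modifyList(ctl, list(...))
}

#' Optimize gene positions for metabolite homeostasis
#'
#' Runs `n_runs` independent local optimizations (box-constrained
#' quasi-Newton, [stats::nlminb()]) of [objective_F()] over the fractional
#' positions of all genes, each started from a uniformly random layout. The
#' optimizer is local by design: the question is whether gene clusters form
#' under the homeostasis objective, not what the global optimum is.
#'
#' @param model a [linlog_model()].
#' @param cfg an [objective_config()]; built from `model` if `NULL`.
#' @param n_runs number of random restarts.
#' @param seed RNG seed (per-run seeds are derived from it).
#' @param start optional matrix (n_runs x n_genes) of starting layouts,
#'   overriding the random draws - used for matched position/promoter
#'   comparisons.
#' @param control optimizer options, see [nlminb_control()].
#' @return A list of class `optimization_runs`: `runs` (data frame with
#'   `run`, `start_F`, `final_F`, `iterations`, `convergence`, `message`),
#'   `layouts` (n_runs x n_genes matrix of converged positions), `starts`
#'   (matrix of starting layouts) and `mode = "positions"`.
#' @export
optimize_positions <- function(model, cfg = NULL, n_runs = 10, seed = NULL,
                               start = NULL, control = nlminb_control()) {
  if (is.null(cfg)) cfg <- objective_config(model)
  ngene <- length(cfg$model$reactions)
  starts <- if (is.null(start)) {
    with_seed(seed, matrix(stats::runif(n_runs * ngene), n_runs, ngene))
  } else {
    stopifnot(ncol(start) == ngene)
    start[rep_len(seq_len(nrow(start)), n_runs), , drop = FALSE]
  }
  layouts <- matrix(NA_real_, n_runs, ngene,
                    dimnames = list(NULL, cfg$model$reactions))
  runs <- data.frame(run = seq_len(n_runs), start_F = NA_real_,
                     final_F = NA_real_, iterations = NA_integer_,
                     convergence = NA_integer_, message = NA_character_,
                     stringsAsFactors = FALSE)
  for (i in seq_len(n_runs)) {
    p0 <- starts[i, ]
    runs$start_F[i] <- as.numeric(objective_F(p0, cfg))
    fit <- tryCatch(
      stats::nlminb(p0, function(p) as.numeric(objective_F(p, cfg)),
                    lower = 0, upper = 1, control = control),
      error = function(e) NULL)
    if (is.null(fit)) {
      runs$message[i] <- "optimizer failure"
      next
    }
    layouts[i, ] <- fit$par
    runs$final_F[i] <- min(fit$objective, runs$start_F[i])
    runs$iterations[i] <- fit$iterations
    runs$convergence[i] <- fit$convergence
    runs$message[i] <- fit$message
  }
  structure(list(runs = runs, layouts = layouts, starts = starts,
                 mode = "positions"),
            class = "optimization_runs")
}

#' Optimize promoter strengths at fixed gene positions
#'
#' Same protocol as [optimize_positions()], but genes cannot move: each run
#' fixes a random gene layout and optimizes one multiplier `k_i` per gene
#' (the promoter strength), with enzyme levels `E_i = k_i n(p_i, tau)`.
#' Because a static `k` cannot undo the division-time dependence of the
#' copy-number ratios between genes at different positions, promoter tuning
#' cannot reach the homeostasis attainable by co-locating the genes.
#'
#' @inheritParams optimize_positions
#' @param positions optional matrix (n_runs x n_genes) of fixed layouts;
#'   drawn uniformly at random when `NULL`.
#' @param k_bounds positive box bounds for the multipliers
#'   (default `c(1e-3, 1e3)`).
#' @return As [optimize_positions()], with `layouts` holding the converged
#'   multipliers, `positions` the fixed layouts, and `mode = "promoters"`.
#' @export
optimize_promoters <- function(model, cfg = NULL, n_runs = 10, seed = NULL,
                               positions = NULL, k_bounds = c(1e-3, 1e3),
                               control = nlminb_control()) {
  if (is.null(cfg)) cfg <- objective_config(model)
  ngene <- length(cfg$model$reactions)
  pos <- if (is.null(positions)) {
    with_seed(seed, matrix(stats::runif(n_runs * ngene), n_runs, ngene))
  } else {
    stopifnot(ncol(positions) == ngene)
    positions[rep_len(seq_len(nrow(positions)), n_runs), , drop = FALSE]
  }
  ks <- matrix(NA_real_, n_runs, ngene,
               dimnames = list(NULL, cfg$model$reactions))
  runs <- data.frame(run = seq_len(n_runs), start_F = NA_real_,
                     final_F = NA_real_, iterations = NA_integer_,
                     convergence = NA_integer_, message = NA_character_,
                     stringsAsFactors = FALSE)
  for (i in seq_len(n_runs)) {
    p_fix <- pos[i, ]
    k0 <- cfg$model$E0
    runs$start_F[i] <- as.numeric(objective_F(p_fix, cfg, k = k0))
    fit <- tryCatch(
      stats::nlminb(k0, function(k) as.numeric(objective_F(p_fix, cfg, k = k)),
                    lower = k_bounds[1], upper = k_bounds[2],
                    control = control),
      error = function(e) NULL)
    if (is.null(fit)) {
      runs$message[i] <- "optimizer failure"
      next
    }
    ks[i, ] <- fit$par
    runs$final_F[i] <- min(fit$objective, runs$start_F[i])
    runs$iterations[i] <- fit$iterations
    runs$convergence[i] <- fit$convergence
    runs$message[i] <- fit$message
  }
  structure(list(runs = runs, layouts = ks, positions = pos, mode = "promoters"),
            class = "optimization_runs")
}

#' Group genes into position clusters
#'
#' Single-linkage grouping of genes whose converged positions are within
#' `distance_threshold` of each other on the ori-ter axis; cluster labels
#' are deterministic, ordered by mean cluster position.
#'
#' @param layout numeric vector of fractional positions (named by gene).
#' @param distance_threshold linkage threshold in fractional position units,
#'   in (0, 1).
#' @return Integer vector of cluster labels aligned with `layout`.
#' @export
cluster_summary <- function(layout, distance_threshold = 0.02) {
  if (distance_threshold <= 0 || distance_threshold >= 1) {
    stop("`distance_threshold` must be in (0, 1)", call. = FALSE)
  }
  n <- length(layout)
  if (n == 1L) return(stats::setNames(1L, names(layout)))
  hc <- stats::hclust(stats::dist(layout), method = "single")
  raw <- stats::cutree(hc, h = distance_threshold)
  means <- tapply(layout, raw, mean)
  relabel <- rank(means, ties.method = "first")
  stats::setNames(as.integer(relabel[as.character(raw)]), names(layout))
}
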