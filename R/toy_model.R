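#' Two-enzyme source-sink toy pathway
#'
#' The minimal system `Xin -(E1 k1)-> s -(E2 k2)-> Xout` under mass action:
#' a single intermediate metabolite `s` produced from an external substrate
#' and drained to an external product. Its steady state is available in
#' closed form and depends on the enzymes only through the ratio `E1 / E2`,
#' making it the simplest setting in which replication-driven dosage
#' imbalance between two genes perturbs a metabolite pool.
#'
#' @param k1,k2 mass-action rate constants (1/min per enzyme unit, > 0).
#' @param Xin external substrate concentration (> 0).
#' @param E1,E2 enzyme abundances (> 0).
#' @return An object of class `toy_pathway`.
#' @export
toy_pathway <- function(k1 = 1, k2 = 1, Xin = 1, E1 = 1, E2 = 1) {
  for (nm in c("k1", "k2", "Xin", "E1", "E2")) {
    stopifnot_scalar_pos(get(nm), nm)
  }
  structure(list(k1 = k1, k2 = k2, Xin = Xin, E1 = E1, E2 = E2),
            class = "toy_pathway")
}

#' Steady-state concentration of the toy-pathway intermediate
#'
#' `s_ss = (E1/E2) (k1/k2) Xin`: linear in `E1`, inversely proportional to
#' `E2`, hence constant under any uniform scaling of both enzymes.
#'
#' @param tp a [toy_pathway()].
#' @return Steady-state concentration of `s`.
#' @export
steady_state_intermediate <- function(tp) {
  stopifnot(inherits(tp, "toy_pathway"))
  (tp$E1 / tp$E2) * (tp$k1 / tp$k2) * tp$Xin
}

#' Scaled sensitivity of the intermediate to the division time
#'
#' Substituting the average copy number at positions `p1` (producing enzyme)
#' and `p2` (consuming enzyme) for the enzyme abundances gives
#' \deqn{\frac{\partial \ln s_{ss}}{\partial \ln C/\tau} =
#'   \frac{C}{\tau}\,\ln 2\,(p_2 - p_1) = \mu C \Delta p,}
#' with `mu = ln 2 / tau`. The sensitivity vanishes iff the two genes are at
#' the same position; if `p1 > p2`, faster growth (larger `C/tau`) depletes
#' the pool.
#'
#' @param params a [replication_params()].
#' @param p1,p2 fractional positions of the producing and consuming gene.
#' @return The scaled sensitivity (dimensionless).
#' @export
growth_sensitivity <- function(params, p1, p2) {
  stopifnot(inherits(params, "replication_params"))
  check_position(p1); check_position(p2)
  (params$C / params$tau) * log(2) * (p2 - p1)
}

#' Configuration for the two-gene position scan
#'
#' @param genome_length virtual chromosome length in nucleotides (default
#'   2e6, linear: position 0 is ori, `genome_length` is ter).
#' @param position_grid number of grid points per gene axis (default 41).
#' @param taus division times over which homeostasis is assessed; default 5
#'   equally spaced values in \[20, 60\] minutes.
#' @param C,D replication period and division delay, minutes. Defaults
#'   C = 40, D = 20 (classic fast-growth values for an E. coli-like cell).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(genome_length = 2e6, position_grid = 41,
                        taus = seq(20, 60, length.out = 5), C = 40, D = 20) {
  stopifnot_scalar_pos(genome_length, "genome_length")
  if (length(taus) < 1L || any(taus <= 0)) stop("`taus` must be a nonempty positive vector", call. = FALSE)
  if (position_grid < 2L) stop("`position_grid` must be >= 2", call. = FALSE)
  structure(list(genome_length = genome_length, position_grid = position_grid,
                 taus = as.numeric(taus), C = C, D = D), class = "scan_config")
}

#' Scan genomic positions of the two toy-pathway genes
#'
#' For every grid pair `(p1, p2)` the enzyme abundances are set to the
#' average copy numbers at the two positions for each division time in
#' `cfg$taus`; the coefficient of variation of `s_ss` across those division
#' times measures how badly homeostasis is broken by that gene arrangement.
#' The CV is exactly zero on the diagonal (`p1 = p2`: the copy-number
#' ratio is division-time invariant) and grows with `|p1 - p2|`.
#'
#' @param tp a [toy_pathway()]; its `E1`, `E2` are replaced by copy numbers.
#' @param cfg a [scan_config()].
#' @return A list of class `position_scan` with the ori-based position grid
#'   `p`, the CV matrix `cv` (rows: `p1`, columns: `p2`) and
#'   `ter_distance = (1 - p) * genome_length` for plotting against distance
#'   from the terminus.
#' @export
position_scan <- function(tp, cfg) {
  stopifnot(inherits(tp, "toy_pathway"), inherits(cfg, "scan_config"))
  p <- seq(0, 1, length.out = cfg$position_grid)
  # copy number per (position, tau)
  ncop <- vapply(cfg$taus, function(tau) {
    average_copy_number(replication_params(cfg$C, cfg$D, tau), p)
  }, numeric(length(p)))                      # grid x taus
  base <- (tp$k1 / tp$k2) * tp$Xin
  np <- length(p)
  cv <- matrix(0, np, np)
  for (i in seq_len(np)) {
    # s_ss across taus for all p2 at once: base * n(p1, tau) / n(p2, tau)
    s <- base * matrix(ncop[i, ], np, length(cfg$taus), byrow = TRUE) / ncop
    mu <- rowMeans(s)
    sdev <- apply(s, 1, stats::sd)
    cv[i, ] <- ifelse(mu > 0, sdev / mu, 0)
  }
  if (length(cfg$taus) == 1L) cv[] <- 0
  structure(list(p = p, cv = cv, ter_distance = (1 - p) * cfg$genome_length,
                 taus = cfg$taus, C = cfg$C, D = cfg$D),
            class = "position_scan")
}

#' Long-format view of a position scan
#'
#' @param x a [position_scan()] result.
#' @param ... unused.
#' @return A data frame with columns `p1`, `p2`, `ter_distance1`,
#'   `ter_distance2` and `cv`.
#' @export
as.data.frame.position_scan <- function(x, ...) {
  grid <- expand.grid(i = seq_along(x$p), j = seq_along(x$p))
  data.frame(p1 = x$p[grid$i], p2 = x$p[grid$j],
             ter_distance1 = x$ter_distance[grid$i],
             ter_distance2 = x$ter_distance[grid$j],
             cv = x$cv[cbind(grid$i, grid$j)])
}
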