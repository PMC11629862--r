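#' Replication parameters of the Helmstetter-Cooper cell-cycle model
#'
#' Bundles the three quantities that govern locus multiplicity in a growing
#' bacterial population: the C period (time to replicate the chromosome), the
#' D period (delay between termination of replication and cell division) and
#' the division time tau. Overlapping replication rounds (mero-oligoploidy)
#' correspond to `C/tau > 1`.
#'
#' @param C DNA replication period, minutes (> 0).
#' @param D post-replication division delay, minutes (>= 0).
#' @param tau division time, minutes (> 0).
#'
#' @return An object of class `replication_params`, a list with elements
#'   `C`, `D` and `tau`.
#' @examples
#' rp <- replication_params(C = 40, D = 20, tau = 60)
#' average_copy_number(rp, p = 0)   # 2 copies at the origin
#' log2_ptr(rp)                     # C / tau
#' @export
replication_params <- function(C, D, tau) {
  stopifnot_scalar_pos(C, "C")
  stopifnot_scalar_pos(D, "D", allow_zero = TRUE)
  stopifnot_scalar_pos(tau, "tau")
  structure(list(C = C, D = D, tau = tau), class = "replication_params")
}

#' @export
print.replication_params <- function(x, ...) {
  cat(sprintf("replication_params: C = %g min, D = %g min, tau = %g min (C/tau = %.3f)\n",
              x$C, x$D, x$tau, x$C / x$tau))
  invisible(x)
}

check_position <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("fractional position `p` must lie in [0, 1] (p = 0 at ori, p = 1 at ter)",
         call. = FALSE)
  }
  p
}

#' Average population copy number of a locus
#'
#' Mean number of copies of a locus at fractional ori-ter position `p` in an
#' exponentially growing population, `n(p) = 2^(((1 - p) C + D) / tau)`.
#' Positions are measured per replichore: `p = 0` at the origin, `p = 1` at
#' the terminus, each chromosome arm mapping independently onto [0, 1].
#'
#' @param params a [replication_params()] object.
#' @param p fractional ori-ter position(s) in [0, 1]; vectorized.
#'
#' @return Numeric vector of average copy numbers (always >= 1 for D >= 0),
#'   strictly decreasing in `p`.
#' @export
average_copy_number <- function(params, p) {
  stopifnot(inherits(params, "replication_params"))
  check_position(p)
  2^(((1 - p) * params$C + params$D) / params$tau)
}

#' log2 origin-to-terminus coverage ratio
#'
#' Under the Helmstetter-Cooper model the log2 of the peak-to-trough coverage
#' ratio (ori:ter) equals `C / tau` exactly, which is what makes sequencing
#' coverage informative about in vivo division times.
#'
#' @param params a [replication_params()] object.
#' @return `C / tau` (dimensionless).
#' @export
log2_ptr <- function(params) {
  stopifnot(inherits(params, "replication_params"))
  params$C / params$tau
}

#' Growth rate from the division time
#'
#' Converts a division time into the specific growth rate `mu = ln(2) / tau`.
#'
#' @param tau division time in minutes.
#' @param unit `"per_hour"` (default) or `"per_minute"`.
#' @return Growth rate in the requested unit.
#' @examples
#' growth_rate(20)   # fast growth, ~2.07 per hour
#' growth_rate(120)  # slow growth, ~0.345 per hour
#' @export
growth_rate <- function(tau, unit = c("per_hour", "per_minute")) {
  unit <- match.arg(unit)
  if (any(tau <= 0)) stop("`tau` must be > 0", call. = FALSE)
  mu <- log(2) / tau
  if (unit == "per_hour") mu * 60 else mu
}

#' Instantaneous (per-cell) copy number with nested replication rounds
#'
#' The single-cell, integer view of locus multiplicity: replication round `i`
#' (oldest first) carries `2^(i-1)` forks per arm, and a locus at position
#' `p` has been copied by every round whose fork has already passed it, so it
#' is present in `2^k` copies where `k` is the number of rounds with progress
#' greater than `p`. With rounds at progress `c(0.9, 0.2)` (three forks in
#' total) an ori-proximal and a ter-proximal locus are in a 4:1 ratio; with a
#' single mid-chromosome fork the ratio is 2:1.
#'
#' @param round_progress numeric vector of fractional fork progress per
#'   active replication round, ordered oldest first and strictly decreasing;
#'   each value in (0, 1). `numeric(0)` means no active replication.
#' @param p fractional locus position in [0, 1].
#'
#' @return Integer copy number `2^k`.
#' @examples
#' instantaneous_copy_number(c(0.9, 0.2), p = 0.05)  # 4
#' instantaneous_copy_number(c(0.9, 0.2), p = 0.95)  # 1
#' @export
instantaneous_copy_number <- function(round_progress, p) {
  check_position(p)
  stopifnot(length(p) == 1L)
  if (length(round_progress) == 0L) return(1L)
  if (!is.numeric(round_progress) || any(round_progress <= 0) || any(round_progress >= 1)) {
    stop("each round progress must lie strictly in (0, 1)", call. = FALSE)
  }
  if (length(round_progress) > 1L && any(diff(round_progress) >= 0)) {
    stop("round progresses must be strictly decreasing (oldest round first); ",
         "a younger round cannot have overtaken an older one", call. = FALSE)
  }
  k <- sum(round_progress > p)
  as.integer(2^k)
}

#' Steady-state transcript abundance of a replicating locus
#'
#' At transcriptional steady state the abundance of a transcript produced at
#' rate `f_y` per gene copy and degraded at rate `gamma` is
#' `n(p) * f_y / gamma`, with `n(p)` the average copy number: gene dosage
#' multiplies promoter output.
#'
#' @param params a [replication_params()] object.
#' @param p fractional locus position(s) in [0, 1].
#' @param f_y promoter output (transcription rate per gene copy, >= 0).
#' @param gamma transcript degradation rate (1/minutes, > 0).
#' @return Steady-state transcript abundance.
#' @export
transcript_steady_state <- function(params, p, f_y, gamma) {
  if (any(f_y < 0)) stop("`f_y` must be >= 0", call. = FALSE)
  if (any(gamma <= 0)) stop("`gamma` must be > 0", call. = FALSE)
  average_copy_number(params, p) * f_y / gamma
}

#' Relative change in enzyme abundance across a change in division time
#'
#' When the division time switches from `tau0` to `tauk`, the steady-state
#' abundance of the enzyme encoded at position `p` changes by
#' \deqn{r = 2^{[(1-p)C + D]\,(\tau_0-\tau_k)/(\tau_k \tau_0)} \cdot
#'   (f_k/f_0) \cdot (\gamma_0/\gamma_k),}
#' the dosage term being the ratio of average copy numbers at the two
#' division times. Faster growth (`tauk < tau0`) raises the dosage of every
#' locus with `p < 1` (and leaves a ter-located locus with `D = 0`
#' unchanged), so `r > 1` in that case when promoters and degradation rates
#' do not change.
#'
#' @param C,D replication period and division delay, minutes.
#' @param p fractional locus position(s) in [0, 1].
#' @param tau0,tauk reference and new division times, minutes.
#' @param f0,fk promoter output in the reference and new condition.
#' @param gamma0,gammak degradation rates in the reference and new condition.
#' @return Fold change(s) `r` (dimensionless).
#' @export
relative_abundance_change <- function(C, D, p, tau0, tauk,
                                      f0 = 1, fk = 1, gamma0 = 1, gammak = 1) {
  stopifnot_scalar_pos(C, "C")
  stopifnot_scalar_pos(D, "D", allow_zero = TRUE)
  stopifnot_scalar_pos(tau0, "tau0")
  stopifnot_scalar_pos(tauk, "tauk")
  check_position(p)
  if (any(f0 <= 0) || any(fk <= 0)) stop("promoter outputs must be > 0", call. = FALSE)
  if (any(gamma0 <= 0) || any(gammak <= 0)) stop("degradation rates must be > 0", call. = FALSE)
  dosage <- 2^(((1 - p) * C + D) * (tau0 - tauk) / (tauk * tau0))
  dosage * (fk / f0) * (gamma0 / gammak)
}
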