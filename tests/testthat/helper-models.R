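# small fixtures built in code

# two-reaction source -> s -> sink chain in linlog form; mirrors the
# mass-action toy pathway qualitatively (s increases with E1/E2)
chain2_model <- function() {
  random_linlog(m = 1, r = 2, seed = 1, jitter = 0)
}

# brute-force single-linkage clustering oracle: grow clusters by repeatedly
# merging the closest pair of clusters while the minimum inter-cluster
# point distance is <= threshold
single_linkage_oracle <- function(x, threshold) {
  clusters <- as.list(seq_along(x))
  repeat {
    if (length(clusters) == 1L) break
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- min(abs(outer(x[clusters[[i]]], x[clusters[[j]]], "-")))
      if (d < bestd) { bestd <- d; best <- c(i, j) }
    }
    if (bestd > threshold) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  clusters
}

# brute-force cluster scanner over a linear target/non-target sequence
# (TRUE = target); returns pure runs (>=2 targets) and mixed stretches
scan_clusters_oracle <- function(is_t) {
  n <- length(is_t)
  pure <- list()
  i <- 1L
  while (i <= n) {
    if (is_t[i]) {
      j <- i
      while (j < n && is_t[j + 1L]) j <- j + 1L
      if (j - i + 1L >= 2L) pure[[length(pure) + 1L]] <- i:j
      i <- j + 1L
    } else i <- i + 1L
  }
  # mixed: all maximal stretches bounded by targets, internal gaps <= 2,
  # containing at least one internal non-target
  mixed <- list()
  tpos <- which(is_t)
  if (length(tpos) >= 2L) {
    start <- tpos[1]; last <- tpos[1]
    flush <- function(start, last) {
      span <- start:last
      if (sum(is_t[span]) >= 2L && any(!is_t[span])) span else NULL
    }
    for (t in tpos[-1]) {
      if (t - last - 1L <= 2L) last <- t
      else {
        if (!is.null(s <- flush(start, last))) mixed[[length(mixed) + 1L]] <- s
        start <- t; last <- t
      }
    }
    if (!is.null(s <- flush(start, last))) mixed[[length(mixed) + 1L]] <- s
  }
  list(pure = pure, mixed = mixed)
}

# hand-built genome arrangement for cluster tests: codes as in the package
# (-1 ori, -2 ter, >0 target, 0 neutral)
make_arrangement <- function(pattern, n_loci = length(pattern) + 2L,
                             ter_at_end = TRUE) {
  # pattern: logical vector (TRUE = target) laid out after ori
  arr <- integer(n_loci)
  arr[1] <- -1L
  body <- ifelse(pattern, 1L, 0L)
  body[pattern] <- seq_len(sum(pattern))
  arr[2:(1 + length(pattern))] <- body
  arr[n_loci] <- -2L
  arr
}
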