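#' Genome annotation with functional-module membership
#'
#' @param genome_length chromosome length in nucleotides.
#' @param genes data frame with columns `id`, `start`, `end` (0-based
#'   half-open coordinates) and `strand` (`"+"`/`"-"`).
#' @param modules named list mapping module id to a character vector of gene
#'   ids; modules with fewer than 2 genes contribute no distances.
#' @param circular whether the chromosome is circular (default `TRUE`).
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome_length, genes, modules, circular = TRUE) {
  stopifnot_scalar_pos(genome_length, "genome_length")
  need <- c("id", "start", "end", "strand")
  if (!all(need %in% names(genes))) {
    stop("`genes` must have columns id, start, end, strand", call. = FALSE)
  }
  if (any(genes$start < 0) || any(genes$end > genome_length) ||
      any(genes$end <= genes$start)) {
    stop("gene coordinates must satisfy 0 <= start < end <= genome_length", call. = FALSE)
  }
  if (anyDuplicated(genes$id)) stop("duplicated gene ids", call. = FALSE)
  missing <- setdiff(unlist(modules), genes$id)
  if (length(missing)) {
    stop("modules reference unknown genes: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  structure(list(genome_length = genome_length, circular = circular,
                 genes = genes, modules = modules),
            class = "genome_annotation")
}

#' Read a genome annotation from BED-like + module-map TSV files
#'
#' @param bed_path TSV with columns chrom, start, end, gene id, strand (no
#'   header, BED order).
#' @param module_path TSV with columns module id, gene id (no header).
#' @param genome_length chromosome length in nucleotides.
#' @param circular whether the chromosome is circular.
#' @return A [genome_annotation()].
#' @export
read_genome_annotation <- function(bed_path, module_path, genome_length,
                                   circular = TRUE) {
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "id", "strand"))
  mm <- utils::read.table(module_path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("module", "gene"))
  genome_annotation(genome_length,
                    genes = bed[, c("id", "start", "end", "strand")],
                    modules = split(mm$gene, mm$module), circular = circular)
}

#' Write a genome annotation to BED-like + module-map TSV files
#'
#' @param ann a [genome_annotation()].
#' @param bed_path,module_path output paths (see [read_genome_annotation()]).
#' @param chrom chromosome name written in the BED column.
#' @return `bed_path`, invisibly.
#' @export
write_genome_annotation <- function(ann, bed_path, module_path, chrom = "chr") {
  stopifnot(inherits(ann, "genome_annotation"))
  bed <- data.frame(chrom = chrom, start = ann$genes$start, end = ann$genes$end,
                    id = ann$genes$id, strand = ann$genes$strand)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  mm <- data.frame(module = rep(names(ann$modules), lengths(ann$modules)),
                   gene = unlist(ann$modules, use.names = FALSE))
  utils::write.table(mm, module_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bed_path)
}

circular_distance <- function(a, b, genome_length, circular = TRUE) {
  d <- abs(a - b)
  if (circular) pmin(d, genome_length - d) else d
}

#' Proximity score of a genome
#'
#' Pools the distances between all unordered pairs of genes within each
#' functional module (modules with >= 2 genes), takes the first quartile Q1
#' of the pooled distances, and returns `PS = log2(1 / Q1) = -log2(Q1)`.
#' Larger PS means functionally related genes sit closer together.
#' Distances are measured between gene midpoints, as the minimum arc on a
#' circular chromosome, and floored at 1 nt so coincident midpoints cannot
#' yield an infinite score. Q1 uses the standard linear-interpolation
#' quantile (R type 7); the dialect is recorded in the output attributes.
#'
#' @param ann a [genome_annotation()].
#' @param anchor `"midpoint"` (default) or `"start"`: the per-gene anchor
#'   between which distances are measured.
#' @return The proximity score (scalar), with attributes `q1`,
#'   `n_distances` and `quantile_type`.
#' @export
proximity_score <- function(ann, anchor = c("midpoint", "start")) {
  stopifnot(inherits(ann, "genome_annotation"))
  anchor <- match.arg(anchor)
  g <- ann$genes
  pos <- if (anchor == "midpoint") (g$start + g$end) / 2 else g$start
  names(pos) <- g$id
  dists <- unlist(lapply(ann$modules, function(ids) {
    if (length(ids) < 2L) return(numeric(0))
    pp <- pos[ids]
    cmb <- utils::combn(length(pp), 2L)
    circular_distance(pp[cmb[1L, ]], pp[cmb[2L, ]], ann$genome_length, ann$circular)
  }), use.names = FALSE)
  if (!length(dists)) {
    stop("proximity score undefined: no module holds >= 2 genes", call. = FALSE)
  }
  q1 <- max(1, stats::quantile(dists, 0.25, names = FALSE, type = 7))
  structure(-log2(q1), q1 = q1, n_distances = length(dists), quantile_type = 7L)
}

#' Coverage profile around the origin and terminus
#'
#' @param ori,ter data frames with columns `position` and `depth` covering
#'   the 50-kb windows centered on the replication origin and terminus.
#' @param window_length window length in nucleotides (default 50000).
#' @return An object of class `coverage_profile`.
#' @export
coverage_profile <- function(ori, ter, window_length = 5e4) {
  for (w in list(ori, ter)) {
    if (!all(c("position", "depth") %in% names(w))) {
      stop("windows need `position` and `depth` columns", call. = FALSE)
    }
    if (any(w$depth < 0)) stop("depth must be nonnegative", call. = FALSE)
  }
  structure(list(ori = ori, ter = ter, window_length = window_length),
            class = "coverage_profile")
}

#' log2 peak-to-trough ratio from coverage windows
#'
#' `log2(mean depth in the ori window / mean depth in the ter window)`.
#' Coverage is deliberately not normalized: only the ratio at the two loci
#' matters. Under the Helmstetter-Cooper model this estimates `C / tau`.
#'
#' @param cov a [coverage_profile()].
#' @return The log2 PTR estimate (scalar).
#' @export
ptr_from_coverage <- function(cov) {
  stopifnot(inherits(cov, "coverage_profile"))
  mo <- mean(cov$ori$depth)
  mt <- mean(cov$ter$depth)
  if (mt <= 0 || mo <= 0) {
    stop("both windows must have positive mean depth", call. = FALSE)
  }
  log2(mo / mt)
}

#' Replication-activity tests on per-library log2 PTR values
#'
#' One-sided one-sample t-tests of mean log2 PTR > 0 (some replication
#' activity, PTR > 1) and > 1 (overlapping replication rounds, PTR > 2),
#' with the 95% confidence interval of the mean. A species is flagged
#' mero-oligoploid when the > 1 test has p <= `alpha`. Species with fewer
#' than `min_libraries` values are excluded with a reason.
#'
#' @param log2ptrs numeric vector of per-library log2 PTR values for one
#'   species.
#' @param min_libraries minimum number of libraries required (default 5).
#' @param alpha significance level for the mero-oligoploid call (default 0.01).
#' @return A one-row data frame with `n`, `mean`, `ci_lower`, `ci_upper`,
#'   `p_gt0`, `p_gt1`, `mero_oligoploid`, `excluded`, `reason`.
#' @export
ptr_tests <- function(log2ptrs, min_libraries = 5L, alpha = 0.01) {
  n <- length(log2ptrs)
  if (n < min_libraries) {
    return(data.frame(n = n, mean = if (n) mean(log2ptrs) else NA_real_,
                      ci_lower = NA_real_, ci_upper = NA_real_,
                      p_gt0 = NA_real_, p_gt1 = NA_real_,
                      mero_oligoploid = NA, excluded = TRUE,
                      reason = sprintf("fewer than %d libraries", min_libraries)))
  }
  if (stats::sd(log2ptrs) == 0) {
    # degenerate: constant values; one-sided decision is exact
    m <- log2ptrs[1]
    return(data.frame(n = n, mean = m, ci_lower = m, ci_upper = m,
                      p_gt0 = if (m > 0) 0 else 1,
                      p_gt1 = if (m > 1) 0 else 1,
                      mero_oligoploid = m > 1, excluded = FALSE, reason = NA_character_))
  }
  t0 <- stats::t.test(log2ptrs, mu = 0, alternative = "greater")
  t1 <- stats::t.test(log2ptrs, mu = 1, alternative = "greater")
  ci <- stats::t.test(log2ptrs)$conf.int
  data.frame(n = n, mean = mean(log2ptrs), ci_lower = ci[1], ci_upper = ci[2],
             p_gt0 = t0$p.value, p_gt1 = t1$p.value,
             mero_oligoploid = t1$p.value <= alpha,
             excluded = FALSE, reason = NA_character_)
}

#' Association between proximity score and log2 PTR across species
#'
#' Ordinary least squares of mean log2 PTR on PS, either per species or
#' after averaging both traits within genera, plus a two-group Welch t-test
#' of PS between mero-oligoploid species and the rest.
#'
#' @param table data frame with columns `species`, `ps`, `log2ptr`, and
#'   optionally `mero_oligoploid` (logical) and `genus`.
#' @param level `"species"` (default) or `"genus"`.
#' @return A list of class `ps_ptr_report`: `fit` (the `lm` object), `slope`,
#'   `slope_p`, `adj_r2`, `n`, and - when the grouping column is present -
#'   `group_test` (the `htest` comparing PS between groups).
#' @export
ps_ptr_association <- function(table, level = c("species", "genus")) {
  level <- match.arg(level)
  need <- c("ps", "log2ptr")
  if (!all(need %in% names(table))) stop("table needs `ps` and `log2ptr` columns", call. = FALSE)
  dat <- table
  if (level == "genus") {
    if (!"genus" %in% names(table)) stop("genus-level model needs a `genus` column", call. = FALSE)
    dat <- do.call(rbind, lapply(split(table, table$genus), function(d) {
      data.frame(genus = d$genus[1], ps = mean(d$ps), log2ptr = mean(d$log2ptr))
    }))
  }
  if (nrow(dat) < 3L) stop("need at least 3 rows for the regression", call. = FALSE)
  if (stats::sd(dat$ps) == 0) stop("degenerate predictor: PS has no variance", call. = FALSE)
  fit <- stats::lm(log2ptr ~ ps, data = dat)
  sm <- summary(fit)
  out <- list(fit = fit, slope = unname(stats::coef(fit)[2]),
              slope_p = sm$coefficients[2, 4], adj_r2 = sm$adj.r.squared,
              n = nrow(dat), level = level)
  if ("mero_oligoploid" %in% names(table) &&
      length(unique(table$mero_oligoploid)) == 2L) {
    out$group_test <- stats::t.test(ps ~ mero_oligoploid, data = table)
  }
  class(out) <- "ps_ptr_report"
  out
}

#' @export
print.ps_ptr_report <- function(x, ...) {
  cat(sprintf("PS ~ log2PTR association (%s level, n = %d): slope = %.4f (p = %.3g), adj R2 = %.3f\n",
              x$level, x$n, x$slope, x$slope_p, x$adj_r2))
  if (!is.null(x$group_test)) {
    cat(sprintf("PS mero-oligoploid vs rest: t-test p = %.3g\n", x$group_test$p.value))
  }
  invisible(x)
}
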