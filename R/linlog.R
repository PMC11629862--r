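#' Construct a linlog metabolic model
#'
#' In the linlog format each reaction rate is the enzyme level times a linear
#' combination of logarithms of metabolite concentrations,
#' `v = E (A' + B' log x + C' log c)`, which admits a closed-form steady
#' state. A model is defined by its stoichiometry, a reference steady state
#' (enzymes `E0`, fluxes `J0`, variable metabolites `x0`, external
#' metabolites `c0`) and elasticity matrices `Bx` (w.r.t. variable
#' metabolites) and `Bc` (w.r.t. external metabolites). Elasticities are
#' fixed parameters here, a stated limitation of the format: substrate and
#' product dependencies are assumed constant across growth conditions.
#'
#' @param N stoichiometry matrix, m metabolites x r reactions.
#' @param E0 reference enzyme abundances (length r, > 0).
#' @param J0 reference steady-state fluxes (length r) with `N %*% J0 = 0`.
#' @param x0 reference variable-metabolite concentrations (length m, > 0).
#' @param c0 external-metabolite concentrations (> 0).
#' @param Bx elasticities w.r.t. variable metabolites, r x m.
#' @param Bc elasticities w.r.t. external metabolites, r x length(c0).
#' @param metabolites,reactions,externals optional name vectors; taken from
#'   dimnames when missing.
#' @param output_reaction name or index of the reaction whose flux is treated
#'   as "the pathway flux" by default in control analyses; defaults to the
#'   last reaction.
#'
#' @return An object of class `linlog_model`.
#' @seealso [derive_parameters()], [linlog_rates()], [linlog_steady_state()]
#' @export
linlog_model <- function(N, E0, J0, x0, c0, Bx, Bc,
                         metabolites = NULL, reactions = NULL,
                         externals = NULL, output_reaction = NULL) {
  N <- as.matrix(N)
  Bx <- as.matrix(Bx)
  Bc <- as.matrix(Bc)
  m <- nrow(N); r <- ncol(N)
  if (is.null(metabolites)) metabolites <- rownames(N) %||% paste0("x", seq_len(m))
  if (is.null(reactions))  reactions  <- colnames(N) %||% paste0("v", seq_len(r))
  if (is.null(externals))  externals  <- names(c0)   %||% paste0("c", seq_along(c0))
  if (length(E0) != r || length(J0) != r) stop("E0 and J0 must have one entry per reaction", call. = FALSE)
  if (length(x0) != m) stop("x0 must have one entry per variable metabolite", call. = FALSE)
  if (!all(dim(Bx) == c(r, m))) stop("Bx must be r x m", call. = FALSE)
  if (!all(dim(Bc) == c(r, length(c0)))) stop("Bc must be r x n_ext", call. = FALSE)
  if (any(E0 <= 0) || any(x0 <= 0) || any(c0 <= 0)) {
    stop("reference enzyme and metabolite levels must be strictly positive", call. = FALSE)
  }
  resid <- max(abs(N %*% J0))
  if (resid > 1e-8 * max(1, max(abs(J0)))) {
    stop(sprintf("reference fluxes are not at steady state: max |N J0| = %g", resid),
         call. = FALSE)
  }
  if (is.null(output_reaction)) output_reaction <- reactions[r]
  if (is.numeric(output_reaction)) output_reaction <- reactions[output_reaction]
  if (!output_reaction %in% reactions) stop("unknown `output_reaction`", call. = FALSE)
  dimnames(N) <- list(metabolites, reactions)
  dimnames(Bx) <- list(reactions, metabolites)
  dimnames(Bc) <- list(reactions, externals)
  structure(list(N = N, E0 = stats::setNames(as.numeric(E0), reactions),
                 J0 = stats::setNames(as.numeric(J0), reactions),
                 x0 = stats::setNames(as.numeric(x0), metabolites),
                 c0 = stats::setNames(as.numeric(c0), externals),
                 Bx = Bx, Bc = Bc,
                 metabolites = metabolites, reactions = reactions,
                 externals = externals, output_reaction = output_reaction),
            class = "linlog_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.linlog_model <- function(x, ...) {
  cat(sprintf("linlog_model: %d reactions, %d variable metabolites, %d external (%s)\n",
              length(x$reactions), length(x$metabolites), length(x$externals),
              paste(x$externals, collapse = ", ")))
  cat(sprintf("output reaction: %s\n", x$output_reaction))
  invisible(x)
}

#' Derive the absolute-quantity linlog parameters from the reference state
#'
#' Folds the reference state into the rate-law parameters so rates can be
#' evaluated with absolute quantities:
#' `A' = (J0/E0) (1 - Bx log x0 - Bc log c0)`, `B' = (J0/E0) Bx` and
#' `C' = (J0/E0) Bc` (row-wise scaling, natural logarithms). By construction,
#' evaluating the rates at the reference state returns `J0` exactly.
#'
#' @param model a [linlog_model()].
#' @return A list of class `linlog_params` with `Ap` (length r), `Bp`
#'   (r x m) and `Cp` (r x n_ext).
#' @export
derive_parameters <- function(model) {
  stopifnot(inherits(model, "linlog_model"))
  scl <- model$J0 / model$E0
  Ap <- scl * as.numeric(1 - model$Bx %*% log(model$x0) - model$Bc %*% log(model$c0))
  Bp <- model$Bx * scl   # row-wise: scl recycles down columns of an r x m matrix
  Cp <- model$Bc * scl
  structure(list(Ap = stats::setNames(Ap, model$reactions), Bp = Bp, Cp = Cp),
            class = "linlog_params")
}

#' Evaluate linlog reaction rates
#'
#' `v_i = E_i (A'_i + sum_j B'_ij log x_j + sum_k C'_ik log c_k)`.
#'
#' @param model a [linlog_model()].
#' @param params matching [derive_parameters()] output; recomputed if `NULL`.
#' @param E enzyme abundances (length r, >= 0); defaults to `E0`.
#' @param x variable-metabolite concentrations (length m, > 0); defaults to `x0`.
#' @param c external-metabolite concentrations (> 0); defaults to `c0`.
#' @return Flux vector of length r.
#' @export
linlog_rates <- function(model, params = NULL, E = model$E0, x = model$x0,
                         c = model$c0) {
  stopifnot(inherits(model, "linlog_model"))
  if (is.null(params)) params <- derive_parameters(model)
  if (any(x <= 0) || any(c <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (any(E < 0)) stop("enzyme abundances must be >= 0", call. = FALSE)
  as.numeric(E * (params$Ap + params$Bp %*% log(x) + params$Cp %*% log(c)))
}

#' Analytic linlog steady state
#'
#' Solves `N v = 0` for the variable metabolites:
#' `log x = -(N E B')^{-1} (N E A' + N E C' log c)`, with `E` entering as a
#' diagonal matrix. Uniformly scaling all enzymes (`E = r * E0`) leaves the
#' steady-state concentrations unchanged and scales all fluxes by `r` -
#' perfect homeostasis under a coordinate change, the algebraic reason why
#' co-located genes buffer division-time changes.
#'
#' @inheritParams linlog_rates
#' @param check if `TRUE`, verify the steady-state residual `N v(x_ss)`.
#' @return Named vector of steady-state concentrations `x_ss`.
#'   Throws a classed error (`replimet_singular_error`) if `N E B'` is
#'   numerically singular; callers that optimize or evolve treat that as a
#'   lethal/invalid phenotype rather than aborting.
#' @export
linlog_steady_state <- function(model, params = NULL, E = model$E0,
                                c = model$c0, check = FALSE) {
  stopifnot(inherits(model, "linlog_model"))
  if (is.null(params)) params <- derive_parameters(model)
  if (any(E <= 0)) stop("steady state requires strictly positive enzyme levels", call. = FALSE)
  if (any(c <= 0)) stop("external concentrations must be > 0", call. = FALSE)
  a_eff <- params$Ap + as.numeric(params$Cp %*% log(c))
  M <- model$N %*% (params$Bp * E)          # N diag(E) B'
  rhs <- as.numeric(model$N %*% (E * a_eff))
  logx <- tryCatch(-solve(M, rhs), error = function(e) NULL)
  if (is.null(logx) || anyNA(logx) || any(!is.finite(logx))) {
    singular_steady_state_error()
  }
  x_ss <- stats::setNames(exp(as.numeric(logx)), model$metabolites)
  if (check) {
    v <- linlog_rates(model, params, E = E, x = x_ss, c = c)
    resid <- max(abs(model$N %*% v)) / max(1, max(abs(v)))
    if (resid > 1e-8) singular_steady_state_error(
      sprintf("steady-state residual too large (%g)", resid))
  }
  x_ss
}

# --- model IO -----------------------------------------------------------

#' Write a linlog model to disk
#'
#' Two bit-equivalent dialects: a single JSON document (`format = "json"`)
#' or three TSV tables sharing a path prefix (`<prefix>_reactions.tsv`,
#' `<prefix>_state.tsv`, `<prefix>_elasticities.tsv`). The reactions table
#' holds the stoichiometry in sparse triplet form; the state table the
#' reference condition; the elasticities table all nonzero entries of `Bx`
#' and `Bc` (external metabolites flagged).
#'
#' @param model a [linlog_model()].
#' @param path output file (json) or path prefix (tsv).
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_linlog_model <- function(model, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(model, "linlog_model"))
  stoich <- which(model$N != 0, arr.ind = TRUE)
  stoich_df <- data.frame(
    reaction = model$reactions[stoich[, 2]],
    metabolite = model$metabolites[stoich[, 1]],
    coefficient = model$N[stoich],
    stringsAsFactors = FALSE)
  ex <- which(model$Bx != 0, arr.ind = TRUE)
  ec <- which(model$Bc != 0, arr.ind = TRUE)
  elas_df <- rbind(
    data.frame(reaction = model$reactions[ex[, 1]],
               metabolite = model$metabolites[ex[, 2]],
               external = FALSE, value = model$Bx[ex], stringsAsFactors = FALSE),
    data.frame(reaction = model$reactions[ec[, 1]],
               metabolite = model$externals[ec[, 2]],
               external = TRUE, value = model$Bc[ec], stringsAsFactors = FALSE))
  state_df <- rbind(
    data.frame(kind = "reaction", name = model$reactions,
               E0 = model$E0, J0 = model$J0, x0 = NA_real_, stringsAsFactors = FALSE),
    data.frame(kind = "metabolite", name = model$metabolites,
               E0 = NA_real_, J0 = NA_real_, x0 = model$x0, stringsAsFactors = FALSE),
    data.frame(kind = "external", name = model$externals,
               E0 = NA_real_, J0 = NA_real_, x0 = model$c0, stringsAsFactors = FALSE))
  if (format == "json") {
    doc <- list(metabolites = model$metabolites, reactions = model$reactions,
                externals = model$externals, output_reaction = model$output_reaction,
                stoichiometry = stoich_df, state = state_df, elasticities = elas_df)
    jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  } else {
    utils::write.table(stoich_df, paste0(path, "_reactions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(state_df, paste0(path, "_state.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cbind(elas_df,
                             output_reaction = c(model$output_reaction,
                                                 rep(NA, nrow(elas_df) - 1L))),
                       paste0(path, "_elasticities.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a linlog model from disk
#'
#' Counterpart of [write_linlog_model()]; validates every model invariant
#' (dimensions, positivity, `N J0 = 0`) and fails with a descriptive error
#' on violation.
#'
#' @param path JSON file or TSV path prefix.
#' @param format `"json"` or `"tsv"`.
#' @return A validated [linlog_model()].
#' @export
read_linlog_model <- function(path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    stoich_df <- doc$stoichiometry; state_df <- doc$state; elas_df <- doc$elasticities
    metab <- doc$metabolites; rxns <- doc$reactions; exts <- doc$externals
    out_rxn <- doc$output_reaction
  } else {
    stoich_df <- utils::read.table(paste0(path, "_reactions.tsv"), sep = "\t",
                                   header = TRUE, stringsAsFactors = FALSE)
    state_df <- utils::read.table(paste0(path, "_state.tsv"), sep = "\t",
                                  header = TRUE, stringsAsFactors = FALSE)
    elas_df <- utils::read.table(paste0(path, "_elasticities.tsv"), sep = "\t",
                                 header = TRUE, stringsAsFactors = FALSE)
    out_rxn <- elas_df$output_reaction[1]
    elas_df$output_reaction <- NULL
    metab <- state_df$name[state_df$kind == "metabolite"]
    rxns <- state_df$name[state_df$kind == "reaction"]
    exts <- state_df$name[state_df$kind == "external"]
  }
  m <- length(metab); r <- length(rxns)
  if (m == 0L || r == 0L) stop("model file lists no metabolites or no reactions", call. = FALSE)
  bad <- setdiff(unique(stoich_df$metabolite), metab)
  if (length(bad)) stop("stoichiometry references unknown metabolites: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  N <- matrix(0, m, r, dimnames = list(metab, rxns))
  N[cbind(match(stoich_df$metabolite, metab), match(stoich_df$reaction, rxns))] <-
    stoich_df$coefficient
  rstate <- state_df[state_df$kind == "reaction", ]
  mstate <- state_df[state_df$kind == "metabolite", ]
  estate <- state_df[state_df$kind == "external", ]
  E0 <- rstate$E0[match(rxns, rstate$name)]
  J0 <- rstate$J0[match(rxns, rstate$name)]
  x0 <- mstate$x0[match(metab, mstate$name)]
  c0 <- stats::setNames(estate$x0[match(exts, estate$name)], exts)
  Bx <- matrix(0, r, m, dimnames = list(rxns, metab))
  Bc <- matrix(0, r, length(exts), dimnames = list(rxns, exts))
  ev <- elas_df[!elas_df$external, ]
  ee <- elas_df[elas_df$external, ]
  Bx[cbind(match(ev$reaction, rxns), match(ev$metabolite, metab))] <- ev$value
  if (nrow(ee)) Bc[cbind(match(ee$reaction, rxns), match(ee$metabolite, exts))] <- ee$value
  linlog_model(N, E0, J0, x0, c0, Bx, Bc, metabolites = metab, reactions = rxns,
               externals = exts, output_reaction = out_rxn)
}
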