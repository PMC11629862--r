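#' Central-carbon linlog benchmark model
#'
#' A deterministic, code-generated linlog model of E. coli carbon
#' metabolism - glycolysis, pentose-phosphate pathway, TCA cycle, glyoxylate
#' shunt and acetate excretion/import - sized at exactly 34 enzymatic
#' reactions, 26 variable metabolites and 2 external metabolites (glucose
#' and acetate). The model is a synthetic benchmark: its topology is the
#' textbook network, the reference state is normalized (`E0 = 1`, `x0 = 1`,
#' `c0 = 1`), elasticities are +1 for substrates and -1 for products, and
#' `J0` is a hand-balanced strictly positive flux vector in the null space
#' of the stoichiometry (glucose uptake 10, split 7:3 between glycolysis and
#' the oxidative PPP, glyoxylate shunt carrying 2, acetate overflow 4 with
#' an import flux of 1, biosynthetic drains on R5P and AKG). It is meant for
#' probing systemic responses to enzyme-level perturbations, not for
#' quantitative comparison with measured metabolite levels.
#'
#' @param jitter optional standard deviation of multiplicative log-normal
#'   jitter applied to the nonzero elasticities (default 0 = the
#'   deterministic fixture); used to generate perturbed variants.
#' @param seed RNG seed used only when `jitter > 0`.
#'
#' @return A [linlog_model()] with 34 reactions and 26 variable metabolites;
#'   its default output reaction is pyruvate kinase (`pyk`).
#' @examples
#' mod <- carbon_fixture()
#' length(mod$reactions)    # 34
#' length(mod$metabolites)  # 26
#' @export
carbon_fixture <- function(jitter = 0, seed = NULL) {
  mets <- c("g6p", "f6p", "fbp", "dhap", "gap", "pg3", "pg2", "pep", "pyr",
            "accoa", "pgl", "pgc", "ru5p", "x5p", "r5p", "s7p", "e4p",
            "cit", "icit", "akg", "succoa", "suc", "fum", "mal", "oaa", "glx")
  exts <- c("glucose", "acetate")
  # reaction list: name, substrates (variable), products (variable),
  # external substrate / product, reference flux
  rxn <- list(
    list("pts",   character(), "g6p",            "glucose", NA,        10),
    list("pgi",   "g6p",       "f6p",            NA, NA,               7),
    list("pfk",   "f6p",       "fbp",            NA, NA,               8),
    list("fba",   "fbp",       c("dhap", "gap"), NA, NA,               8),
    list("tpi",   "dhap",      "gap",            NA, NA,               8),
    list("gapA",  "gap",       "pg3",            NA, NA,               16.5),
    list("gpm",   "pg3",       "pg2",            NA, NA,               16.5),
    list("eno",   "pg2",       "pep",            NA, NA,               16.5),
    list("pyk",   "pep",       "pyr",            NA, NA,               15.5),
    list("pdh",   "pyr",       "accoa",          NA, NA,               15.5),
    list("zwf",   "g6p",       "pgl",            NA, NA,               3),
    list("pgl",   "pgl",       "pgc",            NA, NA,               3),
    list("gnd",   "pgc",       "ru5p",           NA, NA,               3),
    list("rpe",   "ru5p",      "x5p",            NA, NA,               1),
    list("rpi",   "ru5p",      "r5p",            NA, NA,               2),
    list("tktA",  c("x5p", "r5p"), c("s7p", "gap"), NA, NA,            0.5),
    list("tal",   c("s7p", "gap"), c("e4p", "f6p"), NA, NA,            0.5),
    list("tktB",  c("x5p", "e4p"), c("f6p", "gap"), NA, NA,            0.5),
    list("gltA",  c("accoa", "oaa"), "cit",      NA, NA,               10.5),
    list("acn",   "cit",       "icit",           NA, NA,               10.5),
    list("icd",   "icit",      "akg",            NA, NA,               8.5),
    list("sucAB", "akg",       "succoa",         NA, NA,               5.5),
    list("sucCD", "succoa",    "suc",            NA, NA,               5.5),
    list("sdh",   "suc",       "fum",            NA, NA,               7.5),
    list("fumC",  "fum",       "mal",            NA, NA,               7.5),
    list("mdh",   "mal",       "oaa",            NA, NA,               9.5),
    list("aceA",  "icit",      c("glx", "suc"),  NA, NA,               2),
    list("aceB",  c("glx", "accoa"), "mal",      NA, NA,               2),
    list("ppc",   "pep",       "oaa",            NA, NA,               2),
    list("pck",   "oaa",       "pep",            NA, NA,               1),
    list("pta",   "accoa",     character(),      NA, "acetate",        4),
    list("acs",   character(), "accoa",          "acetate", NA,        1),
    list("prs",   "r5p",       character(),      NA, NA,               1.5),
    list("akgDM", "akg",       character(),      NA, NA,               3)
  )
  r <- length(rxn); m <- length(mets)
  rxn_names <- vapply(rxn, `[[`, "", 1)
  N <- matrix(0, m, r, dimnames = list(mets, rxn_names))
  Bx <- matrix(0, r, m, dimnames = list(rxn_names, mets))
  Bc <- matrix(0, r, 2, dimnames = list(rxn_names, exts))
  J0 <- numeric(r)
  for (i in seq_len(r)) {
    subs <- rxn[[i]][[2]]; prods <- rxn[[i]][[3]]
    ext_s <- rxn[[i]][[4]]; ext_p <- rxn[[i]][[5]]
    N[subs, i] <- N[subs, i] - 1
    N[prods, i] <- N[prods, i] + 1
    Bx[i, subs] <- 1
    Bx[i, prods] <- -1
    if (!is.na(ext_s)) Bc[i, ext_s] <- 1
    if (!is.na(ext_p)) Bc[i, ext_p] <- -1
    J0[i] <- rxn[[i]][[6]]
  }
  if (jitter > 0) {
    with_seed(seed, {
      Bx[Bx != 0] <- Bx[Bx != 0] * exp(stats::rnorm(sum(Bx != 0), 0, jitter))
      Bc[Bc != 0] <- Bc[Bc != 0] * exp(stats::rnorm(sum(Bc != 0), 0, jitter))
    })
  }
  linlog_model(N, E0 = rep(1, r), J0 = J0, x0 = rep(1, m),
               c0 = stats::setNames(c(1, 1), exts), Bx = Bx, Bc = Bc,
               metabolites = mets, reactions = rxn_names, externals = exts,
               output_reaction = "pyk")
}
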