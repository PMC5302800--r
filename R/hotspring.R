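## Reduced three-guild hot-spring mat community (synthetic reconstruction).
##
## Guild physiology is summarized by three community-level budgets -- light
## energy, carbon and nitrogen -- with per-growth quotas chosen so that (i)
## every guild's solo FBA optimum is exactly 1 h^-1 and (ii) the community
## Pareto front carries the five-vertex trade-off structure characteristic of
## this mat ecosystem.  The quotas are exact rationals; see the vignette for
## their derivation from the front geometry.

.hsQuota <- list(
  energy = c(SYN = 1, FAP = 1, SRB = 73 / 89),
  nitrogen = c(SYN = 1694 / 1755, FAP = 1, SRB = 54 / 65),
  carbon = c(SYN = 11 / 27, FAP = 35 / 46, SRB = 1),
  nitrateReductionPerPhoton = 0.5,
  oxygenaseRatio = 0.03)

#' Build the reduced hot-spring mat community model
#'
#' Constructs the three-guild model (SYN, FAP, SRB) and its thermodynamic
#' table in code.  \code{\link{loadHotSpringFixture}} reads the same model
#' from the packaged fixture files; the two agree field for field.
#'
#' SYN is an oxygenic photoautotroph: it captures photons, fixes CO2 through
#' Rubisco (with the oxygenase side reaction RXN-961 pinned at a 0.03 flux
#' ratio, producing glycolate), reduces nitrate in fixed proportion to its
#' photon flux (so ammonia not used for growth is exported to the pool), and
#' can divert photosynthate to acetate exported to the pool.  FAP is a
#' phototrophic carbon fixer that takes ammonia, acetate and glycolate from
#' the pool.  SRB is a heterotrophic sulfate reducer growing on pool acetate
#' and ammonia, exporting sulfide.  Light, total nitrogen and total carbon
#' exchanged with the environment are capped at one unit each.
#'
#' @return list with \code{community} and \code{thermo}.
#' @export
makeHotSpringCommunity <- function() {
  q <- .hsQuota
  eR <- q$energy[["SRB"]]
  strainS <- function(id, mets, external, rxns, stoich) {
    S <- Matrix::Matrix(0, length(mets), nrow(rxns), sparse = TRUE,
                        dimnames = list(mets, rxns$id))
    for (tr in stoich) S[tr[[1]], tr[[2]]] <- as.numeric(tr[[3]])
    StrainModel(id = id,
                mets = data.frame(id = mets, external = mets %in% external),
                rxns = rxns, S = S)
  }

  syn <- strainS(
    "SYN",
    mets = c("ph", "chx", "nh3i", "hv", "h2o", "co2", "no3", "nh3", "ac", "glyc"),
    external = c("hv", "h2o", "co2", "no3", "nh3", "ac", "glyc"),
    rxns = data.frame(
      id = c("PSII", "RIBULOSE-BISPHOSPHATE-CARBOXYLASE-RXN", "RXN-961",
             "NAR", "AMT", "ACS", "BIO_SYN",
             "EX_hv", "EX_h2o", "EX_co2", "EX_no3", "EX_nh3", "EX_ac", "EX_glyc"),
      lb = c(0, 0, 0, 0, -1000, 0, 0, -1, -1000, -2, -10, -10, 0, 0),
      ub = c(1000, 1000, 1000, 1000, 1000, 1000, 1000, 0, 1000, 1000, 1000, 1000, 1000, 1000),
      kind = c(rep("internal", 6), "biomass", rep("exchange", 7))),
    stoich = list(
      list("hv", "PSII", -1), list("h2o", "PSII", -1), list("ph", "PSII", 1),
      list("co2", "RIBULOSE-BISPHOSPHATE-CARBOXYLASE-RXN", -1),
      list("chx", "RIBULOSE-BISPHOSPHATE-CARBOXYLASE-RXN", 1),
      list("chx", "RXN-961", -1), list("glyc", "RXN-961", 1),
      list("no3", "NAR", -1), list("nh3i", "NAR", 1),
      list("nh3", "AMT", -1), list("nh3i", "AMT", 1),
      list("ph", "ACS", -eR), list("chx", "ACS", -1), list("ac", "ACS", 1),
      list("ph", "BIO_SYN", -1), list("chx", "BIO_SYN", -q$carbon[["SYN"]]),
      list("nh3i", "BIO_SYN", -q$nitrogen[["SYN"]]),
      list("hv", "EX_hv", -1), list("h2o", "EX_h2o", -1),
      list("co2", "EX_co2", -1), list("no3", "EX_no3", -1),
      list("nh3", "EX_nh3", -1), list("ac", "EX_ac", -1),
      list("glyc", "EX_glyc", -1)))

  fap <- strainS(
    "FAP",
    mets = c("ph", "chx", "hv", "co2", "nh3", "ac", "glyc"),
    external = c("hv", "co2", "nh3", "ac", "glyc"),
    rxns = data.frame(
      id = c("PSB", "CFX", "ACU", "GLU", "RSP", "BIO_FAP",
             "EX_hv", "EX_co2", "EX_nh3", "EX_ac", "EX_glyc"),
      lb = c(0, 0, 0, -1000, 0, 0, -1, -2, -10, -2, -10),
      ub = c(1000, 1000, 1000, 1000, 1000, 1000, 0, 1000, 0, 0, 1000),
      kind = c(rep("internal", 5), "biomass", rep("exchange", 5))),
    stoich = list(
      list("hv", "PSB", -1), list("ph", "PSB", 1),
      list("co2", "CFX", -1), list("chx", "CFX", 1),
      list("ac", "ACU", -1), list("chx", "ACU", 1),
      list("glyc", "GLU", -1), list("chx", "GLU", 1),
      list("chx", "RSP", -1), list("co2", "RSP", 1),
      list("ph", "BIO_FAP", -1), list("chx", "BIO_FAP", -q$carbon[["FAP"]]),
      list("nh3", "BIO_FAP", -q$nitrogen[["FAP"]]),
      list("hv", "EX_hv", -1), list("co2", "EX_co2", -1),
      list("nh3", "EX_nh3", -1), list("ac", "EX_ac", -1),
      list("glyc", "EX_glyc", -1)))

  srb <- strainS(
    "SRB",
    mets = c("ac", "nh3", "so4", "h2s"),
    external = c("ac", "nh3", "so4", "h2s"),
    rxns = data.frame(
      id = c("BIO_SRB", "EX_ac", "EX_nh3", "EX_so4", "EX_h2s"),
      lb = c(0, -1, -10, -10, 0),
      ub = c(1000, 0, 0, 0, 1000),
      kind = c("biomass", rep("exchange", 4))),
    stoich = list(
      list("ac", "BIO_SRB", -1), list("nh3", "BIO_SRB", -q$nitrogen[["SRB"]]),
      list("so4", "BIO_SRB", -0.5), list("h2s", "BIO_SRB", 0.5),
      list("ac", "EX_ac", -1), list("nh3", "EX_nh3", -1),
      list("so4", "EX_so4", -1), list("h2s", "EX_h2s", -1)))

  pool <- poolSpec(
    c("hv", "h2o", "co2", "no3", "nh3", "ac", "glyc", "so4", "h2s"),
    data.frame(met = c("hv", "h2o", "co2", "no3", "nh3", "ac", "glyc", "so4", "h2s"),
               lb = c(-1, -1000, -2, -10, -10, 0, 0, -10, 0),
               ub = c(0, 1000, 1000, 0, 1000, 1000, 1000, 1000, 1000)))

  couplings <- list(
    list(terms = data.frame(strain = "SYN",
                            rxn = c("RXN-961", "RIBULOSE-BISPHOSPHATE-CARBOXYLASE-RXN"),
                            coef = c(1, -q$oxygenaseRatio)),
         relation = "eq", rhs = 0),
    list(terms = data.frame(strain = "SYN", rxn = c("NAR", "PSII"),
                            coef = c(1, -q$nitrateReductionPerPhoton)),
         relation = "eq", rhs = 0),
    ## total nitrogen exchanged with the environment (net uptake <= 1)
    list(terms = data.frame(strain = ".pool", rxn = c("EX_no3", "EX_nh3"),
                            coef = c(1, 1)),
         relation = "ge", rhs = -1),
    ## total carbon exchanged with the environment (net uptake <= 1)
    list(terms = data.frame(strain = ".pool", rxn = c("EX_co2", "EX_ac", "EX_glyc"),
                            coef = c(1, 1, 1)),
         relation = "ge", rhs = -1))

  community <- assembleCommunity(list(syn, fap, srb), pool, couplings)

  dg <- computeDg(348.15, 1e3)
  thermo <- new("ThermoTable", temperature = 348.15, entries = data.frame(
    metabolite = c("hv", "h2o", "co2", "no3", "nh3", "ac", "glyc", "so4", "h2s", "glc"),
    mu0 = c(68.6, 0, -25, -20, -30, 50, 40, -40, 20, 3142.8),
    dg = c(0, 0, rep(dg, 8)),
    stringsAsFactors = FALSE))
  list(community = community, thermo = thermo)
}
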