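## Chemical-potential bookkeeping and chemical-motive-force maximization.
##
## The chemical motive force cmf = sum_i mu_i v_i is taken over the
## pool-to-environment boundary fluxes, oriented so that uptake from the
## environment is positive ("consumption of external chemical potential
## drives the internal fluxes").  Within MO-FVA flux ranges [a_i, b_i] and
## potential boxes mu0_i +/- dg_i the problem is separable per metabolite, so
## the exact maximum is attained at an interval corner; a box-constrained
## quasi-Newton optimizer is kept as a numerical cross-check.

R_GAS <- 8.314  # J mol^-1 K^-1

#' Chemical-potential half-width from a concentration range
#'
#' \code{dg = R T ln(ratio)} in kJ/mol, the half-width of the chemical
#' potential interval when the metabolite concentration may vary by the
#' factor \code{ratio} around its reference.
#'
#' @param temperatureK temperature in kelvin (> 0).
#' @param concRatio ratio of highest to reference concentration (> 0).
#' @return kJ/mol.
#' @examples
#' computeDg(348.15, 1e3)  # about 20 kJ/mol at 75 degrees Celsius
#' @export
computeDg <- function(temperatureK, concRatio) {
  if (!is.numeric(temperatureK) || temperatureK <= 0)
    stop("temperature must be positive (kelvin)")
  if (!is.numeric(concRatio) || concRatio <= 0)
    stop("concentration ratio must be positive")
  R_GAS * temperatureK * log(concRatio) / 1000
}

#' Photon chemical potential from a reference synthesis reaction
#'
#' Solves \code{Delta mu = 0} for the photon potential of a photon-driven
#' synthesis reaction: with stoichiometry \code{S} over the non-photon
#' species (reactants negative, products positive) and \code{n} photons
#' consumed, \code{mu_hv = sum(S_i mu0_i) / n}.  The default reaction is
#' glucose synthesis from CO2 and water driven by 48 photons.
#'
#' @param thermo a \linkS4class{ThermoTable} supplying \code{mu0} for every
#'   non-photon participant.
#' @param stoich named numeric vector of non-photon stoichiometric
#'   coefficients.
#' @param nPhotons number of photons consumed (> 0).
#' @return the photon potential, kJ/mol.
#' @export
photonPotential <- function(thermo,
                            stoich = c(co2 = -6, h2o = -6, glc = 1),
                            nPhotons = 48) {
  stopifnot(is(thermo, "ThermoTable"), nPhotons > 0)
  i <- match(names(stoich), thermo@entries$metabolite)
  if (anyNA(i))
    stop("no standard chemical potential for metabolite(s): ",
         paste(names(stoich)[is.na(i)], collapse = ", "))
  mu0 <- thermo@entries$mu0[i]
  sum(stoich * mu0) / nPhotons
}

#' Maximize the chemical motive force over flux and potential boxes
#'
#' Maximizes \code{sum_i mu_i v_i} subject to \code{a_i <= v_i <= b_i} (the
#' MO-FVA exchange-flux ranges, uptake positive) and
#' \code{mu0_i - dg_i <= mu_i <= mu0_i + dg_i}.  The problem separates per
#' metabolite; \code{method = "corner"} evaluates the four products of
#' interval endpoints exactly, \code{method = "numeric"} runs a
#' box-constrained quasi-Newton ascent (L-BFGS-B) per metabolite from the
#' interval corners and midpoint.
#'
#' @param ranges a \linkS4class{FluxRangeSet} over boundary fluxes whose
#'   \code{reaction} labels name the exchanged metabolites, or a data.frame
#'   with columns \code{reaction}, \code{vmin}, \code{vmax}.
#' @param thermo a \linkS4class{ThermoTable} covering every metabolite.
#' @param method \code{"corner"} (exact, default) or \code{"numeric"}.
#' @return a \linkS4class{CmfResult}.
#' @examples
#' tt <- new("ThermoTable",
#'           entries = data.frame(metabolite = "m", mu0 = 10, dg = 20),
#'           temperature = 348.15)
#' rng <- data.frame(reaction = "m", vmin = -2, vmax = 3)
#' maximizeCmf(rng, tt)  # cmf = 90 at v = 3, mu = 30
#' @export
maximizeCmf <- function(ranges, thermo, method = c("corner", "numeric")) {
  method <- match.arg(method)
  stopifnot(is(thermo, "ThermoTable"))
  rg <- if (is(ranges, "FluxRangeSet")) ranges@ranges else as.data.frame(ranges)
  stopifnot(all(c("reaction", "vmin", "vmax") %in% names(rg)))
  if (any(!is.finite(rg$vmin)) || any(!is.finite(rg$vmax)))
    stop("infinite flux bounds: the chemical motive force would be unbounded")
  i <- match(rg$reaction, thermo@entries$metabolite)
  if (anyNA(i))
    stop("no thermodynamic entry for metabolite(s): ",
         paste(rg$reaction[is.na(i)], collapse = ", "))
  mu_lo <- thermo@entries$mu0[i] - thermo@entries$dg[i]
  mu_hi <- thermo@entries$mu0[i] + thermo@entries$dg[i]
  n <- nrow(rg)
  mu_opt <- v_opt <- numeric(n)
  for (q in seq_len(n)) {
    vs <- c(rg$vmin[q], rg$vmax[q])
    ms <- c(mu_lo[q], mu_hi[q])
    if (method == "corner") {
      corners <- expand.grid(v = vs, mu = ms)
      prods <- corners$v * corners$mu
      best <- which.max(prods)
      v_opt[q] <- corners$v[best]; mu_opt[q] <- corners$mu[best]
    } else {
      f <- function(x) -(x[1] * x[2])
      g <- function(x) c(-x[2], -x[1])
      starts <- rbind(expand.grid(v = vs, mu = ms),
                      data.frame(v = mean(vs), mu = mean(ms)))
      best <- -Inf
      for (s in seq_len(nrow(starts))) {
        o <- optim(as.numeric(starts[s, ]), f, g, method = "L-BFGS-B",
                   lower = c(vs[1], ms[1]), upper = c(vs[2], ms[2]))
        if (-o$value > best) {
          best <- -o$value; v_opt[q] <- o$par[1]; mu_opt[q] <- o$par[2]
        }
      }
    }
  }
  new("CmfResult", cmf = sum(mu_opt * v_opt),
      mu = setNames(mu_opt, rg$reaction), v = setNames(v_opt, rg$reaction),
      method = method)
}

#' Chemical motive force over a Pareto-front mesh
#'
#' For each mesh point, runs MO-FVA restricted to the pool-to-environment
#' exchange reactions, flips the ranges to the uptake-positive orientation,
#' and maximizes the chemical motive force over the resulting boxes.
#'
#' @param model a \linkS4class{CommunityModel}.
#' @param mesh a \linkS4class{ParetoMesh}.
#' @param thermo a \linkS4class{ThermoTable} covering the pool metabolites.
#' @param alpha fraction of the optimum for the MO-FVA floors.
#' @param method passed to \code{\link{maximizeCmf}}.
#' @return data.frame with the barycentric coordinates and \code{cmf} of each
#'   mesh point; the attribute \code{"argmax"} holds the row index of the
#'   maximal cmf.
#' @export
cmfOverMesh <- function(model, mesh, thermo, alpha = 0.9,
                        method = c("corner", "numeric")) {
  method <- match.arg(method)
  stopifnot(is(model, "CommunityModel"), is(mesh, "ParetoMesh"))
  envCols <- which(model@rxnMap$strain == ".pool")
  if (!length(envCols)) stop("community has no pool exchange reactions")
  labels <- paste(".pool", model@rxnMap$rxn[envCols], sep = ":")
  mets <- sub("^EX_", "", model@rxnMap$rxn[envCols])
  cmf <- numeric(nrow(mesh@points))
  for (q in seq_len(nrow(mesh@points))) {
    frs <- tryCatch(
      mofvaAtPoint(model, mesh@points[q, ], alpha = alpha, reactions = labels),
      error = function(e)
        stop("MO-FVA failed at mesh point ", q, ": ", conditionMessage(e)))
    ## env exchange is export-positive; cmf uses uptake-positive fluxes
    rg <- data.frame(reaction = mets,
                     vmin = -frs@ranges$vmax, vmax = -frs@ranges$vmin)
    cmf[q] <- maximizeCmf(rg, thermo, method = method)@cmf
  }
  out <- data.frame(point = seq_len(nrow(mesh@points)),
                    b1 = mesh@bary[, 1], b2 = mesh@bary[, 2], b3 = mesh@bary[, 3],
                    cmf = cmf)
  attr(out, "argmax") <- which.max(cmf)
  out
}
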