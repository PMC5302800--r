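## S4 classes for strain and community constraint-based models and for the
## results of the multi-objective analyses.

setOldClass("data.frame")

#' StrainModel: a single organism's constraint-based model
#'
#' Holds the stoichiometric matrix \code{S} (metabolites x reactions, reactants
#' negative, products positive), per-reaction flux bounds and kinds, and the
#' linear growth objective.  Metabolites flagged \code{external} cross the
#' organism boundary and are the ones mirrored into the community pool.
#'
#' @slot id strain identifier.
#' @slot mets data.frame with columns \code{id}, \code{name},
#'   \code{compartment}, \code{external} (logical), \code{mu0}, \code{conc_lo},
#'   \code{conc_hi}; one row per metabolite, ids unique.
#' @slot rxns data.frame with columns \code{id}, \code{lb}, \code{ub},
#'   \code{kind} (one of internal/exchange/biomass); one row per reaction,
#'   order matches the columns of \code{S}.
#' @slot S sparse stoichiometric matrix (\code{dgCMatrix}).
#' @slot objective numeric vector over reactions (the vector \code{c} of FBA).
#' @export
setClass("StrainModel",
  representation(id = "character", mets = "data.frame", rxns = "data.frame",
                 S = "Matrix", objective = "numeric"))

setValidity("StrainModel", function(object) {
  msg <- character(0)
  m <- object@mets; r <- object@rxns; S <- object@S
  if (length(object@id) != 1L || !nzchar(object@id)) msg <- c(msg, "id must be a single non-empty string")
  need_m <- c("id", "name", "compartment", "external")
  if (!all(need_m %in% names(m))) msg <- c(msg, "mets must have columns id, name, compartment, external")
  if (anyDuplicated(m$id)) msg <- c(msg, "duplicate metabolite ids")
  if (anyDuplicated(r$id)) msg <- c(msg, "duplicate reaction ids")
  if (nrow(S) != nrow(m) || ncol(S) != nrow(r))
    msg <- c(msg, "S dimensions do not match metabolite/reaction tables")
  if (length(object@objective) != nrow(r)) msg <- c(msg, "objective length != number of reactions")
  if (!all(r$kind %in% c("internal", "exchange", "biomass")))
    msg <- c(msg, "reaction kind must be internal, exchange or biomass")
  if (any(r$lb > r$ub + 1e-12))
    msg <- c(msg, paste0("lb > ub for reaction(s): ",
                         paste(r$id[r$lb > r$ub + 1e-12], collapse = ", ")))
  if (sum(r$kind == "biomass") != 1L)
    msg <- c(msg, "exactly one biomass reaction is required")
  nz <- Matrix::colSums(S != 0)
  if (nrow(r) && any(nz == 0))
    msg <- c(msg, paste0("empty stoichiometry for reaction(s): ",
                         paste(r$id[nz == 0], collapse = ", ")))
  if (!any(object@objective != 0)) msg <- c(msg, "objective has no nonzero entry")
  ex <- which(r$kind == "exchange")
  if (length(ex)) {
    extrows <- which(m$external)
    touches <- Matrix::colSums(S[extrows, ex, drop = FALSE] != 0) > 0
    if (!all(touches))
      msg <- c(msg, paste0("exchange reaction(s) touching no external metabolite: ",
                           paste(r$id[ex[!touches]], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' PoolSpec: shared-pool specification of a community
#'
#' @slot shared ids of the external metabolites present in the shared pool.
#' @slot envBounds data.frame (\code{met}, \code{lb}, \code{ub}) of bounds for
#'   the pool-to-environment exchange of each shared metabolite; flux is
#'   positive when the pool exports to the environment, so an uptake cap of
#'   \code{u} is written \code{lb = -u}.
#' @export
setClass("PoolSpec",
  representation(shared = "character", envBounds = "data.frame"))

setValidity("PoolSpec", function(object) {
  b <- object@envBounds
  if (!all(c("met", "lb", "ub") %in% names(b))) return("envBounds needs columns met, lb, ub")
  if (!setequal(b$met, object@shared)) return("envBounds must cover exactly the shared metabolites")
  if (any(b$lb > b$ub)) return("envBounds lb > ub")
  TRUE
})

#' CommunityModel: a compartmentalized multi-strain model
#'
#' Strain stoichiometric matrices sit in diagonal blocks of the community
#' matrix; every strain exchange of a shared metabolite is mirrored (with sign
#' flipped) into a pool row, and each pool metabolite has one environment
#' exchange column.  Linear flux couplings (for instance a fixed flux ratio
#' between two reactions) are kept symbolically and added as extra LP rows, so
#' the stoichiometric matrix itself stays purely chemical.
#'
#' @slot strains named list of \linkS4class{StrainModel}.
#' @slot pool a \linkS4class{PoolSpec}.
#' @slot couplings list of couplings, each a list with elements \code{terms}
#'   (data.frame \code{strain}, \code{rxn}, \code{coef}; the pseudo-strain
#'   \code{".pool"} addresses environment exchanges), \code{relation}
#'   (\code{"eq"}, \code{"le"}, \code{"ge"}) and \code{rhs}.
#' @slot Ssigma community stoichiometric matrix (strain rows then pool rows).
#' @slot C objective matrix, one column per strain, in community column space.
#' @slot rxnMap data.frame (\code{strain}, \code{rxn}, \code{lb}, \code{ub},
#'   \code{kind}) describing the community columns in order.
#' @slot metMap data.frame (\code{strain}, \code{met}) describing the rows.
#' @export
setClass("CommunityModel",
  representation(strains = "list", pool = "PoolSpec", couplings = "list",
                 Ssigma = "Matrix", C = "matrix", rxnMap = "data.frame",
                 metMap = "data.frame"))

setValidity("CommunityModel", function(object) {
  msg <- character(0)
  k <- length(object@strains)
  if (k == 0L) return("community must contain at least one strain")
  ids <- vapply(object@strains, function(s) s@id, "")
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate strain ids")
  if (!identical(names(object@strains), unname(ids)))
    msg <- c(msg, "strain list names must equal strain ids")
  if (ncol(object@C) != k) msg <- c(msg, "objective matrix must have one column per strain")
  if (nrow(object@C) != ncol(object@Ssigma)) msg <- c(msg, "C rows != community columns")
  if (nrow(object@rxnMap) != ncol(object@Ssigma)) msg <- c(msg, "rxnMap rows != community columns")
  if (nrow(object@metMap) != nrow(object@Ssigma)) msg <- c(msg, "metMap rows != community rows")
  for (cp in object@couplings) {
    for (i in seq_len(nrow(cp$terms))) {
      st <- cp$terms$strain[i]; rx <- cp$terms$rxn[i]
      hit <- object@rxnMap$strain == st & object@rxnMap$rxn == rx
      if (!any(hit)) msg <- c(msg, paste0("coupling references unknown reaction ", st, ":", rx))
    }
    if (!cp$relation %in% c("eq", "le", "ge")) msg <- c(msg, "coupling relation must be eq/le/ge")
  }
  if (length(msg)) msg else TRUE
})

#' FBAResult: outcome of a single-objective flux balance analysis
#'
#' @slot zStar optimal objective value (unique even when the flux vector is
#'   not); \code{NA} unless status is \code{"optimal"}.
#' @slot flux one optimal flux vector, named by reaction.
#' @slot status \code{"optimal"}, \code{"infeasible"} or \code{"unbounded"}.
#' @export
setClass("FBAResult",
  representation(zStar = "numeric", flux = "numeric", status = "character"))

#' FluxRangeSet: per-reaction flux ranges at a fraction of an optimum
#'
#' @slot alpha the fraction of the optimum retained (0 to 1).
#' @slot ranges data.frame (\code{reaction}, \code{vmin}, \code{vmax}).
#' @slot reference the FBA optimum \code{z*} (length 1) or the Pareto point
#'   \code{f*} (length k) whose fraction was enforced.
#' @export
setClass("FluxRangeSet",
  representation(alpha = "numeric", ranges = "data.frame", reference = "numeric"))

setValidity("FluxRangeSet", function(object) {
  r <- object@ranges
  if (!all(c("reaction", "vmin", "vmax") %in% names(r))) return("ranges needs reaction, vmin, vmax")
  if (any(r$vmin > r$vmax + 1e-6)) return("vmin > vmax")
  if (object@alpha < 0 || object@alpha > 1) return("alpha must be in [0, 1]")
  TRUE
})

#' ParetoFront: vertex/facet description of the image of efficient solutions
#'
#' @slot k number of objectives.
#' @slot vertices matrix of Pareto-optimal vertices (rows), in objective space.
#' @slot rays matrix of recession directions of the efficient image (rows);
#'   empty for the bounded growth fronts this package targets.
#' @slot facetNormals matrix of outer facet normals (rows, componentwise
#'   non-negative) of the upper image.
#' @slot facetOffsets offsets \code{b} so every feasible objective point
#'   satisfies \code{normal \%*\% y <= b}.
#' @export
setClass("ParetoFront",
  representation(k = "numeric", vertices = "matrix", rays = "matrix",
                 facetNormals = "matrix", facetOffsets = "numeric"))

setValidity("ParetoFront", function(object) {
  v <- object@vertices
  if (nrow(v) == 0) return("front must contain at least one vertex")
  if (ncol(v) != object@k) return("vertex dimension != k")
  if (nrow(object@facetNormals) != length(object@facetOffsets))
    return("facet normals/offsets mismatch")
  scale <- max(1, max(abs(v)))
  ## no vertex may dominate another
  for (i in seq_len(nrow(v))) for (j in seq_len(nrow(v))) {
    if (i != j && all(v[i, ] >= v[j, ] - 1e-9 * scale) &&
        any(v[i, ] > v[j, ] + 1e-9 * scale))
      return("vertex set contains a dominated point")
  }
  if (length(object@facetOffsets)) {
    slack <- object@facetNormals %*% t(v) - object@facetOffsets
    if (max(slack) > 1e-6 * scale) return("a vertex violates a facet inequality")
  }
  TRUE
})

#' ParetoMesh: barycentric lattice on a face of the Pareto front
#'
#' @slot anchors k x k matrix whose rows are the spanning front vertices.
#' @slot n number of subdivisions per edge.
#' @slot bary matrix of barycentric weights (rows sum to 1, non-negative).
#' @slot points matrix of the corresponding objective-space points \code{f*}.
#' @slot mode \code{"flat"} (points on the anchor simplex) or \code{"lifted"}
#'   (points raised onto the Pareto surface).
#' @export
setClass("ParetoMesh",
  representation(anchors = "matrix", n = "numeric", bary = "matrix",
                 points = "matrix", mode = "character"))

#' ThermoTable: standard chemical potentials and concentration half-widths
#'
#' @slot entries data.frame (\code{metabolite}, \code{mu0}, \code{dg}), both in
#'   kJ/mol; \code{dg} is the half-width R T ln(x/x0) of the potential interval
#'   induced by the allowed concentration range, zero for fixed-concentration
#'   species such as water and photons.
#' @slot temperature kelvin.
#' @export
setClass("ThermoTable",
  representation(entries = "data.frame", temperature = "numeric"))

setValidity("ThermoTable", function(object) {
  e <- object@entries
  if (!all(c("metabolite", "mu0", "dg") %in% names(e))) return("entries needs metabolite, mu0, dg")
  if (anyDuplicated(e$metabolite)) return("duplicate metabolite in thermo table")
  if (any(e$dg < 0)) return("dg must be non-negative")
  if (object@temperature <= 0) return("temperature must be positive (kelvin)")
  TRUE
})

#' CmfResult: maximized chemical motive force over flux/potential boxes
#'
#' @slot cmf the maximum of \code{sum(mu * v)} in kJ/gDW/h.
#' @slot mu optimizing chemical potentials, named by metabolite.
#' @slot v optimizing boundary fluxes, named by metabolite.
#' @slot method \code{"corner"} (exact corner enumeration) or
#'   \code{"numeric"} (box-constrained quasi-Newton cross-check).
#' @export
setClass("CmfResult",
  representation(cmf = "numeric", mu = "numeric", v = "numeric",
                 method = "character"))

## ---- constructors ---------------------------------------------------------

#' Construct a strain model
#'
#' @param id strain identifier.
#' @param mets metabolite table; minimally a column \code{id}.  Missing
#'   columns are filled (\code{name} = id, \code{compartment} = strain id,
#'   \code{external} = FALSE, \code{mu0}/\code{conc_lo}/\code{conc_hi} = NA).
#' @param rxns reaction table with columns \code{id}, \code{lb}, \code{ub},
#'   \code{kind}; missing bounds default to [-1000, 1000] (or [0, 1000] for
#'   rows flagged irreversible via \code{lb = 0}).
#' @param S stoichiometric matrix (metabolites x reactions).
#' @param objective numeric objective vector over reactions; default puts
#'   weight 1 on the biomass reaction.
#' @return a validated \linkS4class{StrainModel}.
#' @export
StrainModel <- function(id, mets, rxns, S, objective = NULL) {
  mets <- as.data.frame(mets, stringsAsFactors = FALSE)
  rxns <- as.data.frame(rxns, stringsAsFactors = FALSE)
  if (is.null(mets$name)) mets$name <- mets$id
  if (is.null(mets$compartment)) mets$compartment <- id
  if (is.null(mets$external)) mets$external <- FALSE
  for (col in c("mu0", "conc_lo", "conc_hi"))
    if (is.null(mets[[col]])) mets[[col]] <- NA_real_
  if (is.null(rxns$lb)) rxns$lb <- -1000
  if (is.null(rxns$ub)) rxns$ub <- 1000
  rxns$lb[is.na(rxns$lb)] <- -1000
  rxns$ub[is.na(rxns$ub)] <- 1000
  if (is.null(rxns$kind)) rxns$kind <- "internal"
  S <- as(as(Matrix::Matrix(S, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  dimnames(S) <- list(mets$id, rxns$id)
  if (is.null(objective)) {
    objective <- as.numeric(rxns$kind == "biomass")
  }
  new("StrainModel", id = id, mets = mets, rxns = rxns, S = S,
      objective = as.numeric(objective))
}

#' Construct a pool specification
#'
#' @param shared character vector of shared (pool) metabolite ids.
#' @param envBounds data.frame (\code{met}, \code{lb}, \code{ub}); metabolites
#'   omitted get the default bounds \code{[0, 1000]} (export free, no uptake
#'   from the environment).
#' @return a \linkS4class{PoolSpec}.
#' @export
poolSpec <- function(shared, envBounds = NULL) {
  eb <- data.frame(met = shared, lb = 0, ub = 1000, stringsAsFactors = FALSE)
  if (!is.null(envBounds)) {
    envBounds <- as.data.frame(envBounds, stringsAsFactors = FALSE)
    i <- match(envBounds$met, eb$met)
    if (anyNA(i)) stop("envBounds for metabolites not in `shared`: ",
                       paste(envBounds$met[is.na(i)], collapse = ", "))
    eb$lb[i] <- envBounds$lb
    eb$ub[i] <- envBounds$ub
  }
  new("PoolSpec", shared = as.character(shared), envBounds = eb)
}

## ---- accessors ------------------------------------------------------------

#' @describeIn StrainModel number of reactions
#' @param x a StrainModel
#' @export
nReactions <- function(x) {
  if (is(x, "CommunityModel")) nrow(x@rxnMap) else nrow(x@rxns)
}

#' Strain ids of a community
#' @param x a CommunityModel
#' @export
strainIds <- function(x) names(x@strains)

#' Objective matrix C = [c1, ..., ck] of a community
#' @param x a CommunityModel
#' @export
objectiveMatrix <- function(x) x@C

#' Community (or strain) stoichiometric matrix
#' @param x a StrainModel or CommunityModel
#' @export
stoichiometry <- function(x) if (is(x, "CommunityModel")) x@Ssigma else x@S

#' Pareto-front vertices (rows, objective space)
#' @param x a ParetoFront
#' @export
paretoVertices <- function(x) x@vertices

#' Pareto-front facet inequalities
#' @param x a ParetoFront
#' @return list with matrix \code{normals} and vector \code{offsets}
#' @export
paretoFacets <- function(x) list(normals = x@facetNormals, offsets = x@facetOffsets)

#' Flux ranges table of a FluxRangeSet
#' @param x a FluxRangeSet
#' @export
fluxRanges <- function(x) x@ranges

## ---- show methods ---------------------------------------------------------

setMethod("show", "StrainModel", function(object) {
  cat("StrainModel", object@id, ":", nrow(object@mets), "metabolites x",
      nrow(object@rxns), "reactions (",
      sum(object@rxns$kind == "exchange"), "exchange )\n")
  cat("  biomass:", object@rxns$id[object@rxns$kind == "biomass"], "\n")
})

setMethod("show", "CommunityModel", function(object) {
  cat("CommunityModel with", length(object@strains), "strain(s):",
      paste(strainIds(object), collapse = ", "), "\n")
  cat("  S^sigma:", nrow(object@Ssigma), "rows x", ncol(object@Ssigma),
      "columns;", length(object@pool@shared), "pool metabolite(s);",
      length(object@couplings), "coupling(s)\n")
})

setMethod("show", "FBAResult", function(object) {
  cat("FBAResult:", object@status)
  if (object@status == "optimal") cat("  z* =", format(object@zStar, digits = 8))
  cat("\n")
})

setMethod("show", "FluxRangeSet", function(object) {
  cat("FluxRangeSet at alpha =", object@alpha, "for", nrow(object@ranges),
      "reaction(s)\n")
  print(utils::head(object@ranges, 6))
  if (nrow(object@ranges) > 6) cat("  ...\n")
})

setMethod("show", "ParetoFront", function(object) {
  cat("ParetoFront in", object@k, "objective(s):", nrow(object@vertices),
      "vertex/vertices,", nrow(object@facetNormals), "facet(s)\n")
  print(round(object@vertices, 6))
})

setMethod("show", "ParetoMesh", function(object) {
  cat("ParetoMesh (", object@mode, "): n =", object@n, ",",
      nrow(object@points), "points\n")
})

setMethod("show", "ThermoTable", function(object) {
  cat("ThermoTable at", object@temperature, "K for",
      nrow(object@entries), "metabolite(s)\n")
})

setMethod("show", "CmfResult", function(object) {
  cat("CmfResult (", object@method, "): cmf =", format(object@cmf, digits = 8),
      "kJ/gDW/h\n")
})
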