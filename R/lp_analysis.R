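## Single-objective flux balance and flux variability analysis.

#' Flux balance analysis
#'
#' Maximizes a linear objective \code{c' v} over the flux space
#' \code{S v = 0}, \code{l <= v <= u} (plus any community couplings).
#' Infeasible or unbounded models are reported through the \code{status} slot
#' of the result, never as an error.
#'
#' @param model a \linkS4class{StrainModel} or \linkS4class{CommunityModel}.
#' @param objective optional objective vector over the model's columns; the
#'   default is the strain's own objective, or for a community the sum of all
#'   strain objectives (columns of \code{C}).
#' @return an \linkS4class{FBAResult}.
#' @examples
#' toy <- makeCompetition(yields = 1, cap = 10)$model
#' fba(toy)
#' @export
setGeneric("fba", function(model, objective = NULL) standardGeneric("fba"))

.fbaCore <- function(model, objective) {
  lp <- .lpData(model)
  res <- solveLP(objective, lp$A, lp$rhs, lp$sense, lp$lb, lp$ub, maximize = TRUE)
  st <- if (res$status %in% c("optimal", "infeasible", "unbounded")) res$status else "infeasible"
  new("FBAResult",
      zStar = if (st == "optimal") res$objval else NA_real_,
      flux = if (st == "optimal") setNames(res$x, lp$cols) else setNames(numeric(0), character(0)),
      status = st)
}

#' @rdname fba
#' @export
setMethod("fba", "StrainModel", function(model, objective = NULL) {
  if (is.null(objective)) objective <- model@objective
  stopifnot(length(objective) == nrow(model@rxns))
  .fbaCore(model, objective)
})

#' @rdname fba
#' @export
setMethod("fba", "CommunityModel", function(model, objective = NULL) {
  if (is.null(objective)) objective <- rowSums(model@C)
  stopifnot(length(objective) == nrow(model@rxnMap))
  .fbaCore(model, objective)
})

#' Flux variability analysis
#'
#' For each reaction, minimizes and maximizes its flux subject to the model
#' constraints and to retaining at least the fraction \code{alpha} of the FBA
#' optimum, \code{c' v >= alpha * z*}.
#'
#' @inheritParams fba
#' @param alpha fraction of the optimum in [0, 1].
#' @param reactions optional subset of reaction names (strain models) or
#'   \code{"strain:rxn"} labels (community models) to range over.
#' @return a \linkS4class{FluxRangeSet}.
#' @export
setGeneric("fva", function(model, objective = NULL, alpha = 1, reactions = NULL)
  standardGeneric("fva"))

.fvaCore <- function(model, objective, alpha, reactions) {
  stopifnot(alpha >= 0, alpha <= 1)
  base <- .fbaCore(model, objective)
  if (base@status != "optimal")
    stop("FVA needs an optimal base FBA; status was '", base@status, "'")
  zstar <- base@zStar
  if (zstar < -1e-9)
    stop("alpha-scaling requires a non-negative optimum (z* = ",
         format(zstar), "); rescale the objective")
  lp <- .lpData(model)
  A <- rbind(lp$A, Matrix::Matrix(objective, 1, sparse = TRUE))
  rhs <- c(lp$rhs, alpha * zstar)
  sense <- c(lp$sense, ">=")
  idx <- if (is.null(reactions)) seq_along(lp$cols) else match(reactions, lp$cols)
  if (anyNA(idx)) stop("unknown reaction(s): ",
                       paste(reactions[is.na(idx)], collapse = ", "))
  vmin <- vmax <- numeric(length(idx))
  e <- numeric(length(lp$cols))
  for (q in seq_along(idx)) {
    e[] <- 0; e[idx[q]] <- 1
    up <- solveLP(e, A, rhs, sense, lp$lb, lp$ub, maximize = TRUE)
    lo <- solveLP(e, A, rhs, sense, lp$lb, lp$ub, maximize = FALSE)
    if (up$status != "optimal" || lo$status != "optimal")
      stop("FVA subproblem not optimal for ", lp$cols[idx[q]],
           " (", up$status, "/", lo$status, ")")
    vmax[q] <- up$objval; vmin[q] <- lo$objval
  }
  new("FluxRangeSet", alpha = alpha,
      ranges = data.frame(reaction = lp$cols[idx], vmin = vmin, vmax = vmax,
                          stringsAsFactors = FALSE),
      reference = zstar)
}

#' @rdname fva
#' @export
setMethod("fva", "StrainModel", function(model, objective = NULL, alpha = 1,
                                         reactions = NULL) {
  if (is.null(objective)) objective <- model@objective
  .fvaCore(model, objective, alpha, reactions)
})

#' @rdname fva
#' @export
setMethod("fva", "CommunityModel", function(model, objective = NULL, alpha = 1,
                                            reactions = NULL) {
  if (is.null(objective)) objective <- rowSums(model@C)
  .fvaCore(model, objective, alpha, reactions)
})

#' Write flux ranges as TSV
#'
#' @param x a \linkS4class{FluxRangeSet}.
#' @param path output file.
#' @export
writeFluxRanges <- function(x, path) {
  write.table(x@ranges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
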