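## Assembly of strain models into a compartmentalized community model.

#' Assemble strain models into a community model
#'
#' Builds the community stoichiometric matrix: strain matrices as diagonal
#' blocks, one pool row per shared metabolite mirroring (with flipped sign)
#' every strain exchange of that metabolite, and one pool-to-environment
#' exchange column per shared metabolite.  Steady state applies to the pool
#' rows exactly as to strain-internal metabolites, so shared metabolites are
#' routed through the pool, never directly between a strain and the
#' environment.
#'
#' @param strains list of \linkS4class{StrainModel}; ids must be unique.
#' @param pool a \linkS4class{PoolSpec}; every shared metabolite must be
#'   exchanged by at least one strain.
#' @param couplings optional list of linear flux couplings (see
#'   \linkS4class{CommunityModel}); each adds one LP row
#'   \code{sum(coef * v) (relation) rhs}.
#' @return a validated \linkS4class{CommunityModel}.
#' @examples
#' m <- makeCompetition(yields = c(1, 0.5), cap = 10)$model
#' m
#' @export
assembleCommunity <- function(strains, pool, couplings = list()) {
  if (length(strains) == 0L) stop("community must contain at least one strain")
  ids <- vapply(strains, function(s) s@id, "")
  if (anyDuplicated(ids)) stop("duplicate strain id: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(strains) <- ids
  for (s in strains) validObject(s)
  validObject(pool)

  ## every shared metabolite must be external in, and exchanged by, >= 1 strain
  for (met in pool@shared) {
    exchanged <- FALSE
    for (s in strains) {
      i <- match(met, s@mets$id)
      if (is.na(i) || !s@mets$external[i]) next
      ex <- which(s@rxns$kind == "exchange")
      if (length(ex) && any(s@S[i, ex] != 0)) { exchanged <- TRUE; break }
    }
    if (!exchanged)
      stop("shared metabolite never exchanged by any strain: ", met)
  }

  nr <- vapply(strains, function(s) nrow(s@rxns), 0L)
  nm <- vapply(strains, function(s) nrow(s@mets), 0L)
  npool <- length(pool@shared)
  ncols <- sum(nr) + npool
  nrows <- sum(nm) + npool

  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  roff <- 0L; coff <- 0L
  metMap <- data.frame(strain = character(0), met = character(0))
  rxnMap <- data.frame(strain = character(0), rxn = character(0),
                       lb = numeric(0), ub = numeric(0), kind = character(0))
  poolRow <- sum(nm) + seq_len(npool)
  names(poolRow) <- pool@shared

  for (s in strains) {
    tm <- as(s@S, "TsparseMatrix")
    trip_i <- c(trip_i, tm@i + 1L + roff)
    trip_j <- c(trip_j, tm@j + 1L + coff)
    trip_x <- c(trip_x, tm@x)
    ## mirror exchange columns of shared metabolites into the pool rows
    ex <- which(s@rxns$kind == "exchange")
    for (j in ex) {
      touched <- which(s@S[, j] != 0 & s@mets$external)
      for (i in touched) {
        met <- s@mets$id[i]
        if (met %in% pool@shared) {
          trip_i <- c(trip_i, poolRow[[met]])
          trip_j <- c(trip_j, j + coff)
          trip_x <- c(trip_x, -s@S[i, j])
        }
      }
    }
    metMap <- rbind(metMap, data.frame(strain = s@id, met = s@mets$id))
    rxnMap <- rbind(rxnMap, data.frame(strain = s@id, rxn = s@rxns$id,
                                       lb = s@rxns$lb, ub = s@rxns$ub,
                                       kind = s@rxns$kind))
    roff <- roff + nrow(s@mets); coff <- coff + nrow(s@rxns)
  }
  ## environment exchange columns: consume the pool metabolite, positive flux
  ## is export from the pool to the environment
  eb <- pool@envBounds[match(pool@shared, pool@envBounds$met), ]
  for (q in seq_len(npool)) {
    trip_i <- c(trip_i, poolRow[[q]])
    trip_j <- c(trip_j, sum(nr) + q)
    trip_x <- c(trip_x, -1)
  }
  metMap <- rbind(metMap, data.frame(strain = ".pool", met = pool@shared))
  if (npool > 0)
    rxnMap <- rbind(rxnMap, data.frame(strain = ".pool",
                                       rxn = paste0("EX_", pool@shared),
                                       lb = eb$lb, ub = eb$ub, kind = "exchange"))
  Ssigma <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                                 dims = c(nrows, ncols))

  k <- length(strains)
  C <- matrix(0, ncols, k, dimnames = list(NULL, unname(ids)))
  coff <- 0L
  for (j in seq_len(k)) {
    C[coff + seq_len(nr[j]), j] <- strains[[j]]@objective
    coff <- coff + nr[j]
  }
  ## do.call with an explicit `Class` keeps the slot name C from partially
  ## matching new()'s first formal
  obj <- do.call(methods::new,
                 list(Class = "CommunityModel", strains = strains, pool = pool,
                      couplings = couplings, Ssigma = Ssigma, C = C,
                      rxnMap = rxnMap, metMap = metMap))
  validObject(obj)
  obj
}

#' Add a fixed flux-ratio coupling between two reactions of a strain
#'
#' Appends the linear constraint \code{v_a - rho * v_b = 0}, i.e. reaction
#' \code{rxnA} is forced to run at a fixed ratio \code{rho} of reaction
#' \code{rxnB} (used, for instance, to pin the Rubisco oxygenase/carboxylase
#' flux ratio of a cyanobacterial guild).
#'
#' @param model a \linkS4class{CommunityModel}.
#' @param strain strain id owning both reactions.
#' @param rxnA,rxnB reaction ids.
#' @param rho the ratio.
#' @return the community model with the extra coupling.
#' @export
addRatioCoupling <- function(model, strain, rxnA, rxnB, rho) {
  for (rx in c(rxnA, rxnB)) {
    if (!any(model@rxnMap$strain == strain & model@rxnMap$rxn == rx))
      stop("unknown reaction ", strain, ":", rx)
  }
  cp <- list(terms = data.frame(strain = strain, rxn = c(rxnA, rxnB),
                                coef = c(1, -rho)),
             relation = "eq", rhs = 0)
  model@couplings <- c(model@couplings, list(cp))
  validObject(model)
  model
}

## ---- internal LP extraction ----------------------------------------------

## Rows of an LP in the model's column space: the stoichiometric steady-state
## equalities plus coupling rows.
.lpData <- function(model) {
  if (is(model, "StrainModel")) {
    return(list(A = model@S, rhs = rep(0, nrow(model@S)),
                sense = rep("=", nrow(model@S)),
                lb = model@rxns$lb, ub = model@rxns$ub,
                cols = model@rxns$id))
  }
  stopifnot(is(model, "CommunityModel"))
  A <- model@Ssigma
  rhs <- rep(0, nrow(A))
  sense <- rep("=", nrow(A))
  if (length(model@couplings)) {
    extra <- matrix(0, length(model@couplings), ncol(A))
    for (ii in seq_along(model@couplings)) {
      cp <- model@couplings[[ii]]
      for (t in seq_len(nrow(cp$terms))) {
        j <- which(model@rxnMap$strain == cp$terms$strain[t] &
                   model@rxnMap$rxn == cp$terms$rxn[t])
        extra[ii, j] <- extra[ii, j] + cp$terms$coef[t]
      }
    }
    A <- rbind(A, Matrix::Matrix(extra, sparse = TRUE))
    rhs <- c(rhs, vapply(model@couplings, function(cp) cp$rhs, 0))
    sense <- c(sense, vapply(model@couplings, function(cp)
      switch(cp$relation, eq = "=", le = "<=", ge = ">="), ""))
  }
  list(A = A, rhs = rhs, sense = sense,
       lb = model@rxnMap$lb, ub = model@rxnMap$ub,
       cols = paste(model@rxnMap$strain, model@rxnMap$rxn, sep = ":"))
}

## Column index of a (strain, reaction) pair in community space.
.colIndex <- function(model, strain, rxn) {
  j <- which(model@rxnMap$strain == strain & model@rxnMap$rxn == rxn)
  if (!length(j)) stop("unknown reaction ", strain, ":", rxn)
  j
}
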