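## Synthetic community generators with known ground truth.

#' Competition toy community with a closed-form Pareto front
#'
#' \code{k} strains draw one pooled nutrient (environment uptake capped at
#' \code{cap} mmol/gDW/h); strain \code{j} converts it to biomass with yield
#' \code{yields[j]} (growth per unit nutrient).  The Pareto front is the
#' simplex \code{sum_j f_j / (yields_j * cap) <= 1}, with one vertex
#' \code{yields_j * cap} on each axis.
#'
#' @param yields positive per-strain biomass yields.
#' @param cap non-negative shared nutrient uptake cap.
#' @return list with \code{model} (a \linkS4class{CommunityModel}) and
#'   \code{front}, the closed-form front as a list of \code{vertices} (matrix)
#'   and \code{facet} (list \code{normal}, \code{offset}).
#' @export
makeCompetition <- function(yields, cap) {
  k <- length(yields)
  if (k == 0L) stop("at least one strain is required")
  stopifnot(all(yields > 0), cap >= 0)
  strains <- lapply(seq_len(k), function(j) {
    id <- paste0("S", j)
    mets <- data.frame(id = "nutrient", external = TRUE)
    rxns <- data.frame(id = c("EX_nutrient", "BIO"),
                       lb = c(-cap, 0), ub = c(1000, 1000),
                       kind = c("exchange", "biomass"))
    S <- matrix(c(-1, -1 / yields[j]), 1, 2,
                dimnames = list("nutrient", rxns$id))
    StrainModel(id = id, mets = mets, rxns = rxns, S = S)
  })
  pool <- poolSpec("nutrient", data.frame(met = "nutrient", lb = -cap, ub = 1000))
  model <- assembleCommunity(strains, pool)
  vertices <- diag(yields * cap, nrow = k)
  front <- list(vertices = vertices,
                facet = if (cap > 0) list(normal = 1 / (yields * cap), offset = 1)
                        else list(normal = rep(1, k), offset = 0))
  list(model = model, front = front)
}

#' Cross-feeding toy community
#'
#' A producer strain takes up an environment-capped substrate and exports an
#' organic acid to the pool in fixed proportion to its growth; consumer
#' strains grow only on that acid.  With the producer silenced the consumers'
#' FBA optimum is zero, which makes the obligate dependency testable.
#'
#' @param producerYield growth of the producer per unit substrate.
#' @param consumerYields growth of each consumer per unit acid.
#' @param cap environment uptake cap on the producer substrate.
#' @param acidPerGrowth acid exported by the producer per unit of its growth.
#' @param crossfeed optional data.frame (\code{from}, \code{to}) of feeding
#'   edges; the default feeds every consumer from the producer.  Cycles are
#'   rejected.
#' @return a \linkS4class{CommunityModel}; the first strain is the producer.
#' @export
makeCrossfeed <- function(producerYield = 1, consumerYields = 1, cap = 10,
                          acidPerGrowth = 1, crossfeed = NULL) {
  k <- 1L + length(consumerYields)
  if (k < 2L) stop("at least one consumer is required")
  ids <- c("P", paste0("C", seq_along(consumerYields)))
  if (is.null(crossfeed))
    crossfeed <- data.frame(from = "P", to = ids[-1])
  ## cycle check on the feeding graph
  edges <- crossfeed
  order_left <- unique(c(edges$from, edges$to))
  repeat {
    sinks <- setdiff(order_left, edges$from)
    if (!length(sinks)) {
      if (length(order_left)) stop("cyclic crossfeed specification")
      break
    }
    order_left <- setdiff(order_left, sinks)
    edges <- edges[!edges$to %in% sinks, , drop = FALSE]
    if (!nrow(edges)) break
  }
  producer <- StrainModel(
    id = "P",
    mets = data.frame(id = c("substrate", "acid"), external = TRUE),
    rxns = data.frame(id = c("EX_substrate", "EX_acid", "BIO"),
                      lb = c(-cap, 0, 0), ub = c(1000, 1000, 1000),
                      kind = c("exchange", "exchange", "biomass")),
    S = matrix(c(-1, 0,
                 0, -1,
                 -1 / producerYield, acidPerGrowth), 2, 3,
               dimnames = list(c("substrate", "acid"), NULL)))
  consumers <- lapply(seq_along(consumerYields), function(j) {
    StrainModel(
      id = ids[j + 1L],
      mets = data.frame(id = "acid", external = TRUE),
      rxns = data.frame(id = c("EX_acid", "BIO"),
                        lb = c(-1000, 0), ub = c(1000, 1000),
                        kind = c("exchange", "biomass")),
      S = matrix(c(-1, -1 / consumerYields[j]), 1, 2,
                 dimnames = list("acid", NULL)))
  })
  pool <- poolSpec(c("substrate", "acid"),
                   data.frame(met = c("substrate", "acid"),
                              lb = c(-cap, 0), ub = c(1000, 1000)))
  assembleCommunity(c(list(producer), consumers), pool)
}

#' Random feasible community
#'
#' Generates \code{k} strains, each built around a guaranteed substrate-to-
#' biomass chain (so the model is feasible and every objective bounded), plus
#' random mass-conserving side reactions.  All strains draw one shared pooled
#' substrate, so the community front is a non-trivial competition trade-off.
#' Fully reproducible from the seed; no global RNG state is left behind.
#'
#' @param seed integer seed.
#' @param k number of strains (>= 1).
#' @param reactionsPerStrain total reactions per strain (>= 3).
#' @return a \linkS4class{CommunityModel}.
#' @export
randomCommunity <- function(seed, k = 3L, reactionsPerStrain = 10L) {
  stopifnot(k >= 1L, reactionsPerStrain >= 3L)
  rng <- local({ set.seed(seed); new.env() })
  set.seed(seed)
  strains <- lapply(seq_len(k), function(j) {
    id <- paste0("R", j)
    nchain <- sample(2:max(2, min(5, reactionsPerStrain - 2L)), 1)
    chain_mets <- c("sub", paste0("m", seq_len(nchain)))
    nextra <- max(0L, reactionsPerStrain - (nchain + 2L))
    mets <- data.frame(id = chain_mets,
                       external = chain_mets == "sub")
    yield <- runif(1, 0.3, 2)
    rid <- c("EX_sub", paste0("T", seq_len(nchain)), "BIO")
    S <- matrix(0, length(chain_mets), length(rid),
                dimnames = list(chain_mets, rid))
    S["sub", "EX_sub"] <- -1
    for (q in seq_len(nchain)) {
      S[chain_mets[q], paste0("T", q)] <- -1
      S[chain_mets[q + 1L], paste0("T", q)] <- 1
    }
    S[chain_mets[nchain + 1L], "BIO"] <- -1 / yield
    rxns <- data.frame(id = rid,
                       lb = c(-runif(1, 2, 15), rep(0, nchain), 0),
                       ub = 1000,
                       kind = c("exchange", rep("internal", nchain), "biomass"))
    ## mass-conserving side reactions: move one unit between internal mets
    for (e in seq_len(nextra)) {
      pick <- sample(chain_mets[-1], 2)
      col <- rep(0, length(chain_mets)); names(col) <- chain_mets
      col[pick[1]] <- -1; col[pick[2]] <- 1
      S <- cbind(S, col)
      colnames(S)[ncol(S)] <- paste0("X", e)
      rxns <- rbind(rxns, data.frame(id = paste0("X", e), lb = 0,
                                     ub = runif(1, 0.5, 10), kind = "internal"))
    }
    StrainModel(id = id, mets = mets, rxns = rxns, S = S)
  })
  cap <- runif(1, 3, 12)
  pool <- poolSpec("sub", data.frame(met = "sub", lb = -cap, ub = 1000))
  assembleCommunity(strains, pool)
}
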