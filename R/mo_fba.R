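## Multi-objective FBA: exact Pareto fronts of per-strain growth objectives.
##
## The solver is an outer-approximation scheme of the Benson type: efficient
## points found by (lexicographically refined) weighted-sum LPs form an inner
## polyhedral approximation of the upper image, whose facet normals are used
## as the next weight vectors; a facet whose weighted-sum optimum does not
## improve on its offset is a confirmed facet of the exact front.  The outer
## polytope -- the intersection of all supporting halfspaces returned by the
## weighted-sum LPs -- then coincides with the inner hull, which certifies
## exactness at the working tolerance.

## Lexicographically refined weighted-sum solve: first maximize w'C'v, then,
## holding that optimum, maximize total growth 1'C'v so the returned point is
## efficient even when w has zero components.
.efficientPoint <- function(model, w, lp = NULL) {
  if (is.null(lp)) lp <- .lpData(model)
  C <- model@C
  obj1 <- as.numeric(C %*% w)
  s1 <- solveLP(obj1, lp$A, lp$rhs, lp$sense, lp$lb, lp$ub, maximize = TRUE)
  if (s1$status != "optimal") return(list(status = s1$status))
  ## hold the stage-1 optimum exactly: a relaxed floor would let the second
  ## stage drift along near-degenerate edges of the optimal face
  A2 <- rbind(lp$A, Matrix::Matrix(obj1, 1, sparse = TRUE))
  rhs2 <- c(lp$rhs, s1$objval)
  sense2 <- c(lp$sense, "=")
  obj2 <- rowSums(C)
  s2 <- solveLP(obj2, A2, rhs2, sense2, lp$lb, lp$ub, maximize = TRUE)
  v <- if (s2$status == "optimal") s2$x else s1$x
  list(status = "optimal", y = as.numeric(crossprod(C, v)), v = v)
}

## Greedy row deduplication at an absolute tolerance.
.dedupRows <- function(M, tol) {
  if (nrow(M) <= 1L) return(M)
  keep <- 1L
  for (i in 2:nrow(M)) {
    if (all(vapply(keep, function(j) max(abs(M[i, ] - M[j, ])) > tol, TRUE)))
      keep <- c(keep, i)
  }
  M[keep, , drop = FALSE]
}

## Facets with componentwise non-negative normals of the upper image
## conv(points) - R_{>=0}^k, found by exhaustive k-tuple enumeration (k <= 3).
## Downward-shifted copies of the points supply the vertical facets; facet
## offsets are recomputed as exact supports over the points, so every point
## satisfies every returned inequality by construction.
.upperFacets <- function(P, tol = 1e-7) {
  scale <- max(1, max(abs(P)))
  P <- .dedupRows(P, tol * scale)
  k <- ncol(P)
  if (k == 1L)
    return(list(normals = matrix(1, 1, 1), offsets = max(P)))
  ## keep only non-dominated points; dominated ones cannot support a facet
  keep <- rep(TRUE, nrow(P))
  for (i in seq_len(nrow(P))) for (j in seq_len(nrow(P))) {
    if (i != j && keep[i] && all(P[j, ] >= P[i, ] - 1e-12) && any(P[j, ] > P[i, ] + 1e-12))
      keep[i] <- FALSE
  }
  P <- P[keep, , drop = FALSE]
  M <- 2 * (max(P) - min(P)) + 1
  aug <- P
  for (j in seq_len(k)) {
    sh <- P; sh[, j] <- sh[, j] - M
    aug <- rbind(aug, sh)
  }
  n_orig <- nrow(P)
  if (nrow(aug) < k) return(list(normals = matrix(0, 0, k), offsets = numeric(0)))
  cmb <- combn(nrow(aug), k)
  normals <- matrix(0, 0, k); offsets <- numeric(0)
  if (k == 2L) {
    u <- aug[cmb[2, ], , drop = FALSE] - aug[cmb[1, ], , drop = FALSE]
    N <- cbind(u[, 2], -u[, 1])
  } else {
    u <- aug[cmb[2, ], , drop = FALSE] - aug[cmb[1, ], , drop = FALSE]
    v <- aug[cmb[3, ], , drop = FALSE] - aug[cmb[1, ], , drop = FALSE]
    N <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  len <- sqrt(rowSums(N^2))
  ok <- len > 1e-10
  if (!any(ok)) return(list(normals = matrix(0, 0, k), offsets = numeric(0)))
  N <- N[ok, , drop = FALSE] / len[ok]
  base <- aug[cmb[1, ok], , drop = FALSE]
  d <- rowSums(N * base)
  G <- tcrossprod(aug, N)                 # n_aug x n_facets of n . p
  gmax <- do.call(pmax, asplit(G, 1))
  gmin <- do.call(pmin, asplit(G, 1))
  span <- max(1, max(abs(aug)))
  below <- (gmax - d) <= tol * span
  above <- (d - gmin) <= tol * span
  flip <- above & !below
  N[flip, ] <- -N[flip, , drop = FALSE]
  valid <- below | flip
  N <- N[valid, , drop = FALSE]
  if (!nrow(N)) return(list(normals = matrix(0, 0, k), offsets = numeric(0)))
  nonneg <- apply(N, 1, function(r) all(r >= -1e-7))
  N <- N[nonneg, , drop = FALSE]
  if (!nrow(N)) return(list(normals = matrix(0, 0, k), offsets = numeric(0)))
  N[N < 0] <- 0
  len <- sqrt(rowSums(N^2)); N <- N / len
  ## merge near-identical normals, then recompute exact supports over the
  ## original points (shifted copies lie strictly below for n >= 0)
  N <- .dedupRows(N, 1e-5)
  Gp <- tcrossprod(P, N)
  d <- apply(Gp, 2, max)
  ## keep planes supported by >= k points of the augmented set (true facets);
  ## shifted copies legitimately support vertical facets
  Ga <- tcrossprod(aug, N)
  touch <- vapply(seq_len(nrow(N)), function(q)
    sum(Ga[, q] >= d[q] - 1e-7 * span) >= k, TRUE)
  list(normals = N[touch, , drop = FALSE], offsets = d[touch])
}

## Is point p an extreme point of conv(others) - R_{>=0}^k?  It is NOT extreme
## iff some convex combination of the other points dominates it.
.isExtreme <- function(p, others, tol = 1e-7) {
  n <- nrow(others)
  if (n == 0) return(TRUE)
  k <- length(p)
  ## feasibility LP: lambda >= 0, sum lambda = 1, others' lambda >= p
  A <- rbind(t(others), rep(1, n))
  res <- solveLP(rep(0, n), A, c(p, 1), c(rep(">=", k), "="),
                 rep(0, n), rep(1, n), maximize = TRUE)
  res$status != "optimal"
}

#' Solve the multi-objective FBA problem of a community
#'
#' Computes the exact Pareto front of the per-strain growth objectives
#' \code{(c1'v, ..., ck'v)} over the community flux space, as a set of
#' non-dominated vertices plus the facet inequalities of the upper image, by
#' outer approximation with supporting hyperplanes obtained from weighted-sum
#' LPs.
#'
#' @param model a \linkS4class{CommunityModel}.
#' @param tol tolerance for facet confirmation and vertex deduplication.
#' @param maxIter cap on refinement rounds.
#' @return a \linkS4class{ParetoFront}.
#' @examples
#' toy <- makeCompetition(yields = c(1, 0.5), cap = 10)$model
#' solveMOFBA(toy)
#' @export
solveMOFBA <- function(model, tol = 1e-6, maxIter = 200L) {
  stopifnot(is(model, "CommunityModel"))
  lp <- .lpData(model)
  k <- ncol(model@C)
  ## boundedness / feasibility screen, one FBA per strain objective
  for (j in seq_len(k)) {
    r <- solveLP(model@C[, j], lp$A, lp$rhs, lp$sense, lp$lb, lp$ub, maximize = TRUE)
    if (r$status == "unbounded")
      stop("objective of strain '", strainIds(model)[j], "' is unbounded")
    if (r$status != "optimal")
      stop("community model is ", r$status)
  }
  pts <- matrix(0, 0, k)
  ## appends the efficient point for weights w; FALSE when it was known already
  addPoint <- function(w) {
    ep <- .efficientPoint(model, w, lp)
    if (ep$status != "optimal") stop("scalarized LP returned ", ep$status)
    sc <- max(1, abs(ep$y), if (nrow(pts)) abs(pts) else 0)
    if (nrow(pts) && any(apply(pts, 1, function(p) max(abs(p - ep$y))) <= 1e-10 * sc))
      return(FALSE)
    pts <<- rbind(pts, ep$y)
    TRUE
  }
  for (j in seq_len(k)) addPoint(as.numeric(seq_len(k) == j))
  addPoint(rep(1 / k, k))
  if (k > 1L) {
    for (it in seq_len(maxIter)) {
      fac <- .upperFacets(pts)
      improved <- FALSE
      ## confirmation threshold near solver precision: an absolute threshold
      ## of `tol` would let vertices drift by tol over the smallest weight
      confTol <- 1e-9 * max(1, max(abs(pts)))
      for (q in seq_len(nrow(fac$normals))) {
        w <- fac$normals[q, ]
        obj1 <- as.numeric(model@C %*% w)
        s <- solveLP(obj1, lp$A, lp$rhs, lp$sense, lp$lb, lp$ub, maximize = TRUE)
        if (s$status != "optimal") stop("scalarized LP returned ", s$status)
        if (s$objval > fac$offsets[q] + confTol && addPoint(w))
          improved <- TRUE
      }
      if (!improved) break
      if (it == maxIter) warning("front refinement hit maxIter; result may be an inner approximation")
    }
  }
  ## vertex extraction: deduplicate, drop dominated, keep extreme points
  scale <- max(1, max(abs(pts)))
  pts <- .dedupRows(pts, tol * scale)
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) for (j in seq_len(nrow(pts))) {
    if (i != j && keep[i] && keep[j] &&
        all(pts[j, ] >= pts[i, ] - tol * scale) &&
        any(pts[j, ] > pts[i, ] + tol * scale))
      keep[i] <- FALSE
  }
  pts <- pts[keep, , drop = FALSE]
  ext <- vapply(seq_len(nrow(pts)), function(i)
    .isExtreme(pts[i, ], pts[-i, , drop = FALSE]), TRUE)
  verts <- pts[ext, , drop = FALSE]
  verts[abs(verts) < 1e-8 * scale] <- 0   # snap solver jitter at zero
  ord <- do.call(order, c(as.data.frame(verts), list(decreasing = TRUE)))
  verts <- verts[ord, , drop = FALSE]
  rownames(verts) <- NULL
  colnames(verts) <- strainIds(model)
  fac <- .upperFacets(verts)
  colnames(fac$normals) <- strainIds(model)
  new("ParetoFront", k = k, vertices = verts,
      rays = matrix(0, 0, k), facetNormals = fac$normals,
      facetOffsets = fac$offsets)
}

#' Weighted-sum scalarization
#'
#' Maximizes \code{sum(lambda_j * f_j)} over the community flux space.  As the
#' problem is a convex MOLP, every weighted-sum solution with non-negative,
#' not-all-zero weights is an efficient (Pareto-optimal) point; a secondary
#' lexicographic pass makes the returned point efficient even when some
#' weights are zero.
#'
#' @param model a \linkS4class{CommunityModel}.
#' @param lambda non-negative weights, at least one positive.
#' @return list with \code{point} (objective-space point) and \code{flux}.
#' @export
weightedSum <- function(model, lambda) {
  stopifnot(is(model, "CommunityModel"))
  k <- ncol(model@C)
  if (length(lambda) != k) stop("lambda must have one weight per strain")
  if (any(lambda < 0) || all(lambda == 0))
    stop("weights must be non-negative with at least one positive entry")
  ep <- .efficientPoint(model, lambda)
  if (ep$status != "optimal") stop("weighted-sum LP returned ", ep$status)
  list(point = setNames(ep$y, strainIds(model)), flux = ep$v)
}

#' Epsilon-constraint scalarization
#'
#' Maximizes objective \code{j} subject to floors \code{f_i >= eps_i} for all
#' other objectives; the solution is weakly efficient.
#'
#' @param model a \linkS4class{CommunityModel}.
#' @param j index of the retained objective.
#' @param eps numeric floors, either length k (entry j ignored) or length k-1
#'   in strain order with strain j omitted.
#' @return list with \code{point} and \code{flux}.
#' @export
epsilonConstraint <- function(model, j, eps) {
  stopifnot(is(model, "CommunityModel"))
  k <- ncol(model@C)
  stopifnot(j >= 1, j <= k)
  if (length(eps) == k - 1L) {
    full <- numeric(k); full[-j] <- eps; eps <- full
  }
  stopifnot(length(eps) == k)
  lp <- .lpData(model)
  others <- setdiff(seq_len(k), j)
  A <- rbind(lp$A, Matrix::t(Matrix::Matrix(model@C[, others, drop = FALSE], sparse = TRUE)))
  rhs <- c(lp$rhs, eps[others])
  sense <- c(lp$sense, rep(">=", length(others)))
  s <- solveLP(model@C[, j], A, rhs, sense, lp$lb, lp$ub, maximize = TRUE)
  if (s$status != "optimal")
    stop(errorCondition(
      paste0("epsilon-constraint problem is ", s$status,
             " for floors (", paste(signif(eps[others], 6), collapse = ", "), ")"),
      status = s$status, class = c("mofbaStatusError", "error", "condition")))
  list(point = setNames(as.numeric(crossprod(model@C, s$x)), strainIds(model)),
       flux = s$x)
}

#' Verify a Pareto front by random weighted-sum sampling
#'
#' Draws random strictly positive weight vectors, solves the weighted-sum LP
#' for each, and checks that every solution lies on the front boundary (inside
#' all facets, tight on at least one) and that no solution dominates any front
#' vertex.
#'
#' @param front a \linkS4class{ParetoFront}.
#' @param model the community the front was computed from.
#' @param nSamples number of random weight vectors.
#' @param seed RNG seed.
#' @param tol tolerance.
#' @return list with \code{ok} (logical) and \code{violations} (data.frame of
#'   offending weight vectors and the reason).
#' @export
verifyFront <- function(front, model, nSamples = 100L, seed = 1L, tol = 1e-6) {
  stopifnot(is(front, "ParetoFront"), is(model, "CommunityModel"))
  k <- front@k
  set.seed(seed)
  bad <- data.frame(sample = integer(0), reason = character(0), weights = character(0))
  scale <- max(1, max(abs(front@vertices)))
  for (s in seq_len(nSamples)) {
    w <- runif(k, 0.01, 1); w <- w / sum(w)
    y <- weightedSum(model, w)$point
    slack <- as.numeric(front@facetNormals %*% y) - front@facetOffsets
    reason <- NULL
    if (length(slack) && max(slack) > tol * scale) reason <- "outside a facet"
    else if (length(slack) && min(abs(slack)) > tol * scale) reason <- "not on the boundary"
    else {
      for (i in seq_len(nrow(front@vertices))) {
        u <- front@vertices[i, ]
        if (all(y >= u - tol * scale) && any(y > u + tol * scale)) {
          reason <- "dominates a vertex"; break
        }
      }
    }
    if (!is.null(reason))
      bad <- rbind(bad, data.frame(sample = s, reason = reason,
                                   weights = paste(signif(w, 6), collapse = ",")))
  }
  list(ok = nrow(bad) == 0L, violations = bad)
}

#' Export a Pareto front
#'
#' @param x a \linkS4class{ParetoFront}.
#' @param path output file.
#' @param format \code{"json"} (vertices, rays, facets) or \code{"tsv"}
#'   (vertices only).
#' @export
writeParetoFront <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(
      k = x@k,
      vertices = x@vertices,
      rays = x@rays,
      facets = list(normals = x@facetNormals, offsets = x@facetOffsets)
    ), path, digits = NA, matrix = "rowmajor")
  } else {
    write.table(as.data.frame(x@vertices), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
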