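## Multi-objective FVA: flux variability near a Pareto point, barycentric
## meshing of the front, and regional aggregation.

#' Flux variability near a Pareto point
#'
#' For each reaction, minimizes and maximizes its flux subject to the
#' community constraints and the componentwise vector constraint
#' \code{C' v >= alpha * fStar}: every strain must retain at least the
#' fraction \code{alpha} of its own coordinate of the Pareto point.
#'
#' @param model a \linkS4class{CommunityModel}.
#' @param fStar length-k objective-space point on or below the front.
#' @param alpha fraction of the optimum in [0, 1]; defaults to 0.9.
#' @param reactions optional subset of \code{"strain:rxn"} column labels.
#' @return a \linkS4class{FluxRangeSet} whose \code{reference} is
#'   \code{fStar}.
#' @export
mofvaAtPoint <- function(model, fStar, alpha = 0.9, reactions = NULL) {
  stopifnot(is(model, "CommunityModel"), alpha >= 0, alpha <= 1)
  k <- ncol(model@C)
  stopifnot(length(fStar) == k)
  lp <- .lpData(model)
  A <- rbind(lp$A, Matrix::t(Matrix::Matrix(model@C, sparse = TRUE)))
  rhs <- c(lp$rhs, alpha * fStar)
  sense <- c(lp$sense, rep(">=", k))
  feas <- solveLP(rep(0, length(lp$lb)), A, rhs, sense, lp$lb, lp$ub)
  if (feas$status != "optimal")
    stop(errorCondition(
      paste0("objective floors alpha * f* are ", feas$status,
             "; is f* above the Pareto front?"),
      status = feas$status, class = c("mofbaStatusError", "error", "condition")))
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
      stop("MO-FVA subproblem not optimal for ", lp$cols[idx[q]])
    vmax[q] <- up$objval; vmin[q] <- lo$objval
  }
  new("FluxRangeSet", alpha = alpha,
      ranges = data.frame(reaction = lp$cols[idx], vmin = vmin,
                          vmax = pmax(vmin, vmax), stringsAsFactors = FALSE),
      reference = as.numeric(fStar))
}

#' Barycentric mesh on a triangular face of the Pareto front
#'
#' Places \code{(n+1)(n+2)/2} points at all barycentric combinations
#' \code{(i/n, j/n, (n-i-j)/n)} of three anchor vertices.  In \code{"flat"}
#' mode (default) the points lie on the anchor triangle, which is feasible by
#' convexity; in \code{"lifted"} mode each point is raised onto the Pareto
#' surface by maximizing total growth subject to componentwise floors at the
#' flat point (an epsilon-constraint lift).
#'
#' @param front a \linkS4class{ParetoFront} with k = 3.
#' @param anchors indices (or vertex matrix rows) of the three anchor
#'   vertices; the default takes, for each objective, the vertex maximizing
#'   that coordinate.
#' @param n number of subdivisions per edge.
#' @param mode \code{"flat"} or \code{"lifted"}.
#' @param model community model, required for \code{mode = "lifted"}.
#' @return a \linkS4class{ParetoMesh}.
#' @export
meshFront <- function(front, anchors = NULL, n = 100L, mode = c("flat", "lifted"),
                      model = NULL) {
  mode <- match.arg(mode)
  if (front@k != 3L)
    stop("meshing is supported for k = 3 objectives only (got k = ", front@k, ")")
  V <- front@vertices
  if (is.null(anchors)) anchors <- apply(V, 2, which.max)
  A <- V[anchors, , drop = FALSE]
  if (nrow(A) != 3L) stop("exactly three anchor vertices are required")
  ij <- expand.grid(i = 0:n, j = 0:n)
  ij <- ij[ij$i + ij$j <= n, ]
  bary <- cbind(ij$i, ij$j, n - ij$i - ij$j) / n
  pts <- bary %*% A
  if (mode == "lifted") {
    if (is.null(model)) stop("mode = 'lifted' needs the community model")
    for (q in seq_len(nrow(pts))) {
      lifted <- tryCatch(epsilonLift(model, pts[q, ]), error = function(e) NULL)
      if (!is.null(lifted)) pts[q, ] <- lifted
    }
  }
  new("ParetoMesh", anchors = A, n = as.numeric(n), bary = bary,
      points = pts, mode = mode)
}

#' Lift a feasible objective point onto the Pareto surface
#'
#' Maximizes total growth subject to componentwise floors at \code{p}.
#'
#' @param model a \linkS4class{CommunityModel}.
#' @param p feasible objective-space point.
#' @return the lifted objective-space point.
#' @export
epsilonLift <- function(model, p) {
  lp <- .lpData(model)
  A <- rbind(lp$A, Matrix::t(Matrix::Matrix(model@C, sparse = TRUE)))
  rhs <- c(lp$rhs, p)
  sense <- c(lp$sense, rep(">=", ncol(model@C)))
  s <- solveLP(rowSums(model@C), A, rhs, sense, lp$lb, lp$ub)
  if (s$status != "optimal")
    stop(errorCondition(paste0("lift problem is ", s$status),
                        status = s$status,
                        class = c("mofbaStatusError", "error", "condition")))
  as.numeric(crossprod(model@C, s$x))
}

#' Aggregate mesh-point flux ranges over triangular regions
#'
#' Splits the barycentric triangle into \code{r^2} congruent sub-triangles
#' (\code{r(r+1)/2} upward, \code{r(r-1)/2} downward) and reports, per region
#' and reaction, the mean of the member points' maxima and the mean of their
#' minima.
#'
#' @param mesh a \linkS4class{ParetoMesh}.
#' @param results list of \linkS4class{FluxRangeSet}, one per mesh point, in
#'   mesh order.
#' @param r regional resolution per edge.
#' @return data.frame with columns \code{region}, \code{nPoints},
#'   \code{reaction}, \code{vminMean}, \code{vmaxMean}.
#' @export
aggregateRegions <- function(mesh, results, r) {
  stopifnot(is(mesh, "ParetoMesh"), r >= 1)
  npts <- nrow(mesh@bary)
  if (length(results) != npts)
    stop("need one FluxRangeSet per mesh point (", npts, ")")
  regionOf <- function(b) {
    x <- b[1] * r; y <- b[2] * r
    u <- min(floor(x + 1e-9), r - 1)
    v <- min(floor(y + 1e-9), r - 1)
    if (u + v > r - 1) return(NA_integer_)  # outside (numerical guard)
    fa <- x - u; fb <- y - v
    down <- (fa + fb > 1 + 1e-9) && (u + v < r - 1)
    ## upward cells indexed first, then downward cells
    ## upward cells: u + v <= r - 1, ordered by v then u
    upIndex <- function(u, v) v * r - v * (v - 1) / 2 + u + 1
    as.integer(if (!down) upIndex(u, v)
               else r * (r + 1) / 2 + v * (r - 1) - v * (v - 1) / 2 + u + 1)
  }
  region <- vapply(seq_len(npts), function(q) regionOf(mesh@bary[q, ]), 1L)
  region[is.na(region)] <- 1L
  nRegions <- r * r
  counts <- tabulate(region, nbins = nRegions)
  if (any(counts == 0))
    stop("empty region(s) at resolution r = ", r,
         "; the mesh (n = ", mesh@n, ") is too coarse")
  rxns <- results[[1]]@ranges$reaction
  out <- do.call(rbind, lapply(seq_len(nRegions), function(g) {
    members <- which(region == g)
    pick <- function(field) {
      m <- vapply(members, function(q) results[[q]]@ranges[[field]],
                  numeric(length(rxns)))
      rowMeans(matrix(m, nrow = length(rxns)))
    }
    vmin <- pick("vmin"); vmax <- pick("vmax")
    data.frame(region = g, nPoints = length(members), reaction = rxns,
               vminMean = vmin, vmaxMean = vmax, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run MO-FVA over a whole mesh
#'
#' @param model a \linkS4class{CommunityModel}.
#' @param mesh a \linkS4class{ParetoMesh}.
#' @param alpha fraction of the optimum.
#' @param reactions optional subset of reaction labels (default: all).
#' @return list of \linkS4class{FluxRangeSet}, one per mesh point.
#' @export
mofvaOverMesh <- function(model, mesh, alpha = 0.9, reactions = NULL) {
  lapply(seq_len(nrow(mesh@points)), function(q)
    mofvaAtPoint(model, mesh@points[q, ], alpha = alpha, reactions = reactions))
}
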