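#' Solve a linear program
#'
#' Minimal solve contract used by every analysis in the package: maximise (or
#' minimise) \code{obj \%*\% x} subject to \code{A x (sense) rhs} and box bounds
#' \code{lb <= x <= ub}.  Backed by the package's compiled bounded-variable
#' two-phase simplex.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n), dense or \pkg{Matrix} sparse.
#' @param rhs numeric right-hand sides (length m).
#' @param sense character vector of \code{"<="}, \code{"="}, \code{">="} per row.
#' @param lb,ub variable bounds; \code{-Inf}/\code{Inf} allowed.
#' @param maximize logical; maximise if \code{TRUE} (default).
#' @param maxit simplex iteration cap per phase.
#' @return list with \code{status} (\code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}, \code{"maxit"}), \code{objval}, primal point \code{x}
#'   and row \code{duals}.
#' @export
solveLP <- function(obj, A, rhs, sense, lb, ub, maximize = TRUE, maxit = 20000L) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(sense) == m,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12))
    stop("solveLP: lower bound exceeds upper bound for variable(s) ",
         paste(which(lb > ub + 1e-12), collapse = ", "))
  if (m == 0L) {
    # pure box problem
    s <- if (maximize) 1 else -1
    x <- ifelse(s * obj > 0, ub, ifelse(s * obj < 0, lb, pmin(pmax(0, lb), ub)))
    if (any(!is.finite(x) & obj != 0))
      return(list(status = "unbounded", objval = NA_real_, x = x, duals = numeric(0)))
    x[!is.finite(x)] <- 0
    return(list(status = "optimal", objval = sum(obj * x), x = x, duals = numeric(0)))
  }
  sn <- match(sense, c("<=", "=", ">=")) - 2L
  if (anyNA(sn)) stop("solveLP: sense must be one of '<=', '=', '>='")
  res <- .cpp_simplex(A, as.numeric(rhs), sn, as.numeric(lb), as.numeric(ub),
                      as.numeric(obj), isTRUE(maximize), as.integer(maxit))
  res$objval <- as.numeric(res$objval)
  res
}
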