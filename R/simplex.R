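#' Dense primal simplex for origin-feasible linear programs
#'
#' Solves \eqn{\min c'x} subject to \eqn{Ax \le b}, \eqn{x \ge 0}, for
#' problems with \eqn{b \ge 0}, i.e. problems where the origin is feasible.
#' The biomarker-selection model built by [build_lp()] always has this form
#' (every constraint row compares a non-negative weighted deviation against a
#' radius or a bound), so no phase-1 is required: the slack basis is a valid
#' starting vertex.
#'
#' The implementation is a full-tableau simplex with row and column
#' equilibration (deviation coefficients for edge features can exceed the node
#' coefficients by many orders of magnitude), Dantzig pricing, a
#' largest-pivot-element tie-break in the ratio test, and an automatic switch
#' to Bland's rule when the objective stalls on degenerate vertices -- the
#' radius constraints make vertices of this model massively degenerate.
#'
#' @param cc numeric objective coefficients (length `n`).
#' @param A  dense constraint matrix (`m x n`), rows are `<=` constraints.
#' @param b  right-hand side, all entries `>= 0`.
#' @param maxit iteration cap; default `50 * (nrow(A) + ncol(A))`.
#' @param tol pivot / reduced-cost tolerance on the equilibrated problem.
#'
#' @return A list with `status` (`"optimal"`, `"unbounded"`, or `"failed"`),
#'   the primal solution `x`, `objective = c'x`, the number of `iterations`,
#'   and `residual`, the largest scaled violation of `Ax <= b`.
#' @keywords internal
simplex_solve <- function(cc, A, b, maxit = NULL, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cc) == n, length(b) == m)
  if (any(b < 0)) stop("simplex_solve requires b >= 0 (origin-feasible form)")
  if (is.null(maxit)) maxit <- 50L * (m + n)

  ## -- equilibrate: scale columns then rows to unit max magnitude ----------
  colmax <- apply(abs(A), 2, max)
  cs <- ifelse(colmax > 0, colmax, 1)
  As <- sweep(A, 2, cs, "/")
  rowmax <- apply(abs(As), 1, max)
  rs <- ifelse(rowmax > 0, rowmax, 1)
  As <- As / rs
  bs <- b / rs
  ccs <- cc / cs
  obj_scale <- max(abs(ccs), 1)
  ccs <- ccs / obj_scale

  ## -- tableau: [A | I | b], objective row appended -------------------------
  T <- cbind(As, diag(m), bs)
  zrow <- c(ccs, numeric(m), 0)          # reduced costs; objective = -zrow[last]
  basis <- n + seq_len(m)                # slack basis
  ncols <- n + m
  bland <- FALSE
  stall <- 0L
  last_obj <- 0
  it <- 0L
  status <- "failed"

  while (it < maxit) {
    it <- it + 1L
    rc <- zrow[seq_len(ncols)]
    if (bland) {
      cand <- which(rc < -tol)
      if (!length(cand)) { status <- "optimal"; break }
      pc <- cand[1L]
    } else {
      pc <- which.min(rc)
      if (rc[pc] >= -tol) { status <- "optimal"; break }
    }
    col <- T[, pc]
    pos <- which(col > tol)
    if (!length(pos)) { status <- "unbounded"; break }
    ratio <- T[pos, ncols + 1L] / col[pos]
    rmin <- min(ratio)
    tied <- pos[ratio <= rmin + tol * (1 + abs(rmin))]
    if (bland) {
      pr <- tied[which.min(basis[tied])]
    } else {
      pr <- tied[which.max(col[tied])]   # largest pivot element for stability
    }
    piv <- T[pr, pc]
    T[pr, ] <- T[pr, ] / piv
    fac <- T[, pc]; fac[pr] <- 0
    T <- T - outer(fac, T[pr, ])
    zrow <- zrow - zrow[pc] * T[pr, ]
    basis[pr] <- pc

    obj <- -zrow[ncols + 1L]
    if (obj < last_obj - tol * (1 + abs(last_obj))) {
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (!bland && stall > 2L * (m + 5L)) bland <- TRUE
    }
    last_obj <- obj
  }

  x <- numeric(n)
  inb <- basis <= n
  x[basis[inb]] <- pmax(T[inb, ncols + 1L], 0)
  x <- x / cs                            # undo column scaling
  resid <- if (m > 0) max(c(0, (A %*% x - b) / pmax(1, abs(b), apply(abs(A), 1, max)))) else 0
  list(status = status,
       x = x,
       objective = sum(cc * x),
       iterations = it,
       residual = resid)
}
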