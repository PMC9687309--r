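#' One update of the Method of Moving Asymptotes (single constraint)
#'
#' Svanberg-style MMA step for minimizing f(x) subject to one inequality
#' constraint g(x) <= 0 and box bounds. Each function is replaced by a
#' separable convex approximation built from moving lower/upper asymptotes;
#' the convex subproblem is solved exactly through its one-dimensional dual
#' (bisection on the constraint multiplier).
#'
#' @param x Current design vector.
#' @param df Gradient of the objective at \code{x}.
#' @param dg Gradient of the constraint at \code{x}.
#' @param g Constraint value at \code{x} (must be <= 0 at a feasible point).
#' @param state List carried between calls: \code{xold1}, \code{xold2},
#'   \code{low}, \code{upp}, \code{iter}. Pass \code{NULL} on the first call.
#' @param xmin,xmax Box bounds.
#' @param move Move limit as a fraction of the box range (default 0.2).
#' @param asyinit Initial asymptote distance as a fraction of the range.
#' @param asydecr,asyincr Asymptote adaptation factors applied when the
#'   variable oscillates / moves monotonically. The default shrink factor
#'   0.5 damps bound-to-bound cycling of individual elements.
#' @return List with \code{x} (updated design) and \code{state};
#'   \code{state$restored} flags a constraint-restoration fallback.
#' @export
mma_update <- function(x, df, dg, g, state = NULL,
                       xmin = 0.01, xmax = 1, move = 0.2,
                       asyinit = 0.5, asydecr = 0.7, asyincr = 1.2) {
  n <- length(x)
  stopifnot(length(df) == n, length(dg) == n, all(is.finite(df)),
            all(is.finite(dg)), is.finite(g))
  rng <- xmax - xmin
  if (is.null(state))
    state <- list(xold1 = NULL, xold2 = NULL, low = NULL, upp = NULL,
                  iter = 0L)
  it <- state$iter + 1L

  if (it <= 2L || is.null(state$low)) {
    low <- x - asyinit * rng
    upp <- x + asyinit * rng
  } else {
    zzz <- (x - state$xold1) * (state$xold1 - state$xold2)
    fac <- rep(1, n)
    fac[zzz < 0] <- asydecr
    fac[zzz > 0] <- asyincr
    low <- x - fac * (state$xold1 - state$low)
    upp <- x + fac * (state$upp - state$xold1)
    low <- pmin(pmax(low, x - 10 * rng), x - 1e-4 * rng)
    upp <- pmax(pmin(upp, x + 10 * rng), x + 1e-4 * rng)
  }

  alfa <- pmax(xmin, pmax(low + 0.1 * (x - low), x - move * rng))
  beta <- pmin(xmax, pmin(upp - 0.1 * (upp - x), x + move * rng))

  ux <- upp - x
  xl <- x - low
  feps <- 1e-5 / rng
  p0 <- ux^2 * (pmax(df, 0) + 0.001 * abs(df) + feps)
  q0 <- xl^2 * (pmax(-df, 0) + 0.001 * abs(df) + feps)
  p1 <- ux^2 * pmax(dg, 0)
  q1 <- xl^2 * pmax(-dg, 0)
  # subproblem constraint: sum(p1/(upp-x) + q1/(x-low)) <= b
  b <- sum(p1 / ux + q1 / xl) - g

  xsub <- function(lam) {
    pl <- p0 + lam * p1
    ql <- q0 + lam * q1
    sp <- sqrt(pl); sq <- sqrt(ql)
    xi <- (sp * low + sq * upp) / (sp + sq)
    pmin(pmax(xi, alfa), beta)
  }
  gsub <- function(lam) {
    xi <- xsub(lam)
    sum(p1 / (upp - xi) + q1 / (xi - low)) - b
  }

  restored <- FALSE
  if (all(p1 == 0) && all(q1 == 0)) {
    lam <- 0
  } else if (gsub(0) <= 0) {
    lam <- 0
  } else {
    hi <- 1
    while (gsub(hi) > 0 && hi < 1e12) hi <- hi * 10
    if (gsub(hi) > 0) {
      # subproblem infeasible within bounds: restoration step toward the
      # least-constraint-violating point of the box
      restored <- TRUE
      lam <- hi
    } else {
      lo <- 0
      for (k in 1:80) {
        mid <- (lo + hi) / 2
        if (gsub(mid) > 0) lo <- mid else hi <- mid
      }
      lam <- hi
    }
  }
  xnew <- xsub(lam)

  state <- list(xold1 = x, xold2 = state$xold1, low = low, upp = upp,
                iter = it, restored = restored)
  list(x = xnew, state = state)
}
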