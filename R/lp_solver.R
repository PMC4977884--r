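# Dense bounded-variable two-phase revised simplex.
#
# Solves   max/min  c'x   s.t.  A x = b,  l <= x <= u
# with all bounds finite, which is the shape of every LP this package
# builds (flux bounds are finite by construction, so no unbounded rays
# can occur in a well-formed model).  The basis inverse is maintained
# by product-form pivots and refactorised periodically; basic variable
# values are recomputed from the inverse every iteration, so the
# iterate is always consistent with the (basis, bound-status) state.
# Pricing is Dantzig with a Bland fallback to rule out cycling on the
# highly degenerate stoichiometric systems this package feeds it.

#' Solve a bounded linear program
#'
#' Maximise or minimise \code{c'x} subject to \code{A x = b} and
#' \code{l <= x <= u}.  All bounds must be finite.  This is the
#' optimisation core behind [maximize()] and the gapfilling search; it
#' is exposed so that small programs can be solved directly in tests
#' and scripts.
#'
#' @param obj numeric objective vector (length \code{ncol(A)}).
#' @param A dense constraint matrix of equality rows.
#' @param b right-hand side vector.
#' @param lower,upper finite variable bounds.
#' @param maximize logical; maximise (default) or minimise.
#' @param tol feasibility/optimality tolerance (default \code{1e-9}).
#'
#' @return A list with elements \code{status} (\code{"optimal"} or
#'   \code{"infeasible"}), \code{objval}, and the primal solution
#'   \code{x}.
#' @export
solve_lp <- function(obj, A, b, lower, upper, maximize = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m,
            length(lower) == n, length(upper) == n)
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("solve_lp() requires finite variable bounds")
  if (any(lower > upper + 1e-12))
    stop("solve_lp(): lower bound exceeds upper bound")
  cc <- if (maximize) as.numeric(obj) else -as.numeric(obj)

  # Shift to x' = x - l in [0, s]; artificial columns give a start basis.
  s <- upper - lower
  b0 <- as.numeric(b - A %*% lower)
  sgn <- ifelse(b0 >= 0, 1, -1)
  Aa <- cbind(A, diag(sgn, m))        # n structural + m artificial
  ntot <- n + m
  lo <- rep(0, ntot)
  hi <- c(s, abs(b0))                 # artificials start at |b0|, only shrink

  st <- new.env(parent = emptyenv())
  st$basis <- (n + 1L):ntot
  st$at_upper <- rep(FALSE, ntot)     # meaningful for nonbasic columns
  st$Binv <- diag(sgn, nrow = m)      # inverse of the +/-1 artificial basis

  refact <- function() {
    B <- Aa[, st$basis, drop = FALSE]
    out <- try(solve(B), silent = TRUE)
    if (inherits(out, "try-error"))
      stop("singular basis encountered in simplex")
    st$Binv <- out
  }

  basic_values <- function() {
    nonb <- setdiff(seq_len(ntot), st$basis)
    xn <- ifelse(st$at_upper[nonb], hi[nonb], lo[nonb])
    rhs <- b0 - as.numeric(Aa[, nonb, drop = FALSE] %*% xn)
    as.numeric(st$Binv %*% rhs)
  }

  run_phase <- function(cost, allow_art) {
    iter <- 0L; bland <- FALSE; since_refact <- 0L
    max_iter <- 200L * (m + n) + 5000L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter)
        stop("simplex iteration limit reached; system is numerically degenerate")
      if (since_refact >= 60L) { refact(); since_refact <- 0L }
      nonb <- setdiff(seq_len(ntot), st$basis)
      if (!allow_art) nonb <- nonb[nonb <= n]
      if (!length(nonb)) break
      xB <- basic_values()
      y <- as.numeric(crossprod(st$Binv, cost[st$basis]))
      d <- cost[nonb] - as.numeric(crossprod(Aa[, nonb, drop = FALSE], y))
      up <- st$at_upper[nonb]
      cand <- (!up & d > tol) | (up & d < -tol)
      if (!any(cand)) break
      if (!bland && iter > 60L * (m + 10L)) bland <- TRUE
      idx <- which(cand)
      j_rel <- if (bland) idx[which.min(nonb[idx])] else idx[which.max(abs(d[idx]))]
      q <- nonb[j_rel]                   # entering column
      dir <- if (st$at_upper[q]) -1 else 1
      w <- as.numeric(st$Binv %*% Aa[, q])
      delta <- -dir * w                  # d x_B / d t
      t_max <- hi[q] - lo[q]             # bound-flip distance
      leave <- 0L; leave_to_upper <- FALSE
      piv_tol <- 1e-10
      for (i in seq_len(m)) {
        bi <- st$basis[i]
        if (delta[i] < -piv_tol) {       # basic decreases, hits lower
          t_i <- (xB[i] - lo[bi]) / (-delta[i])
          hit_up <- FALSE
        } else if (delta[i] > piv_tol) { # basic increases, hits upper
          t_i <- (hi[bi] - xB[i]) / delta[i]
          hit_up <- TRUE
        } else next
        if (t_i < -1e-9) t_i <- 0
        if (t_i < t_max - 1e-12 ||
            (bland && leave > 0L && t_i <= t_max + 1e-12 && bi < st$basis[leave])) {
          t_max <- max(t_i, 0); leave <- i; leave_to_upper <- hit_up
        }
      }
      if (leave == 0L) {
        # entering variable flips to its other bound; basis unchanged
        st$at_upper[q] <- !st$at_upper[q]
      } else {
        p <- st$basis[leave]
        st$at_upper[p] <- leave_to_upper
        st$basis[leave] <- q
        st$at_upper[q] <- FALSE          # basic; flag now irrelevant
        wp <- w[leave]
        if (abs(wp) < 1e-11) {
          refact(); since_refact <- 0L
        } else {
          eta <- -w / wp; eta[leave] <- 1 / wp
          e_l <- rep(0, m); e_l[leave] <- 1
          st$Binv <- st$Binv + (eta - e_l) %o% st$Binv[leave, ]
          since_refact <- since_refact + 1L
        }
      }
    }
    invisible(NULL)
  }

  # Phase 1: drive artificial mass to zero (maximise its negative)
  c1 <- c(rep(0, n), rep(-1, m))
  run_phase(c1, allow_art = TRUE)
  refact()
  xB <- basic_values()
  art_val <- numeric(m)
  in_basis <- st$basis > n
  art_val[st$basis[in_basis] - n] <- xB[in_basis]
  nonb_art <- setdiff((n + 1L):ntot, st$basis)
  art_val[nonb_art - n] <- ifelse(st$at_upper[nonb_art], hi[nonb_art], 0)
  if (sum(art_val) > 1e-7)
    return(list(status = "infeasible", objval = NA_real_, x = rep(NA_real_, n)))
  # pin artificials to zero for phase 2
  hi[(n + 1L):ntot] <- 0

  c2 <- c(cc, rep(0, m))
  run_phase(c2, allow_art = FALSE)

  refact()
  xB <- basic_values()
  x <- numeric(ntot)
  nonb <- setdiff(seq_len(ntot), st$basis)
  x[nonb] <- ifelse(st$at_upper[nonb], hi[nonb], lo[nonb])
  x[st$basis] <- xB
  x <- x[seq_len(n)] + lower
  x <- pmin(pmax(x, lower), upper)
  list(status = "optimal", objval = sum(as.numeric(obj) * x), x = x)
}
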