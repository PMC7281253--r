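# Dense two-phase simplex for box-constrained flux LPs.
#
# Solves: optimize c'v  s.t.  S v = 0, lb <= v <= ub  (all bounds finite).
# The problem is shifted to w = v - lb >= 0 and upper bounds become explicit
# rows, giving a standard-form tableau with slack and artificial variables.
# Pivoting uses Dantzig's rule and falls back to Bland's rule (guaranteed
# termination under degeneracy) after a fixed number of iterations. Problem
# sizes in this package are tiny (tens of rows), so the dense tableau is
# both simple and fast.

SIMPLEX_TOL <- 1e-9

# Run the simplex on a canonical tableau.
# tab: m x (n+1) matrix, last column RHS (>= 0); basis: length-m column
# indices with tab[, basis] = I; cost: length-n objective (maximized).
simplex_iterate <- function(tab, basis, cost, bland_after = 300L, maxit = 20000L) {
  m <- nrow(tab)
  n <- ncol(tab) - 1L
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > maxit) stop("simplex: iteration limit exceeded", call. = FALSE)
    red <- cost - as.numeric(crossprod(cost[basis], tab[, seq_len(n), drop = FALSE]))
    red[basis] <- 0
    cand <- which(red > SIMPLEX_TOL)
    if (!length(cand)) {
      return(list(tab = tab, basis = basis, status = "optimal"))
    }
    j <- if (it > bland_after) cand[1L] else cand[which.max(red[cand])]
    col <- tab[, j]
    pos <- which(col > SIMPLEX_TOL)
    if (!length(pos)) {
      return(list(tab = tab, basis = basis, status = "unbounded"))
    }
    ratio <- tab[pos, n + 1L] / col[pos]
    rmin <- min(ratio)
    ties <- pos[ratio <= rmin + SIMPLEX_TOL]
    # Bland tie-break: leave the variable with the smallest index
    prow <- ties[which.min(basis[ties])]
    piv <- tab[prow, j]
    tab[prow, ] <- tab[prow, ] / piv
    other <- setdiff(seq_len(m), prow)
    tab[other, ] <- tab[other, ] - outer(tab[other, j], tab[prow, ])
    tab[, j] <- 0
    tab[prow, j] <- 1
    tab[, n + 1L][tab[, n + 1L] < 0 & tab[, n + 1L] > -SIMPLEX_TOL] <- 0
    basis[prow] <- j
  }
}

#' Solve a box-constrained steady-state flux LP
#'
#' Optimizes `obj' v` subject to `S v = 0` and `lb <= v <= ub`. This is the
#' single LP primitive behind [maximize_flux()], [fva()] and
#' [max_production()].
#'
#' @param obj numeric objective vector (length = number of reactions).
#' @param S stoichiometric matrix (dense or `Matrix` sparse).
#' @param lb,ub finite bound vectors.
#' @param sense `"max"` or `"min"`.
#' @return List with `status` (`"optimal"` or `"infeasible"`), `objective`
#'   (the optimum, `NA` unless optimal) and `flux` (an optimal flux vector).
#' @export
lp_solve <- function(obj, S, lb, ub, sense = c("max", "min")) {
  sense <- match.arg(sense)
  S <- as.matrix(S)
  n <- length(obj)
  stopifnot(ncol(S) == n, length(lb) == n, length(ub) == n)
  if (any(lb > ub + SIMPLEX_TOL)) {
    return(list(status = "infeasible", objective = NA_real_, flux = NULL))
  }
  cc <- if (sense == "min") -obj else obj
  m <- nrow(S)
  u <- ub - lb
  beq <- as.numeric(-S %*% lb)
  flip <- beq < 0
  Seq <- S
  Seq[flip, ] <- -Seq[flip, , drop = FALSE]
  beq[flip] <- -beq[flip]

  mtot <- m + n
  nvar <- 2L * n + m           # w, upper-bound slacks, artificials
  tab <- matrix(0, mtot, nvar + 1L)
  tab[seq_len(m), seq_len(n)] <- Seq
  tab[seq_len(m), 2L * n + seq_len(m)] <- diag(m)
  tab[m + seq_len(n), seq_len(n)] <- diag(n)
  tab[m + seq_len(n), n + seq_len(n)] <- diag(n)
  tab[, nvar + 1L] <- c(beq, u)
  basis <- c(2L * n + seq_len(m), n + seq_len(n))

  # phase 1: drive artificials to zero
  c1 <- c(rep(0, 2L * n), rep(-1, m))
  r1 <- simplex_iterate(tab, basis, c1)
  if (r1$status != "optimal") stop("simplex phase 1: ", r1$status, call. = FALSE)
  art <- 2L * n + seq_len(m)
  rhs <- r1$tab[, nvar + 1L]
  art_val <- sum(rhs[which(r1$basis %in% art)])
  scale <- max(1, max(abs(beq)))
  if (art_val > 1e-7 * scale) {
    return(list(status = "infeasible", objective = NA_real_, flux = NULL))
  }
  tab <- r1$tab
  basis <- r1$basis
  # pivot basic zero-valued artificials out, or drop redundant rows
  keep <- rep(TRUE, mtot)
  for (r in which(basis %in% art)) {
    row <- tab[r, seq_len(2L * n)]
    j <- which(abs(row) > SIMPLEX_TOL)
    if (length(j)) {
      j <- j[1L]
      piv <- tab[r, j]
      tab[r, ] <- tab[r, ] / piv
      other <- setdiff(seq_len(nrow(tab)), r)
      tab[other, ] <- tab[other, ] - outer(tab[other, j], tab[r, ])
      tab[, j] <- 0
      tab[r, j] <- 1
      basis[r] <- j
    } else {
      keep[r] <- FALSE
    }
  }
  tab <- tab[keep, c(seq_len(2L * n), nvar + 1L), drop = FALSE]
  basis <- basis[keep]

  # phase 2
  c2 <- c(cc, rep(0, n))
  r2 <- simplex_iterate(tab, basis, c2)
  if (r2$status != "optimal") stop("simplex phase 2: ", r2$status, call. = FALSE)
  w <- numeric(2L * n)
  w[r2$basis] <- r2$tab[, ncol(r2$tab)]
  v <- w[seq_len(n)] + lb
  objective <- sum(obj * v)
  list(status = "optimal", objective = objective, flux = v)
}
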