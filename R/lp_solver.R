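# Dense two-phase primal simplex for the small LPs arising in flux analysis.
#
# All models handled by this package are toy- to fixture-scale (tens of
# variables), so a dense tableau with Bland's anti-cycling rule is both fast
# enough and free of external solver dependencies.

#' Solve a small linear program
#'
#' Minimizes (or maximizes) \code{obj \%*\% x} subject to
#' \code{Aeq x = beq}, \code{Ale x <= ble} and \code{lb <= x <= ub}.
#'
#' Infinite bounds are replaced internally by a large box (\code{big});
#' a solution pressed against that artificial box on a variable whose
#' original bound was infinite is reported as \code{"unbounded"}.
#'
#' @param obj numeric objective coefficients (length n).
#' @param Aeq equality constraint matrix (may have zero rows).
#' @param beq equality right-hand sides.
#' @param Ale inequality (\code{<=}) constraint matrix or NULL.
#' @param ble inequality right-hand sides.
#' @param lb,ub variable bounds; \code{-Inf}/\code{Inf} allowed.
#' @param maximize if TRUE, maximize the objective instead.
#' @param big box used to replace infinite bounds.
#' @param tol pivot / feasibility tolerance.
#' @return list with \code{status} ("optimal", "infeasible", "unbounded"),
#'   \code{objective}, and primal solution \code{x}.
#' @keywords internal
lp_solve <- function(obj, Aeq, beq, Ale = NULL, ble = NULL,
                     lb, ub, maximize = FALSE, big = 1e7, tol = 1e-9) {
  n <- length(obj)
  stopifnot(ncol(Aeq) == n, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) return(list(status = "infeasible", objective = NA_real_, x = NULL))
  cvec <- if (maximize) -obj else obj

  inf_lb <- !is.finite(lb)
  inf_ub <- !is.finite(ub)
  lb2 <- ifelse(inf_lb, -big, lb)
  ub2 <- ifelse(inf_ub, big, ub)

  # fold <= rows into equalities with slack variables
  n_le <- if (is.null(Ale)) 0L else nrow(Ale)
  A <- Aeq
  b <- beq
  if (n_le > 0L) {
    A <- rbind(Aeq, Ale)
    b <- c(beq, ble)
  }
  m <- nrow(A)
  nv <- n + n_le                       # structural + inequality slacks
  Afull <- matrix(0, m, nv)
  Afull[, seq_len(n)] <- A
  if (n_le > 0L)
    Afull[cbind(nrow(Aeq) + seq_len(n_le), n + seq_len(n_le))] <- 1
  clow <- c(lb2, rep(0, n_le))
  cupp <- c(ub2, rep(big, n_le))       # slack upper bound generous
  cobj <- c(cvec, rep(0, n_le))

  # shift x = v - lb so all variables are in [0, u]
  u <- cupp - clow
  b2 <- b - as.vector(Afull %*% clow)

  # upper-bound rows x_i + s_i = u_i give each variable a slack partner
  M <- m + nv
  N <- nv + nv
  T <- matrix(0, M, N + 1)
  T[seq_len(m), seq_len(nv)] <- Afull
  T[seq_len(m), N + 1] <- b2
  for (i in seq_len(nv)) {
    T[m + i, i] <- 1
    T[m + i, nv + i] <- 1
    T[m + i, N + 1] <- u[i]
  }
  # make rhs nonnegative
  neg <- T[, N + 1] < 0
  if (any(neg)) T[neg, ] <- -T[neg, ]

  # artificials for the first m rows; bound rows start basic in their slack
  nart <- m
  full <- cbind(T[, seq_len(N), drop = FALSE],
                rbind(diag(nart), matrix(0, nv, nart)),
                T[, N + 1])
  basis <- c(N + seq_len(nart), nv + seq_len(nv))
  rhs_col <- N + nart + 1

  pivot <- function(tab, basis, prow, pcol) {
    tab[prow, ] <- tab[prow, ] / tab[prow, pcol]
    other <- setdiff(seq_len(nrow(tab)), prow)
    fac <- tab[other, pcol]
    nz <- which(abs(fac) > 0)
    if (length(nz))
      tab[other[nz], ] <- tab[other[nz], , drop = FALSE] -
        outer(fac[nz], tab[prow, ])
    basis[prow] <- pcol
    list(tab = tab, basis = basis)
  }

  run_simplex <- function(tab, basis, cost, allowed) {
    # reduced-cost row maintained explicitly
    z <- cost
    for (i in seq_len(M)) {
      bi <- basis[i]
      if (abs(z[bi]) > 0) z <- z - z[bi] * tab[i, seq_along(z)]
    }
    repeat {
      cand <- which(allowed & z < -tol)
      if (!length(cand)) break
      pcol <- cand[1L]                       # Bland: smallest index
      col <- tab[, pcol]
      rows <- which(col > tol)
      if (!length(rows)) return(list(tab = tab, basis = basis, z = z,
                                     status = "unbounded"))
      ratio <- tab[rows, rhs_col] / col[rows]
      best <- min(ratio)
      tie <- rows[ratio <= best + tol]
      prow <- tie[which.min(basis[tie])]     # Bland tie-break
      res <- pivot(tab, basis, prow, pcol)
      tab <- res$tab; basis <- res$basis
      z <- z - z[pcol] * tab[prow, seq_along(z)]
    }
    list(tab = tab, basis = basis, z = z, status = "optimal")
  }

  # phase 1
  cost1 <- c(rep(0, N), rep(1, nart))
  allowed1 <- rep(TRUE, N + nart)
  r1 <- run_simplex(full, basis, cost1, allowed1)
  full <- r1$tab; basis <- r1$basis
  p1 <- sum(full[basis > N, rhs_col])
  art_basic <- which(basis > N)
  if (length(art_basic)) p1 <- sum(full[art_basic, rhs_col]) else p1 <- 0
  if (p1 > 1e-7) return(list(status = "infeasible", objective = NA_real_, x = NULL))

  # drive remaining basic artificials out; rows where that is impossible are
  # redundant (all-zero over structural columns) and can safely stay
  for (i in which(basis > N)) {
    cand <- which(abs(full[i, seq_len(N)]) > tol)
    if (length(cand)) {
      res <- pivot(full, basis, i, cand[1L])
      full <- res$tab
      basis <- res$basis
    }
  }

  # phase 2: artificial columns may no longer enter
  cost2 <- c(cobj, rep(0, nv), rep(0, nart))
  allowed2 <- c(rep(TRUE, N), rep(FALSE, nart))
  r2 <- run_simplex(full, basis, cost2, allowed2)
  if (r2$status == "unbounded")
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  full <- r2$tab; basis <- r2$basis

  xshift <- numeric(N)
  inb <- basis <= N
  xshift[basis[inb]] <- full[inb, rhs_col]
  xall <- xshift[seq_len(nv)] + clow
  x <- xall[seq_len(n)]

  # artificial-box detection => genuinely unbounded direction was used
  hit_hi <- inf_ub & (x > big * 0.999)
  hit_lo <- inf_lb & (x < -big * 0.999)
  if (any(hit_hi) || any(hit_lo)) {
    relevant <- (hit_hi & cvec < -tol) | (hit_lo & cvec > tol)
    if (any(relevant))
      return(list(status = "unbounded", objective = NA_real_, x = NULL))
  }
  objv <- sum(obj * x)
  list(status = "optimal", objective = objv, x = x)
}
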