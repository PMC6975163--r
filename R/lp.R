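# Dense two-phase simplex for small bounded linear programs.
#
# Flux balance problems on curated-scale test networks are tiny (tens of
# variables), so a dense full-tableau method is both adequate and easy to
# audit. Variables must have finite bounds, which holds for constraint-based
# metabolic models where the conventional default bounds are +/-1000
# mmol/gDW/hr.

#' Solve a bounded linear program
#'
#' Minimizes (or maximizes) \code{obj \%*\% x} subject to \code{A \%*\% x = rhs}
#' and \code{lb <= x <= ub}, using a two-phase dense simplex method. All
#' bounds must be finite.
#'
#' @param obj numeric objective coefficient vector (length n).
#' @param A constraint matrix (m x n), equality constraints only.
#' @param rhs right-hand side vector (length m).
#' @param lb,ub finite lower/upper variable bounds (length n).
#' @param sense "min" or "max".
#' @param tol pivot/feasibility tolerance.
#' @param max_iter simplex iteration cap.
#'
#' @return list with \code{status} ("optimal", "infeasible" or "unbounded"),
#'   \code{x} (solution vector, NA unless optimal) and \code{objective}.
#' @keywords internal
lp_solve <- function(obj, A, rhs, lb, ub, sense = c("min", "max"),
                     tol = 1e-9, max_iter = 20000L) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(lb) == n,
            length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_solve requires finite variable bounds")
  if (any(lb > ub + tol))
    stop("lp_solve: lower bound exceeds upper bound")

  cvec <- if (sense == "max") -obj else obj

  # Eliminate fixed variables (lb == ub), e.g. knocked-out reactions.
  fixed <- (ub - lb) <= tol
  x_full <- numeric(n)
  x_full[fixed] <- lb[fixed]
  const_obj <- sum(cvec[fixed] * lb[fixed])
  keep <- which(!fixed)
  if (length(keep) == 0L) {
    feas <- all(abs(A %*% x_full - rhs) <= 1e-7)
    return(list(status = if (feas) "optimal" else "infeasible",
                x = if (feas) x_full else rep(NA_real_, n),
                objective = if (feas) {
                  if (sense == "max") -const_obj else const_obj
                } else NA_real_))
  }
  rhs2 <- rhs - A %*% x_full
  A2 <- A[, keep, drop = FALSE]
  lb2 <- lb[keep]; ub2 <- ub[keep]; c2 <- cvec[keep]
  nk <- length(keep)

  # Shift to 0 <= y <= u, then add explicit bound rows y_i + s_i = u_i.
  u <- ub2 - lb2
  b_struct <- as.numeric(rhs2 - A2 %*% lb2)
  flip <- b_struct < 0
  A2[flip, ] <- -A2[flip, , drop = FALSE]
  b_struct[flip] <- -b_struct[flip]

  nrow_t <- m + nk
  ncol_real <- nk + nk              # y variables then bound slacks
  n_art <- m
  # Tableau columns: y | s | artificials | rhs
  T_ <- matrix(0, nrow_t, ncol_real + n_art + 1L)
  if (m > 0L) {
    T_[seq_len(m), seq_len(nk)] <- A2
    T_[cbind(seq_len(m), ncol_real + seq_len(m))] <- 1
    T_[seq_len(m), ncol_real + n_art + 1L] <- b_struct
  }
  bound_rows <- m + seq_len(nk)
  T_[cbind(bound_rows, seq_len(nk))] <- 1
  T_[cbind(bound_rows, nk + seq_len(nk))] <- 1
  T_[bound_rows, ncol_real + n_art + 1L] <- u

  basis <- c(ncol_real + seq_len(m), nk + seq_len(nk))
  rhs_col <- ncol_real + n_art + 1L

  run_phase <- function(T_, basis, costs, allowed, max_iter, tol) {
    iter <- 0L
    bland_after <- 4L * (nrow(T_) + length(allowed))
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) stop("lp_solve: iteration limit reached")
      cB <- costs[basis]
      # reduced costs over allowed columns
      red <- costs[allowed] - as.numeric(crossprod(cB, T_[, allowed, drop = FALSE]))
      cand <- which(red < -tol)
      if (length(cand) == 0L)
        return(list(T_ = T_, basis = basis, status = "optimal"))
      if (iter > bland_after) {
        jj <- cand[1L]                       # Bland's rule
      } else {
        jj <- cand[which.min(red[cand])]     # Dantzig rule
      }
      j <- allowed[jj]
      col <- T_[, j]
      pos <- which(col > tol)
      if (length(pos) == 0L)
        return(list(T_ = T_, basis = basis, status = "unbounded"))
      ratios <- T_[pos, rhs_col] / col[pos]
      rmin <- min(ratios)
      tie <- pos[ratios <= rmin + tol]
      i <- tie[which.min(basis[tie])]
      # pivot on (i, j)
      piv <- T_[i, j]
      T_[i, ] <- T_[i, ] / piv
      other <- setdiff(seq_len(nrow(T_)), i)
      T_[other, ] <- T_[other, ] - outer(T_[other, j], T_[i, ])
      T_[other, j] <- 0
      basis[i] <- j
      T_[T_[, rhs_col] < 0 & T_[, rhs_col] > -tol, rhs_col] <- 0
    }
  }

  # Phase 1: minimize sum of artificials.
  costs1 <- c(rep(0, ncol_real), rep(1, n_art), 0)
  allowed1 <- seq_len(ncol_real + n_art)
  ph1 <- run_phase(T_, basis, costs1, allowed1, max_iter, tol)
  T_ <- ph1$T_; basis <- ph1$basis
  phase1_obj <- sum(T_[basis > ncol_real, rhs_col])
  if (phase1_obj > 1e-7) {
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objective = NA_real_))
  }
  # Drive lingering artificials out of the basis (degenerate rows).
  drop_rows <- integer(0)
  for (i in which(basis > ncol_real)) {
    cols <- which(abs(T_[i, seq_len(ncol_real)]) > tol)
    if (length(cols) == 0L) {
      drop_rows <- c(drop_rows, i)
    } else {
      j <- cols[1L]
      piv <- T_[i, j]
      T_[i, ] <- T_[i, ] / piv
      other <- setdiff(seq_len(nrow(T_)), i)
      T_[other, ] <- T_[other, ] - outer(T_[other, j], T_[i, ])
      T_[other, j] <- 0
      basis[i] <- j
    }
  }
  if (length(drop_rows) > 0L) {
    T_ <- T_[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }

  # Phase 2 over real columns only.
  costs2 <- c(c2, rep(0, nk), rep(0, n_art), 0)
  allowed2 <- seq_len(ncol_real)
  ph2 <- run_phase(T_, basis, costs2, allowed2, max_iter, tol)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = rep(NA_real_, n),
                objective = NA_real_))
  }
  T_ <- ph2$T_; basis <- ph2$basis
  yval <- numeric(ncol_real)
  in_y <- basis <= ncol_real
  yval[basis[in_y]] <- T_[in_y, rhs_col]
  x_full[keep] <- yval[seq_len(nk)] + lb2
  objective <- sum(cvec * x_full)
  if (sense == "max") objective <- -objective
  list(status = "optimal", x = x_full, objective = objective)
}
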