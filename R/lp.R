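# Dense two-phase simplex for small formulation problems:
#   min  c'x   s.t.  A x {=, <=, >=} b,  x >= 0
# Problems here have <= ~20 variables and <= ~10 rows, so a full-tableau
# implementation with Bland's anti-cycling rule is simple and exact enough.

#' Solve a small linear program
#'
#' Two-phase primal simplex over the standard form with slack and artificial
#' variables.  Intended for the diet-formulation systems (a handful of rows,
#' tens of variables); not a general sparse LP code.
#'
#' @param obj objective coefficients (minimised).
#' @param A constraint matrix.
#' @param sense character vector per row: `"="`, `"<="` or `">="`.
#' @param b right-hand side.
#' @param tol pivot / feasibility tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x`, `value`, and for infeasible systems `violated`, the row names whose
#'   artificial variables remain positive.
#' @export
solve_lp <- function(obj, A, sense, b, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(sense) == m)
  rown <- rownames(A)
  if (is.null(rown)) rown <- paste0("r", seq_len(m))

  # slack columns
  slack_of <- which(sense != "=")
  S <- matrix(0, m, length(slack_of))
  for (k in seq_along(slack_of)) S[slack_of[k], k] <- if (sense[slack_of[k]] == "<=") 1 else -1
  Afull <- cbind(A, S)
  # normalise b >= 0
  neg <- b < 0
  Afull[neg, ] <- -Afull[neg, , drop = FALSE]
  b2 <- ifelse(neg, -b, b)
  # artificials, one per row
  Afull <- cbind(Afull, diag(m))
  ntot <- ncol(Afull)
  art <- (ntot - m + 1):ntot
  basis <- art

  res1 <- simplex_core(Afull, b2, c(rep(0, ntot - m), rep(1, m)), basis, tol)
  if (res1$status == "unbounded") return(list(status = "infeasible", violated = rown))
  Afull <- res1$A; b2 <- res1$b; basis <- res1$basis
  if (res1$value > 1e-7) {
    bad <- which(basis %in% art & b2 > 1e-7)
    return(list(status = "infeasible", violated = rown[bad], phase1 = res1$value))
  }
  # drive remaining zero-level artificials out of the basis
  keep_rows <- rep(TRUE, m)
  for (i in seq_len(m)) {
    if (basis[i] %in% art) {
      piv <- which(abs(Afull[i, seq_len(ntot - m)]) > tol)
      if (length(piv)) {
        pv <- do_pivot(Afull, b2, i, piv[1])
        Afull <- pv$A; b2 <- pv$b
        basis[i] <- piv[1]
      } else keep_rows[i] <- FALSE
    }
  }
  Afull <- Afull[keep_rows, , drop = FALSE]
  b2 <- b2[keep_rows]
  basis <- basis[keep_rows]

  # phase 2: artificials may not re-enter the basis
  cost2 <- c(obj, rep(0, ntot - n))
  allowed <- seq_len(ntot - m)
  res2 <- simplex_core(Afull, b2, cost2, basis, tol, allowed = allowed)
  if (res2$status == "unbounded") return(list(status = "unbounded"))
  x <- numeric(ntot)
  x[res2$basis] <- res2$b
  xx <- x[seq_len(n)]
  names(xx) <- colnames(A)
  list(status = "optimal", x = xx, value = sum(obj * xx))
}

simplex_core <- function(A, b, cost, basis, tol, allowed = seq_len(ncol(A)), maxit = 20000L) {
  for (it in seq_len(maxit)) {
    r <- cost - as.numeric(cost[basis] %*% A)
    cand <- allowed[r[allowed] < -tol]
    if (!length(cand)) {
      return(list(status = "optimal", A = A, b = b, basis = basis,
                  value = sum(cost[basis] * b)))
    }
    j <- min(cand)                       # Bland's rule
    col <- A[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded"))
    ratio <- b[pos] / col[pos]
    i <- pos[ratio == min(ratio)]
    if (length(i) > 1) i <- i[which.min(basis[i])]
    pv <- do_pivot(A, b, i, j)
    A <- pv$A; b <- pv$b
    basis[i] <- j
  }
  abort("simplex iteration limit reached", class = "porkopt_numerical_error")
}

do_pivot <- function(A, b, i, j) {
  piv <- A[i, j]
  A[i, ] <- A[i, ] / piv
  b[i] <- b[i] / piv
  others <- setdiff(seq_len(nrow(A)), i)
  if (length(others)) {
    f <- A[others, j]
    A[others, ] <- A[others, , drop = FALSE] - outer(f, A[i, ])
    b[others] <- b[others] - f * b[i]
  }
  list(A = A, b = b)
}
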