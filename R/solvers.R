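# Internal LP/QP backends shared by all constraint-based programs.
#
# Linear programs go through a two-phase dense tableau simplex implemented
# below (Dantzig pricing with a Bland's-rule anti-cycling fallback); flux
# LPs are small (tens of reactions) but frequently degenerate, which rules
# out the fragile textbook implementations. Quadratic programs go through
# quadprog::solve.QP (Goldfarb-Idnani dual active set). All flux bounds in
# this package are finite, so the shift to x >= 0 is always defined.

# Drop linearly dependent rows of an equality system A v = b.
# quadprog rejects rank-deficient constraint sets; redundant steady-state
# rows are common (mass-consistent networks have dependent metabolite rows).
.reduce_equalities <- function(A, b, tol = 1e-10) {
  if (is.null(A) || nrow(A) == 0L) return(list(A = A, b = b))
  qrA <- qr(t(A), tol = tol)
  keep <- sort(qrA$pivot[seq_len(qrA$rank)])
  list(A = A[keep, , drop = FALSE], b = b[keep])
}

# Primal tableau simplex on standard form  min c'x  s.t.  A x = b (b >= 0),
# x >= 0. Dantzig pricing, switching to Bland's rule after a stall budget so
# degenerate problems cannot cycle. Returns list(status, x, value).
.simplex_core <- function(c_, A, b, basis, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  iter <- 0L; max_iter <- 200L * (m + n); bland_after <- 10L * (m + n)
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) return(list(status = "maxiter"))
    cb <- c_[basis]
    # reduced costs r = c - A' y with y' = cb' B^{-1}; tableau form: A is kept
    # as B^{-1} A throughout, b as B^{-1} b, so r = c - cb' A.
    r <- c_ - as.numeric(crossprod(A, cb))
    r[basis] <- 0
    if (iter > bland_after) {
      j <- which(r < -tol)[1]
    } else {
      j <- which.min(r)
      if (length(j) && r[j] >= -tol) j <- NA_integer_
    }
    if (is.na(j) || !length(j)) {
      x <- numeric(n); x[basis] <- b
      return(list(status = "optimal", x = x, basis = basis,
                  value = sum(c_ * x)))
    }
    col <- A[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded"))
    ratios <- b[pos] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol]
    i <- cand[which.min(basis[cand])]             # Bland tie-break on leaving var
    # pivot on (i, j)
    piv <- A[i, j]
    A[i, ] <- A[i, ] / piv; b[i] <- b[i] / piv
    other <- setdiff(seq_len(m), i)
    if (length(other)) {
      f <- A[other, j]
      A[other, ] <- A[other, , drop = FALSE] - outer(f, A[i, ])
      b[other] <- b[other] - f * b[i]
    }
    b[b < 0 & b > -1e-11] <- 0
    basis[i] <- j
  }
}

# Two-phase wrapper on standard form.
.simplex_two_phase <- function(c_, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg]
  # phase 1: artificials
  A1 <- cbind(A, diag(m))
  c1 <- c(numeric(n), rep(1, m))
  ph1 <- .simplex_core(c1, A1, b, basis = n + seq_len(m), tol = tol)
  if (ph1$status != "optimal" || ph1$value > 1e-7 * max(1, max(abs(b))))
    return(list(status = "infeasible"))
  basis <- ph1$basis
  # rebuild the tableau for phase 2: drive artificials out or drop their rows
  Afull <- A1
  xb <- ph1$x
  # recompute tableau in terms of the final basis
  B <- Afull[, basis, drop = FALSE]
  Binv <- tryCatch(solve(B), error = function(e) NULL)
  if (is.null(Binv)) {
    # degenerate basis with redundant rows: drop dependent rows
    qrB <- qr(B)
    keep <- seq_len(m) %in% qrB$pivot[seq_len(qrB$rank)]
    return(.simplex_two_phase(c_, A[keep, , drop = FALSE], b[keep], tol))
  }
  T2 <- Binv %*% A
  b2 <- as.numeric(Binv %*% b)
  art <- which(basis > n)
  if (length(art)) {
    # pivot artificials out where a structural column is available
    for (i in art) {
      row <- T2[i, ]
      j <- which(abs(row) > 1e-7 & seq_len(n) != basis[i])[1]
      if (!is.na(j)) {
        piv <- T2[i, j]
        T2[i, ] <- T2[i, ] / piv; b2[i] <- b2[i] / piv
        other <- setdiff(seq_len(m), i)
        f <- T2[other, j]
        T2[other, ] <- T2[other, , drop = FALSE] - outer(f, T2[i, ])
        b2[other] <- b2[other] - f * b2[i]
        basis[i] <- j
      }
    }
    still <- which(basis > n)
    if (length(still)) {                          # redundant rows: drop
      keep <- setdiff(seq_len(m), still)
      return(.simplex_two_phase(c_, A[keep, , drop = FALSE], b[keep], tol))
    }
  }
  b2[b2 < 0 & b2 > -1e-9] <- 0
  .simplex_core(c_, T2, b2, basis = basis, tol = tol)
}

# Solve  max/min  obj'v  s.t.  Aeq v = beq, G v >= h, lb <= v <= ub.
# Returns list(status, v, value). status: "optimal", "infeasible", "unbounded".
.solve_lp <- function(obj, Aeq = NULL, beq = NULL, G = NULL, h = NULL,
                      lb, ub, maximize = TRUE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("LP backend requires finite bounds on every reaction", call. = FALSE)

  red <- .reduce_equalities(Aeq, beq)
  Aeq <- red$A; beq <- red$b

  # shift x = v - lb (x >= 0); add slacks for G x >= h and surpluses for
  # x <= u. Standard-form variable layout: [x, s_ineq, s_ub].
  n_ineq <- if (is.null(G)) 0L else nrow(G)
  n_eq <- if (is.null(Aeq)) 0L else nrow(Aeq)
  u <- ub - lb
  rows <- list(); rhs <- numeric(0)
  width <- n + n_ineq + n
  if (n_eq) {
    A_eq <- cbind(Aeq, matrix(0, n_eq, n_ineq + n))
    rows <- c(rows, list(A_eq)); rhs <- c(rhs, beq - as.numeric(Aeq %*% lb))
  }
  if (n_ineq) {
    A_in <- cbind(G, -diag(n_ineq), matrix(0, n_ineq, n))
    rows <- c(rows, list(A_in)); rhs <- c(rhs, h - as.numeric(G %*% lb))
  }
  A_ub <- cbind(diag(n), matrix(0, n, n_ineq), diag(n))
  rows <- c(rows, list(A_ub)); rhs <- c(rhs, u)
  A <- do.call(rbind, rows)
  c_ <- c(if (maximize) -obj else obj, numeric(n_ineq + n))

  res <- .simplex_two_phase(c_, A, rhs)
  if (res$status == "infeasible")
    return(list(status = "infeasible", v = NULL, value = NA_real_))
  if (res$status != "optimal")
    return(list(status = "unbounded", v = NULL, value = NA_real_))
  v <- res$x[seq_len(n)] + lb
  list(status = "optimal", v = v, value = sum(obj * v))
}

# Solve  min  sum_i w_i (v_i - g_i)^2
#        s.t. Aeq v = beq, G v >= h, lb <= v <= ub.
# Reactions with w_i = 0 receive a negligible ridge toward zero so the
# Hessian is strictly positive definite (quadprog requirement); this acts as
# a deterministic tie-break among equivalent optima and perturbs weighted
# coordinates far below reporting tolerance.
.solve_qp <- function(w, g, Aeq = NULL, beq = NULL, G = NULL, h = NULL,
                      lb, ub) {
  n <- length(w)
  stopifnot(length(g) == n, length(lb) == n, length(ub) == n)
  wpos <- w[w > 0]
  if (length(wpos) == 0L) stop("QP objective has no weighted reaction", call. = FALSE)
  ridge <- 1e-8 * min(wpos)
  w2 <- ifelse(w > 0, w, ridge)
  g2 <- ifelse(w > 0, g, 0)
  sc <- mean(w2)                                   # objective scale invariance
  w2 <- w2 / sc

  red <- .reduce_equalities(Aeq, beq)
  Aeq <- red$A; beq <- red$b

  Amat <- diag(n); bvec <- lb                      # v >= lb
  Amat <- rbind(Amat, -diag(n)); bvec <- c(bvec, -ub)
  if (!is.null(G) && nrow(G) > 0L) { Amat <- rbind(G, Amat); bvec <- c(h, bvec) }
  meq <- 0L
  if (!is.null(Aeq) && nrow(Aeq) > 0L) {
    Amat <- rbind(Aeq, Amat); bvec <- c(beq, bvec); meq <- nrow(Aeq)
  }

  qp_try <- function(bv) tryCatch(
    quadprog::solve.QP(Dmat = diag(2 * w2, n), dvec = 2 * w2 * g2,
                       Amat = t(Amat), bvec = bv, meq = meq),
    error = function(e) e)
  sol <- qp_try(bvec)
  if (inherits(sol, "error") &&
      grepl("constraints are inconsistent", conditionMessage(sol))) {
    # Goldfarb-Idnani rejects degenerate vertices (more active constraints
    # than variables); a graded relaxation of the inequality right-hand
    # sides breaks the ties while moving the solution far below tolerance
    n_ineq <- length(bvec) - meq
    for (scale in c(1e-9, 1e-7)) {
      bv <- bvec
      bv[meq + seq_len(n_ineq)] <- bv[meq + seq_len(n_ineq)] -
        scale * seq_len(n_ineq)
      sol <- qp_try(bv)
      if (!inherits(sol, "error")) break
    }
  }
  if (inherits(sol, "error")) {
    msg <- conditionMessage(sol)
    if (grepl("constraints are inconsistent", msg)) {
      # decide feasibility honestly with an LP phase-1 check
      feas <- .solve_lp(numeric(n), Aeq = Aeq, beq = beq,
                        G = if (is.null(G)) NULL else G, h = h,
                        lb = lb, ub = ub, maximize = FALSE)
      status <- if (feas$status == "infeasible") "infeasible" else "error"
    } else status <- "error"
    return(list(status = status, v = NULL, objective = NA_real_, message = msg))
  }
  v <- sol$solution
  obj <- sum(w[w > 0] * (v[w > 0] - g[w > 0])^2)   # report the unridged objective
  list(status = "optimal", v = v, objective = obj, message = "")
}

# Linear constraint fragments ------------------------------------------------

# Interval ratio constraints  lo * v_den <= v_num <= hi * v_den  as G v >= h.
.ratio_interval_rows <- function(n, i_num, i_den, lo, hi) {
  r1 <- numeric(n); r1[i_num] <- 1;  r1[i_den] <- -lo   # v_num - lo v_den >= 0
  r2 <- numeric(n); r2[i_num] <- -1; r2[i_den] <- hi    # hi v_den - v_num >= 0
  list(G = rbind(r1, r2), h = c(0, 0))
}

# Fixed ratio  v_num = r * v_den, optionally with two-sided slack eps.
.ratio_fixed_rows <- function(n, i_num, i_den, r, eps = 0) {
  row <- numeric(n); row[i_num] <- 1; row[i_den] <- -r
  if (eps <= 0) return(list(Aeq = rbind(row), beq = 0, G = NULL, h = NULL))
  list(Aeq = NULL, beq = NULL, G = rbind(row, -row), h = c(-eps, -eps))
}

# Two-sided relative band  target*(1-eps) <= v_i <= target*(1+eps) as G v >= h.
# Handles negative targets (endpoints swap).
.band_rows <- function(n, i, target, eps) {
  e1 <- target * (1 - eps); e2 <- target * (1 + eps)
  lo <- min(e1, e2); hi <- max(e1, e2)
  r1 <- numeric(n); r1[i] <- 1
  list(G = rbind(r1, -r1), h = c(lo, -hi))
}

.stack_rows <- function(...) {
  parts <- Filter(Negate(is.null), list(...))
  G <- do.call(rbind, lapply(parts, `[[`, "G"))
  h <- unlist(lapply(parts, `[[`, "h"), use.names = FALSE)
  Aeq <- do.call(rbind, lapply(parts, function(p) p$Aeq))
  beq <- unlist(lapply(parts, function(p) p$beq), use.names = FALSE)
  list(G = G, h = h, Aeq = Aeq, beq = beq)
}
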