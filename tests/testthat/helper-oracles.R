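# Independent brute-force oracles for the LP/QP backends. These never call
# the package's solvers: LPs are solved by vertex enumeration, QPs by dense
# KKT solves over enumerated active sets.

# Collect all constraints of a flux program in the common form
#   Aeq v = beq (equalities),  Aineq v >= bineq (inequalities incl. bounds).
oracle_constraints <- function(model, ratios = NULL, ratio_eps = 0,
                               extra_eq = NULL, extra_ineq = NULL) {
  n <- length(model$reaction_ids)
  Aeq <- model$S; beq <- numeric(nrow(model$S))
  Aineq <- rbind(diag(n), -diag(n))
  bineq <- c(model$lb, -model$ub)
  tagi <- function(tag) match(model$tags[[tag]], model$reaction_ids)
  add_pair <- function(num, den, r) {
    if (!all(c(num, den) %in% names(model$tags))) return()
    i <- tagi(num); j <- tagi(den)
    if (length(r) == 1L) {
      row <- numeric(n); row[i] <- 1; row[j] <- -r
      if (ratio_eps > 0) {
        Aineq <<- rbind(Aineq, row, -row); bineq <<- c(bineq, -ratio_eps, -ratio_eps)
      } else {
        Aeq <<- rbind(Aeq, row); beq <<- c(beq, 0)
      }
    } else {
      r1 <- numeric(n); r1[i] <- 1; r1[j] <- -r[1]
      r2 <- numeric(n); r2[i] <- -1; r2[j] <- r[2]
      Aineq <<- rbind(Aineq, r1, r2); bineq <<- c(bineq, 0, 0)
    }
  }
  if (!is.null(ratios)) {
    add_pair("carboxylation", "oxygenation", ratios$carb_oxy)
    add_pair("starch_synthesis", "sucrose_synthesis", ratios$starch_sucrose)
  }
  if (!is.null(extra_eq)) { Aeq <- rbind(Aeq, extra_eq$A); beq <- c(beq, extra_eq$b) }
  if (!is.null(extra_ineq)) {
    Aineq <- rbind(Aineq, extra_ineq$A); bineq <- c(bineq, extra_ineq$b)
  }
  list(Aeq = Aeq, beq = beq, Aineq = Aineq, bineq = bineq)
}

# Vertex enumeration LP oracle: max/min obj'v over the constraint polytope.
# Tries every choice of active inequalities completing the equality system to
# a square solvable system; keeps the feasible vertex with the best objective.
oracle_lp <- function(obj, cons, maximize = TRUE, tol = 1e-7) {
  n <- length(obj)
  red <- netgs:::.reduce_equalities(cons$Aeq, cons$beq)
  Aeq <- red$A; beq <- red$b
  k <- n - nrow(Aeq)
  m <- nrow(cons$Aineq)
  best <- NULL; best_val <- if (maximize) -Inf else Inf
  feasible <- function(v) {
    max(abs(cons$Aeq %*% v - cons$beq)) < tol &&
      all(cons$Aineq %*% v - cons$bineq > -tol)
  }
  if (k == 0) {
    v <- tryCatch(solve(Aeq, beq), error = function(e) NULL)
    if (!is.null(v) && feasible(v)) { best <- v; best_val <- sum(obj * v) }
  } else {
    for (idx in utils::combn(m, k, simplify = FALSE)) {
      A <- rbind(Aeq, cons$Aineq[idx, , drop = FALSE])
      b <- c(beq, cons$bineq[idx])
      v <- tryCatch(solve(A, b), error = function(e) NULL)
      if (is.null(v) || !feasible(v)) next
      val <- sum(obj * v)
      if ((maximize && val > best_val + 1e-12) ||
          (!maximize && val < best_val - 1e-12)) {
        best <- v; best_val <- val
      }
    }
  }
  if (is.null(best)) return(list(status = "infeasible"))
  list(status = "optimal", v = unname(best), value = best_val)
}

# Dense KKT QP oracle for min sum_i w_i (v_i - g_i)^2 over the same
# constraint form. Applies the identical negligible ridge the package's
# program definition uses for zero-weight coordinates, then enumerates
# active sets: for each subset of inequalities treated as equalities, solves
# the KKT system and accepts iff primal feasible and multipliers of active
# inequalities are non-negative. The first accepted point is the global
# optimum (strictly convex program).
oracle_qp <- function(w, g, cons, tol = 1e-7) {
  n <- length(w)
  wpos <- w[w > 0]
  ridge <- 1e-8 * min(wpos)
  w2 <- ifelse(w > 0, w, ridge)
  g2 <- ifelse(w > 0, g, 0)
  red <- netgs:::.reduce_equalities(cons$Aeq, cons$beq)
  Aeq <- red$A; beq <- red$b
  m <- nrow(cons$Aineq)
  solve_kkt <- function(act) {
    A <- rbind(Aeq, cons$Aineq[act, , drop = FALSE])
    b <- c(beq, cons$bineq[act])
    # stationarity 2W(v - g) = A' lambda, written as [2W, -A'; A, 0]; with
    # constraints a'v >= b the multipliers of active inequalities must be
    # non-negative at a minimum
    K <- rbind(cbind(diag(2 * w2, n), -t(A)),
               cbind(A, matrix(0, nrow(A), nrow(A))))
    rhs <- c(2 * w2 * g2, b)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    v <- sol[seq_len(n)]
    lam <- sol[-seq_len(n)]
    mu <- if (length(act)) lam[nrow(Aeq) + seq_along(act)] else numeric(0)
    if (any(mu < -tol)) return(NULL)
    if (max(abs(cons$Aeq %*% v - cons$beq)) > tol) return(NULL)
    if (any(cons$Aineq %*% v - cons$bineq < -tol)) return(NULL)
    v
  }
  for (k in 0:min(m, n)) {
    sets <- if (k == 0) list(integer(0)) else utils::combn(m, k, simplify = FALSE)
    for (act in sets) {
      v <- solve_kkt(act)
      if (!is.null(v))
        return(list(status = "optimal", v = unname(v),
                    objective = sum(w[w > 0] * (v[w > 0] - g[w > 0])^2)))
    }
  }
  list(status = "infeasible")
}

# rrBLUP closed-form ridge oracle for fixed shrinkage lambda = se2/su2:
# u = (Z'Z + lambda I)^-1 Z' (y - X beta) with GLS beta.
oracle_ridge <- function(Z, y, lambda) {
  n <- nrow(Z)
  Vl <- solve(tcrossprod(Z) / lambda + diag(n))
  X <- matrix(1, n, 1)
  beta <- solve(crossprod(X, Vl %*% X), crossprod(X, Vl %*% y))
  u <- solve(crossprod(Z) + diag(lambda, ncol(Z)), crossprod(Z, y - X %*% beta))
  list(beta = as.numeric(beta), u = as.numeric(u))
}
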