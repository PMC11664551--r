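#' Dense two-phase simplex for small linear programs
#'
#' Optimizes \code{objective \%*\% x} over \code{x >= 0} subject to
#' \code{A x (dir) rhs} with \code{dir} entries \code{"<="}, \code{">="} or
#' \code{"=="}. Phase 1 drives artificial variables out via Bland's smallest-
#' index pivoting rule (which guarantees termination under degeneracy); phase
#' 2 optimizes the true objective. Intended for the package's small dense
#' programs (tens of variables and constraints), not large sparse ones.
#'
#' @param objective numeric objective vector (length n).
#' @param A constraint matrix (m x n).
#' @param dir character vector of constraint directions, length m.
#' @param rhs numeric right-hand sides, length m.
#' @param maximize maximize (TRUE) or minimize the objective.
#' @param tol pivot/feasibility tolerance (default 1e-9).
#' @return List with \code{status} (\code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}), \code{x} (length n, when optimal) and
#'   \code{value}.
#' @keywords internal
simplex_solve <- function(objective, A, dir, rhs, maximize = TRUE,
                          tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(objective) == n, length(dir) == m, length(rhs) == m,
            all(dir %in% c("<=", ">=", "==")))
  # normalize rows to rhs >= 0
  flip <- rhs < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  rhs[flip] <- -rhs[flip]
  dir[flip] <- ifelse(dir[flip] == "<=", ">=",
                      ifelse(dir[flip] == ">=", "<=", "=="))
  n_slack <- sum(dir != "==")
  n_art <- sum(dir != "<=")
  N <- n + n_slack + n_art
  Tb <- matrix(0, m, N)
  Tb[, seq_len(n)] <- A
  basis <- integer(m)
  js <- n; ja <- n + n_slack
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      js <- js + 1L; Tb[i, js] <- 1; basis[i] <- js
    } else if (dir[i] == ">=") {
      js <- js + 1L; Tb[i, js] <- -1
      ja <- ja + 1L; Tb[i, ja] <- 1; basis[i] <- ja
    } else {
      ja <- ja + 1L; Tb[i, ja] <- 1; basis[i] <- ja
    }
  }
  b <- rhs
  art_cols <- seq.int(n + n_slack + 1L, length.out = n_art)

  # one simplex phase: minimize cost over current tableau, Bland's rule
  run_phase <- function(cost, allowed) {
    repeat {
      cb <- cost[basis]
      red <- cost - drop(crossprod(Tb, cb))  # reduced costs (minimization)
      red[!allowed] <- 0
      enter_candidates <- which(red < -tol & allowed)
      if (length(enter_candidates) == 0) return("optimal")
      j <- enter_candidates[1L]              # Bland: smallest index
      col <- Tb[, j]
      pos <- which(col > tol)
      if (length(pos) == 0) return("unbounded")
      ratio <- b[pos] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      i <- cand[which.min(basis[cand])]      # Bland tie-break on basic index
      # pivot on (i, j)
      piv <- Tb[i, j]
      Tb[i, ] <<- Tb[i, ] / piv
      b[i] <<- b[i] / piv
      for (r in seq_len(m)) {
        if (r != i && abs(Tb[r, j]) > 0) {
          f <- Tb[r, j]
          Tb[r, ] <<- Tb[r, ] - f * Tb[i, ]
          b[r] <<- b[r] - f * b[i]
        }
      }
      b[abs(b) < tol] <<- 0
      basis[i] <<- j
    }
  }

  if (n_art > 0) {
    cost1 <- numeric(N)
    cost1[art_cols] <- 1
    st <- run_phase(cost1, allowed = rep(TRUE, N))
    if (st != "optimal" || sum(b[basis %in% art_cols]) > 1e-7)
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    # pivot lingering artificials (at zero) out of the basis where possible
    for (i in which(basis %in% art_cols)) {
      row <- Tb[i, seq_len(n + n_slack)]
      j <- which(abs(row) > tol)
      if (length(j) > 0) {
        j <- j[1L]
        piv <- Tb[i, j]
        Tb[i, ] <- Tb[i, ] / piv; b[i] <- b[i] / piv
        for (r in seq_len(m)) if (r != i && abs(Tb[r, j]) > 0) {
          f <- Tb[r, j]; Tb[r, ] <- Tb[r, ] - f * Tb[i, ]; b[r] <- b[r] - f * b[i]
        }
        basis[i] <- j
      }
    }
  }
  cost2 <- numeric(N)
  cost2[seq_len(n)] <- if (maximize) -objective else objective
  allowed <- rep(TRUE, N)
  allowed[art_cols] <- FALSE
  st <- run_phase(cost2, allowed)
  if (st == "unbounded")
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  x <- numeric(n)
  in_x <- basis <= n
  x[basis[in_x]] <- b[in_x]
  list(status = "optimal", x = x, value = sum(objective * x))
}
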