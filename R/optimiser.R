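# Dense two-phase primal simplex for small LPs:
#   min c'x  s.t.  A x (dir) b,  0 <= x <= ub
# dir is a vector of "<=", ">=", "=".  Bland's rule, so no cycling.
# Problems here have a handful of variables; no sparsity or scaling needed.
simplex_lp <- function(cvec, A, dir, rhs, ub = NULL, tol = 1e-9) {
  A <- as.matrix(A)
  n <- ncol(A)
  if (!is.null(ub)) {
    fin <- which(is.finite(ub))
    if (length(fin) > 0) {
      Aub <- matrix(0, length(fin), n)
      Aub[cbind(seq_along(fin), fin)] <- 1
      A <- rbind(A, Aub)
      dir <- c(dir, rep("<=", length(fin)))
      rhs <- c(rhs, ub[fin])
    }
  }
  m <- nrow(A)
  # normalise to nonnegative right-hand sides
  for (i in seq_len(m)) {
    if (rhs[i] < 0) {
      A[i, ] <- -A[i, ]
      rhs[i] <- -rhs[i]
      dir[i] <- switch(dir[i], "<=" = ">=", ">=" = "<=", "=" = "=")
    }
  }
  n_slack <- sum(dir != "=")
  n_art <- sum(dir != "<=")
  ncols <- n + n_slack + n_art
  T <- matrix(0, m, ncols)
  T[, seq_len(n)] <- A
  b <- rhs
  basis <- integer(m)
  si <- n
  ai <- n + n_slack
  art_cols <- integer(0)
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      si <- si + 1L
      T[i, si] <- 1
      basis[i] <- si
    } else if (dir[i] == ">=") {
      si <- si + 1L
      T[i, si] <- -1
      ai <- ai + 1L
      T[i, ai] <- 1
      basis[i] <- ai
      art_cols <- c(art_cols, ai)
    } else {
      ai <- ai + 1L
      T[i, ai] <- 1
      basis[i] <- ai
      art_cols <- c(art_cols, ai)
    }
  }

  run_phase <- function(T, b, basis, cost, allowed) {
    repeat {
      cb <- cost[basis]
      # reduced costs: c_j - cb' B^{-1} a_j; tableau is kept in basic form,
      # so B^{-1} a_j is just column j
      red <- cost - as.vector(cb %*% T)
      red[!allowed] <- Inf
      enter <- which(red < -tol)
      if (length(enter) == 0) break
      j <- min(enter)               # Bland's rule
      col <- T[, j]
      pos <- which(col > tol)
      if (length(pos) == 0) {
        return(list(status = "unbounded", T = T, b = b, basis = basis))
      }
      ratio <- b[pos] / col[pos]
      r <- pos[ratio == min(ratio)]
      r <- r[which.min(basis[r])]   # Bland tie-break on leaving variable
      piv <- T[r, j]
      T[r, ] <- T[r, ] / piv
      b[r] <- b[r] / piv
      for (i in seq_len(nrow(T))) {
        if (i != r && abs(T[i, j]) > 0) {
          b[i] <- b[i] - T[i, j] * b[r]
          T[i, ] <- T[i, ] - T[i, j] * T[r, ]
        }
      }
      basis[r] <- j
    }
    list(status = "optimal", T = T, b = b, basis = basis)
  }

  allowed <- rep(TRUE, ncols)
  if (n_art > 0) {
    cost1 <- numeric(ncols)
    cost1[art_cols] <- 1
    ph1 <- run_phase(T, b, basis, cost1, allowed)
    if (ph1$status != "optimal") return(list(status = "infeasible"))
    T <- ph1$T; b <- ph1$b; basis <- ph1$basis
    if (sum(b[basis %in% art_cols]) > tol * max(1, max(abs(rhs)))) {
      return(list(status = "infeasible"))
    }
    # pivot any degenerate artificial out of the basis where possible
    for (r in which(basis %in% art_cols)) {
      j <- which(abs(T[r, seq_len(n + n_slack)]) > tol)
      if (length(j) > 0) {
        j <- j[1]
        piv <- T[r, j]
        T[r, ] <- T[r, ] / piv
        b[r] <- b[r] / piv
        for (i in seq_len(nrow(T))) {
          if (i != r && abs(T[i, j]) > 0) {
            b[i] <- b[i] - T[i, j] * b[r]
            T[i, ] <- T[i, ] - T[i, j] * T[r, ]
          }
        }
        basis[r] <- j
      }
    }
    allowed[art_cols] <- FALSE
  }
  cost2 <- numeric(ncols)
  cost2[seq_len(n)] <- cvec
  ph2 <- run_phase(T, b, basis, cost2, allowed)
  if (ph2$status != "optimal") return(list(status = ph2$status))
  x <- numeric(n)
  in_x <- ph2$basis <= n
  x[ph2$basis[in_x]] <- ph2$b[in_x]
  list(status = "optimal", x = x, value = sum(cvec * x))
}

demand_minutes <- function(demand) {
  if (inherits(demand, "demand_vector")) demand$minutes
  else if (is.numeric(demand) && !is.null(names(demand))) demand
  else stop("demand must be a demand_vector or a named numeric vector")
}

make_workforce_result <- function(x, cadres, objective, status,
                                  rounding = "nearest") {
  wte <- stats::setNames(x, cadres)
  res <- structure(list(wte_continuous = wte,
                        wte_reported = stats::setNames(rep(NA_real_,
                                                           length(wte)),
                                                       cadres),
                        combined_total = NA_real_,
                        objective_value = objective,
                        status = status,
                        rounding = rounding),
                   class = "workforce_result")
  if (status == "optimal") res <- round_for_report(res, rounding)
  res
}

#' Minimise the workforce needed to meet assigned demand
#'
#' Solves the linear programme `min sum(x)` subject to
#' `H_g * x_g >= D_g` and `x_g >= 0`, where `D_g` are the annual demand
#' minutes assigned to cadre `g` and `H_g` its annual minutes per
#' whole-time equivalent.  Decision variables are continuous WTE; the
#' integers shown in reports come from [round_for_report()].  Optional
#' extensions (per-cadre supply ceilings, cost weights) are off by
#' default.  The solution is verified feasible before return; positive
#' demand on a zero-capacity cadre yields status `"infeasible"` rather
#' than an error.
#'
#' @param demand A `demand_vector` or named numeric vector of annual
#'   minutes by cadre.
#' @param capacities Capacities data frame (see [default_capacities()]) or
#'   named numeric vector of annual minutes per WTE.
#' @param upper_bounds Optional named numeric vector of maximum WTE per
#'   cadre.
#' @param cost Optional named numeric vector of objective weights per WTE
#'   (default 1 for every cadre).
#' @param rounding Reporting mode, `"nearest"` or `"ceil"`.
#' @param feas_tol Absolute feasibility tolerance in minutes.
#' @return An object of class `workforce_result` with elements
#'   `wte_continuous`, `wte_reported`, `combined_total`,
#'   `objective_value`, `status`.
#' @export
solve_lp <- function(demand, capacities, upper_bounds = NULL, cost = NULL,
                     rounding = c("nearest", "ceil"), feas_tol = 1e-6) {
  rounding <- match.arg(rounding)
  D <- demand_minutes(demand)
  H <- capacity_minutes(capacities)
  miss <- setdiff(names(D)[D > 0], names(H))
  if (length(miss) > 0) {
    stop("no capacity given for cadre(s) with positive demand: ",
         paste(miss, collapse = ", "))
  }
  cad <- names(D)
  H <- ifelse(cad %in% names(H), H[cad], 0)
  if (any(D < 0)) stop("demand minutes must be nonnegative")
  if (any(D > 0 & H <= 0)) {
    return(make_workforce_result(rep(NA_real_, length(D)), cad, NA_real_,
                                 "infeasible", rounding))
  }
  w <- rep(1, length(D))
  if (!is.null(cost)) w <- ifelse(cad %in% names(cost), cost[cad], 1)
  ub <- NULL
  if (!is.null(upper_bounds)) {
    ub <- ifelse(cad %in% names(upper_bounds), upper_bounds[cad], Inf)
  }
  # cadres with zero capacity (and hence zero demand) are fixed at 0 WTE
  act <- H > 0
  x <- numeric(length(D))
  if (any(act)) {
    sol <- simplex_lp(w[act], diag(H[act], nrow = sum(act)),
                      rep(">=", sum(act)), D[act],
                      ub = if (is.null(ub)) NULL else ub[act])
    if (sol$status != "optimal") {
      return(make_workforce_result(rep(NA_real_, length(D)), cad, NA_real_,
                                   sol$status, rounding))
    }
    x[act] <- sol$x
  }
  # post-solve verification that no capacity constraint is violated
  if (any(H * x < D - feas_tol)) {
    stop("internal error: solver returned an infeasible point")
  }
  make_workforce_result(x, cad, sum(w * x), "optimal", rounding)
}

#' Closed-form workforce requirement (verification oracle)
#'
#' With fixed delegation shares the programme separates by cadre, so the
#' optimum is simply `x_g = D_g / H_g` (0 where demand is 0).  Used as an
#' independent check on [solve_lp()].
#'
#' @inheritParams solve_lp
#' @return A `workforce_result`.
#' @export
closed_form_oracle <- function(demand, capacities,
                               rounding = c("nearest", "ceil")) {
  rounding <- match.arg(rounding)
  D <- demand_minutes(demand)
  H <- capacity_minutes(capacities)
  cad <- names(D)
  H <- ifelse(cad %in% names(H), H[cad], 0)
  if (any(D > 0 & H <= 0)) {
    return(make_workforce_result(rep(NA_real_, length(D)), cad, NA_real_,
                                 "infeasible", rounding))
  }
  x <- ifelse(D == 0, 0, D / H)
  make_workforce_result(x, cad, sum(x), "optimal", rounding)
}

#' Round continuous WTE for reporting
#'
#' Published workforce numbers are integers; the continuous optimum is
#' rounded per cadre (`"nearest"` rounds halves up, `"ceil"` always rounds
#' up) and the combined total is the sum of the rounded cadre values.
#'
#' @param result A solved `workforce_result`.
#' @param mode `"nearest"` or `"ceil"`.
#' @return The result with `wte_reported` and `combined_total` set.
#' @export
round_for_report <- function(result, mode = c("nearest", "ceil")) {
  mode <- match.arg(mode)
  stopifnot(inherits(result, "workforce_result"))
  if (result$status != "optimal") stop("cannot round an unsolved result")
  x <- result$wte_continuous
  result$wte_reported <- if (mode == "ceil") ceiling(x) else floor(x + 0.5)
  result$combined_total <- sum(result$wte_reported)
  result$rounding <- mode
  result
}

#' @export
print.workforce_result <- function(x, ...) {
  cat("<workforce_result> status: ", x$status, "\n", sep = "")
  if (x$status == "optimal") {
    df <- data.frame(cadre = names(x$wte_continuous),
                     wte_continuous = round(x$wte_continuous, 2),
                     wte_reported = x$wte_reported)
    print(df, row.names = FALSE)
    cat("combined total (reported): ", x$combined_total, "\n", sep = "")
  }
  invisible(x)
}
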