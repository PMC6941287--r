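# Flux balance analysis: max c'v subject to S v = 0, lb <= v <= ub.

# Resolve stage weight names (reaction ids or role names) to column indices.
.resolveStage <- function(network, stage) {
  ids <- network@reactions$id
  nm <- names(stage)
  viaRole <- nm %in% names(network@roles)
  nm[viaRole] <- network@roles[nm[viaRole]]
  idx <- match(nm, ids)
  if (anyNA(idx)) {
    stop("objective references unknown reaction(s)/role(s): ",
         paste(names(stage)[is.na(idx)], collapse = ", "))
  }
  cc <- numeric(length(ids))
  cc[idx] <- cc[idx] + as.numeric(stage)
  cc
}

.fbaResult <- function(network, status, stageValues = numeric(),
                       flux = NULL, support = character()) {
  roles <- network@roles
  named <- numeric()
  mu <- NA_real_
  fluxv <- numeric()
  if (!is.null(flux)) {
    fluxv <- stats::setNames(flux, network@reactions$id)
    if (length(roles)) named <- stats::setNames(fluxv[roles], names(roles))
    if ("biomass" %in% names(roles)) mu <- unname(fluxv[roles[["biomass"]]])
  }
  new("FBAResult", status = status, stageValues = stageValues, flux = fluxv,
      mu = mu, namedFluxes = named, unboundedSupport = support)
}

#' Single-objective flux balance analysis
#'
#' Maximises a linear objective over the steady-state flux polytope
#' `{v : S v = 0, lb <= v <= ub}`. The optimal *value* is the contract;
#' the returned flux vector is one vertex of a possibly non-unique optimal
#' face. With `tieBreak = "l1"` a second LP minimises the total flux
#' `||v||_1` at the fixed optimum, giving a reproducible representative.
#'
#' @param network a [StoichiometricNetwork-class].
#' @param objective an [ObjectiveSpec-class] with exactly one stage (see
#'   [solveLexicographic()] for several), or a named numeric vector.
#' @param scenario optional [FluxScenario-class]; its driven rates,
#'   overrides and (if `objective` is missing) objective are applied.
#' @param tieBreak `"none"` (default) or `"l1"`.
#' @return an [FBAResult-class]
#' @examples
#' net <- networkFromEquations(c(R1 = "-> A[c]", R2 = "A[c] -> B[c]",
#'                               R3 = "B[c] ->"))
#' net <- applyBounds(net, overrides = list(R1 = c(0, 5)))
#' solveFBA(net, c(R3 = 1))   # capped by the uptake: objective 5
#' @export
solveFBA <- function(network, objective = NULL, scenario = NULL,
                     tieBreak = c("none", "l1")) {
  tieBreak <- match.arg(tieBreak)
  if (is.numeric(objective)) objective <- new("ObjectiveSpec",
                                              stages = list(objective))
  if (is.null(objective) && !is.null(scenario)) objective <- scenario@objective
  if (is.null(objective)) stop("an objective is required")
  if (length(objective@stages) != 1L) {
    stop("solveFBA takes a single-stage objective; use solveLexicographic")
  }
  d <- .lpData(network, scenario)
  cc <- .resolveStage(d$network, objective@stages[[1]])
  m <- nrow(d$S)
  r <- .lpSolveBounded(cc, d$S, rep(0, m), d$lb, d$ub)
  if (r$status == "numerical") stop("LP solver failed numerically")
  if (r$status != "optimal") {
    sup <- if (length(r$support)) d$ids[as.integer(r$support)] else character()
    return(.fbaResult(d$network, r$status, support = sup))
  }
  x <- r$x
  if (tieBreak == "l1") x <- .l1Polish(d, list(cc), c(r$obj), x)
  .fbaResult(d$network, "optimal", stageValues = r$obj, flux = x)
}

#' Lexicographic (ordered multi-objective) flux balance analysis
#'
#' Solves the objective stages in order: stage 1 is plain FBA; each later
#' stage is maximised with every earlier stage's optimum anchored as an
#' equality constraint `c_k' v = z_k*` (at the solver's feasibility
#' tolerance, not a relaxed fraction), so stage-1 values always equal the
#' single-objective optimum. This is the reading of a combined objective
#' like "maximise growth and beta-carotene": growth first, pigment second
#' at unchanged growth. A weighted-sum alternative is available via
#' `mode = "weighted"` for sensitivity analysis.
#'
#' @param network a [StoichiometricNetwork-class].
#' @param objective an [ObjectiveSpec-class] (k stages) or list of named
#'   numeric vectors; defaults to the scenario's objective.
#' @param scenario optional [FluxScenario-class].
#' @param mode `"lexicographic"` (default) or `"weighted"`.
#' @param weights stage weights for `mode = "weighted"` (default all 1).
#' @param tieBreak `"none"` or `"l1"` (minimal total flux at fixed optima).
#' @return an [FBAResult-class]; `stageValues` has one entry per stage
#'   (for `mode = "weighted"`, the per-stage values recomputed from the
#'   single weighted optimum).
#' @export
solveLexicographic <- function(network, objective = NULL, scenario = NULL,
                               mode = c("lexicographic", "weighted"),
                               weights = NULL,
                               tieBreak = c("none", "l1")) {
  mode <- match.arg(mode)
  tieBreak <- match.arg(tieBreak)
  if (is.list(objective) && !is(objective, "ObjectiveSpec")) {
    objective <- new("ObjectiveSpec", stages = objective)
  }
  if (is.null(objective) && !is.null(scenario)) objective <- scenario@objective
  if (is.null(objective)) stop("an objective is required")
  d <- .lpData(network, scenario)
  stages <- lapply(objective@stages, .resolveStage, network = d$network)
  k <- length(stages)
  m0 <- nrow(d$S)
  n <- length(d$ids)

  if (mode == "weighted") {
    if (is.null(weights)) weights <- rep(1, k)
    cc <- Reduce(`+`, Map(`*`, stages, as.list(weights)))
    r <- .lpSolveBounded(cc, d$S, rep(0, m0), d$lb, d$ub)
    if (r$status == "numerical") stop("LP solver failed numerically")
    if (r$status != "optimal") {
      sup <- if (length(r$support)) d$ids[as.integer(r$support)] else character()
      return(.fbaResult(d$network, r$status, support = sup))
    }
    vals <- vapply(stages, function(ck) sum(ck * r$x), numeric(1))
    return(.fbaResult(d$network, "optimal", stageValues = vals, flux = r$x))
  }

  A <- d$S
  b <- rep(0, m0)
  vals <- numeric(0)
  x <- NULL
  for (i in seq_len(k)) {
    r <- .lpSolveBounded(stages[[i]], A, b, d$lb, d$ub)
    if (r$status == "numerical") stop("LP solver failed numerically")
    if (r$status != "optimal") {
      sup <- if (length(r$support)) d$ids[as.integer(r$support)] else character()
      return(.fbaResult(d$network, r$status, stageValues = vals, support = sup))
    }
    vals <- c(vals, r$obj)
    x <- r$x
    if (i < k) {             # anchor this stage's optimum as an equality
      A <- rbind(A, stages[[i]])
      b <- c(b, r$obj)
    }
  }
  if (tieBreak == "l1") x <- .l1Polish(d, stages, vals, x)
  .fbaResult(d$network, "optimal", stageValues = vals, flux = x)
}

# minimise ||v||_1 subject to S v = 0, bounds, and all stage optima fixed;
# standard split v = p - q with p, q >= 0 is avoided by exploiting the box:
# minimise sum of t_j with t_j >= v_j, t_j >= -v_j.
.l1Polish <- function(d, stages, vals, x0) {
  n <- length(d$ids)
  m0 <- nrow(d$S)
  A <- d$S
  b <- rep(0, m0)
  for (i in seq_along(stages)) {
    A <- rbind(A, stages[[i]])
    b <- c(b, vals[i])
  }
  # variables (v, t); t_j in [0, max(|lb|,|ub|)]; v_j - t_j <= 0 and
  # -v_j - t_j <= 0 become equalities with slack via extra bounded slacks.
  tmax <- pmax(abs(d$lb), abs(d$ub))
  nA <- nrow(A)
  Ax <- cbind(A, matrix(0, nA, 3 * n))
  # v_j - t_j + s1_j = 0, s1 in [-2*tmax, 0]; -v_j - t_j + s2_j = 0, s2 likewise
  r1 <- cbind(diag(n), -diag(n), diag(n), matrix(0, n, n))
  r2 <- cbind(-diag(n), -diag(n), matrix(0, n, n), diag(n))
  Afull <- rbind(Ax, r1, r2)
  bfull <- c(b, rep(0, 2 * n))
  lb <- c(d$lb, rep(0, n), -2 * tmax, -2 * tmax)
  ub <- c(d$ub, tmax, rep(0, n), rep(0, n))
  cc <- c(numeric(n), rep(-1, n), numeric(2 * n))   # maximise -sum t
  r <- .lpSolveBounded(cc, Afull, bfull, lb, ub)
  if (r$status == "optimal") r$x[seq_len(n)] else x0
}

#' Exhaustive vertex-enumeration oracle for small instances
#'
#' Independent verification path for the LP engine: enumerates every basic
#' solution of `{S v = 0, lb <= v <= ub}` by exhaustively choosing which
#' variables are basic (one set per combination of rank(S) columns) and at
#' which bound each nonbasic variable sits, then returns the best feasible
#' objective value. Because all flux bounds are finite the polytope is
#' bounded and its optimum is attained at such a basic solution. Refuses
#' instances with more than `maxReactions` reactions: this is a test
#' oracle, exponential by construction, not a solver.
#'
#' @param network a [StoichiometricNetwork-class].
#' @param objective single-stage [ObjectiveSpec-class] or named numeric.
#' @param scenario optional [FluxScenario-class].
#' @param maxReactions refusal threshold, default 12.
#' @param tol feasibility tolerance for accepting a basic solution.
#' @return list with `status` (`"optimal"`/`"infeasible"`) and `obj`
#'   (best objective value, `NA` when infeasible).
#' @export
enumerateVerticesOracle <- function(network, objective, scenario = NULL,
                                    maxReactions = 12, tol = 1e-7) {
  d <- .lpData(network, scenario)
  n <- length(d$ids)
  if (n > maxReactions) {
    stop(sprintf("refusing vertex enumeration on %d reactions (limit %d): test oracle only",
                 n, maxReactions))
  }
  if (is.numeric(objective)) objective <- new("ObjectiveSpec",
                                              stages = list(objective))
  cc <- .resolveStage(d$network, objective@stages[[1]])
  S <- d$S
  lb <- d$lb; ub <- d$ub
  if (nrow(S)) {
    qt <- qr(t(S))
    r <- qt$rank
    S <- S[sort(qt$pivot[seq_len(r)]), , drop = FALSE]
  }
  r <- nrow(S)
  best <- -Inf
  feasibleSeen <- FALSE
  scale <- max(1, abs(ub), abs(lb))
  consider <- function(v) {
    if (any(v < lb - tol * scale) || any(v > ub + tol * scale)) return()
    if (r && max(abs(S %*% v)) > tol * scale) return()
    feasibleSeen <<- TRUE
    val <- sum(cc * v)
    if (val > best) best <<- val
  }
  basicSets <- if (r == 0L) list(integer(0)) else
    utils::combn(n, r, simplify = FALSE)
  for (B in basicSets) {
    N <- setdiff(seq_len(n), B)
    SB <- S[, B, drop = FALSE]
    if (r && abs(det(SB)) < 1e-12) next
    # each nonbasic at lower or upper bound
    for (mask in seq_len(2^length(N)) - 1L) {
      pick <- as.logical(bitwAnd(mask, 2^(seq_along(N) - 1L)))
      vN <- ifelse(pick, ub[N], lb[N])
      v <- numeric(n)
      v[N] <- vN
      if (r) {
        rhs <- -S[, N, drop = FALSE] %*% vN
        vB <- tryCatch(solve(SB, rhs), error = function(e) NULL)
        if (is.null(vB)) next
        v[B] <- vB
      }
      consider(v)
    }
  }
  if (!feasibleSeen) list(status = "infeasible", obj = NA_real_)
  else list(status = "optimal", obj = best)
}
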