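# Feasibility and structural consistency diagnostics.

# Resolve a network + optional scenario into the LP data: balanced S,
# complete bounds, reaction ids. Bounds still NA after scenario application
# get the default policy.
.lpData <- function(network, scenario = NULL, policy = defaultBoundsPolicy()) {
  if (!is.null(scenario)) network <- applyScenario(network, scenario)
  network <- applyBounds(network, policy)
  S <- buildStoichiometricMatrix(network, warnOrphans = FALSE)
  list(network = network, S = S,
       lb = network@reactions$lower_bound,
       ub = network@reactions$upper_bound,
       ids = network@reactions$id)
}

#' Check feasibility of a flux scenario
#'
#' Solves the phase-1 linear program for `S v = 0` under the scenario's
#' bounds. If feasible, a witness flux vector is returned (it satisfies the
#' steady-state condition to within `|S v| <= 1e-9 * max(1, ||v||_inf)` per
#' metabolite and all bounds to within 1e-9). If infeasible, a deletion
#' filter (greedy one-at-a-time relaxation of reaction bound intervals)
#' localises an irreducible set of implicated bound constraints.
#'
#' @param network a [StoichiometricNetwork-class].
#' @param scenario optional [FluxScenario-class] applied before the check.
#' @return list of class `FeasibilityResult`: `feasible` (logical),
#'   `witness` (named flux vector or `NULL`), `infeasibleSubsystem`
#'   (character vector of implicated reaction ids, empty when feasible).
#' @examples
#' net <- networkFromEquations(c(R1 = "-> A[c]", R2 = "A[c] -> B[c]",
#'                               R3 = "B[c] ->"))
#' checkFeasibility(net)$feasible
#' @export
checkFeasibility <- function(network, scenario = NULL) {
  d <- .lpData(network, scenario)
  m <- nrow(d$S)
  r <- .lpSolveBounded(numeric(length(d$ids)), d$S, rep(0, m), d$lb, d$ub)
  if (r$status == "numerical") {
    stop("LP solver failed numerically; this is not a statement about feasibility")
  }
  if (r$status == "optimal") {
    witness <- stats::setNames(r$x, d$ids)
    return(structure(list(feasible = TRUE, witness = witness,
                          infeasibleSubsystem = character()),
                     class = "FeasibilityResult"))
  }
  # deletion filter over per-reaction bound intervals
  M <- 1e6
  lb <- d$lb; ub <- d$ub
  relaxed <- rep(FALSE, length(lb))
  implicated <- character()
  feasibleWith <- function(lbx, ubx) {
    rr <- .lpSolveBounded(numeric(length(lbx)), d$S, rep(0, m), lbx, ubx)
    rr$status == "optimal"
  }
  for (i in seq_along(lb)) {
    lbx <- ifelse(relaxed, -M, lb); ubx <- ifelse(relaxed, M, ub)
    lbx[i] <- -M; ubx[i] <- M
    if (feasibleWith(lbx, ubx)) {
      implicated <- c(implicated, d$ids[i])   # removing it repairs: member
    } else {
      relaxed[i] <- TRUE                      # not needed for infeasibility
    }
  }
  structure(list(feasible = FALSE, witness = NULL,
                 infeasibleSubsystem = implicated),
            class = "FeasibilityResult")
}

#' @export
print.FeasibilityResult <- function(x, ...) {
  if (x$feasible) {
    cat("FeasibilityResult: feasible (witness flux available)\n")
  } else {
    cat("FeasibilityResult: infeasible; implicated bound constraints:",
        paste(x$infeasibleSubsystem, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Find blocked reactions
#'
#' A reaction is blocked when its flux is zero in every feasible steady
#' state: both its maximal and minimal achievable flux under `S v = 0` and
#' the bounds are zero (within `tol`). Determined by one maximisation and
#' one minimisation LP per reaction.
#'
#' @param network a [StoichiometricNetwork-class] (bounds applied; missing
#'   bounds get the defaults).
#' @param tol flux magnitude below which a reaction counts as zero.
#' @return character vector of blocked reaction ids.
#' @export
findBlockedReactions <- function(network, tol = 1e-6) {
  d <- .lpData(network)
  n <- length(d$ids)
  m <- nrow(d$S)
  blocked <- logical(n)
  for (j in seq_len(n)) {
    cc <- numeric(n); cc[j] <- 1
    hi <- .lpSolveBounded(cc, d$S, rep(0, m), d$lb, d$ub, maximize = TRUE)
    if (hi$status != "optimal" || abs(hi$obj) > tol) next
    lo <- .lpSolveBounded(cc, d$S, rep(0, m), d$lb, d$ub, maximize = FALSE)
    blocked[j] <- lo$status == "optimal" && abs(lo$obj) <= tol
  }
  d$ids[blocked]
}

#' Find dead-end metabolites
#'
#' Balanced metabolites that can only be produced or only consumed across
#' all reactions, taking reversibility (i.e. the sign range of each
#' reaction's bounds) into account. Such species force their neighbouring
#' reactions to zero at steady state. Metabolites participating in no
#' reaction at all are orphans, reported by [validateNetwork()], not dead
#' ends.
#'
#' @param network a [StoichiometricNetwork-class].
#' @return character vector of dead-end metabolite ids.
#' @export
findDeadEndMetabolites <- function(network) {
  d <- .lpData(network)
  S <- d$S
  canFwd <- d$ub > 0     # reaction can run in its written direction
  canRev <- d$lb < 0     # reaction can run backwards
  out <- character()
  for (i in seq_len(nrow(S))) {
    co <- S[i, ]
    j <- which(co != 0)
    if (!length(j)) next   # orphan
    producible <- any(co[j] > 0 & canFwd[j]) || any(co[j] < 0 & canRev[j])
    consumable <- any(co[j] < 0 & canFwd[j]) || any(co[j] > 0 & canRev[j])
    if (xor(producible, consumable)) out <- c(out, rownames(S)[i])
  }
  out
}
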