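#' Default flux bound policy
#'
#' The network-wide defaults used where a reaction carries no explicit
#' bound: irreversible reactions are constrained to 0..100 mmol/(g dw h)
#' and reversible reactions to -100..100 mmol/(g dw h).
#'
#' @param irreversible length-2 numeric, default `c(0, 100)`.
#' @param reversible length-2 numeric, default `c(-100, 100)`.
#' @return a list of class `BoundsPolicy`
#' @export
defaultBoundsPolicy <- function(irreversible = c(0, 100),
                                reversible = c(-100, 100)) {
  stopifnot(length(irreversible) == 2L, length(reversible) == 2L,
            irreversible[1] <= irreversible[2],
            reversible[1] <= reversible[2])
  structure(list(irreversible = as.numeric(irreversible),
                 reversible = as.numeric(reversible)),
            class = "BoundsPolicy")
}

#' Apply default bounds and per-reaction overrides
#'
#' Reactions without explicit bounds (`NA`) receive the policy defaults by
#' reversibility; `overrides` then replace bounds unconditionally for the
#' named reactions. A fixed flux is expressed as `lb == ub` (e.g. the
#' maintenance ATP drain, `list(R192 = c(0.92, 0.92))`). The operation is
#' idempotent: re-applying the same policy and overrides changes nothing.
#'
#' @param network a [StoichiometricNetwork-class]
#' @param policy a [defaultBoundsPolicy()] object
#' @param overrides named list of `c(lb, ub)` pairs keyed by reaction id
#' @return the network with complete bounds
#' @examples
#' net <- networkFromEquations(c(Ex = "-> A[c]", R192 = "A[c] ->"))
#' bounds(applyBounds(net, overrides = list(R192 = c(0.92, 0.92))))
#' @export
applyBounds <- function(network, policy = defaultBoundsPolicy(),
                        overrides = list()) {
  stopifnot(is(network, "StoichiometricNetwork"),
            inherits(policy, "BoundsPolicy"))
  rxn <- network@reactions
  unknown <- setdiff(names(overrides), rxn$id)
  if (length(unknown)) {
    stop("override(s) reference unknown reaction id(s): ",
         paste(unknown, collapse = ", "))
  }
  fill <- is.na(rxn$lower_bound) | is.na(rxn$upper_bound)
  def <- ifelse(rxn$reversible,
                list(policy$reversible), list(policy$irreversible))
  rxn$lower_bound[fill] <- vapply(def[fill], `[`, numeric(1), 1L)
  rxn$upper_bound[fill] <- vapply(def[fill], `[`, numeric(1), 2L)
  for (id in names(overrides)) {
    p <- as.numeric(overrides[[id]])
    if (length(p) != 2L || any(is.na(p)) || p[1] > p[2]) {
      stop(sprintf("invalid override for '%s': need c(lb, ub) with lb <= ub", id))
    }
    i <- match(id, rxn$id)
    rxn$lower_bound[i] <- p[1]
    rxn$upper_bound[i] <- p[2]
    if (p[1] < 0) rxn$reversible[i] <- TRUE  # keep the reversibility invariant
  }
  network@reactions <- rxn
  validObject(network)
  network
}
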