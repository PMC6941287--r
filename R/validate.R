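#' @importFrom Matrix rowSums colSums
NULL

#' Structural validation of a network
#'
#' Runs the structural checks a model curator needs before analysis:
#' duplicate metabolite/reaction ids, metabolites participating in no
#' reaction (orphans), reactions with empty stoichiometry, stored
#' zero coefficients, bound inconsistencies, and missing or dangling named
#' roles. All findings are report rows, never conditions; an empty report
#' means the network passes every check.
#'
#' @param network a [StoichiometricNetwork-class]
#' @param requireRoles roles expected to be present; absence is reported as
#'   a warning row. Defaults to none for toy models; pass
#'   `c("biomass", "light_exchange", "nitrate_exchange", "maintenance",
#'   "carotene_sink")` for scenario work.
#' @return data.frame with columns `severity` ("error"/"warning"), `code`,
#'   `subject`, `message`; zero rows when all checks pass.
#' @examples
#' net <- networkFromEquations(c(R1 = "-> A[c]", R2 = "A[c] ->"))
#' validateNetwork(net)              # clean: zero rows
#' @export
validateNetwork <- function(network, requireRoles = character()) {
  stopifnot(is(network, "StoichiometricNetwork"))
  met <- network@metabolites
  rxn <- network@reactions
  S <- network@stoichiometry
  rep <- list()
  add <- function(severity, code, subject, message) {
    rep[[length(rep) + 1L]] <<- data.frame(severity = severity, code = code,
                                           subject = subject, message = message)
  }
  for (id in unique(met$id[duplicated(met$id)])) {
    add("error", "duplicate_metabolite_id", id,
        sprintf("metabolite id '%s' occurs more than once", id))
  }
  for (id in unique(rxn$id[duplicated(rxn$id)])) {
    add("error", "duplicate_reaction_id", id,
        sprintf("reaction id '%s' occurs more than once", id))
  }
  participates <- rowSums(S != 0) > 0L
  for (id in met$id[!participates & met$compartment != "external"]) {
    add("warning", "orphan_metabolite", id,
        sprintf("metabolite '%s' participates in no reaction", id))
  }
  nterms <- colSums(S != 0)
  for (id in rxn$id[nterms == 0L]) {
    add("error", "empty_stoichiometry", id,
        sprintf("reaction '%s' has an empty stoichiometry", id))
  }
  if (any(S@x == 0)) {
    add("error", "stored_zero_coefficient", "stoichiometry",
        "stoichiometry stores explicit zero coefficients")
  }
  bad <- which(!is.na(rxn$lower_bound) & !is.na(rxn$upper_bound) &
               rxn$lower_bound > rxn$upper_bound)
  for (i in bad) {
    add("error", "bound_order", rxn$id[i],
        sprintf("reaction '%s' has lower bound %g > upper bound %g",
                rxn$id[i], rxn$lower_bound[i], rxn$upper_bound[i]))
  }
  bad <- which(!rxn$reversible & !is.na(rxn$lower_bound) & rxn$lower_bound < 0)
  for (i in bad) {
    add("error", "irreversible_negative_lb", rxn$id[i],
        sprintf("irreversible reaction '%s' has negative lower bound", rxn$id[i]))
  }
  dangling <- setdiff(network@roles, rxn$id)
  for (id in dangling) {
    add("error", "role_unknown_reaction", id,
        sprintf("named role points at unknown reaction '%s'", id))
  }
  for (role in setdiff(requireRoles, names(network@roles))) {
    add("warning", "role_absent", role,
        sprintf("named role absent: '%s'", role))
  }
  if (length(rep)) do.call(rbind, rep) else
    data.frame(severity = character(), code = character(),
               subject = character(), message = character())
}
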