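# SBML reader/writer built on xml2.
#
# Written form: SBML Level 3 Version 1 core with the flux-balance-constraints
# (fbc, version 2) bound attributes referencing model parameters. Accepted on
# read: the same form, plus the legacy Level 2 dialect where bounds live in
# per-reaction kineticLaw parameters named LOWER_BOUND/UPPER_BOUND. Species
# with boundaryCondition="true" are normalized onto the 'external'
# compartment, so both the single-sided-exchange dialect and the
# explicit-boundary-species dialect import to the same network.
#
# SBML ids must be SId ([A-Za-z_][A-Za-z0-9_]*); ids such as 'glc[c]' are
# sanitized on write and the original id is kept in a notes line
# ('ORIGID: ...') so round-tripping is exact. Numbers are printed with
# "%.17g" so doubles survive a round trip bit-exactly.

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.sanitizeSId <- function(x) {
  y <- gsub("[^A-Za-z0-9_]", "_", x)
  bad <- !grepl("^[A-Za-z_]", y)
  y[bad] <- paste0("x_", y[bad])
  # disambiguate collisions deterministically
  while (anyDuplicated(y)) {
    d <- which(duplicated(y))
    y[d] <- paste0(y[d], "_")
  }
  y
}

.num <- function(x) sprintf("%.17g", x)

#' Write a network as SBML
#'
#' Emits SBML Level 3 (fbc version 2 flux bounds). Output is deterministic:
#' writing the same network twice yields byte-identical documents, and
#' `readSBML(writeSBML(net))` reproduces the network exactly (ids, names,
#' compartments, stoichiometry, reversibility, bounds, annotations, kinds
#' and roles).
#'
#' @param network a [StoichiometricNetwork-class]; must pass
#'   [validateNetwork()] without errors.
#' @param path file path to write to.
#' @return `path`, invisibly.
#' @seealso [readSBML()]
#' @export
writeSBML <- function(network, path) {
  stopifnot(is(network, "StoichiometricNetwork"))
  rep <- validateNetwork(network)
  if (any(rep$severity == "error")) {
    stop("network fails validation: ",
         paste(rep$message[rep$severity == "error"], collapse = "; "))
  }
  met <- network@metabolites
  rxn <- network@reactions
  S <- network@stoichiometry
  mSId <- .sanitizeSId(met$id)
  rSId <- .sanitizeSId(rxn$id)

  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  notes <- function(lines, indent) {
    if (!length(lines)) return(character())
    c(sprintf("%s<notes>", indent),
      sprintf("%s  <body xmlns=\"http://www.w3.org/1999/xhtml\">", indent),
      sprintf("%s    <p>%s</p>", indent, esc(lines)),
      sprintf("%s  </body>", indent),
      sprintf("%s</notes>", indent))
  }

  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<sbml xmlns=\"%s\" xmlns:fbc=\"%s\" level=\"3\" ",
                   "version=\"1\" fbc:required=\"false\">"),
            .SBML_NS, .FBC_NS),
    "  <model id=\"model\" fbc:strict=\"false\">")
  roleLines <- sprintf("ROLE %s: %s", names(network@roles), network@roles)
  out <- c(out, notes(roleLines, "    "))

  comps <- unique(met$compartment)
  out <- c(out, "    <listOfCompartments>",
           sprintf("      <compartment id=\"%s\" constant=\"true\"/>", comps),
           "    </listOfCompartments>")

  out <- c(out, "    <listOfSpecies>")
  for (i in seq_len(nrow(met))) {
    attrs <- sprintf(paste0("id=\"%s\" name=\"%s\" compartment=\"%s\" ",
                            "hasOnlySubstanceUnits=\"false\" ",
                            "boundaryCondition=\"%s\" constant=\"false\""),
                     mSId[i], esc(met$name[i]), met$compartment[i],
                     if (met$compartment[i] == "external") "true" else "false")
    lines <- character()
    if (mSId[i] != met$id[i]) lines <- c(lines, paste0("ORIGID: ", met$id[i]))
    if (!is.na(met$formula[i])) lines <- c(lines, paste0("FORMULA: ", met$formula[i]))
    if (length(lines)) {
      out <- c(out, sprintf("      <species %s>", attrs),
               notes(lines, "        "), "      </species>")
    } else {
      out <- c(out, sprintf("      <species %s/>", attrs))
    }
  }
  out <- c(out, "    </listOfSpecies>")

  haveB <- !is.na(rxn$lower_bound) & !is.na(rxn$upper_bound)
  if (any(haveB)) {
    out <- c(out, "    <listOfParameters>")
    for (i in which(haveB)) {
      out <- c(out,
        sprintf("      <parameter id=\"lb_%s\" value=\"%s\" constant=\"true\"/>",
                rSId[i], .num(rxn$lower_bound[i])),
        sprintf("      <parameter id=\"ub_%s\" value=\"%s\" constant=\"true\"/>",
                rSId[i], .num(rxn$upper_bound[i])))
    }
    out <- c(out, "    </listOfParameters>")
  }

  out <- c(out, "    <listOfReactions>")
  for (j in seq_len(nrow(rxn))) {
    battr <- if (haveB[j]) {
      sprintf(" fbc:lowerFluxBound=\"lb_%s\" fbc:upperFluxBound=\"ub_%s\"",
              rSId[j], rSId[j])
    } else ""
    out <- c(out, sprintf(
      "      <reaction id=\"%s\" name=\"%s\" reversible=\"%s\" fast=\"false\"%s>",
      rSId[j], esc(rxn$name[j]), tolower(as.character(rxn$reversible[j])), battr))
    lines <- paste0("KIND: ", rxn$kind[j])
    if (rSId[j] != rxn$id[j]) lines <- c(lines, paste0("ORIGID: ", rxn$id[j]))
    if (!is.na(rxn$ec_number[j])) lines <- c(lines, paste0("EC: ", rxn$ec_number[j]))
    if (!is.na(rxn$kegg_id[j])) lines <- c(lines, paste0("KEGG: ", rxn$kegg_id[j]))
    out <- c(out, notes(lines, "        "))
    co <- S[, j]
    neg <- which(co < 0); pos <- which(co > 0)
    if (length(neg)) {
      out <- c(out, "        <listOfReactants>",
        sprintf("          <speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
                mSId[neg], .num(-co[neg])),
        "        </listOfReactants>")
    }
    if (length(pos)) {
      out <- c(out, "        <listOfProducts>",
        sprintf("          <speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
                mSId[pos], .num(co[pos])),
        "        </listOfProducts>")
    }
    out <- c(out, "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>", "  </model>", "</sbml>")

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Read a network from SBML
#'
#' Accepts SBML Level 2 (flux bounds as kineticLaw parameters named
#' `LOWER_BOUND`/`UPPER_BOUND`) and Level 3 with fbc-v2 bound attributes.
#' Compartment identifiers are mapped onto the canonical four compartments
#' via `compartmentMap`; an unmapped compartment is an error listing the id.
#' Species flagged `boundaryCondition="true"` are normalized to the
#' `external` compartment.
#'
#' @param path path to an SBML file.
#' @param compartmentMap named character, see [defaultCompartmentMap()].
#' @param inferRoles when the document itself declares no roles, assign the
#'   canonical named roles from conventional reaction ids (`mu` or
#'   `biomass` for the biomass reaction, `Ex01` light exchange, `Ex06`
#'   nitrate exchange, `R192` maintenance, `Car14` carotene sink), matched
#'   case-insensitively. Set `FALSE` for a strictly literal import.
#' @return a [StoichiometricNetwork-class]
#' @seealso [writeSBML()]
#' @export
readSBML <- function(path, compartmentMap = defaultCompartmentMap(),
                     inferRoles = TRUE) {
  if (!file.exists(path)) stop("cannot read SBML: no such file: ", path)
  doc <- xml2::read_xml(path)  # malformed XML errors here
  find <- function(node, what) {
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", what))
  }
  attr1 <- function(node, what) {
    v <- xml2::xml_attr(node, what)
    if (is.na(v)) NULL else v
  }
  getNotes <- function(node) {
    ps <- xml2::xml_find_all(node,
      "./*[local-name()='notes']//*[local-name()='p']")
    xml2::xml_text(ps)
  }
  noteVal <- function(lines, key) {
    hit <- grep(paste0("^", key, ":\\s*"), lines, value = TRUE)
    if (!length(hit)) NA_character_ else sub(paste0("^", key, ":\\s*"), "", hit[1])
  }

  model <- find(doc, "model")
  if (!length(model)) stop("not an SBML document: no <model> element")
  model <- model[[1]]

  compNodes <- find(model, "compartment")
  compIds <- xml2::xml_attr(compNodes, "id")
  compMap <- vapply(compIds, function(id) {
    hit <- compartmentMap[tolower(id)]
    if (is.na(hit)) NA_character_ else unname(hit)
  }, character(1))
  unknownComp <- compIds[is.na(compMap)]
  if (length(unknownComp)) {
    stop("unknown compartment id(s) without mapping: ",
         paste(unknownComp, collapse = ", "),
         " (extend compartmentMap to import this model)")
  }

  spNodes <- find(model, "species")
  nSp <- length(spNodes)
  spSId <- character(nSp); spId <- character(nSp); spName <- character(nSp)
  spComp <- character(nSp); spFormula <- rep(NA_character_, nSp)
  for (i in seq_len(nSp)) {
    nd <- spNodes[[i]]
    spSId[i] <- xml2::xml_attr(nd, "id")
    cid <- xml2::xml_attr(nd, "compartment")
    if (is.na(cid) || !cid %in% compIds) {
      stop(sprintf("species '%s' references missing compartment '%s'",
                   spSId[i], if (is.na(cid)) "<none>" else cid))
    }
    comp <- compMap[[cid]]
    if (identical(attr1(nd, "boundaryCondition"), "true")) comp <- "external"
    spComp[i] <- comp
    lines <- getNotes(nd)
    orig <- noteVal(lines, "ORIGID")
    spId[i] <- if (is.na(orig)) spSId[i] else orig
    nm <- attr1(nd, "name")
    spName[i] <- if (is.null(nm)) spId[i] else nm
    f <- noteVal(lines, "FORMULA")
    if (is.na(f)) {
      fa <- attr1(nd, "chemicalFormula")
      if (!is.null(fa)) f <- fa
    }
    spFormula[i] <- f
  }

  parVal <- local({
    pn <- xml2::xml_find_all(model,
      "./*[local-name()='listOfParameters']/*[local-name()='parameter']")
    stats::setNames(as.numeric(xml2::xml_attr(pn, "value")),
                    xml2::xml_attr(pn, "id"))
  })

  rxNodes <- xml2::xml_find_all(model,
    "./*[local-name()='listOfReactions']/*[local-name()='reaction']")
  nRx <- length(rxNodes)
  rxId <- character(nRx); rxName <- character(nRx); rxRev <- logical(nRx)
  rxLb <- rep(NA_real_, nRx); rxUb <- rep(NA_real_, nRx)
  rxEc <- rep(NA_character_, nRx); rxKegg <- rep(NA_character_, nRx)
  rxKind <- rep(NA_character_, nRx)
  stoich <- vector("list", nRx)
  for (j in seq_len(nRx)) {
    nd <- rxNodes[[j]]
    sid <- xml2::xml_attr(nd, "id")
    lines <- getNotes(nd)
    orig <- noteVal(lines, "ORIGID")
    rxId[j] <- if (is.na(orig)) sid else orig
    nm <- attr1(nd, "name")
    rxName[j] <- if (is.null(nm)) rxId[j] else nm
    rev <- attr1(nd, "reversible")
    rxRev[j] <- if (is.null(rev)) TRUE else identical(rev, "true")  # SBML default
    rxEc[j] <- noteVal(lines, "EC")
    rxKegg[j] <- noteVal(lines, "KEGG")
    rxKind[j] <- noteVal(lines, "KIND")

    co <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(nd, sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']", side))
      if (!length(refs)) next
      sp <- xml2::xml_attr(refs, "species")
      missing <- setdiff(sp, spSId)
      if (length(missing)) {
        stop(sprintf("reaction '%s' references unknown species: %s",
                     rxId[j], paste(missing, collapse = ", ")))
      }
      st <- xml2::xml_attr(refs, "stoichiometry")
      st <- ifelse(is.na(st), 1, as.numeric(st))
      sgn <- if (side == "listOfReactants") -1 else 1
      v <- stats::setNames(sgn * st, spId[match(sp, spSId)])
      co <- c(co, v)
    }
    if (length(co)) {
      agg <- tapply(co, names(co), sum)
      co <- stats::setNames(as.numeric(agg), names(agg))[unique(names(co))]
      co <- co[co != 0]
    }
    stoich[[j]] <- co

    # bounds: fbc attributes referencing parameters, else kineticLaw (L2)
    lbRef <- attr1(nd, "lowerFluxBound")
    ubRef <- attr1(nd, "upperFluxBound")
    if (!is.null(lbRef) && lbRef %in% names(parVal)) rxLb[j] <- parVal[[lbRef]]
    if (!is.null(ubRef) && ubRef %in% names(parVal)) rxUb[j] <- parVal[[ubRef]]
    if (is.na(rxLb[j]) || is.na(rxUb[j])) {
      kl <- xml2::xml_find_all(nd, paste0(
        "./*[local-name()='kineticLaw']//*[local-name()='parameter' or ",
        "local-name()='localParameter']"))
      if (length(kl)) {
        pid <- xml2::xml_attr(kl, "id")
        pv <- as.numeric(xml2::xml_attr(kl, "value"))
        lo <- pv[pid == "LOWER_BOUND"]
        hi <- pv[pid == "UPPER_BOUND"]
        if (is.na(rxLb[j]) && length(lo)) rxLb[j] <- lo[1]
        if (is.na(rxUb[j]) && length(hi)) rxUb[j] <- hi[1]
      }
    }
  }

  # infer missing kinds from structure
  compOf <- stats::setNames(spComp, spId)
  for (j in seq_len(nRx)) {
    if (!is.na(rxKind[j])) next
    co <- stoich[[j]]
    if (!length(co)) { rxKind[j] <- "internal"; next }
    cps <- compOf[names(co)]
    if (all(co > 0) || all(co < 0) || any(cps == "external")) rxKind[j] <- "exchange"
    else if (length(unique(cps[cps != "external"])) > 1L) rxKind[j] <- "transport"
    else rxKind[j] <- "internal"
  }

  rolesLines <- getNotes(model)
  roleHits <- regmatches(rolesLines,
                         regexec("^ROLE ([a-z_]+): (.+)$", rolesLines))
  roles <- character()
  for (h in roleHits) {
    if (length(h) == 3L) roles[h[2]] <- h[3]
  }
  if (!length(roles) && inferRoles) {
    canon <- list(biomass = c("mu", "biomass", "μ"),
                  light_exchange = "ex01", nitrate_exchange = "ex06",
                  maintenance = "r192", carotene_sink = "car14")
    for (role in names(canon)) {
      hit <- rxId[tolower(rxId) %in% canon[[role]]]
      if (length(hit) == 1L) roles[role] <- hit
    }
  }

  StoichiometricNetwork(
    metabolites = data.frame(id = spId, name = spName, compartment = spComp,
                             formula = spFormula),
    reactions = data.frame(id = rxId, name = rxName, reversible = rxRev,
                           lower_bound = rxLb, upper_bound = rxUb,
                           ec_number = rxEc, kegg_id = rxKegg, kind = rxKind),
    stoichiometry = stats::setNames(stoich, rxId),
    roles = roles
  )
}
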