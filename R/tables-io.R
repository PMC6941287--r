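#' Read a delimited reaction table
#'
#' Reads the tabular form of a reaction list: one row per reaction with an
#' id, an equation string, and optional annotation columns. The delimiter
#' (comma, tab or semicolon) is auto-detected from the header line unless
#' given. Column names are matched case-insensitively against common
#' synonyms (`id`/`reaction_id`/`reaction`; `equation`/`formula`;
#' `ec`/`ec_number`; `kegg`/`kegg_id`; `name`; `compartment`/
#' `compartment_hint`). Missing annotation cells become `NA`, never empty
#' strings.
#'
#' @param path path to the delimited file (header row required).
#' @param delim optional explicit delimiter, overriding detection.
#' @return data.frame with columns `reaction_id`, `equation_text`, `name`,
#'   `ec_number`, `kegg_id`, `compartment_hint`.
#' @seealso [reactionTableToNetwork()], [writeReactionTable()]
#' @export
readReactionTable <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("cannot read reaction table: no such file: ", path)
  header <- readLines(path, n = 1L)
  if (is.null(delim)) {
    counts <- vapply(c("\t", ";", ","),
                     function(d) lengths(regmatches(header, gregexpr(d, header, fixed = TRUE))),
                     integer(1))
    delim <- names(counts)[which.max(counts)]
    if (max(counts) == 0L) delim <- ","
  }
  tab <- utils::read.table(path, sep = delim, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character")
  findCol <- function(candidates) {
    hit <- match(candidates, tolower(names(tab)))
    hit <- hit[!is.na(hit)]
    if (length(hit)) hit[1] else NA_integer_
  }
  idCol <- findCol(c("id", "reaction_id", "reaction"))
  eqCol <- findCol(c("equation", "equation_text", "reaction_equation", "formula"))
  missing <- c(if (is.na(idCol)) "id", if (is.na(eqCol)) "equation")
  if (length(missing)) {
    stop("reaction table lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  pick <- function(candidates) {
    i <- findCol(candidates)
    if (is.na(i)) rep(NA_character_, nrow(tab)) else {
      v <- trimws(tab[[i]])
      ifelse(nzchar(v), v, NA_character_)
    }
  }
  data.frame(
    reaction_id = trimws(tab[[idCol]]),
    equation_text = trimws(tab[[eqCol]]),
    name = pick("name"),
    ec_number = pick(c("ec", "ec_number", "ec number")),
    kegg_id = pick(c("kegg", "kegg_id", "kegg id")),
    compartment_hint = pick(c("compartment", "compartment_hint")),
    stringsAsFactors = FALSE
  )
}

#' Assemble a network from reaction-table rows
#'
#' @param rows data.frame as returned by [readReactionTable()].
#' @param roles named character vector of role assignments.
#' @param compartmentMap see [defaultCompartmentMap()].
#' @return a [StoichiometricNetwork-class]
#' @export
reactionTableToNetwork <- function(rows, roles = character(),
                                   compartmentMap = defaultCompartmentMap()) {
  if (anyDuplicated(rows$reaction_id)) {
    stop("duplicate reaction id(s) in table: ",
         paste(unique(rows$reaction_id[duplicated(rows$reaction_id)]),
               collapse = ", "))
  }
  eq <- stats::setNames(rows$equation_text, rows$reaction_id)
  net <- networkFromEquations(eq, ec_number = rows$ec_number,
                              kegg_id = rows$kegg_id, roles = roles,
                              compartmentMap = compartmentMap)
  if (!all(is.na(rows$name))) {
    nm <- ifelse(is.na(rows$name), rows$reaction_id, rows$name)
    net@reactions$name <- nm
  }
  net
}

#' Write a network as a reaction table
#'
#' Inverse of [readReactionTable()] + [reactionTableToNetwork()]: formats
#' every reaction as an equation string (via [formatReactionEquation()]) and
#' writes a delimited table with id, equation and annotations.
#'
#' @param network a [StoichiometricNetwork-class]
#' @param path output path
#' @param delim delimiter, default comma
#' @return `path`, invisibly
#' @export
writeReactionTable <- function(network, path, delim = ",") {
  rxn <- network@reactions
  S <- network@stoichiometry
  eq <- vapply(seq_len(nrow(rxn)), function(j) {
    co <- S[, j]
    formatReactionEquation(co[co != 0], rxn$reversible[j])
  }, character(1))
  out <- data.frame(id = rxn$id, equation = eq, name = rxn$name,
                    ec_number = rxn$ec_number, kegg_id = rxn$kegg_id,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = delim, row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Write a scenario table in the two-way layout
#'
#' Serialises a scenario table (one row per scenario, as produced by
#' [runScenarios()]) in the printed layout: columns are scenarios, rows are
#' the input rates followed by the computed outputs. Numeric cells are
#' formatted to `digits` decimal places (default 4, the precision of the
#' published tables); the in-memory table keeps full precision.
#'
#' @param table data.frame from [runScenarios()].
#' @param path output path.
#' @param delim delimiter, default comma.
#' @param digits decimal places for numeric cells.
#' @return `path`, invisibly
#' @seealso [readScenarioTable()]
#' @export
writeScenarioTable <- function(table, path, delim = ",", digits = 4) {
  fmt <- function(x) {
    ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
  }
  m <- rbind(
    `Light (Ex01)` = fmt(table$Ex01),
    `Nutrients (Ex06, NO3-)` = fmt(table$Ex06),
    `Objective function` = as.character(table$objective),
    `Calc. growth rate in 1/h` = fmt(table$growth_rate),
    `Calc. beta-carotene production in mmol/(g dw h)` = fmt(table$carotene_flux),
    `Status` = as.character(table$status)
  )
  out <- data.frame(Scenario = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[-1] <- table$label
  utils::write.table(out, path, sep = delim, row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read a scenario table written by [writeScenarioTable()]
#'
#' @param path path to the file.
#' @param delim delimiter, default comma.
#' @return data.frame with one row per scenario (columns `label`, `Ex01`,
#'   `Ex06`, `objective`, `growth_rate`, `carotene_flux`, `status`).
#' @export
readScenarioTable <- function(path, delim = ",") {
  if (!file.exists(path)) stop("cannot read scenario table: no such file: ", path)
  tab <- utils::read.table(path, sep = delim, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  labels <- names(tab)[-1]
  row <- function(key) {
    i <- match(key, tab[[1]])
    if (is.na(i)) rep(NA_character_, length(labels)) else unlist(tab[i, -1])
  }
  num <- function(x) suppressWarnings(as.numeric(ifelse(nzchar(x), x, NA)))
  data.frame(
    label = labels,
    Ex01 = num(row("Light (Ex01)")),
    Ex06 = num(row("Nutrients (Ex06, NO3-)")),
    objective = unname(row("Objective function")),
    growth_rate = num(row("Calc. growth rate in 1/h")),
    carotene_flux = num(row("Calc. beta-carotene production in mmol/(g dw h)")),
    status = unname(row("Status")),
    stringsAsFactors = FALSE
  )
}
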