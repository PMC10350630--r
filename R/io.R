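#' @include pathway-model.R line-profile.R
NULL

#' Write a pathway model to a JSON document
#'
#' Serializes pools, reactions, gene tags and all kinetic parameters at full
#' double precision, so that a write-read cycle reproduces the model with
#' bit-equal parameter values.
#'
#' @param model a \linkS4class{PathwayModel} or \linkS4class{KineticModel}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePathwayModel <- function(model, path) {
  doc <- list(
    variant = if (is(model, "PathwayModel")) model@variant else NULL,
    provenance = if (is(model, "PathwayModel")) model@provenance else NULL,
    pools = model@pools,
    reactions = unname(lapply(model@reactions, function(r) list(
      id = r@id,
      gene = if (is.na(r@gene)) NULL else r@gene,
      substrates = as.list(r@substrates),
      products = as.list(r@products),
      V = r@law@V,
      substrateK = as.list(r@law@substrateK),
      inhibitorK = as.list(r@law@inhibitorK),
      multiplier = r@multiplier))))
  ## I(17): 17 significant digits, enough for exact double round-trips
  json <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a pathway model from a JSON document
#'
#' Inverse of \code{\link{writePathwayModel}}; schema violations are reported
#' with the path of the offending element.
#'
#' @param path JSON file path.
#' @return a \linkS4class{PathwayModel} (when the document carries a variant
#'   tag) or \linkS4class{KineticModel}.
#' @export
readPathwayModel <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$pools) || !length(doc$pools))
    stop("model document schema error at 'pools': missing")
  need <- c("name", "compartment", "role", "basal")
  for (i in seq_along(doc$pools)) {
    miss <- setdiff(need, names(doc$pools[[i]]))
    if (length(miss))
      stop("model document schema error at 'pools[", i, "]$", miss[1],
           "': missing")
  }
  poolsDf <- data.frame(
    name = vapply(doc$pools, `[[`, "", "name"),
    compartment = vapply(doc$pools, `[[`, "", "compartment"),
    role = vapply(doc$pools, `[[`, "", "role"),
    basal = vapply(doc$pools, function(p) as.numeric(p$basal), 0),
    stringsAsFactors = FALSE)
  if (is.null(doc$reactions) || !length(doc$reactions))
    stop("model document schema error at 'reactions': missing or empty")
  rxns <- lapply(seq_along(doc$reactions), function(i) {
    r <- doc$reactions[[i]]
    for (fld in c("id", "substrates", "V", "substrateK"))
      if (is.null(r[[fld]]))
        stop("model document schema error at 'reactions[", i, "]$", fld,
             "': missing")
    new("Reaction", id = r$id,
        substrates = vapply(r$substrates, as.integer, 0L),
        products = if (length(r$products))
          vapply(r$products, as.integer, 0L) else integer(0),
        gene = if (is.null(r$gene)) NA_character_ else r$gene,
        law = new("SaturatingRateLaw", V = as.numeric(r$V),
                  substrateK = vapply(r$substrateK, as.numeric, 0),
                  inhibitorK = if (length(r$inhibitorK))
                    vapply(r$inhibitorK, as.numeric, 0) else numeric(0)),
        multiplier = if (is.null(r$multiplier)) 1 else as.numeric(r$multiplier))
  })
  if (!is.null(doc$variant))
    new("PathwayModel", variant = doc$variant,
        provenance = if (is.null(doc$provenance)) "calibrated" else doc$provenance,
        pools = poolsDf, reactions = rxns)
  else new("KineticModel", pools = poolsDf, reactions = rxns)
}

#' Write line profiles to TSV
#'
#' One row per line: \code{line_id}, \code{variant}, one \code{expr_<gene>}
#' column per gene, one \code{horm_<hormone>} and \code{det_<hormone>}
#' (detected flag) pair per hormone, and the five phenotype columns. Missing
#' values are written as \code{NA}.
#'
#' @param lines list of \linkS4class{LineProfile} objects.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeLineProfiles <- function(lines, path) {
  genes <- unique(unlist(lapply(lines, function(p) names(p@expressionRatio))))
  hs <- unique(unlist(lapply(lines, function(p) p@hormones$hormone)))
  rows <- lapply(lines, function(p) {
    row <- list(line_id = p@lineId, variant = p@variant)
    for (g in genes)
      row[[paste0("expr_", g)]] <-
        if (g %in% names(p@expressionRatio)) p@expressionRatio[[g]] else NA
    for (h in hs) {
      i <- match(h, p@hormones$hormone)
      row[[paste0("horm_", h)]] <- if (is.na(i)) NA else p@hormones$level[i]
      row[[paste0("det_", h)]] <- if (is.na(i)) NA else !p@hormones$belowDetection[i]
    }
    for (ph in .phenotypeNames) row[[ph]] <- p@phenotype[[ph]]
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read line profiles from TSV
#'
#' Inverse of \code{\link{writeLineProfiles}}.
#'
#' @param path TSV file path.
#' @return list of \linkS4class{LineProfile} objects.
#' @export
readLineProfiles <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  exprCols <- grep("^expr_", names(df), value = TRUE)
  hormCols <- grep("^horm_", names(df), value = TRUE)
  lapply(seq_len(nrow(df)), function(i) {
    er <- stats::setNames(as.numeric(df[i, exprCols]),
                          sub("^expr_", "", exprCols))
    hs <- sub("^horm_", "", hormCols)
    lev <- as.numeric(df[i, hormCols])
    det <- as.logical(df[i, paste0("det_", hs)])
    ph <- stats::setNames(as.numeric(df[i, .phenotypeNames]), .phenotypeNames)
    lineProfile(df$line_id[i], df$variant[i], er[!is.na(er)],
                hormones = data.frame(hormone = hs, level = lev,
                                      belowDetection = !det),
                phenotype = ph[!is.na(ph)])
  })
}

.mathmlRate <- function(r) {
  ci <- function(x) paste0("<ci> ", x, " </ci>")
  cn <- function(x) paste0("<cn> ", format(x, digits = 17), " </cn>")
  num <- paste0("<apply><times/>", ci(paste0("V_", r@id)),
                if (r@multiplier != 1) cn(r@multiplier) else "",
                paste(vapply(names(r@law@substrateK), ci, ""), collapse = ""),
                "</apply>")
  denTerm <- function(K, x) paste0("<apply><plus/>", cn(K), ci(x), "</apply>")
  denS <- paste(mapply(denTerm, r@law@substrateK, names(r@law@substrateK)),
                collapse = "")
  den <- if (length(r@law@substrateK) > 1)
    paste0("<apply><times/>", denS, "</apply>") else denS
  if (length(r@law@inhibitorK)) {
    denI <- paste(mapply(denTerm, r@law@inhibitorK, names(r@law@inhibitorK)),
                  collapse = "")
    if (length(r@law@inhibitorK) > 1)
      denI <- paste0("<apply><times/>", denI, "</apply>")
    den <- paste0("<apply><plus/>", den, denI, "</apply>")
  }
  paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">',
         "<apply><divide/>", num, den, "</apply></math>")
}

#' Export a pathway model to SBML Level 3
#'
#' Writes an SBML Level 3 Version 1 document with one species per pool
#' (fixed pools as boundary species), one global parameter per kinetic
#' constant, and one reaction per model reaction with its saturating rate
#' law as an explicit rational MathML expression.
#'
#' @param model a \linkS4class{KineticModel}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSBML <- function(model, path) {
  p <- model@pools
  species <- paste(vapply(seq_len(nrow(p)), function(i) {
    sprintf(paste0('<species id="%s" compartment="%s" ',
                   'initialConcentration="%.17g" hasOnlySubstanceUnits="false" ',
                   'boundaryCondition="%s" constant="%s"/>'),
            p$name[i], p$compartment[i], p$basal[i],
            tolower(p$role[i] == "fixed"), tolower(p$role[i] == "fixed"))
  }, ""), collapse = "\n      ")
  parms <- character(0)
  for (r in model@reactions) {
    parms <- c(parms, sprintf('<parameter id="V_%s" value="%.17g" constant="true"/>',
                              r@id, r@law@V))
  }
  refs <- function(v, tag) {
    if (!length(v)) return(sprintf("<listOf%ss/>", tag))
    inner <- paste(sprintf('<%s species="%s" stoichiometry="%d" constant="true"/>',
                           tolower(tag), names(v), as.integer(v)),
                   collapse = "")
    sprintf("<listOf%ss>%s</listOf%ss>", tag, inner, tag)
  }
  rxns <- paste(vapply(model@reactions, function(r) {
    paste0(sprintf('<reaction id="%s" reversible="false">', r@id),
           refs(r@substrates, "Reactant"), refs(r@products, "Product"),
           "<kineticLaw>", .mathmlRate(r), "</kineticLaw></reaction>")
  }, ""), collapse = "\n      ")
  id <- if (is(model, "PathwayModel"))
    paste0("ipp_dmapp_", model@variant) else "kinetic_model"
  docStr <- sprintf(
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="%s">
    <listOfCompartments>
      <compartment id="cytosol" constant="true" size="1"/>
      <compartment id="plastid" constant="true" size="1"/>
    </listOfCompartments>
    <listOfSpecies>
      %s
    </listOfSpecies>
    <listOfParameters>
      %s
    </listOfParameters>
    <listOfReactions>
      %s
    </listOfReactions>
  </model>
</sbml>', id, species, paste(parms, collapse = "\n      "), rxns)
  doc <- xml2::read_xml(docStr)  # validates well-formedness
  xml2::write_xml(doc, path)
  invisible(path)
}
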