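## Readers and writers: tabular strain dialect, SBML L3 (+FBC) import,
## community JSON, thermodynamic tables.

## ---- tabular strain dialect ----------------------------------------------
##
## One TSV per strain with sections:
##   # id: <strain id>
##   [METABOLITES]  id  name  compartment  external  mu0  conc_lo  conc_hi
##   [REACTIONS]    id  formula  lb  ub  kind  objective
## Formulas are written "a A + b B -> c C"; either side may be empty (exchange
## reactions).  Missing bounds default to [-1000, 1000], or [0, 1000] when an
## optional `reversible` column says FALSE.

.parseFormula <- function(s, rxn) {
  parts <- strsplit(s, "->", fixed = TRUE)[[1]]
  if (length(parts) > 2L)
    stop("malformed formula for reaction '", rxn, "': ", s)
  if (length(parts) == 1L) parts <- c(parts, "")
  out <- list()
  for (side in 1:2) {
    sg <- if (side == 1) -1 else 1
    txt <- trimws(parts[side])
    if (!nzchar(txt)) next
    for (term in trimws(strsplit(txt, "+", fixed = TRUE)[[1]])) {
      if (!nzchar(term)) next
      toks <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(toks) == 1L) { coef <- 1; met <- toks }
      else if (length(toks) == 2L) {
        coef <- suppressWarnings(as.numeric(toks[1]))
        if (is.na(coef)) stop("malformed coefficient in reaction '", rxn, "': ", term)
        met <- toks[2]
      } else stop("malformed term in reaction '", rxn, "': ", term)
      out[[length(out) + 1L]] <- list(met = met, coef = sg * coef)
    }
  }
  out
}

.formulaString <- function(S, j) {
  col <- S[, j]
  nz <- which(col != 0)
  fmt <- function(i) paste(format(abs(col[i]), digits = 12, trim = TRUE),
                           rownames(S)[i])
  lhs <- paste(vapply(nz[col[nz] < 0], fmt, ""), collapse = " + ")
  rhs <- paste(vapply(nz[col[nz] > 0], fmt, ""), collapse = " + ")
  paste(lhs, "->", rhs)
}

#' Read a strain model
#'
#' @param path file path.
#' @param format \code{"tabular"} (the package's sectioned TSV dialect) or
#'   \code{"sbml"} (SBML level 3 with the FBC package's bounds/objective).
#' @return a validated \linkS4class{StrainModel}.
#' @export
readStrainModel <- function(path, format = c("tabular", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "sbml") return(.readSBML(path))
  lines <- readLines(path)
  id <- sub("^#\\s*id:\\s*", "", grep("^#\\s*id:", lines, value = TRUE)[1])
  if (is.na(id)) stop("tabular model lacks an '# id:' header line: ", path)
  secStart <- grep("^\\[", lines)
  secName <- gsub("\\[|\\]", "", lines[secStart])
  readSec <- function(name) {
    i <- which(secName == name)
    if (!length(i)) stop("missing [", name, "] section in ", path)
    from <- secStart[i] + 1L
    to <- if (i < length(secStart)) secStart[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    block <- block[nzchar(trimws(block)) & !startsWith(trimws(block), "#")]
    read.delim(text = paste(block, collapse = "\n"), sep = "\t",
               stringsAsFactors = FALSE, check.names = FALSE)
  }
  mets <- readSec("METABOLITES")
  rxns <- readSec("REACTIONS")
  if (!"id" %in% names(mets)) stop("[METABOLITES] needs an id column in ", path)
  if (!all(c("id", "formula") %in% names(rxns)))
    stop("[REACTIONS] needs id and formula columns in ", path)
  rev_flag <- if ("reversible" %in% names(rxns)) rxns$reversible else rep(TRUE, nrow(rxns))
  if (is.null(rxns$lb)) rxns$lb <- NA_real_
  if (is.null(rxns$ub)) rxns$ub <- NA_real_
  rxns$lb[is.na(rxns$lb)] <- ifelse(rev_flag[is.na(rxns$lb)], -1000, 0)
  rxns$ub[is.na(rxns$ub)] <- 1000
  if (is.null(rxns$kind)) rxns$kind <- "internal"
  S <- Matrix::Matrix(0, nrow(mets), nrow(rxns), sparse = TRUE,
                      dimnames = list(mets$id, rxns$id))
  for (j in seq_len(nrow(rxns))) {
    for (term in .parseFormula(rxns$formula[j], rxns$id[j])) {
      i <- match(term$met, mets$id)
      if (is.na(i)) stop("reaction '", rxns$id[j], "' references unknown metabolite '",
                         term$met, "' in ", path)
      S[i, j] <- S[i, j] + term$coef
    }
  }
  objective <- if ("objective" %in% names(rxns)) {
    o <- rxns$objective; o[is.na(o)] <- 0; as.numeric(o)
  } else NULL
  StrainModel(id = id,
              mets = mets[, intersect(c("id", "name", "compartment", "external",
                                        "mu0", "conc_lo", "conc_hi"), names(mets))],
              rxns = rxns[, c("id", "lb", "ub", "kind")],
              S = S, objective = objective)
}

#' Write a strain model in the tabular dialect
#'
#' @param model a \linkS4class{StrainModel}.
#' @param path output file.
#' @export
writeStrainModel <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("# id:", model@id), "[METABOLITES]"), con)
  m <- model@mets
  num <- function(x) ifelse(is.na(x), "", format(x, digits = 12, trim = TRUE))
  writeLines(paste("id", "name", "compartment", "external", "mu0",
                   "conc_lo", "conc_hi", sep = "\t"), con)
  writeLines(paste(m$id, m$name, m$compartment, m$external, num(m$mu0),
                   num(m$conc_lo), num(m$conc_hi), sep = "\t"), con)
  writeLines("[REACTIONS]", con)
  writeLines(paste("id", "formula", "lb", "ub", "kind", "objective", sep = "\t"), con)
  r <- model@rxns
  writeLines(paste(r$id,
                   vapply(seq_len(nrow(r)), function(j) .formulaString(model@S, j), ""),
                   num(r$lb), num(r$ub), r$kind, num(model@objective),
                   sep = "\t"), con)
  invisible(path)
}

## ---- SBML level 3 + FBC ---------------------------------------------------

.readSBML <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error in ", path, ": ",
                                           conditionMessage(e)))
  sbmlModel <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(sbmlModel, "xml_missing")) stop("no <model> element in ", path)
  id <- xml2::xml_attr(sbmlModel, "id")
  if (is.na(id)) id <- "model"
  sp <- xml2::xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (!length(sp)) stop("no species in ", path)
  mids <- xml2::xml_attr(sp, "id")
  comp <- xml2::xml_attr(sp, "compartment")
  nm <- xml2::xml_attr(sp, "name"); nm[is.na(nm)] <- mids[is.na(nm)]
  external <- comp %in% c("e", "ext", "external", "pool") | grepl("_e$", comp)
  mets <- data.frame(id = mids, name = nm, compartment = comp,
                     external = external, stringsAsFactors = FALSE)
  params <- xml2::xml_find_all(doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pval <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                   xml2::xml_attr(params, "id"))
  rx <- xml2::xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(rx)) stop("no reactions in ", path)
  rids <- xml2::xml_attr(rx, "id")
  S <- Matrix::Matrix(0, nrow(mets), length(rids), sparse = TRUE,
                      dimnames = list(mets$id, rids))
  lb <- ub <- numeric(length(rids))
  for (j in seq_along(rx)) {
    node <- rx[[j]]
    for (side in c("listOfReactants", "listOfProducts")) {
      sg <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(node, paste0("./*[local-name()='", side,
                                              "']/*[local-name()='speciesReference']"))
      for (ref in refs) {
        met <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        coef <- if (is.na(st)) 1 else as.numeric(st)
        i <- match(met, mets$id)
        if (is.na(i)) stop("reaction '", rids[j], "' references unknown species '",
                           met, "' in ", path)
        S[i, j] <- S[i, j] + sg * coef
      }
    }
    lbref <- xml2::xml_attr(node, "lowerFluxBound")
    ubref <- xml2::xml_attr(node, "upperFluxBound")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb[j] <- if (!is.na(lbref) && lbref %in% names(pval)) pval[[lbref]] else if (rev) -1000 else 0
    ub[j] <- if (!is.na(ubref) && ubref %in% names(pval)) pval[[ubref]] else 1000
  }
  fobj <- xml2::xml_find_all(doc, ".//*[local-name()='fluxObjective']")
  objective <- numeric(length(rids))
  for (fo in fobj) {
    r <- xml2::xml_attr(fo, "reaction")
    coefs <- as.numeric(xml2::xml_attr(fo, "coefficient"))
    i <- match(r, rids)
    if (!is.na(i)) objective[i] <- coefs
  }
  kind <- rep("internal", length(rids))
  for (j in seq_along(rids)) {
    touched <- which(S[, j] != 0)
    if (length(touched) && all(mets$external[touched])) kind[j] <- "exchange"
  }
  kind[objective != 0] <- "biomass"
  StrainModel(id = id, mets = mets,
              rxns = data.frame(id = rids, lb = lb, ub = ub, kind = kind,
                                stringsAsFactors = FALSE),
              S = S, objective = objective)
}

## ---- community JSON -------------------------------------------------------

.strainToList <- function(s) {
  tm <- as(s@S, "TsparseMatrix")
  list(id = s@id, mets = s@mets, rxns = s@rxns,
       stoich = data.frame(met = s@mets$id[tm@i + 1L],
                           rxn = s@rxns$id[tm@j + 1L], coef = tm@x),
       objective = s@objective)
}

.strainFromList <- function(l) {
  mets <- as.data.frame(l$mets); rxns <- as.data.frame(l$rxns)
  S <- Matrix::sparseMatrix(i = match(l$stoich$met, mets$id),
                            j = match(l$stoich$rxn, rxns$id),
                            x = l$stoich$coef,
                            dims = c(nrow(mets), nrow(rxns)))
  for (col in c("mu0", "conc_lo", "conc_hi"))
    if (!is.null(mets[[col]])) mets[[col]] <- as.numeric(mets[[col]])
  StrainModel(id = l$id, mets = mets, rxns = rxns, S = S,
              objective = as.numeric(l$objective))
}

#' Write a community model as a single JSON document
#'
#' @param model a \linkS4class{CommunityModel}.
#' @param path output file.
#' @export
writeCommunityModel <- function(model, path) {
  stopifnot(is(model, "CommunityModel"))
  validObject(model)
  doc <- list(
    format = "mofba-community",
    version = 1L,
    strains = lapply(model@strains, .strainToList),
    pool = list(shared = model@pool@shared, envBounds = model@pool@envBounds),
    couplings = lapply(model@couplings, function(cp)
      list(terms = cp$terms, relation = cp$relation, rhs = cp$rhs)))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, na = "null",
                       dataframe = "columns")
  invisible(path)
}

#' Read a community model from JSON
#'
#' @param path file written by \code{\link{writeCommunityModel}}.
#' @return a validated \linkS4class{CommunityModel}.
#' @export
readCommunityModel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "mofba-community"))
    stop("not a community JSON document: ", path)
  if (length(doc$strains) == 0L) stop("community JSON contains no strains")
  strains <- lapply(doc$strains, .strainFromList)
  pool <- poolSpec(shared = unlist(doc$pool$shared),
                   envBounds = as.data.frame(doc$pool$envBounds))
  cps <- doc$couplings
  couplings <- if (is.data.frame(cps)) {
    ## jsonlite simplifies the coupling array into a data.frame whose `terms`
    ## column holds per-coupling list columns
    lapply(seq_len(nrow(cps)), function(i)
      list(terms = data.frame(strain = unlist(cps$terms$strain[[i]]),
                              rxn = unlist(cps$terms$rxn[[i]]),
                              coef = as.numeric(unlist(cps$terms$coef[[i]])),
                              stringsAsFactors = FALSE),
           relation = cps$relation[i], rhs = as.numeric(cps$rhs[i])))
  } else {
    lapply(cps, function(cp)
      list(terms = data.frame(strain = unlist(cp$terms$strain),
                              rxn = unlist(cp$terms$rxn),
                              coef = as.numeric(unlist(cp$terms$coef)),
                              stringsAsFactors = FALSE),
           relation = cp$relation, rhs = as.numeric(cp$rhs)))
  }
  assembleCommunity(strains, pool, couplings)
}

## ---- thermodynamic tables -------------------------------------------------

#' Read a thermodynamic table
#'
#' TSV with columns \code{metabolite}, \code{mu0_kJ_mol}, \code{dg_kJ_mol} and
#' a comment line \code{# temperature_K: <T>}.
#'
#' @param path input file.
#' @return a \linkS4class{ThermoTable}.
#' @export
readThermoTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  tline <- grep("^#\\s*temperature_K:", lines, value = TRUE)
  temperature <- if (length(tline)) as.numeric(sub("^#\\s*temperature_K:\\s*", "", tline[1])) else 298.15
  body <- lines[!startsWith(trimws(lines), "#")]
  df <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("metabolite", "mu0_kJ_mol", "dg_kJ_mol")
  if (!all(need %in% names(df)))
    stop("thermo table needs columns ", paste(need, collapse = ", "), ": ", path)
  new("ThermoTable",
      entries = data.frame(metabolite = df$metabolite, mu0 = df$mu0_kJ_mol,
                           dg = df$dg_kJ_mol, stringsAsFactors = FALSE),
      temperature = temperature)
}

#' Write a thermodynamic table
#'
#' @param x a \linkS4class{ThermoTable}.
#' @param path output file.
#' @export
writeThermoTable <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste("# temperature_K:", format(x@temperature, digits = 12)), con)
  writeLines(paste("metabolite", "mu0_kJ_mol", "dg_kJ_mol", sep = "\t"), con)
  writeLines(paste(x@entries$metabolite,
                   format(x@entries$mu0, digits = 12, trim = TRUE),
                   format(x@entries$dg, digits = 12, trim = TRUE), sep = "\t"), con)
  invisible(path)
}

## ---- packaged hot-spring fixture -----------------------------------------

#' Load the packaged hot-spring mat community
#'
#' Returns the reduced three-guild model of a phototrophic hot-spring mat --
#' SYN (a Synechococcus-like oxygenic primary producer), FAP (filamentous
#' anoxygenic phototroph) and SRB (sulfate-reducing bacterium) -- together
#' with its thermodynamic table.  The model is a synthetic reconstruction:
#' guild quotas and environment caps are calibrated so that each guild's solo
#' FBA optimum is 1 per hour and the community Pareto front carries the
#' characteristic five-vertex trade-off structure of this ecosystem (see the
#' package vignette for the derivation); it is not the genome-scale curated
#' model.  The SYN guild carries the Rubisco oxygenase/carboxylase flux-ratio
#' coupling of 0.03.
#'
#' @return list with elements \code{community} (a
#'   \linkS4class{CommunityModel}) and \code{thermo} (a
#'   \linkS4class{ThermoTable}).
#' @examples
#' hs <- loadHotSpringFixture()
#' hs$community
#' @export
loadHotSpringFixture <- function() {
  dir <- system.file("extdata", "hotspring", package = "MOFBA")
  cj <- file.path(dir, "community_synthetic.json")
  tt <- file.path(dir, "thermo_synthetic.tsv")
  if (!file.exists(cj) || !file.exists(tt))
    stop("hot-spring supplementary data not encoded in this installation")
  list(community = readCommunityModel(cj), thermo = readThermoTable(tt))
}
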