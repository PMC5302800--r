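## End-to-end orchestration: community -> Pareto front -> mesh MO-FVA ->
## regional aggregates -> chemical motive force surface.

#' Run the full community analysis pipeline
#'
#' Computes the Pareto front of a community model, writes it as JSON and TSV,
#' and -- for three-objective communities -- meshes the front, runs MO-FVA at
#' every mesh point, aggregates the ranges over triangular regions, and maps
#' the maximal chemical motive force over the mesh.  All artifacts are
#' written under \code{outDir}; the run is deterministic for a fixed
#' configuration and seed.
#'
#' @param model a \linkS4class{CommunityModel} or the path of a community
#'   JSON file.
#' @param outDir output directory (created if missing).
#' @param thermo optional \linkS4class{ThermoTable} (or path of a thermo
#'   TSV); enables the cmf stage.
#' @param alpha fraction of the optimum for MO-FVA floors.
#' @param n mesh subdivisions per edge.
#' @param r regional resolution per edge.
#' @param reactions optional subset of \code{"strain:rxn"} labels for the
#'   mesh MO-FVA; default restricts to exchange reactions, which keeps the
#'   run size proportional to the community boundary.
#' @param seed integer seed for any randomized step (front verification).
#' @param tol solver tolerance.
#' @param verify number of random weight vectors used to cross-check the
#'   front (0 disables).
#' @return invisibly, a list with the computed objects and artifact paths.
#' @export
runPipeline <- function(model, outDir, thermo = NULL, alpha = 0.9, n = 20L,
                        r = 5L, reactions = NULL, seed = 1L, tol = 1e-6,
                        verify = 25L) {
  if (is.character(model)) {
    if (!file.exists(model)) stop("missing input file: ", model)
    model <- readCommunityModel(model)
  }
  if (is.character(thermo)) {
    if (!file.exists(thermo)) stop("missing input file: ", thermo)
    thermo <- readThermoTable(thermo)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  note <- function(...) message("[mofba] ", ...)
  art <- list()

  note("solving MO-FBA (", length(model@strains), " objectives)")
  front <- solveMOFBA(model, tol = tol)
  art$front_json <- writeParetoFront(front, file.path(outDir, "front.json"), "json")
  art$front_tsv <- writeParetoFront(front, file.path(outDir, "front.tsv"), "tsv")
  note(nrow(front@vertices), " front vertices, ", nrow(front@facetNormals),
       " facets")
  verification <- NULL
  if (verify > 0) {
    verification <- verifyFront(front, model, nSamples = verify, seed = seed, tol = 1e-5)
    note("front verification: ", if (verification$ok) "ok" else
      paste(nrow(verification$violations), "violation(s)"))
  }

  mesh <- ranges <- regions <- cmf <- NULL
  if (front@k == 3L) {
    note("meshing the front at n = ", n)
    mesh <- meshFront(front, n = n, model = model)
    if (is.null(reactions)) {
      ex <- model@rxnMap$kind == "exchange"
      reactions <- paste(model@rxnMap$strain[ex], model@rxnMap$rxn[ex], sep = ":")
    }
    note("MO-FVA over ", nrow(mesh@points), " mesh points x ",
         length(reactions), " reactions at alpha = ", alpha)
    ranges <- mofvaOverMesh(model, mesh, alpha = alpha, reactions = reactions)
    long <- do.call(rbind, lapply(seq_along(ranges), function(q)
      cbind(point = q, b1 = mesh@bary[q, 1], b2 = mesh@bary[q, 2],
            b3 = mesh@bary[q, 3], ranges[[q]]@ranges)))
    art$mesh_tsv <- file.path(outDir, "mesh_ranges.tsv")
    write.table(long, art$mesh_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    regions <- aggregateRegions(mesh, ranges, r)
    art$regions_tsv <- file.path(outDir, "regions.tsv")
    write.table(regions, art$regions_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(thermo)) {
      note("cmf over the mesh")
      cmf <- cmfOverMesh(model, mesh, thermo, alpha = alpha)
      art$cmf_tsv <- file.path(outDir, "cmf.tsv")
      write.table(cmf, art$cmf_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else {
    note("mesh/cmf stages need k = 3 objectives; skipped (k = ", front@k, ")")
  }

  summary <- list(
    strains = strainIds(model),
    nVertices = nrow(front@vertices),
    vertices = front@vertices,
    frontVerified = if (!is.null(verification)) verification$ok else NA,
    alpha = alpha, n = n, r = r, seed = seed,
    nMeshPoints = if (!is.null(mesh)) nrow(mesh@points) else 0L,
    nRegions = if (!is.null(regions)) length(unique(regions$region)) else 0L,
    cmfRange = if (!is.null(cmf)) range(cmf$cmf) else NULL,
    artifacts = lapply(art, normalizePath))
  art$summary_json <- file.path(outDir, "summary.json")
  jsonlite::write_json(summary, art$summary_json, digits = NA,
                       auto_unbox = TRUE, matrix = "rowmajor", null = "null")
  invisible(list(front = front, mesh = mesh, ranges = ranges,
                 regions = regions, cmf = cmf, verification = verification,
                 artifacts = art))
}
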