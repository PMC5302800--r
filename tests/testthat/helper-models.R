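# Small fixture builders shared across the test files.

# three-reaction chain: capped uptake -> conversion -> biomass
chainStrain <- function(cap = 10, id = "chain") {
  StrainModel(
    id = id,
    mets = data.frame(id = c("A", "B"), external = c(TRUE, FALSE)),
    rxns = data.frame(id = c("EX_A", "CONV", "BIO"),
                      lb = c(-cap, 0, 0), ub = c(1000, 1000, 1000),
                      kind = c("exchange", "internal", "biomass")),
    S = matrix(c(-1, 0, -1, 1, 0, -1), 2, 3,
               dimnames = list(c("A", "B"), c("EX_A", "CONV", "BIO"))))
}

# two identical internal pathways feeding one biomass (degenerate optimum)
parallelStrain <- function(cap = 10) {
  StrainModel(
    id = "parallel",
    mets = data.frame(id = c("A", "B"), external = c(TRUE, FALSE)),
    rxns = data.frame(id = c("EX_A", "P1", "P2", "BIO"),
                      lb = c(-cap, 0, 0, 0), ub = c(1000, 1000, 1000, 1000),
                      kind = c("exchange", "internal", "internal", "biomass")),
    S = matrix(c(-1, 0, -1, 1, -1, 1, 0, -1), 2, 4,
               dimnames = list(c("A", "B"), NULL)))
}

# the same toy model written as paired tabular and SBML files; returns paths
writePairedToy <- function(dir = tempdir()) {
  tab <- file.path(dir, "paired_toy.tsv")
  sbml <- file.path(dir, "paired_toy.xml")
  writeLines(c(
    "# id: toy",
    "[METABOLITES]",
    "id\tname\tcompartment\texternal\tmu0\tconc_lo\tconc_hi",
    "A_e\tnutrient\te\tTRUE\t\t\t",
    "B_c\tinter\tc\tFALSE\t\t\t",
    "[REACTIONS]",
    "id\tformula\tlb\tub\tkind\tobjective",
    "EX_A\t1 A_e ->\t-10\t1000\texchange\t0",
    "T1\t1 A_e -> 1 B_c\t0\t1000\tinternal\t0",
    "BIO\t2 B_c ->\t0\t1000\tbiomass\t1"), tab)
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    '      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    '      level="3" version="1" fbc:required="false">',
    '  <model id="toy" fbc:strict="true">',
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '      <compartment id="e" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    '      <species id="A_e" name="nutrient" compartment="e" constant="false"',
    '               hasOnlySubstanceUnits="false" boundaryCondition="false"/>',
    '      <species id="B_c" name="inter" compartment="c" constant="false"',
    '               hasOnlySubstanceUnits="false" boundaryCondition="false"/>',
    '    </listOfSpecies>',
    '    <listOfParameters>',
    '      <parameter id="lb_m10" value="-10" constant="true"/>',
    '      <parameter id="lb_0" value="0" constant="true"/>',
    '      <parameter id="ub_1000" value="1000" constant="true"/>',
    '    </listOfParameters>',
    '    <listOfReactions>',
    '      <reaction id="EX_A" reversible="true" fast="false" fbc:lowerFluxBound="lb_m10" fbc:upperFluxBound="ub_1000">',
    '        <listOfReactants><speciesReference species="A_e" stoichiometry="1" constant="true"/></listOfReactants>',
    '      </reaction>',
    '      <reaction id="T1" reversible="false" fast="false" fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_1000">',
    '        <listOfReactants><speciesReference species="A_e" stoichiometry="1" constant="true"/></listOfReactants>',
    '        <listOfProducts><speciesReference species="B_c" stoichiometry="1" constant="true"/></listOfProducts>',
    '      </reaction>',
    '      <reaction id="BIO" reversible="false" fast="false" fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_1000">',
    '        <listOfReactants><speciesReference species="B_c" stoichiometry="2" constant="true"/></listOfReactants>',
    '      </reaction>',
    '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    '          <fbc:fluxObjective fbc:reaction="BIO" fbc:coefficient="1"/>',
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>',
    '</sbml>'), sbml)
  list(tabular = tab, sbml = sbml)
}

# random weight grid over the k-simplex (strictly includes the corners)
weightGrid <- function(k, npts) {
  if (k == 1) return(matrix(1, 1, 1))
  if (k == 2) {
    g <- seq(0, 1, length.out = npts)
    return(cbind(g, 1 - g))
  }
  m <- ceiling(sqrt(2 * npts))
  W <- as.matrix(expand.grid(i = 0:m, j = 0:m))
  W <- W[rowSums(W) <= m, ]
  W <- cbind(W, m - rowSums(W)) / m
  W[seq_len(min(npts, nrow(W))), , drop = FALSE]
}

expect_point_on_front <- function(y, front, tol = 1e-6) {
  scale <- max(1, max(abs(front@vertices)))
  slack <- as.numeric(front@facetNormals %*% y) - front@facetOffsets
  expect_lte(max(slack), tol * scale)
  expect_lte(min(abs(slack)), tol * scale)
  for (i in seq_len(nrow(front@vertices))) {
    u <- front@vertices[i, ]
    expect_false(all(y >= u - tol * scale) && any(y > u + tol * scale),
                 info = "a sampled efficient point dominates a front vertex")
  }
}
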