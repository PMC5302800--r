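# Community assembly: block structure, pool mirroring, couplings, and the
# compartment semantics that distinguish a community from a supra-organism.

test_that("single strain with its pool reduces to the strain model", {
  s <- chainStrain(cap = 10)
  cm <- assembleCommunity(list(s), poolSpec("A", data.frame(met = "A", lb = -10, ub = 1000)))
  # strain block equals S; one extra pool row and env column
  expect_equal(as.matrix(cm@Ssigma[1:2, 1:3]), as.matrix(s@S),
               ignore_attr = TRUE)
  expect_equal(dim(cm@Ssigma), c(3L, 4L))
  expect_equal(fba(cm)@zStar, fba(s)@zStar)
})

test_that("pool rows mirror strain exchanges with flipped sign", {
  s1 <- chainStrain(cap = 5, id = "u")
  s2 <- chainStrain(cap = 5, id = "w")
  cm <- assembleCommunity(list(s1, s2),
                          poolSpec("A", data.frame(met = "A", lb = -7, ub = 1000)))
  # hand-written community matrix: strain blocks + pool row for A
  expected <- matrix(0, 5, 7)
  expected[1:2, 1:3] <- as.matrix(s1@S)
  expected[3:4, 4:6] <- as.matrix(s2@S)
  expected[5, c(1, 4)] <- 1    # mirror of the two EX_A columns (-(-1))
  expected[5, 7] <- -1         # pool -> environment exchange
  expect_equal(as.matrix(cm@Ssigma), expected, ignore_attr = TRUE)
  # community optimum is limited by the pool cap, not the strain caps
  expect_equal(fba(cm)@zStar, 7, tolerance = 1e-7)
})

test_that("community columns count strains plus pool exchanges", {
  hs <- makeHotSpringCommunity()
  cm <- hs$community
  nbar <- sum(vapply(cm@strains, function(s) nrow(s@rxns), 0L)) +
    length(cm@pool@shared)
  expect_equal(ncol(cm@Ssigma), nbar)
  expect_equal(nrow(cm@rxnMap), nbar)
  expect_equal(ncol(cm@C), 3L)
})

test_that("assembly validates shared metabolites and strain ids", {
  s <- chainStrain()
  expect_error(
    assembleCommunity(list(s), poolSpec(c("A", "ghost"))),
    "never exchanged")
  expect_error(
    assembleCommunity(list(s, s), poolSpec("A")),
    "duplicate strain id")
})

test_that("mass balance holds for feasible community fluxes, pool included", {
  for (seed in c(3, 14)) {
    cm <- randomCommunity(seed, k = 3, reactionsPerStrain = 9)
    r <- fba(cm)
    expect_equal(r@status, "optimal")
    expect_lte(max(abs(cm@Ssigma %*% r@flux)), 1e-7)
  }
  hs <- makeHotSpringCommunity()
  r <- fba(hs$community)
  expect_lte(max(abs(hs$community@Ssigma %*% r@flux)), 1e-7)
})

test_that("ratio couplings constrain fluxes as written", {
  toy <- makeCompetition(c(1, 1), 10)$model
  # rho = 0 forces the first reaction to zero
  m0 <- addRatioCoupling(toy, "S1", "BIO", "EX_nutrient", 0)
  r0 <- fba(m0, objective = m0@C[, 1])
  expect_equal(r0@zStar, 0, tolerance = 1e-9)
  # rho = 1 on duplicated reactions forces equal fluxes
  m1 <- addRatioCoupling(toy, "S1", "BIO", "BIO", 1)
  expect_equal(fba(m1, objective = m1@C[, 1])@zStar, 10, tolerance = 1e-7)
  expect_error(addRatioCoupling(toy, "S1", "BIO", "nope", 1), "unknown reaction")
})

test_that("the Rubisco oxygenase ratio holds in every optimal hot-spring flux", {
  cm <- makeHotSpringCommunity()$community
  for (j in 1:3) {
    r <- fba(cm, objective = cm@C[, j])
    v961 <- r@flux[["SYN:RXN-961"]]
    vrbc <- r@flux[["SYN:RIBULOSE-BISPHOSPHATE-CARBOXYLASE-RXN"]]
    expect_equal(v961, 0.03 * vrbc, tolerance = 1e-7)
  }
})

test_that("de-compartmentalization changes FBA optima", {
  # strain A owns the converting enzyme, strain B does not: in compartments B
  # cannot grow, merged into one bag its biomass can use A's enzyme
  mkA <- function() StrainModel("A",
    mets = data.frame(id = c("s", "p"), external = c(TRUE, FALSE)),
    rxns = data.frame(id = c("EX_s", "ENZ", "BIO"),
                      lb = c(-5, 0, 0), ub = c(1000, 1000, 1000),
                      kind = c("exchange", "internal", "biomass")),
    S = matrix(c(-1, 0, -1, 1, 0, -1), 2, 3))
  mkB <- function() StrainModel("B",
    mets = data.frame(id = c("s", "p"), external = c(TRUE, FALSE)),
    rxns = data.frame(id = c("EX_s", "BIO"),
                      lb = c(-5, 0), ub = c(1000, 1000),
                      kind = c("exchange", "biomass")),
    S = matrix(c(-1, 0, 0, -1), 2, 2))
  cm <- assembleCommunity(list(mkA(), mkB()),
                          poolSpec("s", data.frame(met = "s", lb = -10, ub = 1000)))
  compartmentalized <- fba(cm)@zStar
  merged <- StrainModel("bag",
    mets = data.frame(id = c("s", "p"), external = c(TRUE, FALSE)),
    rxns = data.frame(id = c("EX_s", "ENZ", "BIO_A", "BIO_B"),
                      lb = c(-10, 0, 0, 0), ub = rep(1000, 4),
                      kind = c("exchange", "internal", "biomass", "internal")),
    S = matrix(c(-1, 0, -1, 1, 0, -1, 0, -1), 2, 4),
    objective = c(0, 0, 1, 1))
  expect_equal(compartmentalized, 5, tolerance = 1e-7)   # only A grows
  expect_equal(fba(merged)@zStar, 10, tolerance = 1e-7)  # the bag overcounts
})

test_that("k copies of a strain with a generous pool keep their solo optimum", {
  base <- chainStrain(cap = 4, id = "c1")
  copies <- lapply(1:3, function(i) { s <- base; s@id <- paste0("c", i); s })
  cm <- assembleCommunity(copies,
                          poolSpec("A", data.frame(met = "A", lb = -1000, ub = 1000)))
  solo <- fba(base)@zStar
  for (j in 1:3)
    expect_equal(fba(cm, objective = cm@C[, j])@zStar, solo, tolerance = 1e-7)
})
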