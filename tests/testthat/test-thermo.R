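# Chemical potentials and chemical-motive-force maximization.

test_that("computeDg evaluates R T ln(ratio) and guards its domain", {
  expect_equal(computeDg(348.15, 1e3), 8.314 * 348.15 * log(1e3) / 1000)
  expect_equal(computeDg(348.15, 1e3), 20, tolerance = 0.01)   # about 20 kJ/mol
  expect_equal(computeDg(500, 1), 0)
  expect_equal(computeDg(298.15, 10), 8.314 * 298.15 * log(10) / 1000)
  expect_equal(computeDg(298.15, 10), 5.708, tolerance = 1e-3)
  expect_error(computeDg(-1, 10), "positive")
  expect_error(computeDg(300, 0), "positive")
})

test_that("photonPotential solves Delta-mu = 0 for the printed reaction", {
  tt <- makeHotSpringCommunity()$thermo
  expect_equal(photonPotential(tt), 68.6, tolerance = 1e-9)
  # homogeneity: doubling the stoichiometry and photon count changes nothing
  expect_equal(photonPotential(tt, c(co2 = -12, h2o = -12, glc = 2), 96),
               68.6, tolerance = 1e-9)
  # all-zero potentials give a zero photon potential
  t0 <- new("ThermoTable",
            entries = data.frame(metabolite = c("co2", "h2o", "glc"),
                                 mu0 = 0, dg = 0),
            temperature = 348.15)
  expect_equal(photonPotential(t0), 0)
  expect_error(photonPotential(tt, c(ghost = -1), 10), "ghost")
})

test_that("corner enumeration solves the box cmf problem exactly", {
  tt <- new("ThermoTable",
            entries = data.frame(metabolite = "m", mu0 = 10, dg = 20),
            temperature = 348.15)
  r <- maximizeCmf(data.frame(reaction = "m", vmin = -2, vmax = 3), tt)
  expect_equal(r@cmf, 90)
  expect_equal(unname(r@v), 3)
  expect_equal(unname(r@mu), 30)
  expect_equal(r@cmf, sum(r@mu * r@v))
})

test_that("no freedom means cmf = sum(mu0 * v)", {
  tt <- new("ThermoTable",
            entries = data.frame(metabolite = c("a", "b"), mu0 = c(5, -3),
                                 dg = c(0, 0)),
            temperature = 348.15)
  rg <- data.frame(reaction = c("a", "b"), vmin = c(2, -1), vmax = c(2, -1))
  expect_equal(maximizeCmf(rg, tt)@cmf, 5 * 2 + (-3) * (-1))
})

test_that("boxes containing zero always allow a non-negative cmf", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(1:6, 1)
    tt <- new("ThermoTable",
              entries = data.frame(metabolite = paste0("m", 1:n),
                                   mu0 = runif(n, -50, 50), dg = runif(n, 10, 60)),
              temperature = 348.15)
    rg <- data.frame(reaction = paste0("m", 1:n),
                     vmin = runif(n, -5, 0), vmax = runif(n, 0, 5))
    expect_gte(maximizeCmf(rg, tt)@cmf, 0)
  }
})

test_that("corner maximum bounds random feasible (mu, v) samples", {
  set.seed(9)
  n <- 5
  tt <- new("ThermoTable",
            entries = data.frame(metabolite = paste0("m", 1:n),
                                 mu0 = runif(n, -40, 40), dg = runif(n, 0, 30)),
            temperature = 348.15)
  rg <- data.frame(reaction = paste0("m", 1:n),
                   vmin = runif(n, -4, 1), vmax = runif(n, 1, 4))
  best <- maximizeCmf(rg, tt)@cmf
  i <- match(rg$reaction, tt@entries$metabolite)
  for (s in 1:200) {
    v <- runif(n, rg$vmin, rg$vmax)
    mu <- runif(n, tt@entries$mu0[i] - tt@entries$dg[i],
                tt@entries$mu0[i] + tt@entries$dg[i])
    expect_lte(sum(mu * v), best + 1e-9)
  }
})

test_that("numeric optimizer never exceeds and matches the corner oracle", {
  set.seed(10)
  for (i in 1:30) {
    n <- sample(1:8, 1)
    tt <- new("ThermoTable",
              entries = data.frame(metabolite = paste0("m", 1:n),
                                   mu0 = runif(n, -100, 100), dg = runif(n, 0, 40)),
              temperature = 348.15)
    rg <- data.frame(reaction = paste0("m", 1:n),
                     vmin = runif(n, -6, 2), vmax = NA)
    rg$vmax <- rg$vmin + runif(n, 0, 6)
    corner <- maximizeCmf(rg, tt, method = "corner")@cmf
    numeric <- maximizeCmf(rg, tt, method = "numeric")@cmf
    expect_lte(numeric, corner + 1e-9 * max(1, abs(corner)))
    expect_equal(numeric, corner, tolerance = 1e-6)
  }
})

test_that("cmf grows when flux intervals or potential boxes are enlarged", {
  tt <- new("ThermoTable",
            entries = data.frame(metabolite = c("a", "b"), mu0 = c(12, -7),
                                 dg = c(5, 5)),
            temperature = 348.15)
  rg <- data.frame(reaction = c("a", "b"), vmin = c(-1, -2), vmax = c(2, 1))
  base <- maximizeCmf(rg, tt)@cmf
  wide <- rg; wide$vmin <- wide$vmin - 1; wide$vmax <- wide$vmax + 1
  expect_gte(maximizeCmf(wide, tt)@cmf, base)
  tt2 <- tt; tt2@entries$dg <- tt@entries$dg + 10
  expect_gte(maximizeCmf(rg, tt2)@cmf, base)
})

test_that("infinite flux ranges and missing entries are refused", {
  tt <- new("ThermoTable",
            entries = data.frame(metabolite = "a", mu0 = 1, dg = 0),
            temperature = 300)
  expect_error(maximizeCmf(data.frame(reaction = "a", vmin = 0, vmax = Inf), tt),
               "unbounded")
  expect_error(maximizeCmf(data.frame(reaction = "zz", vmin = 0, vmax = 1), tt),
               "zz")
})

test_that("cmf over a mesh counts points and reports the argmax", {
  hs <- makeHotSpringCommunity()
  front <- solveMOFBA(hs$community)
  mesh <- meshFront(front, n = 1)
  cmf <- cmfOverMesh(hs$community, mesh, hs$thermo, alpha = 0.9)
  expect_equal(nrow(cmf), 3L)
  expect_true(all(is.finite(cmf$cmf)))
  expect_equal(attr(cmf, "argmax"), which.max(cmf$cmf))
})

test_that("in a photon-driven producer toy, cmf peaks with producer growth", {
  # single phototroph community: growth is proportional to photon intake, so
  # the maximal cmf coincides with maximal growth
  s <- StrainModel("prod",
    mets = data.frame(id = c("hv"), external = TRUE),
    rxns = data.frame(id = c("EX_hv", "BIO"), lb = c(-8, 0), ub = c(0, 1000),
                      kind = c("exchange", "biomass")),
    S = matrix(c(-1, -1), 1, 2))
  cm <- assembleCommunity(list(s), poolSpec("hv", data.frame(met = "hv", lb = -8, ub = 0)))
  tt <- new("ThermoTable",
            entries = data.frame(metabolite = "hv", mu0 = 68.6, dg = 0),
            temperature = 348.15)
  cmfAt <- function(g) {
    fr <- fva(cm, alpha = g / 8, reactions = ".pool:EX_hv")
    rg <- data.frame(reaction = "hv", vmin = -fr@ranges$vmax, vmax = -fr@ranges$vmin)
    maximizeCmf(rg, tt)@cmf
  }
  vals <- vapply(c(0.25, 0.5, 1), cmfAt, 0)
  expect_equal(vals, c(68.6 * 8, 68.6 * 8, 68.6 * 8))  # max uptake always allowed
  # force uptake tight to growth: fix the exchange by alpha = 1 at partial growth
  cm2 <- cm
  cm2@rxnMap$lb[cm2@rxnMap$rxn == "EX_hv"] <- -4
  fr <- fva(cm2, alpha = 1, reactions = ".pool:EX_hv")
  rg <- data.frame(reaction = "hv", vmin = -fr@ranges$vmax, vmax = -fr@ranges$vmin)
  expect_equal(maximizeCmf(rg, tt)@cmf, 68.6 * 4, tolerance = 1e-6)
})
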