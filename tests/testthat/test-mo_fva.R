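# MO-FVA: vector fraction-of-optimum floors, front meshing, regional
# aggregation.

test_that("objective floors at a vertex with alpha = 1 pin the biomasses", {
  hs <- makeHotSpringCommunity()
  cm <- hs$community
  front <- solveMOFBA(cm)
  v <- front@vertices[2, ]  # the mixed SYN/SRB vertex
  fr <- mofvaAtPoint(cm, v, alpha = 1,
                     reactions = c("SYN:BIO_SYN", "FAP:BIO_FAP", "SRB:BIO_SRB"))
  expect_equal(fr@ranges$vmin, unname(v), tolerance = 1e-6)
  expect_equal(fr@ranges$vmax, unname(v), tolerance = 1e-6)
})

test_that("a zero component of f* leaves that strain's floor vacuous", {
  toy <- makeCompetition(c(1, 0.5), 10)$model
  fr <- mofvaAtPoint(toy, c(5, 0), alpha = 1,
                     reactions = c("S1:BIO", "S2:BIO"))
  expect_equal(fr@ranges$vmin[1], 5, tolerance = 1e-7)   # floored
  expect_equal(fr@ranges$vmin[2], 0, tolerance = 1e-9)   # vacuous
  expect_equal(fr@ranges$vmax[2], 2.5, tolerance = 1e-7) # half the residual cap
})

test_that("points above the front are rejected with a status error", {
  toy <- makeCompetition(c(1, 0.5), 10)$model
  err <- tryCatch(mofvaAtPoint(toy, c(10, 5), alpha = 1), error = identity)
  expect_s3_class(err, "mofbaStatusError")
})

test_that("MO-FVA at alpha = 0 equals unconstrained community FVA", {
  toy <- makeCompetition(c(1, 0.5), 10)$model
  a <- mofvaAtPoint(toy, c(10, 0), alpha = 0)
  b <- fva(toy, alpha = 0)
  expect_equal(a@ranges$vmin, b@ranges$vmin, tolerance = 1e-6)
  expect_equal(a@ranges$vmax, b@ranges$vmax, tolerance = 1e-6)
})

test_that("MO-FVA ranges are nested in alpha", {
  hs <- makeHotSpringCommunity()
  cm <- hs$community
  p <- c(0.27, 0, 0.89)
  rxns <- paste0(".pool:EX_", c("hv", "co2", "nh3", "ac"))
  prev <- NULL
  for (a in c(0, 0.5, 0.9, 1)) {
    fr <- mofvaAtPoint(cm, p, alpha = a, reactions = rxns)
    if (!is.null(prev)) {
      expect_true(all(fr@ranges$vmin >= prev$vmin - 1e-6))
      expect_true(all(fr@ranges$vmax <= prev$vmax + 1e-6))
    }
    prev <- fr@ranges
  }
})

test_that("reported bounds are attained by feasible flux vectors", {
  hs <- makeHotSpringCommunity()
  cm <- hs$community
  p <- c(0.27, 0, 0.89)
  rxns <- c("SYN:EX_nh3", ".pool:EX_hv", "SRB:BIO_SRB")
  fr <- mofvaAtPoint(cm, p, alpha = 0.9, reactions = rxns)
  lp <- MOFBA:::.lpData(cm)
  A <- rbind(lp$A, Matrix::t(Matrix::Matrix(cm@C, sparse = TRUE)))
  rhs <- c(lp$rhs, 0.9 * p)
  sense <- c(lp$sense, rep(">=", 3))
  for (q in seq_len(nrow(fr@ranges))) {
    j <- match(fr@ranges$reaction[q], lp$cols)
    for (bound in c(fr@ranges$vmin[q], fr@ranges$vmax[q])) {
      lb <- lp$lb; ub <- lp$ub
      lb[j] <- bound - 1e-7; ub[j] <- bound + 1e-7
      s <- solveLP(rep(0, length(lb)), A, rhs, sense, lb, ub)
      expect_equal(s$status, "optimal")
    }
  }
})

test_that("pool steady state limits strain exchanges at mesh points", {
  # net strain exports of a pool metabolite must match the environment range
  hs <- makeHotSpringCommunity()
  cm <- hs$community
  p <- c(0.27, 0, 0.89)
  labels <- c("SYN:EX_nh3", "FAP:EX_nh3", "SRB:EX_nh3", ".pool:EX_nh3")
  fr <- mofvaAtPoint(cm, p, alpha = 0.9, reactions = labels)
  rg <- fr@ranges
  strainSum <- function(col) sum(rg[[col]][1:3])
  expect_gte(rg$vmax[4], strainSum("vmin") - 1e-6)
  expect_lte(rg$vmin[4], strainSum("vmax") + 1e-6)
})

test_that("mesh sizes follow the triangular-number law", {
  front <- solveMOFBA(makeHotSpringCommunity()$community)
  expect_equal(nrow(meshFront(front, n = 1)@points), 3L)
  expect_equal(nrow(meshFront(front, n = 2)@points), 6L)
  expect_equal(nrow(meshFront(front, n = 100)@points), 5151L)
  m1 <- meshFront(front, n = 1)
  # anchors are the per-objective maxima
  expect_equal(sort(rowSums(m1@points)), c(1, 1, 1), tolerance = 1e-9)
})

test_that("meshing refuses fronts with k != 3", {
  f2 <- solveMOFBA(makeCompetition(c(1, 0.5), 10)$model)
  expect_error(meshFront(f2, n = 5), "k = 3")
})

test_that("lifted mesh points dominate their flat counterparts", {
  cm <- makeHotSpringCommunity()$community
  front <- solveMOFBA(cm)
  flat <- meshFront(front, n = 4)
  lifted <- meshFront(front, n = 4, mode = "lifted", model = cm)
  expect_true(all(lifted@points >= flat@points - 1e-7))
  expect_gte(sum(lifted@points - flat@points), 0.01)  # interior points rise
})

test_that("regional aggregation partitions the mesh into r^2 regions", {
  cm <- makeHotSpringCommunity()$community
  front <- solveMOFBA(cm)
  mesh <- meshFront(front, n = 9)
  rs <- mofvaOverMesh(cm, mesh, alpha = 0.9, reactions = ".pool:EX_hv")
  agg3 <- aggregateRegions(mesh, rs, r = 3)
  expect_equal(length(unique(agg3$region)), 9L)
  expect_equal(sum(agg3$nPoints[!duplicated(agg3$region)]), nrow(mesh@bary))
  # r = 1: one region holding the global means
  agg1 <- aggregateRegions(mesh, rs, r = 1)
  expect_equal(length(unique(agg1$region)), 1L)
  expect_equal(agg1$vminMean, mean(vapply(rs, function(x) x@ranges$vmin, 0)))
  expect_equal(agg1$vmaxMean, mean(vapply(rs, function(x) x@ranges$vmax, 0)))
  # constant ranges aggregate to that constant
  const <- lapply(seq_along(rs), function(q)
    new("FluxRangeSet", alpha = 0.9,
        ranges = data.frame(reaction = "x", vmin = -1.5, vmax = 2.5),
        reference = c(0, 0, 0)))
  aggc <- aggregateRegions(mesh, const, r = 3)
  expect_true(all(aggc$vminMean == -1.5) && all(aggc$vmaxMean == 2.5))
  # incompatible resolution: some regions catch no mesh point
  expect_error(aggregateRegions(mesh, rs, r = 15), "empty region")
})
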