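# Multi-objective FBA: exact fronts, scalarizations and their properties.

test_that("two-strain competition front matches the closed form", {
  toy <- makeCompetition(c(1, 0.5), 10)
  front <- solveMOFBA(toy$model)
  expect_equal(front@vertices, rbind(c(10, 0), c(0, 5)),
               ignore_attr = TRUE, tolerance = 1e-7)
  # the trade-off facet f1/10 + f2/5 <= 1 must be present (up to scaling)
  nf <- front@facetNormals / front@facetOffsets
  hit <- apply(nf, 1, function(r) isTRUE(all.equal(unname(r), c(0.1, 0.2),
                                                   tolerance = 1e-6)))
  expect_true(any(hit))
})

test_that("k = 1 front degenerates to the FBA optimum", {
  toy <- makeCompetition(1.3, 7)$model
  front <- solveMOFBA(toy)
  expect_equal(dim(front@vertices), c(1L, 1L))
  expect_equal(unname(front@vertices[1, 1]), fba(toy)@zStar, tolerance = 1e-9)
})

test_that("degenerate fronts: zero nutrient cap collapses to the origin", {
  front <- solveMOFBA(makeCompetition(c(1, 0.5), 0)$model)
  expect_equal(front@vertices, rbind(c(0, 0)), ignore_attr = TRUE)
})

test_that("unbounded strain objectives are refused by name", {
  s <- chainStrain(cap = 10, id = "ubd")
  s@rxns$ub[] <- Inf
  s@rxns$lb[s@rxns$id == "EX_A"] <- -Inf
  cm <- assembleCommunity(list(s), poolSpec("A", data.frame(met = "A", lb = -Inf, ub = Inf)))
  expect_error(solveMOFBA(cm), "ubd")
})

test_that("weighted sums land on the front with the supporting-plane property", {
  toy <- makeCompetition(c(1, 0.5), 10)
  front <- solveMOFBA(toy$model)
  # unit weight on strain j recovers the embedded solo optimum
  expect_equal(weightedSum(toy$model, c(1, 0))$point,
               c(S1 = 10, S2 = 0), tolerance = 1e-7)
  # equal weights prefer the higher-yield strain
  expect_equal(weightedSum(toy$model, c(1, 1))$point,
               c(S1 = 10, S2 = 0), tolerance = 1e-7)
  # any positive weights: on the boundary, tight on >= 1 facet
  set.seed(4)
  for (i in 1:20) {
    w <- runif(2, 0.05, 1)
    expect_point_on_front(weightedSum(toy$model, w)$point, front)
  }
  expect_error(weightedSum(toy$model, c(0, 0)), "positive")
})

test_that("epsilon-constraint floors behave as constraints", {
  toy <- makeCompetition(c(1, 0.5), 10)$model
  # nutrient fully consumed by strain 1 leaves nothing for strain 2
  expect_equal(epsilonConstraint(toy, 2, eps = 10)$point,
               c(S1 = 10, S2 = 0), tolerance = 1e-7)
  # zero floors reduce to the community solo optimum
  expect_equal(epsilonConstraint(toy, 1, eps = 0)$point[["S1"]], 10,
               tolerance = 1e-7)
  err <- tryCatch(epsilonConstraint(toy, 2, eps = 11), error = identity)
  expect_s3_class(err, "mofbaStatusError")
  expect_match(conditionMessage(err), "infeasible")
})

test_that("verifyFront accepts a correct front and flags a sabotaged one", {
  toy <- makeCompetition(c(1, 0.5), 10)
  front <- solveMOFBA(toy$model)
  rep <- verifyFront(front, toy$model, nSamples = 100, seed = 2)
  expect_true(rep$ok)
  expect_equal(nrow(rep$violations), 0L)
  # inject a dominated vertex: samples on the true front now dominate it
  bad <- front
  bad@vertices <- rbind(front@vertices, c(5, 0))
  rep2 <- verifyFront(bad, toy$model, nSamples = 50, seed = 2)
  expect_false(rep2$ok)
  expect_gte(nrow(rep2$violations), 1L)
})

test_that("front vertices scale covariantly with per-strain objectives", {
  toy <- makeCompetition(c(1, 0.5), 10)$model
  f1 <- solveMOFBA(toy)
  scaled <- toy
  scaled@strains$S1@objective <- 3 * scaled@strains$S1@objective
  scaled@C[, 1] <- 3 * scaled@C[, 1]
  f2 <- solveMOFBA(scaled)
  v1 <- f1@vertices[order(f1@vertices[, 1]), ]
  v2 <- f2@vertices[order(f2@vertices[, 1]), ]
  expect_equal(v2[, 1], 3 * v1[, 1], tolerance = 1e-6)
  expect_equal(v2[, 2], v1[, 2], tolerance = 1e-6)
})

test_that("weight-grid scalarization confirms computed fronts (oracle route)", {
  for (seed in c(21, 33, 48)) {
    k <- 2 + seed %% 2
    cm <- randomCommunity(seed, k = k, reactionsPerStrain = 8)
    front <- solveMOFBA(cm)
    expect_gte(nrow(front@vertices), 1L)
    W <- weightGrid(k, 60)
    for (q in seq_len(nrow(W))) {
      w <- W[q, ]
      if (all(w == 0)) next
      expect_point_on_front(weightedSum(cm, w)$point, front)
    }
  }
})

test_that("every front vertex is recovered by weights from its normal cone", {
  for (model in list(makeCompetition(c(2, 1, 0.5), 6)$model,
                     makeHotSpringCommunity()$community)) {
    front <- solveMOFBA(model)
    scale <- max(1, max(abs(front@vertices)))
    for (i in seq_len(nrow(front@vertices))) {
      v <- front@vertices[i, ]
      active <- abs(as.numeric(front@facetNormals %*% v) - front@facetOffsets) <=
        1e-6 * scale
      expect_true(any(active))
      w <- colMeans(front@facetNormals[active, , drop = FALSE])
      y <- weightedSum(model, w)$point
      expect_equal(unname(y), unname(v), tolerance = 1e-5)
    }
  }
})
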