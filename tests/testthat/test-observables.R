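test_that("exchange bookkeeping: burial at 4 neighbours, release at 0, no nesting", {
  # scripted series: buried at t=3, freed at t=10 -> one 7 s passage
  log <- exchangeEventsFromCounts(time = c(1, 3, 6, 10),
                                  count = c(2, 4, 2, 0), tEnd = 20)
  expect_equal(nrow(log), 1L)
  expect_equal(log$release - log$burial, 7)
  expect_false(log$censored)

  # double burial without an intervening release stays one open interval
  log2 <- exchangeEventsFromCounts(time = c(1, 4, 5, 9),
                                   count = c(4, 3, 4, 0), tEnd = 20)
  expect_equal(nrow(log2), 1L)
  expect_equal(log2$burial, 1)
  expect_equal(log2$release, 9)

  # unresolved burial is censored at tEnd
  log3 <- exchangeEventsFromCounts(time = 2, count = 4, tEnd = 11)
  expect_true(log3$censored)
  expect_equal(log3$release, 11)

  # never buried -> empty log
  expect_equal(nrow(exchangeEventsFromCounts(c(1, 2), c(2, 3), 10)), 0L)
})

test_that("meanExchangeTime averages completed passages and reports censoring", {
  log <- data.frame(particle = c(1, 2), burial = c(3, 0),
                    release = c(10, 3), censored = c(FALSE, FALSE))
  m <- meanExchangeTime(log)
  expect_equal(m$mean, 5)
  expect_equal(m$censoringFraction, 0)

  cens <- data.frame(particle = 1:2, burial = c(0, 1), release = c(5, 6),
                     censored = c(TRUE, TRUE))
  mc <- meanExchangeTime(cens)
  expect_true(is.na(mc$mean))
  expect_equal(mc$censoringFraction, 1)

  # the Kaplan-Meier-style bound never exceeds the completed-event mean
  mix <- rbind(log, cens)
  mm <- meanExchangeTime(mix)
  expect_lte(mm$kmLowerBound, mm$mean)
  expect_equal(mm$censoringFraction, 0.5)
})

test_that("valencyUtilization splits free-valency fractions by largest cluster", {
  lam2 <- SimParams(latticeSize = 9, nParticles = 4, valency = 2, tEnd = 1,
                    snapshotInterval = 1)
  # chain of 3 bonded particles plus a distant monomer
  st <- mkState(9, cbind(c(4, 4, 4, 0), c(3, 4, 5, 0)))
  st <- placeBond(st, 1, 2, lam2)
  st <- placeBond(st, 2, 3, lam2)
  lab <- labelClusters(st)
  u <- valencyUtilization(st, lab, lam2)
  expect_equal(unname(u["inside"]), 1 - 4 / 6)
  expect_equal(unname(u["outside"]), 1)

  fresh <- makeFixture("adjacent_pair")
  uf <- valencyUtilization(fresh, labelClusters(fresh), lam2)
  expect_equal(unname(uf["inside"]), 1)

  lam0 <- SimParams(latticeSize = 9, nParticles = 4, valency = 0, tEnd = 1,
                    snapshotInterval = 1)
  expect_error(valencyUtilization(st, lab, lam0), "valency")
})

test_that("phase classification follows the L_clus and bonding thresholds", {
  expect_equal(classifyPhase(1.0, 3, 100), "macrophase")
  expect_equal(classifyPhase(0.5, 3, 100), "macrophase")
  expect_equal(classifyPhase(0.02, 0.01, 100), "NoPS")
  expect_equal(classifyPhase(0.3, 2, 100), "microphase")
  # low L_clus but substantial bonding is still clustered matter, not NoPS
  expect_equal(classifyPhase(0.04, 2, 100), "microphase")
  expect_error(classifyPhase(NA_real_, 1, 100), "missing")
})

test_that("criticalEpsilon returns the first grid crossing or a sentinel", {
  eps <- seq(0.5, 3, 0.5)
  expect_true(is.na(criticalEpsilon(eps, rep(0.2, 6))))
  expect_equal(criticalEpsilon(eps, c(0.05, 0.2, 0.55, 0.7, 0.9, 1)), 1.5)
  expect_error(criticalEpsilon(rev(eps), rep(0.2, 6)), "ascending")
})

test_that("a 1x1 sweep reproduces a direct run and is order-independent", {
  tpl <- SimParams(latticeSize = 20, phi = 0.05, valency = 5, epsSp = 3,
                   tEnd = 120, snapshotInterval = 120, seed = 3)
  sw <- phaseSweep(data.frame(epsSp = 3), tpl, replicates = 1, baseSeed = 50)
  direct <- runTrajectory(tpl, seed = as.integer(condensateKMC:::.seedFor(50, 1, 1)))
  sm <- trajectorySummary(direct)
  expect_equal(sw$meanLclus,
               sm$largestCluster[nrow(sm)] / nParticles(tpl))
  # rerunning gives byte-identical results (deterministic seed schedule)
  sw2 <- phaseSweep(data.frame(epsSp = 3), tpl, replicates = 1, baseSeed = 50)
  expect_identical(sw, sw2)
})

test_that("sweep failures are recorded per cell without aborting the sweep", {
  tpl <- SimParams(latticeSize = 15, phi = 0.05, valency = 5, epsSp = 3,
                   tEnd = 30, snapshotInterval = 30, seed = 3)
  grid <- data.frame(phiLattice = c(0.05, 2))  # second cell is invalid
  sw <- phaseSweep(grid, tpl, replicates = 1, baseSeed = 9)
  expect_false(is.na(sw$meanLclus[1]))
  expect_true(is.na(sw$meanLclus[2]))
  expect_match(sw$error[2], "density|nParticles")
})

test_that("exchange MFPT rises with bond strength on a small grid", {
  eps <- c(1.5, 2, 2.5)
  mfpt <- vapply(eps, function(e) {
    p <- microParams(L = 30, phi = 0.04, epsSp = e, tEnd = 3600, seed = 1)
    measureExchangeTimes(p, replicates = 6, baseSeed = 600)$mfpt$mean
  }, numeric(1))
  expect_true(all(is.finite(mfpt)))
  expect_gt(suppressWarnings(stats::cor(eps, mfpt, method = "spearman")), 0)
  expect_gt(mfpt[3] / mfpt[1], 1)
})
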