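pairParams <- function(valency = 1, epsSp = 2)
  SimParams(latticeSize = 9, nParticles = 2, valency = valency, epsSp = epsSp,
            epsNs = 0.35, kDiff = 1, kBond = 1, tEnd = 1, snapshotInterval = 1)

test_that("enumeration of an isolated particle gives four free moves", {
  p <- SimParams(latticeSize = 9, nParticles = 1, valency = 0, tEnd = 1,
                 snapshotInterval = 1)
  ev <- enumerateEvents(makeFixture("single_particle"), p)
  tab <- eventTable(ev)
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$kind == "monomer_move"))
  expect_equal(tab$rate, rep(kDiff(p), 4))
  expect_equal(rTotal(ev), 4 * kDiff(p))
  expect_setequal(tab$direction, c("N", "S", "E", "W"))
})

test_that("enumeration of an adjacent unbonded pair matches the hand-derived rates", {
  ev <- enumerateEvents(makeFixture("adjacent_pair"), pairParams())
  tab <- eventTable(ev)
  mono <- tab[tab$kind == "monomer_move", ]
  expect_equal(nrow(mono), 6L)
  expect_equal(mono$rate, rep(exp(-0.35), 6))
  expect_equal(sum(tab$kind == "bond_form"), 1L)
  expect_equal(sum(tab$kind == "cluster_move"), 4L)
  expect_equal(tab$rate[tab$kind == "cluster_move"], rep(0.5, 4))
  expect_equal(rTotal(ev), 6 * exp(-0.35) + 1 + 2, tolerance = 1e-12)
})

test_that("a bonded pair at full valency offers breakage but not formation", {
  ev <- enumerateEvents(makeFixture("bonded_dimer"), pairParams())
  tab <- eventTable(ev)
  expect_equal(sum(tab$kind == "bond_form"), 0L)
  brk <- tab[tab$kind == "bond_break", ]
  expect_equal(nrow(brk), 1L)
  expect_equal(brk$rate, exp(-2))          # k_break = k_bond exp(-eps_sp)
  # escape rate pays the full interaction energy
  mono <- tab[tab$kind == "monomer_move", ]
  expect_equal(mono$rate, rep(exp(-(2 + 0.35)), 6))
})

test_that("bond_break events are listed once per bond copy", {
  pair <- makeFixture("adjacent_pair")
  p <- pairParams(valency = 5)
  for (k in 1:3) pair <- placeBond(pair, 1, 2, p)
  tab <- eventTable(enumerateEvents(pair, p))
  expect_equal(sum(tab$kind == "bond_break"), 3L)
  expect_equal(sum(tab$kind == "bond_form"), 1L)  # spare valency remains
})

test_that("drawEvent picks the cumulative-rate interval containing u * rTotal", {
  ev <- new("EventSet",
            events = data.frame(kind = c("bond_form", "bond_form"),
                                a = 1:2, b = 2:3,
                                direction = NA_character_, rate = c(1, 3)),
            rTotal = 4)
  expect_equal(drawEvent(ev, 0.1)$a, 1L)
  expect_equal(drawEvent(ev, 0.5)$a, 2L)
  one <- new("EventSet",
             events = data.frame(kind = "bond_form", a = 1L, b = 2L,
                                 direction = NA_character_, rate = 2),
             rTotal = 2)
  for (u in c(0, 0.3, 0.999)) expect_equal(drawEvent(one, u)$a, 1L)
  empty <- new("EventSet", events = one@events[0, ], rTotal = 0)
  expect_error(drawEvent(empty, 0.5), "rTotal")
})

test_that("drawEvent frequencies follow r_i / r_total", {
  ev <- new("EventSet",
            events = data.frame(kind = rep("bond_form", 3), a = 1:3, b = 2:4,
                                direction = NA_character_, rate = c(1, 3, 6)),
            rTotal = 10)
  set.seed(2024)
  n <- 1e5
  u <- stats::runif(n)
  picks <- vapply(u, function(ui) drawEvent(ev, ui)$a, integer(1))
  freq <- tabulate(picks, 3) / n
  p <- c(0.1, 0.3, 0.6)
  sigma <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(freq - p) < 3 * sigma + 1e-9))
})

test_that("waitingTime is the exponential inverse transform", {
  expect_equal(waitingTime(5, 1), 0)
  expect_equal(waitingTime(2, exp(-1)), 0.5)
  expect_error(waitingTime(2, 0), "u must")
  expect_error(waitingTime(0, 0.5), "rTotal")
  set.seed(11)
  r <- 3.7
  dt <- waitingTime(r, stats::runif(1e5))
  expect_equal(mean(dt), 1 / r, tolerance = 3 / sqrt(1e5))
})

test_that("applyEvent executes the four event kinds correctly", {
  p <- pairParams(valency = 2)
  pair <- makeFixture("adjacent_pair")
  form <- data.frame(kind = "bond_form", a = 1L, b = 2L,
                     direction = NA_character_, rate = 1)
  brk <- data.frame(kind = "bond_break", a = 1L, b = 2L,
                    direction = NA_character_, rate = exp(-2))
  s2 <- applyEvent(applyEvent(pair, form, p), brk, p)
  expect_identical(bonds(s2), bonds(pair))
  expect_identical(usedValency(s2), usedValency(pair))

  # rigid dimer translation preserves the internal bond
  dimer <- makeFixture("bonded_dimer")
  cm <- data.frame(kind = "cluster_move", a = 1L, b = NA_integer_,
                   direction = "E", rate = 0.5)
  s3 <- applyEvent(dimer, cm, p)
  expect_equal(positions(s3)[, "col"], positions(dimer)[, "col"] + 1L)
  expect_identical(bonds(s3), bonds(dimer))

  # a monomer move severs every bond of the mover
  lam3 <- SimParams(latticeSize = 9, nParticles = 3, valency = 3, tEnd = 1,
                    snapshotInterval = 1)
  tri <- mkState(9, cbind(c(4, 4, 4), c(3, 4, 5)))
  tri <- placeBond(tri, 1, 2, lam3)
  tri <- placeBond(tri, 2, 3, lam3)
  mv <- data.frame(kind = "monomer_move", a = 2L, b = NA_integer_,
                   direction = "N", rate = 1)
  s4 <- applyEvent(tri, mv, lam3)
  expect_equal(nrow(bonds(s4)), 0L)
  expect_equal(usedValency(s4), c(0L, 0L, 0L))
  expect_equal(unname(positions(s4)[2, ]), c(3, 4))

  # stale events are refused
  occupied <- data.frame(kind = "monomer_move", a = 1L, b = NA_integer_,
                         direction = "E", rate = 1)
  expect_error(applyEvent(makeFixture("adjacent_pair"), occupied, p), "stale")
})

test_that("compiled enumeration equals the brute-force oracle on random states", {
  set.seed(314)
  for (rep in 1:250) {
    L <- sample(5:8, 1)
    lambda <- sample(0:3, 1)
    st <- randomState(L, maxN = 10, lambda = lambda)
    params <- SimParams(latticeSize = L, nParticles = nParticles(st),
                        valency = lambda, epsSp = stats::runif(1, 0, 3),
                        epsNs = stats::runif(1, 0, 1),
                        kDiff = stats::runif(1, 0.5, 2),
                        kBond = stats::runif(1, 0, 2), tEnd = 1,
                        snapshotInterval = 1)
    got <- canonicalEvents(eventTable(enumerateEvents(st, params)))
    want <- canonicalEvents(oracleEvents(st, params))
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$kind, want$kind)
    expect_equal(got$a, want$a)
    expect_equal(got$b, want$b)
    expect_equal(got$direction, want$direction)
    expect_equal(got$rate, want$rate, tolerance = 1e-12)
  }
})

test_that("trajectories are reproducible and conserve particles", {
  p <- SimParams(latticeSize = 15, nParticles = 10, valency = 3, epsSp = 2,
                 tEnd = 40, snapshotInterval = 10, seed = 31)
  tr1 <- runTrajectory(p, storeSnapshots = TRUE)
  tr2 <- runTrajectory(p, storeSnapshots = TRUE)
  expect_identical(trajectorySummary(tr1), trajectorySummary(tr2))
  expect_identical(positions(finalState(tr1)), positions(finalState(tr2)))
  # validity of every snapshot guarantees distinct sites; count is conserved
  for (s in snapshots(tr1)) expect_equal(nParticles(s), 10L)
  expect_equal(nParticles(finalState(tr1)), 10L)
  # bonds in snapshots always connect adjacent sites (validity re-checks)
  for (s in snapshots(tr1)) expect_true(validObject(s))
})

test_that("a zero-length run contains only the initial snapshot", {
  p <- SimParams(latticeSize = 10, nParticles = 5, tEnd = 0, seed = 2)
  tr <- runTrajectory(p, storeSnapshots = TRUE)
  expect_equal(nrow(trajectorySummary(tr)), 1L)
  expect_equal(trajectorySummary(tr)$time, 0)
  expect_equal(tr@stats$nEvents, 0)
})

test_that("event payloads in the log replay to the engine's exchange bookkeeping", {
  p <- SimParams(latticeSize = 8, nParticles = 12, valency = 4, epsSp = 1.5,
                 epsNs = 0.35, tEnd = 30, snapshotInterval = 30, seed = 77)
  tr <- runTrajectory(p, storeSnapshots = TRUE, recordEvents = TRUE)
  stored <- recordExchangeEvents(tr, method = "stored")
  replay <- recordExchangeEvents(tr, method = "replay")
  ord <- function(x) x[order(x$particle, x$burial), , drop = FALSE]
  a <- ord(stored); b <- ord(replay)
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$particle, b$particle)
  expect_equal(a$burial, b$burial, tolerance = 1e-12)
  expect_equal(a$release, b$release, tolerance = 1e-12)
  expect_equal(a$censored, b$censored)
})
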