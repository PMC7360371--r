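# independent per-term oracles: direct sums written from the formulas
oracleStretch <- function(xyz, r0, ks, half = FALSE) {
  E <- 0
  for (i in seq_len(nrow(xyz) - 1))
    E <- E + ks * (sqrt(sum((xyz[i, ] - xyz[i + 1, ])^2)) - r0[i])^2
  if (half) E / 2 else E
}
oracleBend <- function(xyz, kappa) {
  E <- 0
  for (i in seq_len(nrow(xyz) - 2)) {
    v1 <- xyz[i + 1, ] - xyz[i, ]
    v2 <- xyz[i + 2, ] - xyz[i + 1, ]
    ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    E <- E + kappa * (1 - ct)
  }
  E
}
oracleLJ <- function(xyz, types, eps, sL, sD, cut) {
  E <- 0
  M <- nrow(xyz)
  sig <- function(i, j) {
    si <- if (types[i] == "linker") sL else sD
    sj <- if (types[j] == "linker") sL else sD
    (si + sj) / 2
  }
  for (i in seq_len(M - 1)) for (j in seq(i + 1, M)) {
    if (j == i + 1) next
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    s <- sig(i, j)
    if (r < cut * s) E <- E + 4 * eps * ((s / r)^12 - (s / r)^6)
  }
  E
}

mkConf <- function(xyz, types, r0 = NULL) {
  topo <- new("ChainTopology", types = types,
              r0 = if (is.null(r0)) condensateKMC:::.defaultR0(types) else r0,
              diameters = ifelse(types == "linker", 4.2, 20))
  new("ChainConformation", coords = xyz, topology = topo,
      specificBonds = matrix(integer(0), ncol = 2))
}

test_that("stretching energy is zero at equilibrium and quadratic away from it", {
  ff <- forceFieldParams()
  toy <- makeFixture("toy_chain")
  expect_equal(stretchEnergy(toy, ff), 0, tolerance = 1e-12)

  # one linker bond stretched to 5.5 A: 5 * (1.0)^2 = 5 kT
  xyz <- cbind(c(0, 5.5, 10), 0, 0)
  conf <- mkConf(xyz, rep("linker", 3), r0 = c(4.5, 4.5))
  expect_equal(stretchEnergy(conf, ff), 5 * 1^2 + 5 * 0.0, tolerance = 1e-12)

  ffHalf <- forceFieldParams(halfPrefactor = TRUE)
  expect_equal(stretchEnergy(conf, ffHalf), stretchEnergy(conf, ff) / 2)
})

test_that("bending energy follows kappa * (1 - cos theta)", {
  kKT <- convertEnergy(2, "kcal/mol", "kT")
  ff <- forceFieldParams()  # kappa = 2 kcal/mol stored in kT
  straight <- mkConf(cbind(c(0, 4.5, 9), 0, 0), rep("linker", 3))
  expect_equal(bendEnergy(straight, ff), 0, tolerance = 1e-12)

  kink <- mkConf(rbind(c(0, 0, 0), c(4.5, 0, 0), c(4.5, 4.5, 0)),
                 rep("linker", 3))
  expect_equal(bendEnergy(kink, ff), kKT * 1, tolerance = 1e-12)
  ffKcal <- forceFieldParams(energyUnit = "kcal/mol")
  expect_equal(bendEnergy(kink, ffKcal), 2, tolerance = 1e-12)

  hairpin <- mkConf(rbind(c(0, 0, 0), c(4.5, 0, 0), c(0, 0, 0) + 1e-9),
                    rep("linker", 3))
  expect_equal(bendEnergy(hairpin, ff), 2 * kKT, tolerance = 1e-6)
  bad <- mkConf(rbind(c(0, 0, 0), c(0, 0, 0), c(4.5, 0, 0)),
                rep("linker", 3))
  expect_error(bendEnergy(bad, ff), "zero-length")
})

test_that("Lennard-Jones term has its root at sigma, minimum at 2^(1/6) sigma, cutoff at 2.5 sigma", {
  ff <- forceFieldParams(epsNs = 1, epsNsUnit = "kT", energyUnit = "kT")
  s <- 4.2
  at <- function(r) {
    # beads 1 and 3 interact; bead 2 (bonded to both) is excluded
    xyz <- rbind(c(0, 0, 0), c(500, 500, 0), c(r, 0, 0))
    ljEnergy(mkConf(xyz, rep("linker", 3)), ff)
  }
  expect_equal(at(s), 0, tolerance = 1e-12)
  expect_equal(at(2^(1 / 6) * s), -1, tolerance = 1e-12)
  expect_equal(at(2.6 * s), 0)
  expect_lt(at(2.499 * s), 0)   # plain truncation, no shift
  expect_gt(at(0.8 * s), 0)
})

test_that("all three energies match brute-force oracles on random conformations", {
  set.seed(5)
  ff <- forceFieldParams(epsNs = 0.7, epsNsUnit = "kT", energyUnit = "kT")
  ksKT <- ff@ks; kapKT <- ff@kappa
  for (rep in 1:25) {
    M <- sample(4:20, 1)
    types <- sample(c("linker", "domainA", "domainB"), M, replace = TRUE)
    xyz <- cbind(cumsum(stats::runif(M, 3, 8)),
                 stats::rnorm(M, sd = 2), stats::rnorm(M, sd = 2))
    conf <- mkConf(xyz, types)
    expect_equal(stretchEnergy(conf, ff),
                 oracleStretch(xyz, conf@topology@r0, ksKT),
                 tolerance = 1e-10)
    expect_equal(bendEnergy(conf, ff), oracleBend(xyz, kapKT),
                 tolerance = 1e-10)
    expect_equal(ljEnergy(conf, ff),
                 oracleLJ(xyz, types, 0.7, 4.2, 20, 2.5),
                 tolerance = 1e-10)
  }
})

test_that("energies are invariant under rigid rotation and translation", {
  set.seed(17)
  ff <- forceFieldParams(epsNs = 0.5, epsNsUnit = "kT", energyUnit = "kT")
  for (rep in 1:10) {
    M <- 12
    types <- sample(c("linker", "domainA"), M, replace = TRUE)
    xyz <- cbind(cumsum(stats::runif(M, 3, 8)), stats::rnorm(M), stats::rnorm(M))
    conf <- mkConf(xyz, types)
    # random rotation via QR of a Gaussian matrix, plus a translation
    qr_ <- qr(matrix(stats::rnorm(9), 3))
    R <- qr.Q(qr_); if (det(R) < 0) R[, 1] <- -R[, 1]
    shift <- stats::rnorm(3, sd = 50)
    conf2 <- mkConf(sweep(xyz %*% R, 2, -shift), types)
    e1 <- chainEnergy(conf, ff); e2 <- chainEnergy(conf2, ff)
    for (term in c("stretch", "bend", "lj", "total"))
      expect_equal(e2[[term]], e1[[term]],
                   tolerance = 1e-8 * max(1, abs(e1[[term]])))
  }
})

test_that("specific bonds form within the capture radius, one per domain", {
  # one A and one B domain, 10 A apart (< 22.5 A)
  xyz <- rbind(c(0, 0, 0), c(10, 0, 0))
  conf <- new("ChainConformation", coords = xyz,
              topology = new("ChainTopology",
                             types = c("domainA", "domainB"),
                             r0 = 12.1, diameters = c(20, 20)),
              specificBonds = matrix(integer(0), ncol = 2))
  ff1 <- forceFieldParams(pForm = 1)
  set.seed(1)
  b1 <- tryFormSpecificBonds(conf, ff1)
  expect_equal(nrow(b1@specificBonds), 1L)

  ff0 <- forceFieldParams(pForm = 0)
  expect_equal(nrow(tryFormSpecificBonds(conf, ff0)@specificBonds), 0L)

  # out of range: no bond
  confFar <- initialize(conf, coords = rbind(c(0, 0, 0), c(30, 0, 0)))
  expect_equal(nrow(tryFormSpecificBonds(confFar, ff1)@specificBonds), 0L)
})

test_that("competing partners are chosen fairly and valency-1 is respected", {
  # A flanked by two Bs, all mutually in range: exactly one bond forms,
  # each partner roughly half the time over many randomized scans
  xyz <- rbind(c(0, 0, 0), c(-10, 0, 0), c(10, 0, 0))
  conf <- new("ChainConformation", coords = xyz,
              topology = new("ChainTopology",
                             types = c("domainA", "domainB", "domainB"),
                             r0 = c(12.1, 12.1), diameters = rep(20, 3)),
              specificBonds = matrix(integer(0), ncol = 2))
  ff <- forceFieldParams(pForm = 1)
  set.seed(23)
  partners <- replicate(400, {
    out <- tryFormSpecificBonds(conf, ff)
    expect_equal(nrow(out@specificBonds), 1L)
    out@specificBonds[1, 2]
  })
  f2 <- mean(partners == 2)
  expect_lt(abs(f2 - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("bonds break beyond r0 + 2.2 A unless irreversible", {
  mk <- function(r) new("ChainConformation",
    coords = rbind(c(0, 0, 0), c(r, 0, 0)),
    topology = new("ChainTopology", types = c("domainA", "domainB"),
                   r0 = 12.1, diameters = c(20, 20)),
    specificBonds = rbind(c(1L, 2L)))
  ff <- forceFieldParams()
  expect_equal(nrow(tryBreakSpecificBonds(mk(20), ff)@specificBonds), 1L)
  expect_equal(nrow(tryBreakSpecificBonds(mk(22.1), ff)@specificBonds), 1L)
  expect_equal(nrow(tryBreakSpecificBonds(mk(22.3), ff)@specificBonds), 0L)
  ffIrr <- forceFieldParams(irreversible = TRUE)
  expect_equal(nrow(tryBreakSpecificBonds(mk(40), ffIrr)@specificBonds), 1L)
})

test_that("energy units are tagged and converted at 310 K", {
  expect_equal(convertEnergy(1, "kT", "kcal/mol"), 0.61596)
  expect_equal(convertEnergy(0.61596, "kcal/mol", "kT"), 1)
  expect_equal(convertEnergy(3, "kT", "kT"), 3)
  expect_error(convertEnergy(1, "kT", "eV"), "units")
  ff <- forceFieldParams()  # kappa tagged kcal/mol, stored in kT
  expect_equal(ff@kappa, 2 / 0.61596, tolerance = 1e-12)
  expect_equal(ff@ks, 5)  # tagged kT, stored in kT
})

test_that("conformation files round-trip including specific bonds", {
  toy <- makeFixture("toy_chain")
  toy2 <- initialize(toy, specificBonds = rbind(c(1L, 9L)))
  f <- tempfile()
  expect_error(validObject(toy2), NA)  # 2 domains of complementary use ok
  writeConformation(toy2, f)
  back <- readConformation(f)
  expect_equal(back@coords, toy2@coords, tolerance = 1e-9)
  expect_identical(back@topology@types, toy2@topology@types)
  expect_identical(back@specificBonds, toy2@specificBonds)
  expect_equal(stretchEnergy(back, forceFieldParams()), 0, tolerance = 1e-12)
})
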