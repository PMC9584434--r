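test_that("stored parameter table matches the published values", {
  tab <- groundTruthParamTable()
  expect_equal(tab["Gamma_B,F", "col1"], 0.1071294686)
  expect_equal(tab["theta_D,C", "col3"], 0.1931413047)
  expect_equal(tab["Omega_F,A", "col2"], 2.1341889294)
  expect_equal(dim(tab), c(30L, 3L))
  p <- groundTruthParams(1)
  expect_equal(p$nHill, 5)
  expect_length(p$Gamma, 10)
  expect_equal(unname(p$theta[["F,A"]]), 0.7285164419)
})

test_that("zero regulation amplitudes decouple the system to fixed points", {
  p <- groundTruthParams(1)
  p$Omega[] <- 0
  y0 <- setNames(rep(1, 6), c("A", "B", "C", "D", "E", "F"))
  out <- coreosc:::.integrate(coreosc:::.gtRhs, y0, seq(0, 40, 0.2), p)
  late <- out[out[, "time"] > 30, -1]
  # every variable settles; late window has negligible amplitude
  expect_lt(max(apply(late, 2, function(v) diff(range(v)))), 1e-6)
  # basal fixed points: A* = Gamma_F,A etc. for the simple chain nodes
  expect_equal(unname(late[nrow(late), "A"]), unname(p$Gamma[["F,A"]]),
               tolerance = 1e-6)
})

test_that("simulations are solver-tolerance convergent and positive", {
  g <- seq(0, 30, by = 0.25)
  a <- exprValues(simulateGroundTruth(2, g, rtol = 1e-6, atol = 1e-8))
  b <- exprValues(simulateGroundTruth(2, g, rtol = 1e-10, atol = 1e-12))
  expect_lt(max(abs(a - b)) / max(abs(b)), 1e-5)
  expect_true(all(b > 0))
  p <- groundTruthParams(2)
  # bounded by the largest attainable production (unit decay); node C's
  # production is a product of its two input-group factors
  go <- p$Gamma + p$Omega
  prodBound <- max((go[["A,C"]] + go[["E,C"]]) * go[["D,C"]],
                   go[["A,D"]] * go[["E,D"]],
                   go[["B,E"]] * go[["F,E"]])
  expect_lt(max(b), max(prodBound, max(go)) + 1e-6)
})

test_that("spurious wave has the documented range, mean and period", {
  tg <- seq(0, 4, by = 0.001)  # nine whole periods of omega = 4.5*pi
  g <- spuriousWave(tg, omega = 4.5 * pi, amplitude = 2)
  expect_equal(min(g), 0, tolerance = 1e-4)
  expect_equal(max(g), 4, tolerance = 1e-4)
  expect_equal(mean(g[-length(g)]), 2, tolerance = 1e-3)
  # period check: autocorrelation peaks at 2*pi/omega
  per <- 2 * pi / (4.5 * pi)
  shift <- round(per / 0.001)
  expect_equal(cor(g[seq_len(2000)], g[seq_len(2000) + shift]), 1,
               tolerance = 1e-3)
})

test_that("fold-change check reports the minimum peak-to-trough ratio", {
  flat <- TimeSeriesSet(matrix(2, 1, 20, dimnames = list("x", NULL)), 1:20)
  expect_equal(foldChangeCheck(flat), 1)
  osc <- TimeSeriesSet(matrix(rep(c(1, 4), 10), 1, 20,
                              dimnames = list("x", NULL)), 1:20)
  expect_equal(foldChangeCheck(osc), 4)
  neg <- TimeSeriesSet(matrix(seq(1, -0.1, length.out = 20), 1, 20,
                              dimnames = list("x", NULL)), 1:20)
  expect_error(foldChangeCheck(neg), "nonpositive")
})

test_that("re-inserting node D's terms recovers the six-variable flow", {
  p <- groundTruthParams(1)
  n <- p$nHill
  set.seed(4)
  for (rep in 1:20) {
    y <- runif(6, 0.1, 3)
    names(y) <- c("A", "B", "C", "D", "E", "F")
    full <- coreosc:::.gtRhs(0, y, p)[[1]]
    red <- coreosc:::.gtRhsReduced(0, y[c(1, 2, 3, 5, 6)], p)[[1]]
    # A, B, E, F equations are identical
    expect_equal(red[c(1, 2, 4, 5)], full[c(1, 2, 5, 6)], tolerance = 1e-12)
    # C's reduced flow times the re-inserted D factor equals the full flow
    sumAE <- red[3] + y[["C"]]
    dFac <- p$Gamma[["D,C"]] + p$Omega[["D,C"]] *
      p$theta[["D,C"]]^n / (y[["D"]]^n + p$theta[["D,C"]]^n)
    expect_equal(sumAE * dFac - y[["C"]], full[3], tolerance = 1e-12)
  }
})

test_that("removing node D kills the oscillation only where D is core", {
  g <- seq(0, 75, by = 0.25)
  r1 <- exprValues(simulateReduced(1, g))
  r3 <- exprValues(simulateReduced(3, g))
  amp <- function(v, sel) diff(range(v[sel]))
  early <- g >= 10 & g < 30
  late <- g >= 55
  # parameterisation 1: decay to equilibrium
  ratio1 <- max(vapply(rownames(r1), function(gn)
    amp(r1[gn, ], late) / max(amp(r1[gn, ], early), 1e-12), 0))
  expect_lt(ratio1, 0.1)
  # parameterisation 3: sustained oscillation with real amplitude
  ratio3 <- min(vapply(rownames(r3), function(gn)
    amp(r3[gn, ], late) / max(amp(r3[gn, ], early), 1e-12), 0))
  expect_gt(ratio3, 0.5)
  expect_gt(min(apply(r3[, late], 1, function(v) diff(range(v)))), 0.1)
})
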