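test_that("extremum extraction finds, merges and brackets events", {
  tt <- seq(0, 4 * pi, length.out = 400)
  # strictly monotone trace: no interior events
  expect_equal(nrow(extractEvents(seq_len(20), 1:20)), 0)
  # dense sine at eps = 0: alternating extrema at grid argmax/argmin
  tr <- sin(tt)
  ev <- extractEvents(tr, tt, 0, "s")
  expect_equal(ev$kind, c("max", "min", "max", "min"))
  expect_equal(ev$time[1], tt[which.max(tr[tt < pi])], tolerance = 1e-9)
  expect_true(all(ev$tLo == ev$time & ev$tHi == ev$time))
  # a small wiggle below the band is merged away
  wig <- sin(tt) + 0.03 * sin(15 * tt)
  evW <- extractEvents(wig, tt, epsilon = 0.15, gene = "w")
  expect_equal(sum(evW$kind == "max"), 2)
  evW0 <- extractEvents(wig, tt, epsilon = 0, gene = "w")
  expect_gt(nrow(evW0), nrow(evW))
  expect_error(extractEvents(c(1, 2), c(1, 2)), "3 samples")
})

test_that("data graphs encode exactly the interval precedence order", {
  # one gene, max then min: 2-chain
  dg <- buildDataGraph(mkEvents(c("a", "a"), c("max", "min"), c(1, 3)))
  expect_equal(edgeList(dg), rbind(c(1L, 2L)))
  # overlapping intervals across genes: incomparable
  dg2 <- buildDataGraph(mkEvents(c("a", "b"), c("max", "max"), c(1, 2),
                                 lo = c(0, 1.5), hi = c(1.8, 3)))
  expect_equal(nrow(edgeList(dg2)), 0)
  # random event sets match the brute-force pairwise comparison oracle
  set.seed(21)
  for (rep in 1:5) {
    n <- 6
    t0 <- runif(n, 0, 10)
    w <- runif(n, 0, 2)
    ev <- mkEvents(sample(c("a", "b", "c"), n, TRUE),
                   sample(c("max", "min"), n, TRUE),
                   t0, lo = t0 - w, hi = t0 + w)
    dg3 <- buildDataGraph(ev)
    for (i in 1:n) for (j in 1:n) {
      want <- i != j &&
        (ev$tHi[i] < ev$tLo[j] ||
           (ev$gene[i] == ev$gene[j] && ev$time[i] < ev$time[j]))
      has <- any(edgeList(dg3)[, 1] == i & edgeList(dg3)[, 2] == j)
      expect_equal(has, want)
    }
  }
})

test_that("raising the noise level never adds precedence edges", {
  set.seed(8)
  tt <- seq(0, 20, by = 0.05)
  traces <- rbind(a = sin(tt) + 0.1 * sin(7 * tt),
                  b = cos(1.3 * tt))
  eps <- c(0, 0.05, 0.15, 0.3)
  edgeSets <- lapply(eps, function(e) {
    ev <- rbind(extractEvents(traces["a", ], tt, e, "a"),
                extractEvents(traces["b", ], tt, e, "b"))
    dg <- buildDataGraph(ev)
    apply(edgeList(dg), 1, function(r)
      paste(dg@events$gene[r], dg@events$kind[r], collapse = "<"))
  })
  # comparable events shared between levels must keep their orientation;
  # check via the count of cross-gene precedence pairs, which shrinks
  nCross <- vapply(edgeSets, length, 0L)
  expect_true(all(diff(nCross) <= 0))
})

test_that("cycle event words have the hand-oracle structure", {
  regs <- enumerateParameterRegions(negLoop(), TRUE)
  stg <- buildSTG(negLoop(), regs[[1]])
  mg <- morseGraph(stg)
  cyc <- which(mg@annotation == "full_cycle")
  cs <- cycleEventSequence(stg, mg, cyc)
  # rotation-equivalent to max_A max_B min_A min_B
  w <- cs$word
  expect_length(w, 4)
  rot <- vapply(seq_along(w), function(r)
    paste(w[c(r:length(w), seq_len(r - 1))], collapse = " "), "")
  expect_true("max_A max_B min_A min_B" %in% rot)
  # per-gene parity: equal numbers of max and min
  for (g in c("A", "B"))
    expect_equal(sum(w == paste0("max_", g)), sum(w == paste0("min_", g)))
  # fixed-point components are rejected
  regsP <- enumerateParameterRegions(posLoop(), TRUE)
  stgP <- buildSTG(posLoop(), regsP[[1]])
  mgP <- morseGraph(stgP)
  fp <- which(mgP@annotation == "fixed_point")[1]
  expect_error(cycleEventSequence(stgP, mgP, fp), "fixed point")
  # self-repressing flip-flop alternates max and min
  flip <- parseNetwork("A : ~A")
  regsF <- enumerateParameterRegions(flip, TRUE)
  stgF <- buildSTG(flip, regsF[[1]])
  mgF <- morseGraph(stgF)
  csF <- cycleEventSequence(stgF, mgF, which(mgF@annotation == "full_cycle"))
  expect_setequal(csF$word, c("max_A", "min_A"))
})

test_that("pattern matching agrees with the exhaustive oracle", {
  regs <- enumerateParameterRegions(negLoop(), TRUE)
  stg <- buildSTG(negLoop(), regs[[1]])
  mg <- morseGraph(stg)
  cyc <- which(mg@annotation == "full_cycle")
  # all 24 orderings of the four toggle events, as total orders
  base <- mkEvents(c("A", "B", "A", "B"), c("max", "max", "min", "min"),
                   1:4)
  perms <- combinat_perms(4)
  for (r in seq_len(nrow(perms))) {
    ev <- base[perms[r, ], ]
    ev$time <- ev$tLo <- ev$tHi <- 1:4
    dg <- buildDataGraph(ev)
    expect_equal(patternMatch(stg, mg, cyc, dg),
                 patternMatchOracle(stg, mg, cyc, dg),
                 info = paste(ev$kind, ev$gene, collapse = " "))
  }
  # partial orders with incomparabilities (shared intervals)
  set.seed(31)
  for (rep in 1:10) {
    t0 <- sample(1:4)
    w <- runif(4, 0, 1.5)
    ev <- base
    ev$time <- t0; ev$tLo <- t0 - w; ev$tHi <- t0 + w
    dg <- buildDataGraph(ev)
    expect_equal(patternMatch(stg, mg, cyc, dg),
                 patternMatchOracle(stg, mg, cyc, dg))
  }
})

test_that("a simulated system matches its own stable cycle", {
  # Hill repressilator at an essential parameter point: l < theta < u
  rhs <- function(t, y, p) {
    hr <- function(x, th) 0.2 + 2.6 * th^5 / (x^5 + th^5)
    list(c(hr(y[3], 1) - y[1], hr(y[1], 1) - y[2], hr(y[2], 1) - y[3]))
  }
  tt <- seq(0, 120, by = 0.05)
  out <- deSolve::ode(c(A = 1, B = 0.5, C = 1.5), tt, rhs, NULL)
  tss <- TimeSeriesSet(t(out[, -1]), tt)
  dg <- periodDataGraph(tss, epsilon = 0)
  expect_equal(nrow(eventTable(dg)), 6)
  net <- repressilator()
  pm <- patternMatchScore(net, dg)
  expect_equal(pm$nOscillating, 1)
  expect_equal(pm$score, 1)
  # a network that cannot oscillate scores zero by convention
  expect_equal(patternMatchScore(posLoop(), dg)$score, 0)
  # self-repression is rejected up front
  expect_error(patternMatchScore(parseNetwork(c("A : ~A")), dg),
               "self-repressing")
})

test_that("tiny-case pattern match score equals the region-by-region oracle", {
  dgGood <- buildDataGraph(mkEvents(c("A", "B", "A", "B"),
                                    c("max", "max", "min", "min"), 1:4))
  dgBad <- buildDataGraph(mkEvents(c("A", "B", "A", "B"),
                                   c("max", "max", "min", "min"),
                                   c(2, 1, 3, 4))[c(2, 1, 3, 4), ])
  net <- negLoop()
  regs <- enumerateParameterRegions(net, TRUE)
  oracleScore <- function(dg) {
    hits <- 0; osc <- 0
    for (r in seq_len(length(regs))) {
      stg <- buildSTG(net, regs[[r]])
      mg <- morseGraph(stg)
      cyc <- which(mg@annotation == "full_cycle" & mg@stable)
      if (!length(cyc)) next
      osc <- osc + 1
      if (any(vapply(cyc, function(cc)
        patternMatchOracle(stg, mg, cc, dg), TRUE))) hits <- hits + 1
    }
    if (osc == 0) 0 else hits / osc
  }
  expect_equal(patternMatchScore(net, dgGood)$score, oracleScore(dgGood))
  expect_equal(patternMatchScore(net, dgBad)$score, oracleScore(dgBad))
  expect_equal(patternMatchScore(net, dgBad)$score, 0)
})

test_that("data graphs round-trip through their TSV serialization", {
  tt <- seq(0, 15, by = 0.05)
  ev <- rbind(extractEvents(sin(tt), tt, 0.05, "a"),
              extractEvents(cos(1.1 * tt), tt, 0.05, "b"))
  dg <- buildDataGraph(ev)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDataGraph(dg, path)
  back <- readDataGraph(path)
  expect_equal(eventTable(back), eventTable(dg), tolerance = 1e-9)
  expect_equal(edgeList(back), edgeList(dg))
})
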