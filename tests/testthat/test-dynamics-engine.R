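test_that("network text format parses and round-trips", {
  net <- groundTruthNetwork()
  el <- edgeList(net)
  expect_equal(nrow(el), 10)
  expect_setequal(
    paste(el$source, el$sign, el$target),
    c("F activation A", "C activation B", "A activation C",
      "E activation C", "D repression C", "A repression D",
      "E repression D", "B repression E", "F activation E",
      "B repression F"))
  # self-activating singleton has two levels
  self <- parseNetwork("A : A")
  expect_equal(unname(nodeLevels(self)), 2L)
  # round trip through the text format
  for (net2 in list(net, self, negLoop(), repressilator())) {
    back <- parseNetwork(serializeNetwork(net2))
    expect_equal(serializeNetwork(back), serializeNetwork(net2))
  }
  expect_error(parseNetwork("A : Q"), "unknown source")
  expect_error(parseNetwork("A : "), "empty expression")
  expect_error(parseNetwork("A : (B"), "parentheses")
})

test_that("parameter region counts hit the pinned anchors", {
  self <- parseNetwork("A : A")  # one node, 1 in / 1 out
  expect_equal(countParameterRegions(self, essentialOnly = FALSE), 3)
  expect_equal(countParameterRegions(self, essentialOnly = TRUE), 1)
  expect_equal(countParameterRegions(negLoop(), essentialOnly = FALSE), 9)
  expect_equal(countParameterRegions(negLoop(), essentialOnly = TRUE), 1)
  # enumerate/count agreement
  expect_equal(length(enumerateParameterRegions(negLoop(), FALSE)), 9)
  expect_equal(length(enumerateParameterRegions(repressilator(), TRUE)), 1)
  # relabelling nodes does not change the count
  relab <- parseNetwork(c("X : ~Y", "Y : X"))
  expect_equal(countParameterRegions(relab, FALSE), 9)
})

test_that("per-node region counts match the randomized-witness oracle", {
  cases <- list(
    list(groups = list(1), m = 1),             # 1 input, 1 output
    list(groups = list(1), m = 2),             # 1 input, 2 outputs
    list(groups = list(1, 2), m = 1),          # 2 inputs, product
    list(groups = list(c(1, 2)), m = 1),       # 2 inputs, summed group
    list(groups = list(1, 2), m = 2))          # 2 inputs, 2 outputs
  for (cs in cases) {
    for (ess in c(FALSE, TRUE)) {
      mine <- length(coreosc:::.nodeAssignments(cs$groups, cs$m, ess))
      oracle <- witnessRegionCount(cs$groups, cs$m, ess)
      expect_equal(mine, oracle,
                   info = sprintf("groups=%s m=%d ess=%s",
                                  paste(lengths(cs$groups), collapse = "+"),
                                  cs$m, ess))
    }
  }
})

test_that("adding an out-edge never decreases a node's region count", {
  for (groups in list(list(1), list(1, 2), list(c(1, 2)))) {
    c1 <- length(coreosc:::.nodeAssignments(groups, 1, FALSE))
    c2 <- length(coreosc:::.nodeAssignments(groups, 2, FALSE))
    expect_gte(c2, c1)
  }
})

test_that("state transition graphs follow the wall rules", {
  # toggle (negative loop): the single essential region is the 4-cycle
  regs <- enumerateParameterRegions(negLoop(), TRUE)
  stg <- buildSTG(negLoop(), regs[[1]])
  expect_equal(nrow(stg@states), 4)
  g <- igraph::graph_from_edgelist(stg@edges)
  expect_true(igraph::is_connected(g, mode = "strong"))
  expect_equal(nrow(stg@edges), 4)  # a pure 4-cycle
  # mutual activation: two absorbing corner states, no cycle
  regsP <- enumerateParameterRegions(posLoop(), TRUE)
  stgP <- buildSTG(posLoop(), regsP[[1]])
  mgP <- morseGraph(stgP)
  expect_equal(sum(mgP@annotation == "fixed_point" & mgP@stable), 2)
  expect_false(any(mgP@annotation == "full_cycle"))
  # ground-truth network state count: product of per-node levels
  net <- groundTruthNetwork()
  expect_equal(prod(nodeLevels(net)), 324)
  regsG <- enumerateParameterRegions(net, TRUE)
  stgG <- buildSTG(net, regsG[[1]])
  expect_equal(nrow(stgG@states), 324)
})

test_that("Morse graphs agree with a brute-force SCC oracle", {
  set.seed(9)
  for (rep in 1:8) {
    n <- 30
    E <- cbind(sample(n, 60, TRUE), sample(n, 60, TRUE))
    E <- E[E[, 1] != E[, 2], , drop = FALSE]
    stg <- new("StateTransitionGraph",
               states = matrix(0L, n, 1), edges = E,
               directions = matrix(0L, n, 1), nodeNames = "x")
    mg <- morseGraph(stg)
    memb <- sccOracle(n, E)
    # identical partitions up to labelling
    expect_equal(length(unique(mg@membership)), length(unique(memb)))
    expect_true(all(tapply(memb, mg@membership,
                           function(v) length(unique(v))) == 1))
    # leaves of the condensation have no out-edges
    if (nrow(mg@condensation))
      expect_false(any(mg@stable[mg@condensation[, 1]]))
    # stable components are those no edge leaves (oracle view)
    leavesOracle <- setdiff(seq_len(max(mg@membership)),
                            unique(mg@membership[E[, 1]][
                              mg@membership[E[, 1]] != mg@membership[E[, 2]]]))
    expect_setequal(which(mg@stable), leavesOracle)
  }
})

test_that("single-state leaves are fixed points, cycles need two states", {
  regsP <- enumerateParameterRegions(posLoop(), TRUE)
  mg <- morseGraph(buildSTG(posLoop(), regsP[[1]]))
  single <- which(vapply(seq_along(mg@stable), function(cc)
    sum(mg@membership == cc) == 1, TRUE))
  expect_true(all(mg@annotation[single] == "fixed_point"))
  mgN <- morseGraph(buildSTG(negLoop(),
                             enumerateParameterRegions(negLoop(), TRUE)[[1]]))
  cyc <- which(mgN@annotation == "full_cycle")
  expect_true(all(vapply(cyc, function(cc)
    sum(mgN@membership == cc) >= 2, TRUE)))
})

test_that("oscillation score separates negative from positive feedback", {
  expect_equal(oscillationScore(negLoop()), 1)
  expect_equal(oscillationScore(posLoop()), 0)
  expect_equal(oscillationScore(repressilator()), 1)
  expect_error(oscillationScore(groundTruthNetwork(), regionCap = 100),
               "cap")
})

test_that("realizability witnesses respect their inequality patterns", {
  # every enumerated essential logic of small signatures has a concrete
  # witness whose sign pattern reproduces the logic
  for (groups in list(list(1, 2), list(c(1, 2)))) {
    S <- coreosc:::.inputStates(2)
    for (a in coreosc:::.nodeAssignments(groups, 1, TRUE)) {
      lam <- a$lam
      # find a witness by rejection sampling
      ok <- FALSE
      set.seed(13)
      for (d in 1:20000) {
        l <- exp(runif(2, -3, 3)); u <- l + exp(runif(2, -3, 3))
        th <- exp(runif(1, -3, 3))
        got <- as.integer(coreosc:::.prodValues(S, groups, l, u) > th)
        if (all(got == lam)) { ok <- TRUE; break }
      }
      expect_true(ok, info = paste(lam, collapse = ""))
    }
  }
})

test_that("in-degree beyond the supported limit raises a capacity error", {
  net <- parseNetwork(c("A : (B)(C)(D)(E)(A)", "B : A", "C : A", "D : A",
                        "E : A"))
  expect_error(countParameterRegions(net), "in-degree")
})
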