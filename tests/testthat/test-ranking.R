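mkScores <- function(osc, pm, m1 = NULL, m2 = NULL) {
  df <- data.frame(network_id = seq_along(osc), oscillation_score = osc,
                   pattern_match_score = pm)
  if (!is.null(m1)) df$match_ds1 <- m1
  if (!is.null(m2)) df$match_ds2 <- m2
  df
}

test_that("top-network selection applies windows, minima and replicates", {
  sc <- mkScores(c(1, 1, 0.3, 0.2, 0.9), c(0.6, 0.49, 1, 1, 0.7),
                 m1 = c(0.5, 0.4, 1, 1, 0.2), m2 = c(0.5, 0.3, 0.8, 0, 0.1))
  # boundary: (1.0, 0.49) is excluded at minimum 0.5
  top <- selectTopNetworks(sc, c(1, 1), 0.5)
  expect_equal(top$network_id, 1L)
  # replicate rule: dataset matched in only one replicate is excluded
  top2 <- selectTopNetworks(sc, c(0.1, 0.4), 1, replicateRule = "all")
  expect_equal(top2$network_id, 3L)
  # set-comprehension oracle on the same table
  oracle <- sc[sc$oscillation_score >= 0.1 & sc$oscillation_score <= 0.4 &
                 sc$pattern_match_score >= 1 &
                 sc$match_ds1 > 0 & sc$match_ds2 > 0, ]
  expect_equal(top2$network_id, oracle$network_id)
  expect_error(selectTopNetworks(sc, c(0.5, 0.1), 0.5), "window")
  expect_warning(selectTopNetworks(sc, c(0, 0), 1.1), "no network")
})

test_that("edge prevalence counts membership in top networks", {
  nets <- list(parseNetwork(c("A : B", "B : A")),
               parseNetwork(c("A : B", "B : ~A")),
               parseNetwork(c("A : B", "B : A")),
               parseNetwork(c("A : B + C", "B : A", "C : A")))
  # candidate list
  cand <- data.frame(
    item = c("B -> A", "A -> B", "A -| B", "A -> C"),
    target = c("A", "B", "B", "C"), source = c("B", "A", "A", "A"),
    sign = c("activation", "activation", "repression", "activation"),
    score = c(0.9, 0.8, 0.7, 0.6), rank = 1:4)
  prev <- edgePrevalence(nets, cand)
  expect_equal(prev$prevalence[prev$item == "B -> A"], 1)     # in all 4
  expect_equal(prev$prevalence[prev$item == "A -> B"], 0.75)  # 3 of 4
  expect_equal(prev$prevalence[prev$item == "A -| B"], 0.25)
  # conservation: total counts equal total candidate-edge memberships
  expect_equal(sum(prev$n_top),
               sum(vapply(nets, function(nt) {
                 e <- edgeList(nt)
                 sum(coreosc:::.edgeKey(e$target, e$source, e$sign) %in%
                       cand$item)
               }, 0L)))
  # an absent edge has prevalence zero
  expect_equal(prev$prevalence[prev$item == "A -> C"], 0.25)
})

test_that("global edge ranking breaks ties locally and collapses zeros", {
  prev <- data.frame(
    item = paste0("e", 1:5), target = letters[1:5], source = letters[5:1],
    sign = "activation", local_rank = c(3, 7, 1, 2, 4),
    n_top = c(2, 2, 4, 0, 0), prevalence = c(0.5, 0.5, 1, 0, 0))
  rt <- globalEdgeRanking(prev, worstRank = 45)
  it <- rankedItems(rt)
  expect_equal(it$item[1], "e3")
  # tied prevalences: the better local rank wins
  expect_lt(it$rank[it$item == "e1"], it$rank[it$item == "e2"])
  # zero-prevalence edges share the stated worst rank
  expect_equal(it$rank[it$item %in% c("e4", "e5")], c(45, 45))
  # sort-with-key oracle on random tables
  set.seed(33)
  for (rep in 1:5) {
    n <- 12
    p <- data.frame(item = paste0("x", 1:n), target = "t", source = "s",
                    sign = "activation", local_rank = sample(n),
                    n_top = 0, prevalence = sample(c(0, 0.25, 0.5, 1), n,
                                                   TRUE))
    rt2 <- globalEdgeRanking(p)
    it2 <- rankedItems(rt2)
    ord <- order(-p$prevalence, p$local_rank)
    expect_equal(it2$item[it2$rank < nrow(p) | it2$score > 0],
                 p$item[ord][seq_len(sum(p$prevalence > 0))])
  }
})

test_that("local-global comparison flags upranked nodes", {
  lp <- rankingTable(data.frame(item = c("a", "b", "c"),
                                score = c(2, 5, 8)), "lower_is_better")
  gp <- rankingTable(data.frame(item = c("a", "b", "c"),
                                score = c(2, 3, 9)), "lower_is_better")
  cmp <- compareRankings(lp, gp)
  expect_equal(cmp$delta[cmp$node == "a"], 0)
  expect_true(cmp$upranked[cmp$node == "b"])
  expect_false(cmp$upranked[cmp$node == "c"])
  # identical rankings: all deltas zero
  cmp0 <- compareRankings(lp, lp)
  expect_true(all(cmp0$delta == 0))
  empty <- rankingTable(data.frame(item = character(0),
                                   score = numeric(0)), "lower_is_better")
  expect_error(compareRankings(lp, empty), "empty")
})
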