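test_that("out_degree counts arcs for responders and is missing otherwise", {
  net <- net_from_edges(
    c("A->B", "A->C", "A->D", "A->E", "A->F"),
    ids = c("A", "B", "C", "D", "E", "F", "G"),
    rings = c(2L, 2L, 2L, 2L, 2L, 3L, 2L))
  expect_identical(out_degree(net, "A"), 5L)
  expect_identical(out_degree(net, "G"), 0L)       # isolated responder
  expect_true(is.na(out_degree(net, "F")))         # ring-3 non-responder
  expect_error(out_degree(net, "Z"), "unknown actor")
})

test_that("average_degree averages observed out-degrees only", {
  net <- net_from_edges(
    c(sprintf("A->%s", c("B", "C", "D", "E")),
      sprintf("B->%s", c("A", "C", "D", "E", "F", "G"))),
    ids = LETTERS[1:8], rings = c(rep(2L, 7), 3L))
  # degrees: A=4, B=6, others 0; ring-3 H excluded entirely
  expect_equal(average_degree(net, rings = 2), mean(c(4, 6, 0, 0, 0, 0, 0)))
  iso <- net_from_edges(ids = c("A", "B"))
  expect_equal(average_degree(iso), 0)
  r3only <- net_from_edges(ids = c("A", "B"), rings = c(3L, 3L))
  expect_error(average_degree(r3only), "no actor with a defined out-degree")
})

test_that("average_degree matches the sum/count oracle on a 4.8 pattern", {
  # ten responders sending 48 arcs in total
  degs <- c(5, 5, 5, 5, 5, 5, 5, 5, 4, 4)
  ids <- sprintf("a%02d", 1:11)
  edges <- unlist(lapply(seq_along(degs), function(i) {
    targets <- setdiff(ids, ids[i])[seq_len(degs[i])]
    sprintf("%s->%s", ids[i], targets)
  }))
  net <- net_from_edges(edges, ids = ids,
                        rings = c(rep(2L, 10), 3L))
  expect_equal(average_degree(net), sum(degs) / length(degs))
  expect_equal(average_degree(net), 4.8)
})

test_that("density spans [0, 1] with the n(n-1) denominator", {
  empty <- net_from_edges(ids = c("A", "B", "C"))
  expect_equal(net_density(empty), 0)
  full <- net_from_edges(
    as.vector(outer(c("A", "B", "C"), c("A", "B", "C"),
                    function(i, j) sprintf("%s->%s", i, j)))[
      c(2, 3, 4, 6, 7, 8)],
    ids = c("A", "B", "C"))
  expect_equal(net_density(full), 1)
  tri <- net_from_edges(c("A->B", "B->A", "B->C"), ids = c("A", "B", "C"))
  expect_equal(net_density(tri), 0.5)   # 3 of 6 possible arcs
  expect_error(net_density(net_from_edges(ids = "A")), "at least 2 actors")
})

test_that("density is monotone under arc addition", {
  net <- random_net(12, 0.2, seed = 42)
  d0 <- net_density(net)
  ids <- net$actors$actor_id
  key <- paste(net$ties$source, net$ties$target)
  for (i in ids) {
    for (j in ids) {
      if (i != j && !paste(i, j) %in% key) {
        bigger <- net
        bigger$ties <- rbind(bigger$ties,
                             data.frame(source = i, target = j,
                                        value = NA_real_))
        expect_gte(net_density(bigger), d0)
      }
    }
  }
})

test_that("reciprocity is the mutual share of connected dyads", {
  sym <- net_from_edges(c("A->B", "B->A", "B->C", "C->B"))
  expect_equal(reciprocity(sym), 1)
  mixed <- net_from_edges(c("A->B", "B->A", "B->C"))
  expect_equal(reciprocity(mixed), 0.5)   # 1 mutual, 1 asymmetric dyad
  oneway <- net_from_edges(c("A->B", "B->C"))
  expect_equal(reciprocity(oneway), 0)
  none <- net_from_edges(ids = c("A", "B"))
  expect_error(reciprocity(none), "no connected dyads")
  # arc-based alternative: 2 mutual arcs of 3
  expect_equal(reciprocity(mixed, method = "arc"), 2 / 3)
})

test_that("reciprocity and density match brute-force enumeration on random graphs", {
  for (s in 1:25) {
    n <- withr::with_seed(s, sample(4:15, 1))
    net <- random_net(n, 0.25, seed = 100 + s)
    expect_equal(net_density(net), oracle_density(net))
    orc <- oracle_dyad_reciprocity(net)
    if (is.na(orc)) {
      expect_error(reciprocity(net), "no connected dyads")
    } else {
      expect_equal(reciprocity(net), orc)
    }
  }
})

test_that("E-I index hits its boundary values", {
  # all group arcs internal to ring 1
  internal <- net_from_edges(c("A->B", "B->C", "C->A"),
                             ids = c("A", "B", "C", "D"),
                             rings = c(1L, 1L, 1L, 2L))
  for (mode in c("boundary", "source")) {
    ei <- ei_decomposition(internal, 1, mode = mode)
    expect_equal(ei$ei_index, -1)
    expect_identical(ei$internal_contacts, 3L)
    expect_identical(ei$external_contacts, 0L)
  }
  # all group arcs external
  external <- net_from_edges(c("A->D", "B->D"),
                             ids = c("A", "B", "D"),
                             rings = c(1L, 1L, 2L))
  for (mode in c("boundary", "source")) {
    expect_equal(ei_decomposition(external, 1, mode = mode)$ei_index, 1)
  }
})

test_that("E-I decomposition counts contacts and average degrees", {
  net <- net_from_edges(c("A->B", "A->D", "B->D"),
                        ids = c("A", "B", "D"), rings = c(1L, 1L, 2L))
  ei <- ei_decomposition(net, 1)
  expect_identical(ei$internal_contacts, 1L)
  expect_identical(ei$external_contacts, 2L)
  expect_equal(ei$ei_index, 1 / 3)
  expect_equal(ei$internal_avg_degree, 1 / 2)
  expect_equal(ei$external_avg_degree, 2 / 2)
})

test_that("boundary mode shares the external count between two rings", {
  net <- net_from_edges(c("A->B", "C->A", "A->C", "B->D", "C->D", "D->C"),
                        ids = c("A", "B", "C", "D"),
                        rings = c(1L, 1L, 2L, 2L))
  e1 <- ei_decomposition(net, 1)
  e2 <- ei_decomposition(net, 2)
  expect_identical(e1$external_contacts, e2$external_contacts)
  # source mode splits cross arcs by sender
  s1 <- ei_decomposition(net, 1, mode = "source")
  s2 <- ei_decomposition(net, 2, mode = "source")
  expect_identical(s1$external_contacts + s2$external_contacts,
                   e1$external_contacts)
})

test_that("E-I index is missing when the group has no contacts", {
  net <- net_from_edges(c("C->D"), ids = c("A", "B", "C", "D"),
                        rings = c(1L, 1L, 2L, 2L))
  expect_true(is.na(ei_decomposition(net, 1)$ei_index))
  # an in-arc from outside is external in boundary mode only
  net2 <- net_from_edges(c("C->A"), ids = c("A", "C"), rings = c(1L, 2L))
  expect_equal(ei_decomposition(net2, 1)$ei_index, 1)
  expect_true(is.na(ei_decomposition(net2, 1, mode = "source")$ei_index))
  expect_error(ei_decomposition(net2, 5), "unknown group label")
  expect_error(ei_decomposition(net2, 3), "no actors in group")
})

test_that("metrics are invariant under actor relabeling", {
  net <- random_net(10, 0.3, seed = 9)
  relab <- net
  perm <- withr::with_seed(1, sample(10))
  new_ids <- sprintf("z%02d", seq_len(10))
  map <- stats::setNames(new_ids, net$actors$actor_id)
  relab$actors$actor_id <- unname(map[net$actors$actor_id])
  relab$ties$source <- unname(map[net$ties$source])
  relab$ties$target <- unname(map[net$ties$target])
  relab$actors <- relab$actors[perm, ]
  expect_equal(net_density(relab), net_density(net))
  expect_equal(reciprocity(relab), reciprocity(net))
  expect_equal(average_degree(relab), average_degree(net))
  expect_equal(mean_diversity(relab)$mean, mean_diversity(net)$mean)
})

test_that("metric ranges hold on randomized networks", {
  for (s in 1:10) {
    net <- random_net(withr::with_seed(s, sample(5:20, 1)), 0.3,
                      seed = 200 + s)
    expect_gte(net_density(net), 0)
    expect_lte(net_density(net), 1)
    r <- tryCatch(reciprocity(net), error = function(e) NA_real_)
    if (!is.na(r)) {
      expect_gte(r, 0)
      expect_lte(r, 1)
    }
    for (g in 1:2) {
      ei <- ei_decomposition(net, g)$ei_index
      if (!is.na(ei)) {
        expect_gte(ei, -1)
        expect_lte(ei, 1)
      }
    }
    h <- vapply(net$actors$actor_id,
                function(a) diversity_index(net, a)$h_i, numeric(1))
    expect_true(all(h[!is.na(h)] >= 0 & h[!is.na(h)] <= 1))
    v <- vapply(net$actors$actor_id,
                function(a) mean_tie_value(net, a), numeric(1))
    expect_true(all(v[!is.na(v)] >= 1 & v[!is.na(v)] <= 10))
  }
})

test_that("mean_tie_value averages rated out-ties only", {
  net <- net_from_edges(c("A->B", "A->C", "A->D", "B->A"),
                        ids = c("A", "B", "C", "D", "E"),
                        rings = c(2L, 2L, 2L, 3L, 3L),
                        values = c(6, 7, 9, NA))
  expect_equal(mean_tie_value(net, "A"), mean(c(6, 7, 9)))
  expect_true(is.na(mean_tie_value(net, "B")))  # only an unrated tie
  expect_true(is.na(mean_tie_value(net, "E")))  # non-responder, no out-ties
  allsame <- net_from_edges(c("A->B", "A->C"), values = c(8, 8))
  expect_equal(mean_tie_value(allsame, "A"), 8)
  # subset to ring 2 drops the rated tie into ring-3 actor D
  expect_equal(tie_value_summary(net, rings = c(2))$mean, mean(c(6, 7)))
})
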