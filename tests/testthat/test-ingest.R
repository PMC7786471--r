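test_that("build_roster unions egos and alters in first-seen order", {
  noms <- data.frame(
    ego = rep(sprintf("e%d", 1:7), each = 3),
    alter = sprintf("x%02d", 1:21)
  )
  noms$alter[21] <- "x01"  # duplicate nomination of the same alter
  roster <- build_roster(noms)
  expect_length(roster, 7 + 20)
  expect_identical(roster[1:2], c("e1", "x01"))
  expect_false(anyDuplicated(roster) > 0)
})

test_that("build_roster drops self-nominations with a warning", {
  noms <- data.frame(ego = c("e1", "e1", "e2"),
                     alter = c("x1", "e1", "x1"))
  expect_warning(roster <- build_roster(noms), "self-nomination")
  expect_identical(roster, c("e1", "x1", "e2"))
})

test_that("build_roster is invariant to response ordering (as a set)", {
  noms <- data.frame(ego = c("e1", "e1", "e2", "e3"),
                     alter = c("x1", "x2", "x3", "x1"))
  r1 <- build_roster(noms)
  for (s in 1:5) {
    perm <- withr::with_seed(s, noms[sample(nrow(noms)), , drop = FALSE])
    expect_setequal(build_roster(perm), r1)
  }
  expect_error(build_roster(noms[0, ]), "no responses")
})

test_that("classify_rings partitions the roster into the three rings", {
  roster <- c("p1", "p2", "r1", "n1", "n2")
  rings <- classify_rings(roster, program_ids = c("p1", "p2"),
                          responder_ids = c("p1", "p2", "r1"))
  expect_identical(unname(rings), c(1L, 1L, 2L, 3L, 3L))
  expect_identical(sum(table(rings)), length(roster))
  expect_error(classify_rings(roster, "p1", c("r1", "ghost")),
               "responder outside network boundary")
  expect_error(classify_rings(roster, c("p1", "ghost"), "r1"),
               "outside network boundary")
})

test_that("assemble_network builds arcs from nominations", {
  roster <- c("p1", "p2", "r1", "n1")
  rings <- classify_rings(roster, c("p1", "p2"), c("p1", "p2", "r1"))
  noms <- data.frame(ego = c("p1", "p1", "p1", "p2", "r1"),
                     alter = c("p2", "r1", "n1", "n1", "p1"),
                     value = c(8, 7, 6, 9, 8))
  net <- assemble_network(noms, roster, rings, timepoint = "T0")
  expect_identical(out_degree(net, "p1"), 3L)
  # ring-3 actor: in-degree 2, out-degree missing
  expect_identical(sum(net$ties$target == "n1"), 2L)
  expect_true(is.na(out_degree(net, "n1")))
  expect_identical(validate_network(net), character(0))
})

test_that("assemble_network deduplicates and rejects conflicts", {
  roster <- c("p1", "r1")
  rings <- classify_rings(roster, "p1", c("p1", "r1"))
  dup <- data.frame(ego = c("p1", "p1"), alter = c("r1", "r1"),
                    value = c(8, 8))
  net <- assemble_network(dup, roster, rings)
  expect_identical(nrow(net$ties), 1L)

  conflict <- data.frame(ego = c("p1", "p1"), alter = c("r1", "r1"),
                         value = c(8, 5))
  expect_error(assemble_network(conflict, roster, rings),
               "conflicting nomination")
})

test_that("assemble_network adds out-of-roster alters as ring 3 with warning", {
  roster <- c("p1", "r1")
  rings <- classify_rings(roster, "p1", c("p1", "r1"))
  noms <- data.frame(ego = "p1", alter = "stranger", value = 7)
  expect_warning(net <- assemble_network(noms, roster, rings),
                 "outside roster")
  expect_identical(net$actors$ring[net$actors$actor_id == "stranger"], 3L)
  expect_error(
    assemble_network(data.frame(ego = "ghost", alter = "p1", value = 1),
                     roster, rings),
    "not on roster")
})

test_that("response_rate is the responder share of the boundary", {
  expect_equal(response_rate(sprintf("a%d", 1:25), sprintf("a%d", 1:10)),
               0.40)
  expect_equal(response_rate(c("a", "b"), character(0)), 0)
  expect_equal(response_rate(c("a", "b"), c("a", "b")), 1)
  expect_error(response_rate(character(0), character(0)), "empty roster")
  expect_error(response_rate(c("a"), c("z")), "outside network boundary")
})

test_that("actor table and tie list round-trip through disk", {
  at <- data.frame(actor_id = c("a", "b"), discipline = c("gp", "nurse"),
                   district = "d1", program = c(TRUE, FALSE),
                   responded_t0 = c(TRUE, FALSE),
                   responded_t1 = c(TRUE, TRUE))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_actor_table(at, f)
  expect_identical(read_actor_table(f), at)

  tl <- data.frame(timepoint = c("T0", "T1"), source = c("a", "a"),
                   target = c("b", "b"), value = c(7.5, NA))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_tie_list(tl, f2)
  back <- read_tie_list(f2)
  expect_identical(back$value, c(7.5, NA))
  expect_identical(back$source, c("a", "a"))
  expect_error(read_actor_table(f2), "missing column")
})

test_that("build_study_from_tables classifies rings from either timepoint", {
  at <- data.frame(
    actor_id = c("p1", "r1", "r2"), discipline = c("gp", "nurse", "gp"),
    district = "d1", program = c(TRUE, FALSE, FALSE),
    responded_t0 = c(TRUE, TRUE, FALSE),
    responded_t1 = c(TRUE, FALSE, TRUE))
  tl <- data.frame(
    timepoint = c("T0", "T0", "T1", "T1"),
    source = c("p1", "r1", "p1", "r2"),
    target = c("n9", "p1", "r2", "p1"),
    value = c(8, 7, 6, 5))
  studies <- build_study_from_tables(at, tl)
  st <- studies[["d1"]]
  a <- st$t0$actors
  expect_identical(a$ring[match(c("p1", "r1", "r2", "n9"), a$actor_id)],
                   c(1L, 2L, 2L, 3L))  # r2 responded only at T1 -> ring 2
  expect_true(is.na(out_degree(st$t0, "r2")))   # did not respond at T0
  expect_identical(out_degree(st$t1, "r2"), 1L)
  expect_identical(st$t0$actors$actor_id, st$t1$actors$actor_id)
})
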