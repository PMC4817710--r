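test_that("the M filter judges the top unique count, not node size", {
  expect_false(passes_M_filter(list(top_unique_count = 99), M = 100))
  expect_true(passes_M_filter(list(top_unique_count = 100), M = 100))
  # large node made of rare uniques still fails
  expect_false(passes_M_filter(list(top_unique_count = 50, size = 500),
                               M = 100))
})

test_that("recommended M is one per 10 000 reads, rounded up, floor 1", {
  expect_equal(recommend_M(373474), 38L)
  expect_equal(recommend_M(10000), 1L)
  expect_equal(recommend_M(10001), 2L)
  expect_equal(recommend_M(5000), 1L)
  expect_equal(recommend_M(1), 1L)
  expect_error(recommend_M(0))
})

test_that("splitting groups sequences by their character tuple", {
  seqs <- c("AAAAA", "AATAA")
  counts <- c(6, 4)
  ch <- split_node(seqs, counts, positions = 3L)
  expect_length(ch, 2L)
  expect_equal(vapply(ch, `[[`, numeric(1), "size"), c(6, 4))
  expect_equal(ch[[1]]$tuple, "A")

  # two positions, three observed tuples
  seqs2 <- c("AxTx", "AxCx", "GxTx")
  seqs2 <- gsub("x", "A", seqs2)
  ch2 <- split_node(seqs2, c(5, 3, 2), positions = c(1L, 3L))
  expect_length(ch2, 3L)
  expect_equal(vapply(ch2, `[[`, character(1), "tuple"),
               c("AT", "AC", "GT"))
  # conservation
  expect_equal(sum(vapply(ch2, `[[`, numeric(1), "size")), 10)

  # tie on size -> tuple lexicographic ascending
  ch3 <- split_node(c("T", "A"), c(2, 2), positions = 1L)
  expect_equal(vapply(ch3, `[[`, character(1), "tuple"), c("A", "T"))

  expect_error(split_node(seqs, counts, integer(0)), "non-empty")
  expect_error(split_node(seqs, counts, 9L), "out of range")
})

test_that("a homogeneous dataset yields a single final node", {
  r <- make_reads(rep("ACGTACGT", 20))
  topo <- med_decompose(r, med_params(M = 1))
  expect_equal(final_nodes(topo), "0")
  expect_equal(topo$nodes[["0"]]$representative, "ACGTACGT")
  expect_equal(topo$nodes[["0"]]$size, 20)
  expect_equal(topo$iteration_log$action, "finalized")
  check_run_invariants(topo)
})

test_that("two templates one position apart resolve in one decomposition step", {
  a <- strrep("A", 20); b <- mutate_seq(a, 10, "T")
  r <- make_reads(c(rep(a, 600), rep(b, 400)))
  topo <- med_decompose(r, med_params(M = 100, m0 = 1e-6,
                                      normalize_m = FALSE))
  fin <- final_nodes(topo)
  expect_length(fin, 2L)
  expect_setequal(final_representatives(topo), c(a, b))
  expect_equal(sum(topo$iteration_log$action == "decomposed"), 1L)
  expect_equal(topo$nodes[["0"]]$discriminant_positions, 10L)
  # children sized 600/400, ids encode lineage rank
  expect_equal(topo$nodes[["0.1"]]$size, 600)
  expect_equal(topo$nodes[["0.2"]]$size, 400)
  check_run_invariants(topo)
})

test_that("a lineage below M ends discarded and leaves final counts", {
  a <- strrep("C", 15); b <- mutate_seq(a, 5, "G")
  r <- make_reads(c(rep(a, 950), rep(b, 30)))
  topo <- med_decompose(r, med_params(M = 50, m0 = 1e-6,
                                      normalize_m = FALSE))
  st <- vapply(topo$nodes, `[[`, character(1), "status")
  expect_equal(sum(st == "discarded"), 1L)
  expect_equal(final_nodes(topo), "0.1")
  expect_equal(topo$nodes[["0.1"]]$size, 950)
  om <- observation_matrix(topo)
  expect_equal(sum(om$counts), 950)  # the 30 b-reads are excluded
  check_run_invariants(topo)
})

test_that("a dataset entirely below M discards the root", {
  r <- make_reads(c("AAAA", "AAAT", "AATT"))
  topo <- med_decompose(r, med_params(M = 10))
  expect_equal(vapply(topo$nodes, `[[`, character(1), "status"),
               c(`0` = "discarded"))
  expect_length(final_nodes(topo), 0L)
})

test_that("nested variable positions resolve stepwise under c = 1", {
  topo <- med_decompose(nested_mock_reads(), med_params(M = 1, c = 1))
  dec <- topo$iteration_log$action == "decomposed"
  expect_equal(sum(dec), 2L)
  for (id in topo$iteration_log$node_id[dec]) {
    expect_length(topo$nodes[[id]]$discriminant_positions, 1L)
  }
  # first step uses the higher-entropy position (3), the second the
  # nested one (7)
  expect_equal(topo$nodes[["0"]]$discriminant_positions, 3L)
  expect_equal(topo$nodes[["0.1"]]$discriminant_positions, 7L)
  expect_length(final_nodes(topo), 3L)
  check_run_invariants(topo)
})

test_that("decomposition is deterministic", {
  r <- pad_reads(random_template_reads(321))
  t1 <- med_decompose(r, med_params(M = 2))
  t2 <- med_decompose(r, med_params(M = 2))
  expect_identical(names(t1$nodes), names(t2$nodes))
  expect_equal(t1$nodes, t2$nodes)
  expect_equal(t1$iteration_log, t2$iteration_log)
  expect_equal(t1$edges, t2$edges)
})

test_that("with the filter off and c = L the partition equals dereplication", {
  # brute-force oracle: reads grouped by identical sequence
  for (seed in 501:530) {
    r <- pad_reads(random_template_reads(seed))
    topo <- med_decompose(r, med_params(M = 1, m0 = 1e-9, c =
                                          r$alignment_length,
                                        normalize_m = FALSE))
    got <- vapply(final_nodes(topo),
                  function(id) paste(node_read_ids(topo, id),
                                     collapse = ","),
                  character(1))
    want <- vapply(split(r$id, r$sequence),
                   function(ids) paste(sort(ids), collapse = ","),
                   character(1))
    expect_identical(sort(unname(got)), sort(unname(want)))
  }
})

test_that("structural invariants hold across random runs with defaults", {
  for (seed in 601:615) {
    r <- pad_reads(random_template_reads(seed))
    topo <- med_decompose(r, med_params(M = 2))
    check_run_invariants(topo)
  }
})

test_that("degenerate inputs are rejected", {
  empty <- read_set(character(0), character(0), character(0))
  expect_error(med_decompose(empty, med_params(M = 1)), "empty")
  unpadded <- make_reads(c("ACG", "ACGT"))
  expect_error(med_decompose(unpadded, med_params(M = 1)), "uniform")
})
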