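# A tiny two-sample dataset resolving into two exact-sequence nodes:
# sample s1 contributes 3 reads to each variant, s2 only 4 to the major
# one.
two_node_topology <- function() {
  x <- strrep("A", 12); y <- mutate_seq(x, 6, "G")
  r <- make_reads(c(rep(x, 3), rep(y, 3), rep(x, 4)),
                  sample = rep(c("s1", "s2"), c(6, 4)))
  med_decompose(r, med_params(M = 1, m0 = 1e-9, normalize_m = FALSE))
}

test_that("observation matrices tally reads per sample and node", {
  # single sample, single node
  topo1 <- med_decompose(make_reads(rep("ACGT", 10)), med_params(M = 1))
  om1 <- observation_matrix(topo1)
  expect_equal(unname(om1$counts), matrix(10L, 1, 1))
  expect_equal(unname(om1$percents), matrix(100, 1, 1))

  # two samples over one node
  r2 <- make_reads(rep("ACGT", 10), sample = rep(c("a", "b"), c(6, 4)))
  om2 <- observation_matrix(med_decompose(r2, med_params(M = 1)))
  expect_equal(unname(om2$counts[, 1]), c(6L, 4L))
  expect_equal(om2$samples, c("a", "b"))  # first-appearance order

  # row normalization: [3,3] -> [50,50]; [4,0] -> [100,0]
  om <- observation_matrix(two_node_topology())
  expect_equal(unname(om$counts), rbind(c(3L, 3L), c(4L, 0L)))
  expect_equal(unname(om$percents), rbind(c(50, 50), c(100, 0)))
  expect_equal(unname(rowSums(om$percents)), c(100, 100))
})

test_that("matrix column sums equal final node sizes exactly", {
  for (seed in c(701, 702, 703)) {
    topo <- med_decompose(pad_reads(random_template_reads(seed)),
                          med_params(M = 2))
    om <- observation_matrix(topo)
    sizes <- vapply(topo$nodes[om$node_ids], function(nd) nd$size,
                    numeric(1))
    expect_equal(unname(colSums(om$counts)), unname(sizes))
    # nodes ordered by size descending
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("matrix TSV files round-trip", {
  om <- observation_matrix(two_node_topology())
  dir <- tempfile(); dir.create(dir)
  write_observation_matrices(om, dir)
  back <- read.delim(file.path(dir, "MATRIX-COUNT.txt"),
                     check.names = FALSE)
  expect_equal(back$sample, om$samples)
  expect_equal(as.matrix(back[, -1]),
               matrix(om$counts, 2, 2,
                      dimnames = list(NULL, om$node_ids)))
})

test_that("representative FASTA strips trailing padding, keeps internal gaps", {
  topo <- med_decompose(pad_reads(make_reads(c(rep("ACGTACGT", 8),
                                               rep("ACGTA", 6)))),
                        med_params(M = 1, m0 = 1e-9,
                                   normalize_m = FALSE))
  fa <- tempfile(fileext = ".fasta")
  write_representatives(topo, fa)
  lines <- readLines(fa)
  heads <- grep("^>", lines, value = TRUE)
  seqs <- grep("^>", lines, value = TRUE, invert = TRUE)
  expect_setequal(heads, c(">0.1|size:8", ">0.2|size:6"))
  expect_setequal(seqs, c("ACGTACGT", "ACGTA"))  # padding stripped

  # internal gaps survive
  topo2 <- med_decompose(make_reads(rep("AC-GT", 5)), med_params(M = 1))
  write_representatives(topo2, fa)
  expect_equal(readLines(fa)[2], "AC-GT")

  # zero final nodes -> warning plus empty file
  topo3 <- med_decompose(make_reads(c("AAAA", "AATT")),
                         med_params(M = 10))
  expect_warning(write_representatives(topo3, fa), "no final nodes")
  expect_equal(file.size(fa), 0)
})

test_that("topology export round-trips and leaves carry terminal statuses", {
  topo <- med_decompose(pad_reads(random_template_reads(808)),
                        med_params(M = 2))
  ed <- tempfile(fileext = ".txt"); gml <- tempfile(fileext = ".gml")
  export_topology(topo, ed, gml)

  back <- read.delim(ed, colClasses = c("character", "character",
                                        "integer", "character"))
  expect_identical(back, topo$edges)
  # re-read edges reconstruct the same tree
  kids <- split(back$child_id, back$parent_id)
  for (id in names(kids)) {
    expect_setequal(kids[[id]], topo$nodes[[id]]$child_ids)
  }
  leaves <- setdiff(back$child_id, back$parent_id)
  expect_true(all(back$child_status[back$child_id %in% leaves] %in%
                    c("final", "discarded")))

  g <- igraph::read_graph(gml, format = "gml")
  expect_equal(igraph::vcount(g), length(topo$nodes))
  expect_equal(igraph::ecount(g), nrow(topo$edges))

  # single-node decomposition: empty edge list, one GML vertex
  topo1 <- med_decompose(make_reads(rep("ACGT", 5)), med_params(M = 1))
  export_topology(topo1, ed, gml)
  expect_equal(nrow(read.delim(ed)), 0L)
  expect_equal(igraph::vcount(igraph::read_graph(gml, format = "gml")),
               1)
})

test_that("run summaries account for every read and echo parameters", {
  topo <- med_decompose(pad_reads(random_template_reads(909)),
                        med_params(M = 2, m0 = 0.05, c = 3,
                                   normalize_m = FALSE))
  s <- run_summary(topo)
  expect_equal(s$final_reads + s$discarded_reads, s$input_reads)
  expect_true(all(diff(s$entropy_trace) <= 1e-9))
  expect_equal(s$params$M, 2L)
  expect_equal(s$params$m0, 0.05)
  expect_equal(s$params$c, 3L)
  expect_false(s$params$normalize_m)
  expect_output(print(s), "input reads")
})

test_that("med_run writes the full output set from a FASTA", {
  tpl <- make_templates(3, 60, min_diff = 5, seed = 11)
  ab <- matrix(150, 2, 3,
               dimnames = list(c("sA", "sB"), names(tpl)))
  sim <- simulate_reads(community_spec(tpl, ab, error_rate = 0,
                                       seed = 12))
  fa <- tempfile(fileext = ".fasta")
  write_reads_fasta(sim$reads, fa)
  out <- tempfile()

  topo <- med_run(fa, out, M = 10, verbose = FALSE)
  expect_setequal(list.files(out),
                  c("MATRIX-COUNT.txt", "MATRIX-PERCENT.txt",
                    "NODE-REPRESENTATIVES.fasta", "TOPOLOGY.txt",
                    "TOPOLOGY.gml", "RUNINFO.txt"))
  expect_length(final_nodes(topo), 3L)
  expect_setequal(final_representatives(topo), unname(tpl))
  info <- readLines(file.path(out, "RUNINFO.txt"))
  expect_true(any(grepl("^M=10$", info)))
  expect_true(any(grepl("^input_reads=900$", info)))

  # quick mode: decomposition outputs only, no RUNINFO
  out2 <- tempfile()
  med_run(fa, out2, M = 10, quick = TRUE)
  expect_false(file.exists(file.path(out2, "RUNINFO.txt")))
  expect_true(file.exists(file.path(out2, "MATRIX-COUNT.txt")))

  # a dataset failing M entirely is an error, with no partial output
  out3 <- tempfile()
  expect_error(med_run(fa, out3, M = 10000), "substantive abundance")
  expect_false(dir.exists(out3))
})
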