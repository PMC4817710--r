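# Shared fixture builders. Everything is generated in code; no files
# ship with the tests.

# Write a FASTA file from a named character vector (names = deflines).
fasta_file <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(rbind(paste0(">", names(seqs)), unname(seqs)), path)
  path
}

# ReadSet straight from sequences, auto-generating ids per sample.
make_reads <- function(seqs, sample = "s1") {
  sample <- rep_len(sample, length(seqs))
  ids <- paste0(sample, "_", stats::ave(seq_along(seqs), sample,
                                        FUN = seq_along))
  read_set(ids, sample, seqs)
}

# Replace single positions of a sequence string.
mutate_seq <- function(seq, pos, base) {
  for (k in seq_along(pos)) substr(seq, pos[k], pos[k]) <- base[k]
  seq
}

# Random small dataset drawn from a handful of templates with point
# mutations, so duplicate sequences occur; used by oracle/property
# suites. Returns a finalized ReadSet.
random_template_reads <- function(seed, max_reads = 100L, max_len = 30L,
                                  n_samples = 2L, mut_rate = 0.05) {
  set.seed(seed)
  n <- sample(5:max_reads, 1L)
  L <- sample(5:max_len, 1L)
  k <- sample(1:4, 1L)
  bases <- c("A", "C", "G", "T")
  tpl <- replicate(k, paste(sample(bases, L, replace = TRUE),
                            collapse = ""))
  pick <- sample(k, n, replace = TRUE)
  seqs <- vapply(pick, function(i) {
    s <- strsplit(tpl[i], "")[[1L]]
    hit <- runif(L) < mut_rate
    if (any(hit)) {
      s[hit] <- vapply(s[hit],
                       function(b) sample(setdiff(bases, b), 1L),
                       character(1))
    }
    paste(s, collapse = "")
  }, character(1))
  make_reads(seqs, sample = paste0("s", sample(n_samples, n,
                                               replace = TRUE)))
}

# Ten-read mock with two nested variable positions: position 3 splits
# the set 6/4 and, within the 6-read group only, position 7 splits 3/3.
# With c = 1 this resolves in exactly two decomposition steps.
nested_mock_reads <- function() {
  base <- strrep("A", 10L)
  seqs <- c(rep(mutate_seq(base, c(3, 7), c("A", "C")), 3),
            rep(mutate_seq(base, c(3, 7), c("A", "G")), 3),
            rep(mutate_seq(base, c(3, 7), c("T", "C")), 4))
  make_reads(seqs)
}

# Read ids contained in one node of a topology.
node_read_ids <- function(topology, id) {
  idx <- topology$nodes[[id]]$unique_idx
  sort(unlist(topology$uniques$members[idx], use.names = FALSE))
}

# Representatives of the final nodes, trailing padding stripped.
final_representatives <- function(topology) {
  vapply(topology$nodes[final_nodes(topology)],
         function(nd) sub("-+$", "", nd$representative), character(1))
}

# Structural invariants every completed run must satisfy; used by the
# property suites and the acceptance tests.
check_run_invariants <- function(topology) {
  nodes <- topology$nodes
  st <- vapply(nodes, `[[`, character(1), "status")
  sizes <- vapply(nodes, function(nd) nd$size, numeric(1))

  # read conservation: final + discarded == input
  expect_equal(sum(sizes[st == "final"]) + sum(sizes[st == "discarded"]),
               topology$n_reads)
  # no pending nodes survive; leaves are exactly final/discarded
  expect_false(any(st == "pending"))
  n_children <- lengths(lapply(nodes, `[[`, "child_ids"))
  expect_true(all((n_children == 0L) == (st %in% c("final", "discarded"))))

  # every final node converged at its own m'
  for (id in names(nodes)[st == "final"]) {
    nd <- nodes[[id]]
    expect_true(is_converged(nd$profile, nd$m_prime))
  }
  # each discriminant position has exactly zero entropy in every child
  for (id in names(nodes)[st == "internal"]) {
    nd <- nodes[[id]]
    expect_true(length(nd$discriminant_positions) >= 1L)
    for (ch in nd$child_ids) {
      expect_identical(
        unname(nodes[[ch]]$profile[nd$discriminant_positions]),
        rep(0, length(nd$discriminant_positions)))
    }
  }
  # the weighted entropy trace never increases
  tr <- topology$iteration_log$total_weighted_entropy
  expect_true(all(diff(tr) <= 1e-9))
  invisible(topology)
}
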