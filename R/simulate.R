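#' Generate template sequences with a minimum pairwise distance
#'
#' Random template sequences over `{A,C,G,T}` whose pairwise Hamming
#' distances are all at least `min_diff`, emulating closely related
#' organisms that differ by as little as a single nucleotide.
#' Deterministic for a given seed.
#'
#' @param n_templates number of templates (>= 1).
#' @param length template length in nt (>= `min_diff`).
#' @param min_diff minimum pairwise Hamming distance (>= 1).
#' @param seed integer random seed.
#' @return Named character vector (`t1`, `t2`, ...) of templates.
#' @export
make_templates <- function(n_templates, length, min_diff = 1L, seed = 1L) {
  n_templates <- as.integer(n_templates)
  length <- as.integer(length)
  min_diff <- as.integer(min_diff)
  if (n_templates < 1L) stop("n_templates must be >= 1")
  if (min_diff < 1L || length < min_diff) {
    stop("length >= min_diff >= 1 is required")
  }
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    mat <- matrix(sample(bases, n_templates * length, replace = TRUE),
                  nrow = n_templates)
    hamming <- function(i, j) sum(mat[i, ] != mat[j, ])
    attempts <- 0L
    repeat {
      viol <- NULL
      if (n_templates > 1L) {
        for (i in seq_len(n_templates - 1L)) {
          for (j in seq(i + 1L, n_templates)) {
            if (hamming(i, j) < min_diff) { viol <- c(i, j); break }
          }
          if (!is.null(viol)) break
        }
      }
      if (is.null(viol)) break
      attempts <- attempts + 1L
      if (attempts > 1000L) {
        stop("could not satisfy min_diff = ", min_diff,
             " after 1000 attempts; constraints likely infeasible")
      }
      mat[viol[2L], ] <- sample(bases, length, replace = TRUE)
    }
    seqs <- apply(mat, 1L, paste, collapse = "")
    names(seqs) <- paste0("t", seq_len(n_templates))
    seqs
  })
}

#' Describe a synthetic amplicon community
#'
#' Bundles the ground truth for a simulation: templates, per-sample
#' template abundances, the substitution error model and optional
#' biological length variants (encoded later as trailing-gap padding by
#' the pipeline).
#'
#' @param templates named character vector of equal-length template
#'   sequences over `{A,C,G,T}` (names auto-assigned if missing).
#' @param abundances read counts per sample and template: either a
#'   numeric matrix/data.frame with samples as rows (rownames) and
#'   templates as columns, or a named numeric vector (one sample named
#'   `"s1"`).
#' @param error_rate per-base substitution probability in `[0, 0.1]`;
#'   either a scalar (uniform across positions, default `0.01` — a
#'   typical short-read error rate) or a vector with one rate per
#'   template position for position-dependent error profiles.
#' @param length_variants optional named integer vector mapping
#'   template names to truncated read lengths, for templates whose
#'   biology yields shorter amplicons.
#' @param seed integer random seed.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(templates, abundances, error_rate = 0.01,
                           length_variants = NULL, seed = 1L) {
  templates <- as.character(templates) |>
    stats::setNames(names(templates) %||% paste0("t", seq_along(templates)))
  if (is.null(names(templates)) || any(!nzchar(names(templates)))) {
    names(templates) <- paste0("t", seq_along(templates))
  }
  L <- unique(nchar(templates))
  if (length(L) != 1L) stop("all templates must have the same base length")
  if (any(grepl("[^ACGT]", templates))) {
    stop("templates must be over {A,C,G,T}")
  }
  if (is.vector(abundances) && !is.matrix(abundances)) {
    abundances <- matrix(abundances, nrow = 1L,
                         dimnames = list("s1", names(abundances)))
  }
  abundances <- as.matrix(abundances)
  if (is.null(colnames(abundances))) colnames(abundances) <- names(templates)
  if (is.null(rownames(abundances))) {
    rownames(abundances) <- paste0("s", seq_len(nrow(abundances)))
  }
  if (!all(colnames(abundances) %in% names(templates))) {
    stop("abundance columns must name templates")
  }
  if (any(abundances < 0) || any(abundances != round(abundances))) {
    stop("abundances must be non-negative integer read counts")
  }
  if (any(error_rate < 0) || any(error_rate > 0.1)) {
    stop("error_rate must be in [0, 0.1]")
  }
  if (length(error_rate) != 1L && length(error_rate) != L) {
    stop("error_rate must be scalar or one rate per template position")
  }
  if (!is.null(length_variants)) {
    if (is.null(names(length_variants)) ||
        !all(names(length_variants) %in% names(templates))) {
      stop("length_variants must be named by template")
    }
    if (any(length_variants < 1L) || any(length_variants > L)) {
      stop("length_variants must be in 1..template length")
    }
  }
  structure(list(templates = templates, abundances = abundances,
                 error_rate = error_rate,
                 length_variants = length_variants,
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' Simulate amplicon reads from a community specification
#'
#' Emits the requested number of reads per sample and template, with
#' each base independently substituted with probability `error_rate` to
#' a uniformly chosen different base. Length-variant templates are
#' truncated before errors are applied. Deflines follow the
#' `sample_serial` convention so [read_amplicon_fasta()]'s default
#' sample pattern recovers the sample. Deterministic given the spec's
#' seed.
#'
#' @param spec a [community_spec()].
#' @return List with `reads` (a [read_set()]) and `truth` (data.frame
#'   `read_id`, `sample`, `template` — the ground-truth assignment
#'   table).
#' @export
simulate_reads <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  bases <- c("A", "C", "G", "T")
  # alt[b, k]: the k-th base different from base index b
  alt <- t(vapply(1:4, function(b) which(1:4 != b), integer(3)))
  L0 <- nchar(spec$templates[[1L]])
  err <- if (length(spec$error_rate) == 1L) {
    rep(spec$error_rate, L0)
  } else {
    spec$error_rate
  }

  with_seed(spec$seed, {
    all_ids <- character(0); all_samples <- character(0)
    all_seqs <- character(0); all_templates <- character(0)
    serial <- integer(nrow(spec$abundances))
    names(serial) <- rownames(spec$abundances)
    for (s in rownames(spec$abundances)) {
      for (t in colnames(spec$abundances)) {
        n <- spec$abundances[s, t]
        if (n == 0) next
        Lt <- if (!is.null(spec$length_variants) &&
                  t %in% names(spec$length_variants)) {
          spec$length_variants[[t]]
        } else {
          L0
        }
        tpl <- match(strsplit(substr(spec$templates[[t]], 1L, Lt),
                              "")[[1L]], bases)
        mat <- matrix(tpl, nrow = n, ncol = Lt, byrow = TRUE)
        hit <- which(matrix(runif(n * Lt), nrow = n) <
                       matrix(err[seq_len(Lt)], nrow = n, ncol = Lt,
                              byrow = TRUE))
        if (length(hit) > 0L) {
          mat[hit] <- alt[cbind(mat[hit],
                                sample.int(3L, length(hit),
                                           replace = TRUE))]
        }
        seqs <- apply(matrix(bases[mat], nrow = n), 1L, paste,
                      collapse = "")
        ids <- sprintf("%s_%06d", s, serial[s] + seq_len(n))
        serial[s] <- serial[s] + n
        all_ids <- c(all_ids, ids)
        all_samples <- c(all_samples, rep(s, n))
        all_seqs <- c(all_seqs, seqs)
        all_templates <- c(all_templates, rep(t, n))
      }
    }
    if (length(all_ids) == 0L) stop("spec requests zero reads")
    list(
      reads = read_set(all_ids, all_samples, all_seqs),
      truth = data.frame(read_id = all_ids, sample = all_samples,
                         template = all_templates,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Write a ground-truth assignment table as TSV
#'
#' @param truth the `truth` data.frame from [simulate_reads()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
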