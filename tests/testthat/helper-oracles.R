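# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive: enumeration and set comprehension, no shared code with
# the implementation under test.

random_reads <- function(n, length = 36, seed = NULL, qual_char = "I") {
  build <- function() {
    tibble::tibble(
      read_id = sprintf("r%05d", seq_len(n)),
      bases = vapply(seq_len(n), function(i) {
        paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
              collapse = "")
      }, character(1)),
      quals = strrep(qual_char, length)
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

read_tbl <- function(bases, quals = NULL) {
  tibble::tibble(
    read_id = sprintf("r%d", seq_along(bases)),
    bases = bases,
    quals = quals %||% strrep("I", nchar(bases))
  )
}

qual_string <- function(q, offset = 33L) {
  intToUtf8(q + offset)
}

# Brute-force Mott oracle: try every truncation length, keep the prefix
# whose removed suffix maximizes sum(cutoff - q); require a positive sum,
# ties broken toward retaining more bases.
mott_oracle_keep <- function(q, cutoff) {
  n <- length(q)
  best_keep <- n
  best_sum <- 0
  for (keep in (n - 1):0) {
    if (n < 1) break
    removed <- q[(keep + 1):n]
    s <- sum(cutoff - removed)
    if (s > best_sum) {  # strict: ties keep the longer prefix
      best_sum <- s
      best_keep <- keep
    }
  }
  best_keep
}

# Set-comprehension re-implementations of the two k-mer filters.
max_run_length <- function(kmer) {
  max(rle(strsplit(kmer, "")[[1]])$lengths)
}

homopolymer_filter_oracle <- function(kmers, k) {
  kmers[vapply(kmers, max_run_length, integer(1)) < max(2L, k %/% 2L)]
}

ratio_filter_oracle <- function(counts, R) {
  f_S <- max(counts)
  names(counts)[f_S / counts <= R]
}

# Path-decomposition oracle for suffix-prefix assembly: valid only when the
# overlap graph is a disjoint union of simple paths; follows edges from
# every source node.
assembly_path_oracle <- function(kmers) {
  k <- nchar(kmers[1])
  pref <- substr(kmers, 1, k - 1)
  suff <- substr(kmers, 2, k)
  succ <- lapply(seq_along(kmers), function(i) which(pref == suff[i]))
  pred <- lapply(seq_along(kmers), function(i) which(suff == pref[i]))
  if (any(lengths(succ) > 1) || any(lengths(pred) > 1)) {
    stop("overlap graph is not path-shaped")
  }
  sources <- which(lengths(pred) == 0)
  if (length(sources) == 0) stop("overlap graph has a cycle")
  merges <- character(0)
  for (s in sources) {
    chain <- s
    while (length(succ[[chain[length(chain)]]]) == 1) {
      chain <- c(chain, succ[[chain[length(chain)]]])
    }
    merges <- c(merges, paste0(
      kmers[chain[1]],
      paste(substr(kmers[chain[-1]], k, k), collapse = "")
    ))
  }
  sort(merges)
}

# Random k-mer set whose overlap graph is a disjoint union of simple paths:
# consecutive k-mers of a few random strings, rejected unless path-shaped.
random_path_kmer_set <- function(k = 5, max_kmers = 8) {
  repeat {
    n_paths <- sample(1:3, 1)
    kmers <- unique(unlist(lapply(seq_len(n_paths), function(i) {
      m <- sample(1:4, 1)
      s <- paste(sample(c("A", "C", "G", "T"), k + m - 1, replace = TRUE),
                 collapse = "")
      substring(s, 1:m, k:(k + m - 1))
    })))
    if (length(kmers) > max_kmers) next
    pref <- substr(kmers, 1, k - 1)
    suff <- substr(kmers, 2, k)
    indeg <- vapply(seq_along(kmers), function(i) sum(suff == pref[i]), 0L)
    outdeg <- vapply(seq_along(kmers), function(i) sum(pref == suff[i]), 0L)
    if (any(indeg > 1) || any(outdeg > 1) || all(indeg > 0)) next
    # reject cyclic components: every node must be reachable from a source
    seen <- logical(length(kmers))
    for (s in which(indeg == 0)) {
      node <- s
      repeat {
        seen[node] <- TRUE
        nxt <- which(pref == suff[node])
        if (length(nxt) == 0 || seen[nxt]) break
        node <- nxt
      }
    }
    if (all(seen)) return(kmers)
  }
}

make_kmer_table <- function(kmers, counts, k = nchar(kmers[1]),
                            total_windows = sum(counts) * 2L) {
  df <- tibble::tibble(kmer = kmers, count = as.integer(counts))
  df <- df[order(-df$count, df$kmer), ]
  structure(df, k = as.integer(k), total_windows = as.integer(total_windows),
            class = c("kmer_table", class(tibble::tibble())))
}

expect_prefix_match <- function(predicted, truth, min_overlap = 9) {
  expect_true(adapters_match(predicted, truth, min_overlap = min_overlap),
              label = sprintf("'%s' prefix-matches '%s'", predicted, truth))
}
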