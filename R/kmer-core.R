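#' Count k-mers over a read sample
#'
#' Slides a window of width `k` over every read and tallies each distinct
#' k-mer. Windows containing `N` are skipped and excluded from the window
#' total, so ambiguous bases neither create spurious k-mers nor deflate the
#' normalized candidate scores.
#'
#' @param reads Tibble of reads (see [read_fastq()]).
#' @param k K-mer length, at least 2.
#' @return A `kmer_table`: a tibble with columns `kmer` and `count`, ordered
#'   by decreasing count (ties lexicographic), carrying attributes `k` and
#'   `total_windows` (the pre-filter total used for score normalization).
#' @export
count_kmers <- function(reads, k) {
  validate_reads(reads)
  k <- as.integer(k)
  stopifnot(k >= 2L, nrow(reads) > 0L)
  bases <- reads$bases
  len <- nchar(bases)
  max_off <- max(len) - k + 1L
  if (max_off < 1L) {
    stop("k = ", k, " is larger than every read in the sample", call. = FALSE)
  }
  uniform <- length(unique(len)) == 1L
  pieces <- vector("list", max_off)
  for (i in seq_len(max_off)) {
    sel <- if (uniform) bases else bases[len >= i + k - 1L]
    pieces[[i]] <- substr(sel, i, i + k - 1L)
  }
  kmers <- unlist(pieces, use.names = FALSE)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  tab <- vctrs::vec_count(kmers, sort = "count")
  new_kmer_table(
    tibble::tibble(kmer = tab$key, count = tab$count),
    k = k, total_windows = length(kmers)
  )
}

new_kmer_table <- function(df, k, total_windows) {
  # order by count desc then kmer, for deterministic downstream tie-breaks
  df <- dplyr::arrange(df, dplyr::desc(.data$count), .data$kmer)
  structure(df, k = as.integer(k),
            total_windows = as.integer(total_windows),
            class = c("kmer_table", class(tibble::tibble())))
}

#' @export
print.kmer_table <- function(x, ...) {
  cat("# k-mer table: k =", attr(x, "k"),
      "| total windows =", attr(x, "total_windows"), "\n")
  NextMethod()
}

kmer_k <- function(table) attr(table, "k")
kmer_total_windows <- function(table) attr(table, "total_windows")

#' Remove low-complexity k-mers
#'
#' Discards every k-mer containing a homopolymer run (a single nucleotide
#' repeated) of length `floor(k/2)` or more, e.g. any 9-mer with a run of 4
#' identical bases. Poly(A) tails and other low-complexity oligos recur
#' across reads much like an adapter does, so without this filter they
#' contaminate the candidate list. The window total is left unchanged:
#' normalization always uses the pre-filter total of the run.
#'
#' @param table A `kmer_table` from [count_kmers()].
#' @return A `kmer_table` restricted to the surviving k-mers.
#' @export
filter_low_complexity <- function(table) {
  stopifnot(inherits(table, "kmer_table"))
  m <- max(2L, kmer_k(table) %/% 2L)
  pat <- sprintf("A{%d,}|C{%d,}|G{%d,}|T{%d,}", m, m, m, m)
  keep <- !grepl(pat, table$kmer)
  new_kmer_table(dplyr::filter(tibble::as_tibble(table), keep),
                 k = kmer_k(table),
                 total_windows = kmer_total_windows(table))
}

#' Remove infrequent k-mers by frequency ratio
#'
#' With `f(S)` the count of the most abundant surviving k-mer, each k-mer
#' `s` gets the ratio `r = f(S) / f(s)`; k-mers with `r` strictly larger
#' than the threshold `R` are discarded. Adapter-derived k-mers occur at
#' nearly the frequency of the adapter itself, so they cluster near `r = 1`
#' while background k-mers fall far behind. The boundary is inclusive:
#' `r == R` survives.
#'
#' @param table A `kmer_table`, normally after [filter_low_complexity()].
#' @param R Ratio threshold, greater than 1.
#' @return A `kmer_table` restricted to the surviving k-mers.
#' @export
filter_by_ratio <- function(table, R) {
  stopifnot(inherits(table, "kmer_table"), R > 1)
  if (nrow(table) == 0L) return(table)
  f_S <- max(table$count)
  keep <- f_S / table$count <= R
  new_kmer_table(dplyr::filter(tibble::as_tibble(table), keep),
                 k = kmer_k(table),
                 total_windows = kmer_total_windows(table))
}

#' Normalize a summed k-mer frequency into a score
#'
#' Divides the summed member frequencies of an assembly by the total k-mer
#' window count of the run, so scores are comparable across runs with
#' different `k` and `R` and can be tallied in iterative mode.
#'
#' @param counts Member k-mer counts.
#' @param total_windows Pre-filter window total of the generating run.
#' @return A score in `[0, 1]`.
#' @export
score_normalize <- function(counts, total_windows) {
  if (total_windows <= 0) {
    stop("score undefined: total window count is zero", call. = FALSE)
  }
  sum(counts) / total_windows
}

#' Assemble surviving k-mers into adapter candidates
#'
#' Chains k-mers whose (k-1)-suffix matches another's (k-1)-prefix into
#' longer sequences. Assembly is greedy and deterministic: each chain is
#' seeded at the highest-count unused k-mer and extended rightward, then
#' leftward, one overlapping k-mer at a time, preferring the higher-count
#' neighbour on branches; a k-mer is used at most once, so cycles
#' terminate. On path-shaped overlap graphs -- the expected structure when
#' the survivors come from a single adapter -- this recovers the maximal
#' paths exactly.
#'
#' @param table A filtered `kmer_table`.
#' @return An `adapter_candidates` tibble with columns `sequence`, `score`
#'   (summed member counts over the run's window total), `n_kmers` and a
#'   `members` list-column of per-chain k-mer/count tibbles, ordered by
#'   decreasing score (ties: higher summed count, then sequence).
#' @export
assemble_kmers <- function(table) {
  stopifnot(inherits(table, "kmer_table"))
  total <- kmer_total_windows(table)
  empty <- tibble::tibble(sequence = character(), score = numeric(),
                          n_kmers = integer(), members = list())
  if (nrow(table) == 0L) {
    return(structure(empty, class = c("adapter_candidates", class(empty))))
  }
  k <- kmer_k(table)
  kmers <- table$kmer  # already count-desc, kmer-asc
  counts <- table$count
  pref <- substr(kmers, 1L, k - 1L)
  suff <- substr(kmers, 2L, k)
  used <- logical(length(kmers))

  chains <- list()
  for (seed in seq_along(kmers)) {
    if (used[seed]) next
    used[seed] <- TRUE
    chain <- seed
    # rightward: next k-mer's prefix equals current suffix
    repeat {
      nxt <- which(!used & pref == suff[chain[length(chain)]])
      if (length(nxt) == 0L) break
      nxt <- nxt[1L]  # table order = highest count first
      used[nxt] <- TRUE
      chain <- c(chain, nxt)
    }
    # leftward: previous k-mer's suffix equals current prefix
    repeat {
      prv <- which(!used & suff == pref[chain[1L]])
      if (length(prv) == 0L) break
      prv <- prv[1L]
      used[prv] <- TRUE
      chain <- c(prv, chain)
    }
    chains[[length(chains) + 1L]] <- chain
  }

  seqs <- vapply(chains, function(ch) {
    paste0(kmers[ch[1L]],
           paste(substr(kmers[ch[-1L]], k, k), collapse = ""))
  }, character(1))
  sums <- vapply(chains, function(ch) sum(counts[ch]), numeric(1))
  out <- tibble::tibble(
    sequence = seqs,
    score = sums / total,
    n_kmers = lengths(chains),
    members = lapply(chains, function(ch) {
      tibble::tibble(kmer = kmers[ch], count = counts[ch])
    })
  )
  # within one table score order and summed-count order coincide (shared
  # denominator), so ties reduce to the lexicographic rule
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$sequence)
  structure(out, class = c("adapter_candidates", class(empty)))
}
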