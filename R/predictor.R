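new_adapter_prediction <- function(candidates, params, sampled_reads, mode) {
  structure(
    list(candidates = candidates, params = params,
         sampled_reads = as.integer(sampled_reads), mode = mode),
    class = "adapter_prediction"
  )
}

run_single_setting <- function(table, R) {
  filtered <- filter_by_ratio(filter_low_complexity(table), R)
  assemble_kmers(filtered)
}

#' Predict the 3' adapter from reads (single mode)
#'
#' Runs the core pipeline once at a fixed parameter setting:
#' k-mer counting over the read sample, low-complexity filtering, the
#' frequency-ratio filter at threshold `R`, and suffix-prefix assembly of
#' the survivors. The top-scoring assembled sequence is the putative 3'
#' adapter. The defaults `k = 9`, `R = 1.4` are the single best-performing
#' combination on public human small RNA libraries.
#'
#' @param reads Tibble of reads; normally the head of a library, e.g.
#'   `read_fastq(path, limit = 50000)`.
#' @param k K-mer length.
#' @param R Frequency-ratio threshold (> 1).
#' @param sample_size Use at most this many reads from the top of `reads`.
#' @return An `adapter_prediction` object; see [tidy.adapter_prediction()]
#'   and [glance.adapter_prediction()]. If every k-mer is filtered out the
#'   candidate list is empty and a warning of class
#'   `adapterscout_empty_result` is signalled.
#' @examples
#' lib <- make_library(library_spec(n_reads = 2000, seed = 1))
#' predict_adapter(lib$reads)
#' @export
predict_adapter <- function(reads, k = 9, R = 1.4, sample_size = 50000) {
  validate_reads(reads)
  stopifnot(nrow(reads) > 0L)
  reads <- utils::head(reads, sample_size)
  cands <- run_single_setting(count_kmers(reads, k), R)
  if (nrow(cands) == 0L) {
    warning(rlang::warning_cnd("adapterscout_empty_result",
      message = "no adapter candidate survived filtering"))
  }
  new_adapter_prediction(
    candidates = tibble::as_tibble(cands)[c("sequence", "score")],
    params = tibble::tibble(k = as.integer(k), R = as.numeric(R)),
    sampled_reads = nrow(reads), mode = "single"
  )
}

#' Predict the 3' adapter by tallying several parameter settings
#'
#' Runs single-mode prediction for every combination in `ks` x `Rs` and
#' re-ranks the assembled sequences by the sum of their normalized scores
#' across runs. The correct adapter is nearly always among the candidates
#' of each run even when it is not ranked first, so tallying across
#' settings recovers adapters that any individual setting misses. Sequences
#' are tallied by exact string identity. The default grid is
#' `k` in \{9, 11\} by `R` in \{1.2, 1.3, 1.4\}.
#'
#' @inheritParams predict_adapter
#' @param ks K-mer lengths to combine.
#' @param Rs Ratio thresholds to combine.
#' @return An `adapter_prediction` object whose scores are tallied over the
#'   grid (each run contributes at most 1, so a tallied score is bounded by
#'   the number of runs).
#' @export
predict_adapter_iterative <- function(reads, ks = c(9, 11),
                                      Rs = c(1.2, 1.3, 1.4),
                                      sample_size = 50000) {
  validate_reads(reads)
  stopifnot(nrow(reads) > 0L, length(ks) > 0L, length(Rs) > 0L)
  reads <- utils::head(reads, sample_size)
  per_run <- purrr::map(sort(unique(as.integer(ks))), function(k) {
    table <- count_kmers(reads, k)
    purrr::map(sort(unique(as.numeric(Rs))), function(R) {
      cands <- run_single_setting(table, R)
      tibble::as_tibble(cands)[c("sequence", "score")]
    })
  })
  runs <- purrr::list_flatten(per_run)
  tallied <- dplyr::bind_rows(runs) |>
    dplyr::summarise(score = sum(.data$score), .by = "sequence") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$sequence)
  if (nrow(tallied) == 0L) {
    warning(rlang::warning_cnd("adapterscout_empty_result",
      message = "no adapter candidate survived filtering in any run"))
  }
  new_adapter_prediction(
    candidates = tallied,
    params = tidyr::expand_grid(k = sort(unique(as.integer(ks))),
                                R = sort(unique(as.numeric(Rs)))),
    sampled_reads = nrow(reads), mode = "iterative"
  )
}

#' Top predicted adapter of a prediction
#'
#' @param x An `adapter_prediction` or `exhaustive_report`.
#' @return The adapter string, or `NA_character_` if no candidate survived.
#' @export
optimal_adapter <- function(x) UseMethod("optimal_adapter")

#' @export
optimal_adapter.adapter_prediction <- function(x) {
  if (nrow(x$candidates) == 0L) NA_character_ else x$candidates$sequence[1L]
}

#' @export
print.adapter_prediction <- function(x, n = 5, ...) {
  cat(sprintf("3' adapter prediction (%s mode, %d reads sampled)\n",
              x$mode, x$sampled_reads))
  if (nrow(x$candidates) == 0L) {
    cat("  no candidates survived filtering\n")
  } else {
    cat(sprintf("  putative adapter: %s (score %.4f)\n",
                x$candidates$sequence[1L], x$candidates$score[1L]))
    cat(sprintf("  %d candidate(s); parameters: %s\n", nrow(x$candidates),
                paste(sprintf("(k=%d, R=%.1f)", x$params$k, x$params$R),
                      collapse = " ")))
  }
  invisible(x)
}

#' Tidy an adapter prediction into its candidate table
#'
#' @param x An `adapter_prediction`.
#' @param ... Unused.
#' @return A tibble with columns `rank`, `sequence`, `score`.
#' @method tidy adapter_prediction
#' @export
tidy.adapter_prediction <- function(x, ...) {
  dplyr::mutate(x$candidates, rank = dplyr::row_number(),
                .before = "sequence")
}

#' One-row summary of an adapter prediction
#'
#' @param x An `adapter_prediction`.
#' @param ... Unused.
#' @return A one-row tibble: `adapter`, `score`, `n_candidates`,
#'   `sampled_reads`, `mode`.
#' @method glance adapter_prediction
#' @export
glance.adapter_prediction <- function(x, ...) {
  tibble::tibble(
    adapter = optimal_adapter(x),
    score = if (nrow(x$candidates)) x$candidates$score[1L] else NA_real_,
    n_candidates = nrow(x$candidates),
    sampled_reads = x$sampled_reads,
    mode = x$mode
  )
}

#' Plot candidate adapter scores
#'
#' Horizontal bar chart of the top candidate sequences by (tallied) score;
#' a clean library shows one dominant bar.
#'
#' @param object An `adapter_prediction`.
#' @param n Number of top candidates to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot adapter_prediction
#' @export
autoplot.adapter_prediction <- function(object, n = 10, ...) {
  df <- utils::head(tidy(object), n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$score,
    y = stats::reorder(.data$sequence, .data$score))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "normalized score", y = NULL,
                  title = sprintf("Adapter candidates (%s mode)", object$mode)) +
    ggplot2::theme_minimal()
}

#' Do a predicted and a reference adapter agree?
#'
#' Two adapters are considered a match when the shorter is a prefix of the
#' longer with at least `min_overlap` shared bases. Prefix agreement is the
#' operative notion: clipping only ever uses the adapter's leading bases,
#' and assembled candidates may legitimately be shorter or longer than the
#' full adapter oligo.
#'
#' @param predicted,truth Adapter strings (`NA` never matches).
#' @param min_overlap Minimum shared prefix length.
#' @return Logical.
#' @export
adapters_match <- function(predicted, truth, min_overlap = 9) {
  if (length(predicted) != 1L || is.na(predicted) || is.na(truth)) return(FALSE)
  n <- min(nchar(predicted), nchar(truth))
  n >= min_overlap &&
    substr(predicted, 1L, n) == substr(truth, 1L, n)
}
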