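#' Specify a user-defined read-mapping command
#'
#' Exhaustive mode shells out to whatever short-read mapper the user
#' prefers. The command is given as a template containing the placeholders
#' `{input}` (FASTQ of processed reads) and `{output}` (SAM destination),
#' each exactly once. Mapping strictness is the user's choice inside the
#' template; requiring perfect matches (e.g. `bowtie -v 0`) is the
#' recommended setting, since a correctly cleansed small RNA read should
#' align exactly.
#'
#' @param command_template Shell command template, e.g.
#'   `"bowtie -v 0 -S idx {input} {output}"`.
#' @return A `mapper_spec` object.
#' @export
mapper_spec <- function(command_template) {
  stopifnot(is.character(command_template), length(command_template) == 1L)
  n_in <- lengths(regmatches(command_template,
                             gregexpr("{input}", command_template, fixed = TRUE)))
  n_out <- lengths(regmatches(command_template,
                              gregexpr("{output}", command_template, fixed = TRUE)))
  if (n_in != 1L || n_out != 1L) {
    stop("mapper template must contain {input} and {output} exactly once",
         call. = FALSE)
  }
  structure(list(command_template = command_template), class = "mapper_spec")
}

# Count primary mapped records in a SAM file: FLAG without 0x4 (unmapped),
# 0x100 (secondary) or 0x800 (supplementary).
count_sam_mapped <- function(sam_path) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) return(0L)
  flags <- suppressWarnings(
    as.integer(vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 2L))
  )
  if (anyNA(flags)) {
    stop("unparseable SAM: missing or non-numeric FLAG field", call. = FALSE)
  }
  sum(bitwAnd(flags, 0x4L) == 0L &
      bitwAnd(flags, 0x100L) == 0L &
      bitwAnd(flags, 0x800L) == 0L)
}

#' Run a user-defined mapper on a FASTQ file
#'
#' Substitutes the reads path and a SAM output path into the mapper
#' template, executes it, and counts primary mapped records in the
#' resulting SAM.
#'
#' @param spec A [mapper_spec()].
#' @param reads_path FASTQ file of reads to map.
#' @return A list with `mapped` (primary mapped record count) and
#'   `submitted` (records in `reads_path`).
#' @export
run_mapper <- function(spec, reads_path) {
  stopifnot(inherits(spec, "mapper_spec"), file.exists(reads_path))
  sam_path <- tempfile(fileext = ".sam")
  on.exit(unlink(sam_path), add = TRUE)
  cmd <- sub("{input}", reads_path, spec$command_template, fixed = TRUE)
  cmd <- sub("{output}", sam_path, cmd, fixed = TRUE)
  err_file <- tempfile(fileext = ".err")
  on.exit(unlink(err_file), add = TRUE)
  status <- system2("sh", c("-c", shQuote(cmd)), stdout = FALSE,
                    stderr = err_file)
  if (status != 0L) {
    diag <- paste(readLines(err_file, warn = FALSE), collapse = "\n")
    stop("mapper command failed (exit ", status, "): ", cmd,
         if (nzchar(diag)) paste0("\n", diag), call. = FALSE)
  }
  if (!file.exists(sam_path)) {
    stop("mapper produced no SAM output at the {output} path", call. = FALSE)
  }
  submitted <- nrow(read_fastq(reads_path))
  list(mapped = count_sam_mapped(sam_path), submitted = submitted)
}

#' Clip a 3' adapter from reads by exact 7-mer prefix search
#'
#' For each read, the leftmost exact occurrence of the adapter's first 7
#' bases marks the insert/adapter junction; everything from the junction on
#' is removed, quality string included. Reads without the 7-mer, and reads
#' whose remaining insert is shorter than `min_insert`, are excluded from
#' the clipped output. The clipped fraction counts every read in which the
#' 7-mer was found, regardless of insert length.
#'
#' @param reads Tibble of reads.
#' @param adapter Adapter sequence, at least 7 nt.
#' @param min_insert Minimum insert length to keep (default 16, the short
#'   end of real small RNAs).
#' @return A list with `reads` (clipped tibble), `clipped_fraction`,
#'   `n_clipped` (7-mer found), `n_kept` (passing `min_insert`) and
#'   `n_input`.
#' @export
clip_adapter <- function(reads, adapter, min_insert = 16) {
  validate_reads(reads)
  if (nchar(adapter) < 7L) {
    stop("adapter must be at least 7 nt for prefix clipping", call. = FALSE)
  }
  stopifnot(min_insert >= 1L)
  key <- substr(toupper(adapter), 1L, 7L)
  pos <- regexpr(key, reads$bases, fixed = TRUE)  # leftmost occurrence, 1-based
  found <- pos > 0L
  insert_len <- ifelse(found, pos - 1L, NA_integer_)
  keep <- found & insert_len >= min_insert
  clipped <- reads[keep, , drop = FALSE]
  clipped$bases <- substr(clipped$bases, 1L, insert_len[keep])
  clipped$quals <- substr(clipped$quals, 1L, insert_len[keep])
  list(
    reads = tibble::as_tibble(clipped),
    clipped_fraction = if (nrow(reads)) sum(found) / nrow(reads) else NA_real_,
    n_clipped = sum(found),
    n_kept = sum(keep),
    n_input = nrow(reads)
  )
}

#' Exhaustive adapter search by genome-mapping rate
#'
#' Runs single-mode prediction over the `ks` x `Rs` grid, takes each run's
#' top candidate, deduplicates, and evaluates every candidate by clipping
#' and mapping the cleansed reads with the user-defined mapper. The raw
#' (unclipped) reads are also mapped. The adapter with the highest
#' genome-mapping rate is the optimal adapter; when the raw reads map at
#' least as well as any clipped candidate (and at or above 20%), the
#' library is judged already processed ("ready-to-map"). A mapping rate
#' below 20% for the winner marks the library as poor quality.
#'
#' Both the clipped and mapped fractions are relative to the number of
#' sampled input reads, so `mapped <= clipped` holds for every candidate.
#'
#' @inheritParams predict_adapter_iterative
#' @param spec A [mapper_spec()].
#' @param min_insert Minimum insert length submitted to the mapper.
#' @param candidates Optional character vector of adapters to evaluate
#'   instead of (in addition to raw) the grid predictions.
#' @return An `exhaustive_report` with an `evaluations` tibble (`adapter`,
#'   `clipped_fraction`, `mapped_fraction`; the raw reads appear as adapter
#'   `"RAW"` with `clipped_fraction = NA`), `optimal_adapter`, `quality_ok`
#'   and `already_processed`.
#' @export
exhaustive_search <- function(reads, spec, ks = c(9, 11),
                              Rs = c(1.2, 1.3, 1.4), sample_size = 50000,
                              min_insert = 16, candidates = NULL) {
  validate_reads(reads)
  stopifnot(inherits(spec, "mapper_spec"), nrow(reads) > 0L)
  reads <- utils::head(reads, sample_size)
  n <- nrow(reads)

  if (is.null(candidates)) {
    grid <- expand.grid(k = sort(unique(as.integer(ks))),
                        R = sort(unique(as.numeric(Rs))))
    candidates <- purrr::map_chr(seq_len(nrow(grid)), function(i) {
      p <- withCallingHandlers(
        predict_adapter(reads, k = grid$k[i], R = grid$R[i], sample_size = n),
        adapterscout_empty_result = function(w) invokeRestart("muffleWarning")
      )
      optimal_adapter(p)
    })
    candidates <- unique(candidates[!is.na(candidates) & nchar(candidates) >= 7L])
  }

  work <- tempfile("adapterscout_exh_")
  dir.create(work)
  on.exit(unlink(work, recursive = TRUE), add = TRUE)

  raw_path <- file.path(work, "raw.fastq")
  write_fastq(reads, raw_path)
  raw_map <- run_mapper(spec, raw_path)
  evals <- tibble::tibble(adapter = "RAW",
                          clipped_fraction = NA_real_,
                          mapped_fraction = raw_map$mapped / n)

  for (i in seq_along(candidates)) {
    cl <- clip_adapter(reads, candidates[i], min_insert = min_insert)
    mapped <- 0L
    if (nrow(cl$reads) > 0L) {
      path <- file.path(work, sprintf("cand%02d.fastq", i))
      write_fastq(cl$reads, path)
      mapped <- run_mapper(spec, path)$mapped
    }
    evals <- dplyr::bind_rows(evals, tibble::tibble(
      adapter = candidates[i],
      clipped_fraction = cl$clipped_fraction,
      mapped_fraction = mapped / n
    ))
  }

  clipped_evals <- dplyr::filter(evals, .data$adapter != "RAW")
  if (nrow(clipped_evals) > 0L) {
    best <- dplyr::slice_max(clipped_evals, .data$mapped_fraction,
                             n = 1L, with_ties = FALSE)
    optimal <- best$adapter
    best_mapped <- best$mapped_fraction
  } else {
    optimal <- NA_character_
    best_mapped <- NA_real_
  }
  raw_mapped <- evals$mapped_fraction[evals$adapter == "RAW"]
  already_processed <- raw_mapped >= 0.20 &&
    (is.na(best_mapped) || raw_mapped >= best_mapped)
  governing <- if (already_processed || is.na(best_mapped)) raw_mapped else best_mapped

  structure(
    list(evaluations = evals, optimal_adapter = optimal,
         quality_ok = governing >= 0.20,
         already_processed = already_processed,
         sampled_reads = n, min_insert = min_insert),
    class = "exhaustive_report"
  )
}

#' @export
optimal_adapter.exhaustive_report <- function(x) x$optimal_adapter

#' Warn when the optimal mapping rate indicates a poor library
#'
#' Emits a structured warning (class `adapterscout_quality_warning`) when
#' the governing mapping rate of an exhaustive report is below 20%; reads
#' from a healthy library should map at a far higher rate once the correct
#' adapter is removed. Pure function of the report; the boundary is
#' inclusive (exactly 20% passes).
#'
#' @param report An `exhaustive_report`.
#' @return `TRUE` (pass) or `FALSE` (warned), invisibly.
#' @export
assess_quality <- function(report) {
  stopifnot(inherits(report, "exhaustive_report"))
  if (!isTRUE(report$quality_ok)) {
    warning(rlang::warning_cnd("adapterscout_quality_warning",
      message = "input library quality is poor: optimal genome-mapping rate is below 20%"))
    return(invisible(FALSE))
  }
  invisible(TRUE)
}

#' @export
print.exhaustive_report <- function(x, ...) {
  cat(sprintf("Exhaustive 3' adapter search (%d reads sampled)\n",
              x$sampled_reads))
  if (x$already_processed) {
    cat("  library is already processed (ready-to-map)\n")
  } else if (!is.na(x$optimal_adapter)) {
    cat(sprintf("  optimal adapter: %s\n", x$optimal_adapter))
  } else {
    cat("  no adapter candidate could be evaluated\n")
  }
  cat(sprintf("  quality: %s\n", if (x$quality_ok) "ok" else
    "POOR (mapping rate < 20%)"))
  print(x$evaluations)
  invisible(x)
}

#' Tidy an exhaustive report into its evaluation table
#'
#' @param x An `exhaustive_report`.
#' @param ... Unused.
#' @return Tibble of per-candidate clipped and mapped fractions, with an
#'   `optimal` flag column.
#' @method tidy exhaustive_report
#' @export
tidy.exhaustive_report <- function(x, ...) {
  dplyr::mutate(x$evaluations,
    optimal = !is.na(x$optimal_adapter) & .data$adapter == x$optimal_adapter)
}

#' One-row summary of an exhaustive report
#'
#' @param x An `exhaustive_report`.
#' @param ... Unused.
#' @return One-row tibble: `optimal_adapter`, `clipped_fraction`,
#'   `mapped_fraction`, `quality_ok`, `already_processed`, `sampled_reads`.
#' @method glance exhaustive_report
#' @export
glance.exhaustive_report <- function(x, ...) {
  row <- dplyr::filter(x$evaluations,
                       !is.na(x$optimal_adapter) & .data$adapter == x$optimal_adapter)
  tibble::tibble(
    optimal_adapter = x$optimal_adapter,
    clipped_fraction = if (nrow(row)) row$clipped_fraction else NA_real_,
    mapped_fraction = if (nrow(row)) row$mapped_fraction else NA_real_,
    quality_ok = x$quality_ok,
    already_processed = x$already_processed,
    sampled_reads = x$sampled_reads
  )
}

#' Plot clipped versus mapped fractions of candidate adapters
#'
#' Scatter of per-candidate clipped and mapped fractions with the 20%
#' quality cutoff marked; the optimal candidate is highlighted.
#'
#' @param object An `exhaustive_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot exhaustive_report
#' @export
autoplot.exhaustive_report <- function(object, ...) {
  df <- tidy(object)
  df <- dplyr::filter(df, .data$adapter != "RAW")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$clipped_fraction,
                                   y = .data$mapped_fraction,
                                   colour = .data$optimal)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = 0.20, colour = "red",
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "steelblue",
                                            `FALSE` = "grey60")) +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(x = "fraction of reads clipped",
                  y = "fraction of reads mapped",
                  colour = "optimal") +
    ggplot2::theme_minimal()
}
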