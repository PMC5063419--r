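# stub mappers with fixed behaviour, written fresh per test
write_stub_mapper <- function(dir, mode = c("all", "none")) {
  mode <- match.arg(mode)
  script <- file.path(dir, paste0("stub_", mode, ".py"))
  flag <- if (mode == "all") 0L else 4L
  writeLines(c(
    "import sys",
    "fastq, out = sys.argv[1:3]",
    "with open(fastq) as fh, open(out, 'w') as o:",
    "    o.write('@HD\\tVN:1.6\\n')",
    "    while True:",
    "        h = fh.readline()",
    "        if not h: break",
    "        s = fh.readline().strip(); fh.readline(); q = fh.readline().strip()",
    sprintf("        o.write('%%s\\t%d\\t*\\t0\\t0\\t*\\t*\\t0\\t0\\t%%s\\t%%s\\n' %% (h[1:].split()[0], s, q))", flag)
  ), script)
  mapper_spec(sprintf("python3 %s {input} {output}", script))
}

test_that("mapper templates are validated", {
  expect_error(mapper_spec("bowtie {input}"), "exactly once")
  expect_error(mapper_spec("bowtie {input} {output} {output}"), "exactly once")
  expect_s3_class(mapper_spec("bowtie {input} {output}"), "mapper_spec")
})

test_that("clip_adapter removes the adapter at the leftmost 7-mer prefix", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  r <- read_tbl("ACGTACGTACGTACGTACGTTGGAATTCTCGG")
  cl <- clip_adapter(r, adapter, min_insert = 16)
  expect_equal(cl$reads$bases, "ACGTACGTACGTACGTACGT")
  expect_equal(nchar(cl$reads$quals), 20)
  expect_equal(cl$clipped_fraction, 1)

  # no 7-mer occurrence: excluded and counted unclipped
  r2 <- read_tbl("ACGTACGTACGTACGTACGTACGTACGTACGT")
  cl2 <- clip_adapter(r2, adapter)
  expect_equal(nrow(cl2$reads), 0)
  expect_equal(cl2$clipped_fraction, 0)

  # adapter at position 0: clipped fraction counts it, min_insert drops it
  r3 <- read_tbl(paste0("TGGAATT", strrep("C", 25)))
  cl3 <- clip_adapter(r3, adapter, min_insert = 1)
  expect_equal(cl3$clipped_fraction, 1)
  expect_equal(nrow(cl3$reads), 0)

  expect_error(clip_adapter(r, "TGGAAT"), "at least 7")
})

test_that("clipped reads are strict prefixes that re-locate in the source", {
  lib <- make_library(library_spec(n_reads = 500, seed = 17))
  cl <- clip_adapter(lib$reads, lib$adapter, min_insert = 16)
  expect_gt(nrow(cl$reads), 0)
  src <- lib$reads$bases[match(cl$reads$read_id, lib$reads$read_id)]
  expect_true(all(nchar(cl$reads$bases) < nchar(src)))
  rebuilt <- paste0(cl$reads$bases, substr(lib$adapter, 1, 7))
  expect_true(all(substr(src, 1, nchar(rebuilt)) == rebuilt))
})

test_that("run_mapper counts primary mapped SAM records from stub mappers", {
  dir <- withr::local_tempdir()
  reads <- random_reads(20, length = 20, seed = 5)
  fq <- file.path(dir, "reads.fastq")
  write_fastq(reads, fq)

  all_map <- run_mapper(write_stub_mapper(dir, "all"), fq)
  expect_equal(all_map$mapped, 20)
  expect_equal(all_map$submitted, 20)
  expect_equal(run_mapper(write_stub_mapper(dir, "none"), fq)$mapped, 0)

  bad <- mapper_spec("false {input} {output}")
  expect_error(run_mapper(bad, fq), "mapper command failed")
})

test_that("exact-match stub agrees with brute-force substring search", {
  genome <- make_genome(10000, seed = 23)
  spec <- make_exact_match_mapper(genome)
  dir <- withr::local_tempdir()

  # half genuine genome substrings (either strand), half random
  reads <- withr::with_seed(29, {
    genuine <- vapply(1:30, function(i) {
      start <- sample(9950, 1)
      s <- substr(genome, start, start + 19)
      if (i %% 2 == 0) {
        s <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
      }
      s
    }, character(1))
    dplyr::bind_rows(read_tbl(genuine), random_reads(30, length = 20))
  })
  fq <- file.path(dir, "mixed.fastq")
  write_fastq(reads, fq)
  res <- run_mapper(spec, fq)

  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  expected <- sum(vapply(reads$bases, function(s) {
    grepl(s, genome, fixed = TRUE) || grepl(rc(s), genome, fixed = TRUE)
  }, logical(1)))
  expect_equal(res$mapped, expected)
  expect_gte(expected, 30)  # every genuine read must map
})

test_that("exhaustive search finds the true adapter and obeys its invariants", {
  lib <- make_library(library_spec(n_reads = 4000, seed = 37))
  rep <- exhaustive_search(lib$reads, make_exact_match_mapper(lib$genome))
  expect_prefix_match(rep$optimal_adapter, lib$adapter)
  expect_false(rep$already_processed)
  expect_true(rep$quality_ok)

  ev <- dplyr::filter(rep$evaluations, adapter != "RAW")
  best <- ev$mapped_fraction[ev$adapter == rep$optimal_adapter]
  expect_true(all(ev$mapped_fraction <= best))
  # both fractions share the sampled-read denominator, so mapped <= clipped
  expect_true(all(ev$mapped_fraction <= ev$clipped_fraction + 1e-12))
  expect_true(all(ev$mapped_fraction >= 0 & ev$mapped_fraction <= 1))
})

test_that("adapter-free libraries are classified as already processed", {
  lib <- make_library(library_spec(n_reads = 2000, seed = 43,
                                   adapter_fraction = 0))
  rep <- exhaustive_search(lib$reads, make_exact_match_mapper(lib$genome))
  expect_true(rep$already_processed)
  expect_gte(rep$evaluations$mapped_fraction[rep$evaluations$adapter == "RAW"],
             0.99)
})

test_that("a library with no genomic origin fails the 20% quality rule", {
  reads <- random_reads(2000, length = 36, seed = 47)
  genome <- make_genome(10000, seed = 53)
  rep <- exhaustive_search(reads, make_exact_match_mapper(genome))
  expect_false(rep$quality_ok)
  expect_warning(assess_quality(rep), class = "adapterscout_quality_warning")
})

test_that("the quality boundary is inclusive at exactly 20%", {
  base <- list(evaluations = tibble::tibble(adapter = c("RAW", "X"),
                                            clipped_fraction = c(NA, 0.5),
                                            mapped_fraction = c(0.01, 0.19)),
               optimal_adapter = "X", already_processed = FALSE,
               sampled_reads = 100L, min_insert = 16L)
  below <- structure(modifyList(base, list(quality_ok = FALSE)),
                     class = "exhaustive_report")
  expect_warning(assess_quality(below), class = "adapterscout_quality_warning")

  at <- base
  at$evaluations$mapped_fraction[2] <- 0.20
  at <- structure(modifyList(at, list(quality_ok = TRUE)),
                  class = "exhaustive_report")
  expect_no_warning(assess_quality(at))

  high <- base
  high$evaluations$mapped_fraction[2] <- 0.85
  high <- structure(modifyList(high, list(quality_ok = TRUE)),
                    class = "exhaustive_report")
  expect_no_warning(assess_quality(high))
})

test_that("exhaustive runs are deterministic with a deterministic mapper", {
  lib <- make_library(library_spec(n_reads = 1500, seed = 59))
  spec <- make_exact_match_mapper(lib$genome)
  r1 <- exhaustive_search(lib$reads, spec)
  r2 <- exhaustive_search(lib$reads, spec)
  expect_equal(r1$evaluations, r2$evaluations)
  expect_identical(r1$optimal_adapter, r2$optimal_adapter)
  expect_identical(glance(r1), glance(r2))
})

test_that("report accessors and plot work", {
  lib <- make_library(library_spec(n_reads = 1500, seed = 67))
  rep <- exhaustive_search(lib$reads, make_exact_match_mapper(lib$genome))
  td <- tidy(rep)
  expect_true(any(td$optimal))
  gl <- glance(rep)
  expect_equal(gl$optimal_adapter, rep$optimal_adapter)
  expect_s3_class(autoplot(rep), "ggplot")
})
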