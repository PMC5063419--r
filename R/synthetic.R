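random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Draw a random adapter-like oligo
#'
#' Uniform random sequence rejected until it is free of homopolymer runs of
#' 4 nt or more, mirroring how real ligation adapters are designed (such
#' runs are avoided to keep synthesis and ligation efficient, and they are
#' indistinguishable from low-complexity background).
#'
#' @param length Oligo length.
#' @return An adapter string.
#' @export
random_adapter <- function(length = 21) {
  stopifnot(length >= 7)
  repeat {
    s <- random_dna(length)
    if (!grepl("A{4,}|C{4,}|G{4,}|T{4,}", s)) return(s)
  }
}

#' Draw a random barcode for a given 3' adapter
#'
#' Uniform random sequence rejected until the concatenated barcoded oligo
#' (barcode followed by the adapter) is free of homopolymer runs of 4 nt or
#' more. A de-multiplexed library's barcoded adapter is one designed
#' sequence, so the same design constraint as [random_adapter()] applies
#' across the barcode-adapter junction.
#'
#' @param adapter The 3' adapter the barcode will be prepended to.
#' @param length Barcode length.
#' @return A barcode string.
#' @export
random_barcode <- function(adapter, length = 4) {
  stopifnot(length >= 1)
  repeat {
    b <- random_dna(length)
    if (!grepl("A{4,}|C{4,}|G{4,}|T{4,}", paste0(b, adapter))) return(b)
  }
}

#' Generate a seeded toy genome
#'
#' Uniform random A/C/G/T sequence; identical `length` and `seed` always
#' yield the identical genome.
#'
#' @param length Genome length (at least 1000).
#' @param seed RNG seed.
#' @param fasta_path Optional path; when given, the genome is also written
#'   as a single-record FASTA.
#' @return The genome string, invisibly carrying no state.
#' @export
make_genome <- function(length = 10000, seed = 1, fasta_path = NULL) {
  stopifnot(length >= 1000)
  genome <- withr::with_seed(seed, random_dna(length))
  if (!is.null(fasta_path)) {
    width <- 70L
    starts <- seq(1L, nchar(genome), by = width)
    writeLines(c(">synthetic_genome",
                 substring(genome, starts, pmin(starts + width - 1L, nchar(genome)))),
               fasta_path)
  }
  genome
}

#' Describe a synthetic small RNA library
#'
#' Collects the ground-truth parameters of a simulated library: short
#' genomic inserts followed by a 3' adapter (optionally barcoded), read to
#' a fixed cycle count, with configurable contamination by one highly
#' abundant small RNA species, by adapter-dimer ligation products (5' and
#' 3' adapters with no insert), and by adapter-free reads emulating an
#' already-processed library.
#'
#' @param n_reads Sequencing depth.
#' @param read_length Fixed read (cycle) length.
#' @param genome_length Toy genome size.
#' @param insert_length_range Inclusive insert-length bounds.
#' @param adapter Ground-truth 3' adapter.
#' @param barcode Optional barcode prepended to the adapter (de-multiplexed
#'   libraries keep their barcode at the adapter's 5' end).
#' @param adapter_fraction Fraction of reads carrying insert + adapter.
#' @param abundant_rna_fraction Fraction of reads that are one fixed
#'   abundant small RNA insert (still adapter-ligated).
#' @param dimer_fraction Fraction of reads that are pure 5'+3' adapter
#'   ligation products.
#' @param quality_start,quality_end Mean Phred score at the first and last
#'   cycle (linear decay between them).
#' @param quality_sd Gaussian noise around the per-cycle mean, clamped to
#'   quality 2..40.
#' @param seed RNG seed for the whole library.
#' @return A `library_spec` list.
#' @export
library_spec <- function(n_reads = 50000, read_length = 36,
                         genome_length = 10000,
                         insert_length_range = c(18, 26),
                         adapter = "TGGAATTCTCGGGTGCCAAGG",
                         barcode = NULL,
                         adapter_fraction = 0.9,
                         abundant_rna_fraction = 0,
                         dimer_fraction = 0,
                         quality_start = 38, quality_end = 30,
                         quality_sd = 3, seed = 1) {
  remainder <- 1 - adapter_fraction - abundant_rna_fraction - dimer_fraction
  stopifnot(
    n_reads >= 1,
    length(insert_length_range) == 2,
    insert_length_range[1] <= insert_length_range[2],
    insert_length_range[2] <= read_length,
    adapter_fraction >= 0, abundant_rna_fraction >= 0, dimer_fraction >= 0,
    remainder > -1e-9
  )
  if ((adapter_fraction > 0 || dimer_fraction > 0) && !nzchar(adapter)) {
    stop("adapter must be nonempty when adapter-bearing reads are requested",
         call. = FALSE)
  }
  structure(list(
    n_reads = as.integer(n_reads), read_length = as.integer(read_length),
    genome_length = as.integer(genome_length),
    insert_length_range = as.integer(insert_length_range),
    adapter = toupper(adapter), barcode = barcode,
    adapter_fraction = adapter_fraction,
    abundant_rna_fraction = abundant_rna_fraction,
    dimer_fraction = dimer_fraction,
    quality_start = quality_start, quality_end = quality_end,
    quality_sd = quality_sd, seed = as.integer(seed)
  ), class = "library_spec")
}

# deterministic largest-remainder allocation of n items to fractions
largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

revcomp <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Illumina-style 5' adapter used only to build dimer (ligation-product) reads
DIMER_5P <- "GTTCAGAGTTCTACAGTCCGACGATC"

#' Simulate a small RNA sequencing library with known ground truth
#'
#' Each genomic read is a substring of the toy genome (either strand)
#' followed by the (optionally barcoded) 3' adapter, truncated to the read
#' length; reads shorter than the cycle count are padded with random bases,
#' modelling sequencing past the end of the construct. Special read
#' classes (abundant small RNA, adapter dimers, adapter-free) are allocated
#' by deterministic largest-remainder quota and shuffled, so emitted class
#' fractions match the spec within one read. Identical spec (including
#' seed) yields a byte-identical library.
#'
#' @param spec A [library_spec()].
#' @param genome Optional genome string; by default a genome of
#'   `spec$genome_length` is generated from the same seed.
#' @param fastq_path,manifest_path Optional output paths for the FASTQ and
#'   the tab-separated ground-truth manifest.
#' @return A list with `reads` (tibble as from [read_fastq()]), `manifest`
#'   (tibble: `read_id`, `class`, `insert_start`, `insert_end`, `strand`),
#'   `adapter` (the full ground-truth adapter, barcode included) and
#'   `genome`.
#' @export
make_library <- function(spec, genome = NULL, fastq_path = NULL,
                         manifest_path = NULL) {
  stopifnot(inherits(spec, "library_spec"))
  if (is.null(genome)) {
    genome <- make_genome(spec$genome_length, seed = spec$seed)
  }
  full_adapter <- paste0(spec$barcode %||% "", spec$adapter)
  n <- spec$n_reads
  L <- spec$read_length

  withr::with_seed(spec$seed, {
    counts <- largest_remainder(n, c(
      adapter = spec$adapter_fraction,
      abundant = spec$abundant_rna_fraction,
      dimer = spec$dimer_fraction,
      plain = max(0, 1 - spec$adapter_fraction - spec$abundant_rna_fraction -
                    spec$dimer_fraction)
    ))
    classes <- sample(rep(c("adapter", "abundant", "dimer", "plain"), counts))

    ins_len <- sample(seq(spec$insert_length_range[1],
                          spec$insert_length_range[2]),
                      n, replace = TRUE)
    start <- 1L + as.integer(floor(stats::runif(n) *
                                     (nchar(genome) - ins_len + 1L)))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    insert <- substring(genome, start, start + ins_len - 1L)
    # minus-strand inserts come from the reverse-complemented genome at
    # mirrored coordinates (vectorized equivalent of per-read revcomp)
    rc_genome <- revcomp(genome)
    G <- nchar(genome)
    neg <- strand == "-"
    insert[neg] <- substring(rc_genome,
                             G - (start[neg] + ins_len[neg] - 1L) + 1L,
                             G - start[neg] + 1L)

    # one fixed abundant small RNA species, drawn once from the genome
    ab_len <- 22L
    ab_start <- sample.int(nchar(genome) - ab_len + 1L, 1L)
    ab_insert <- substr(genome, ab_start, ab_start + ab_len - 1L)

    is_ab <- classes == "abundant"
    insert[is_ab] <- ab_insert
    start[is_ab] <- ab_start
    ins_len[is_ab] <- ab_len
    strand[is_ab] <- "+"

    construct <- ifelse(
      classes == "dimer",
      paste0(DIMER_5P, full_adapter, full_adapter),
      paste0(insert,
             ifelse(classes == "plain", "", full_adapter))
    )
    # adapter-free ("plain") reads stay at their insert length, as in a
    # library whose adapters were already removed; adapter-bearing
    # constructs shorter than the cycle count are padded with random
    # bases, modelling sequencing past the end of the construct
    pad_me <- classes != "plain" & nchar(construct) < L
    if (any(pad_me)) {
      pad <- vapply(L - nchar(construct[pad_me]), random_dna, character(1))
      construct[pad_me] <- paste0(construct[pad_me], pad)
    }
    bases <- substr(construct, 1L, L)

    q <- matrix(stats::rnorm(n * L,
                             mean = seq(spec$quality_start, spec$quality_end,
                                        length.out = L),
                             sd = spec$quality_sd),
                nrow = L)
    q <- pmin(pmax(round(q), 2), 40)
    qchars <- rawToChar(as.raw(as.integer(q) + 33L))
    quals <- substring(qchars, seq(1L, n * L, by = L),
                       seq(L, n * L, by = L))
    quals <- substr(quals, 1L, nchar(bases))

    reads <- tibble::tibble(
      read_id = sprintf("read_%06d", seq_len(n)),
      bases = bases,
      quals = quals
    )
    manifest <- tibble::tibble(
      read_id = reads$read_id,
      class = classes,
      insert_start = ifelse(classes == "dimer", NA_integer_, start),
      insert_end = ifelse(classes == "dimer", NA_integer_,
                          start + ins_len - 1L),
      strand = ifelse(classes == "dimer", NA_character_, strand)
    )
  })

  if (!is.null(fastq_path)) write_fastq(reads, fastq_path,
                                        gzip = grepl("\\.gz$", fastq_path))
  if (!is.null(manifest_path)) {
    utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(reads = reads, manifest = manifest, adapter = full_adapter,
       genome = genome)
}

#' Build an exact-match stub mapper for a toy genome
#'
#' Writes a reference genome FASTA plus a small self-contained executable
#' that reports a read as mapped if and only if the read (or its reverse
#' complement) occurs verbatim in the genome, emitting minimal valid SAM.
#' It plays the role of a real aligner run in perfect-match mode against a
#' genome small enough for substring search, which makes exhaustive-mode
#' results fully checkable.
#'
#' @param genome Genome string.
#' @param dir Directory to place the stub and FASTA in.
#' @return A [mapper_spec()] invoking the stub.
#' @export
make_exact_match_mapper <- function(genome, dir = tempfile("stub_mapper_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fa")
  writeLines(c(">synthetic_genome", genome), fasta)
  script <- file.path(dir, "exact_match_mapper.py")
  writeLines(c(
    "#!/usr/bin/env python3",
    "# Exact-match stub mapper: read mapped iff it or its reverse complement",
    "# occurs verbatim in the genome. Emits minimal SAM.",
    "import sys",
    "",
    "genome_fa, fastq, out = sys.argv[1:4]",
    "with open(genome_fa) as fh:",
    "    genome = ''.join(l.strip() for l in fh if not l.startswith('>'))",
    "rc = str.maketrans('ACGTN', 'TGCAN')",
    "with open(fastq) as fh, open(out, 'w') as o:",
    "    o.write('@HD\\tVN:1.6\\n@SQ\\tSN:synthetic_genome\\tLN:%d\\n' % len(genome))",
    "    while True:",
    "        h = fh.readline()",
    "        if not h:",
    "            break",
    "        seq = fh.readline().strip()",
    "        fh.readline(); qual = fh.readline().strip()",
    "        name = h[1:].split()[0]",
    "        pos = genome.find(seq)",
    "        if pos >= 0:",
    "            o.write('%s\\t0\\tsynthetic_genome\\t%d\\t255\\t%dM\\t*\\t0\\t0\\t%s\\t%s\\n'",
    "                    % (name, pos + 1, len(seq), seq, qual))",
    "            continue",
    "        rseq = seq.translate(rc)[::-1]",
    "        pos = genome.find(rseq)",
    "        if pos >= 0:",
    "            o.write('%s\\t16\\tsynthetic_genome\\t%d\\t255\\t%dM\\t*\\t0\\t0\\t%s\\t%s\\n'",
    "                    % (name, pos + 1, len(seq), rseq, qual[::-1]))",
    "        else:",
    "            o.write('%s\\t4\\t*\\t0\\t0\\t*\\t*\\t0\\t0\\t%s\\t%s\\n'",
    "                    % (name, seq, qual))"
  ), script)
  Sys.chmod(script, "0755")
  mapper_spec(sprintf("python3 %s %s {input} {output}", script, fasta))
}
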