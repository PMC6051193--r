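test_that("FASTA round-trips through write and read", {
  refs <- reference_set(c(chrA = "ACGTACGTACGTACGT", chrB = "TTTTGGGGCCCCAAAA"))
  path <- withr::local_tempfile(fileext = ".fa")
  write_reference_fasta(refs, path)
  back <- read_reference_fasta(path)
  expect_identical(back$seq, refs$seq)
  expect_identical(names(back), c("chrA", "chrB"))
  expect_error(read_reference_fasta(withr::local_tempfile(fileext = ".fa")))
})

test_that("reference slicing pads with N outside the sequence", {
  refs <- reference_set(c(chr1 = "ACGT"))
  expect_identical(ref_slice(refs, "chr1", -3, 2), "NNNAC")
  expect_identical(ref_slice(refs, "chr1", 0, 4), "ACGT")
  expect_identical(ref_slice(refs, "chr1", 2, 7), "GTNNN")
  expect_identical(ref_slice(refs, "chr1", -2, 6), "NNACGTNN")
  expect_identical(ref_slice(refs, "chr1", 10, 12), "NN")
  expect_identical(ref_slice(refs, "chr1", 2, 2), "")
  expect_error(ref_slice(refs, "nope", 0, 1), "unknown reference")
})

test_that("exact_map reports unique hits and counts unmapped/multimapped", {
  set.seed(13)
  seqA <- paste(rand_dna(1, 400), collapse = "")
  refs <- reference_set(c(chrA = seqA), mode = "genome")
  ins_unique <- substr(seqA, 11, 30) # [10, 30) 0-based
  ins_rc <- revcomp(substr(seqA, 6, 25)) # rc of [5, 25)
  reads <- tibble::tibble(
    read_id = c("u", "rc", "none", "multi"),
    insert = c(ins_unique, ins_rc, strrep("A", 20), "X"),
    umi = "AAAAA", sample = "s1", marker_flag = "REMAINING"
  )
  reads$insert[4] <- substr(seqA, 1, 15) # may or may not be unique; force multi:
  refs2 <- reference_set(c(chrA = seqA,
                           chrB = paste0(substr(seqA, 1, 15),
                                         paste(rand_dna(1, 100), collapse = ""))),
                         mode = "genome")
  m <- exact_map(reads, refs2, min_len = 15)
  aln <- m$alignments
  expect_identical(m$stats$mapped, 2L)
  expect_identical(m$stats$unmapped, 1L)
  expect_identical(m$stats$multimapped, 1L)
  u <- aln[aln$read_id == "u", ]
  expect_identical(list(u$ref_name, u$start, u$end, u$strand),
                   list("chrA", 10L, 30L, "+"))
  rc <- aln[aln$read_id == "rc", ]
  expect_identical(list(rc$ref_name, rc$start, rc$end, rc$strand),
                   list("chrA", 5L, 25L, "-"))
})

test_that("transcriptome mode searches the sense strand only", {
  seqA <- "ACGGTTACCGGATTACCAGGTTAACCGGTT"
  insert <- revcomp(substr(seqA, 3, 22))
  reads <- tibble::tibble(read_id = "r", insert = insert)
  g <- exact_map(reads, reference_set(c(t1 = seqA), "genome"), min_len = 15)
  t <- exact_map(reads, reference_set(c(t1 = seqA), "transcriptome"), min_len = 15)
  expect_identical(g$stats$mapped, 1L)
  expect_identical(g$alignments$strand, "-")
  expect_identical(t$stats$mapped, 0L)
  expect_identical(t$stats$unmapped, 1L)
})

test_that("exact_map agrees with a naive all-offsets scan", {
  set.seed(17)
  refs <- reference_set(c(r1 = paste(rand_dna(1, 250), collapse = ""),
                          r2 = paste(rand_dna(1, 180), collapse = "")),
                        mode = "genome")
  inserts <- character(300)
  for (i in seq_along(inserts)) {
    kind <- i %% 3
    if (kind == 0) {
      inserts[i] <- rand_dna(1, sample(15:20, 1))
    } else {
      nm <- sample(names(refs), 1)
      L <- nchar(refs$seq[[nm]])
      len <- sample(15:20, 1)
      st <- sample(L - len, 1)
      piece <- substr(refs$seq[[nm]], st, st + len - 1)
      inserts[i] <- if (kind == 1) piece else revcomp(piece)
    }
  }
  reads <- tibble::tibble(read_id = as.character(seq_along(inserts)),
                          insert = inserts)
  m <- exact_map(reads, refs, min_len = 15)
  for (i in seq_along(inserts)) {
    hits <- oracle_occurrences(inserts[i], refs)
    got <- m$alignments[m$alignments$read_id == as.character(i), ]
    if (length(hits) == 1) {
      expect_identical(nrow(got), 1L)
      expect_identical(got$ref_name, hits[[1]]$ref)
      expect_identical(got$strand, hits[[1]]$strand)
      if (hits[[1]]$strand == "+") {
        expect_identical(got$start, hits[[1]]$start)
      } else {
        expect_identical(got$start, hits[[1]]$start)
        expect_identical(got$end, hits[[1]]$start + nchar(inserts[i]))
      }
    } else {
      expect_identical(nrow(got), 0L)
    }
  }
})

test_that("cDNA starts are strand-aware first aligned bases", {
  aln <- tibble::tibble(read_id = c("a", "b"), ref_name = "chrA",
                        start = c(100L, 100L), end = c(130L, 130L),
                        strand = c("+", "-"),
                        umi = "AAAAA", sample = "s1",
                        marker_flag = "REMAINING")
  st <- assign_cdna_starts(aln)
  expect_identical(st$pos, c(100L, 129L))
  expect_identical(st$strand, c("+", "-"))
})

test_that("starts BED round-trips exactly", {
  starts <- tibble::tibble(
    ref_name = c("chrA", "chrA", "chrB"),
    pos = c(0L, 129L, 42L),
    strand = c("+", "-", "+"),
    umi = c("ACGTA", "TTTTT", "GGGGG"),
    sample = c("s1", "s1", "s2"),
    marker_flag = c("READ_THROUGH", "REMAINING", "REMAINING"),
    support = c(3L, 1L, 7L)
  )
  path <- withr::local_tempfile(fileext = ".bed")
  write_starts_bed(starts, path)
  back <- read_starts_bed(path)
  expect_identical(back, starts)
  # without a support column the score defaults to 1
  path2 <- withr::local_tempfile(fileext = ".bed")
  write_starts_bed(starts[, -7], path2)
  expect_identical(read_starts_bed(path2)$support, c(1L, 1L, 1L))
})

test_that("SAM ingestion keeps primary mapped records and recovers metadata", {
  sam <- withr::local_tempfile(fileext = ".sam")
  lines <- c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:chrA\tLN:1000",
    # plus strand, 5' soft clip: first aligned base is POS
    paste("r1#ACGTC#s1#RT", 0, "chrA", 101, 30, "5S20M", "*", 0, 0,
          strrep("A", 25), strrep("I", 25), sep = "\t"),
    # minus strand
    paste("r2#TTTTT#s1#RE", 16, "chrA", 51, 30, "20M", "*", 0, 0,
          strrep("A", 20), strrep("I", 20), sep = "\t"),
    # low MAPQ
    paste("r3#GGGGG#s1#RE", 0, "chrA", 11, 2, "20M", "*", 0, 0,
          strrep("A", 20), strrep("I", 20), sep = "\t"),
    # secondary and unmapped records are dropped
    paste("r1#ACGTC#s1#RT", 256, "chrA", 301, 30, "25M", "*", 0, 0,
          "*", "*", sep = "\t"),
    paste("r4#CCCCC#s1#RE", 4, "*", 0, 0, "*", "*", 0, 0,
          strrep("A", 20), strrep("I", 20), sep = "\t")
  )
  writeLines(lines, sam)
  aln <- read_sam_alignments(sam)
  expect_identical(sort(aln$read_id), c("r1", "r2", "r3"))
  r1 <- aln[aln$read_id == "r1", ]
  expect_identical(list(r1$start, r1$end, r1$strand, r1$umi, r1$marker_flag),
                   list(100L, 120L, "+", "ACGTC", "READ_THROUGH"))
  r2 <- aln[aln$read_id == "r2", ]
  expect_identical(list(r2$start, r2$end, r2$strand, r2$marker_flag),
                   list(50L, 70L, "-", "REMAINING"))
  st <- assign_cdna_starts(aln)
  expect_identical(st$pos[st$read_id == "r2"], 69L)
  # MAPQ filtering
  expect_identical(sort(read_sam_alignments(sam, min_mapq = 10)$read_id),
                   c("r1", "r2"))
})

test_that("SAM metadata can come from XU/XB/XF tags", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@SQ\tSN:chrA\tLN:1000",
    paste("plain_read", 0, "chrA", 11, 30, "20M", "*", 0, 0,
          strrep("A", 20), strrep("I", 20),
          "XU:Z:ACGTC", "XB:Z:s1", "XF:Z:RT", sep = "\t")
  ), sam)
  aln <- read_sam_alignments(sam)
  expect_identical(aln$umi, "ACGTC")
  expect_identical(aln$sample, "s1")
  expect_identical(aln$marker_flag, "READ_THROUGH")
  # names without annotation and no tags fail loudly
  sam2 <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@SQ\tSN:chrA\tLN:1000",
    paste("plain_read", 0, "chrA", 11, 30, "20M", "*", 0, 0,
          strrep("A", 20), strrep("I", 20), sep = "\t")
  ), sam2)
  expect_error(read_sam_alignments(sam2), "annotation")
})

test_that("simulated reads map back to their true cDNA starts", {
  sim <- tiny_sim(seed = 21, n = 800)
  scheme <- barcode_scheme(sim$config$barcode_pattern, sim$config$sample_table)
  prep <- prepare_reads(sim$reads, scheme, marker_spec(sim$config$marker),
                        adapter = sim$config$adapter)
  m <- exact_map(prep, sim$refs)
  starts <- assign_cdna_starts(m)
  truth_start <- sim$truth$cdna_start_pos[molecule_of(starts$read_id)]
  expect_identical(starts$pos, truth_start)
  expect_true(all(starts$strand == "+"))
})
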