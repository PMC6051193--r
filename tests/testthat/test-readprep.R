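test_that("barcode extraction matches an index-by-index oracle", {
  scheme <- tiny_scheme() # NNNXXXXNN
  set.seed(41)
  seqs <- rand_dna(200, 30)
  reads <- tibble::tibble(read_id = paste0("r", 1:200), sequence = seqs,
                          quality = strrep("I", 30))
  bc <- extract_barcode(reads, scheme)
  pat <- strsplit(scheme$pattern, "")[[1]]
  for (i in sample(200, 25)) {
    chars <- strsplit(seqs[i], "")[[1]]
    expect_identical(bc$umi[i], paste(chars[seq_along(pat)][pat == "N"], collapse = ""))
    expect_identical(bc$expcode[i], paste(chars[seq_along(pat)][pat == "X"], collapse = ""))
    expect_identical(bc$sequence[i], substr(seqs[i], length(pat) + 1, 30))
  }
  # worked example: pattern NNNXXXXNN over ACGTTTTGGCAGTC...
  one <- extract_barcode(tibble::tibble(read_id = "x",
                                        sequence = "ACGTTTTGGCAGTCAAA",
                                        quality = strrep("I", 17)), scheme)
  expect_identical(one$umi, "ACGGG")
  expect_identical(one$expcode, "TTTT")
  expect_true(startsWith(one$sequence, "CAGTC"))
})

test_that("reads not longer than the pattern are flagged too short", {
  scheme <- tiny_scheme()
  reads <- tibble::tibble(read_id = c("a", "b"),
                          sequence = c("ACGTTTTGG", "ACGTTTTGGA"),
                          quality = c("IIIIIIIII", "IIIIIIIIII"))
  bc <- extract_barcode(reads, scheme)
  expect_identical(bc$too_short, c(TRUE, FALSE))
})

test_that("scheme validation rejects bad patterns and colliding barcodes", {
  expect_error(barcode_scheme(""), "non-empty")
  expect_error(barcode_scheme("NNAX"), "only contain")
  expect_error(barcode_scheme("NNXX", c(TT = "a", TTT = "b")), "length")
  expect_error(barcode_scheme("NNXXXX", c(TTTT = "a", TTTA = "b"),
                              max_barcode_mismatches = 1),
               "within max_barcode_mismatches")
  expect_s3_class(barcode_scheme("NNXXXX", c(TTTT = "a", TTTA = "b")),
                  "rtm_scheme")
})

test_that("demultiplex resolves by Hamming distance with brute-force agreement", {
  scheme <- barcode_scheme("XXXX", c(TTTT = "s1", AAAA = "s2"),
                           max_barcode_mismatches = 1)
  expect_identical(demultiplex("TTTT", scheme), "s1")
  expect_identical(demultiplex("TTTA", scheme), "s1")
  expect_identical(demultiplex("TTAA", scheme), "UNASSIGNED")
  strict <- barcode_scheme("XXXX", c(TTTT = "s1"))
  expect_identical(demultiplex("TTTA", strict), "UNASSIGNED")
  # brute force over random codes
  set.seed(42)
  codes <- rand_dna(300, 4)
  got <- demultiplex(codes, scheme)
  keys <- c(TTTT = "s1", AAAA = "s2")
  want <- vapply(codes, function(cd) {
    d <- vapply(names(keys), function(k) {
      sum(strsplit(cd, "")[[1]] != strsplit(k, "")[[1]])
    }, integer(1))
    ok <- d <= 1 & d == min(d) & sum(d == min(d)) == 1
    if (any(ok)) unname(keys[which(ok)[1]]) else "UNASSIGNED"
  }, character(1), USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("equidistant codes within tolerance go UNASSIGNED", {
  scheme <- barcode_scheme("XXXX", c(AAAA = "s1", AATT = "s2"),
                           max_barcode_mismatches = 1)
  # AATA is at distance 1 from both keys
  expect_identical(demultiplex("AATA", scheme), "UNASSIGNED")
})

test_that("marker classification strips the prefix and tolerates configured mismatches", {
  mk <- marker_spec() # CAGTCCGACGATC, mm = 0
  reads <- tibble::tibble(
    sequence = c(paste0("CAGTCCGACGATC", "GATTACA"),
                 paste0("GATTACA", "CAGTCCGACGATC"),
                 paste0("CAGTCCGACGATA", "GATTACA"),
                 "CAGTCCGACGATC"),
    quality = strrep("I", c(20, 20, 20, 13))
  )
  got <- classify_marker(reads, mk)
  expect_identical(got$marker_flag,
                   c("READ_THROUGH", "REMAINING", "REMAINING", "REMAINING"))
  expect_identical(got$sequence[1], "GATTACA")
  expect_identical(got$quality[1], "IIIIIII")
  expect_identical(got$sequence[2], reads$sequence[2]) # prefix-only matching
  # one mismatch at marker position 13, tolerated with mm = 1
  got1 <- classify_marker(reads, marker_spec(max_mismatches = 1))
  expect_identical(got1$marker_flag[3], "READ_THROUGH")
  expect_identical(got1$sequence[3], "GATTACA")
  # brute-force Hamming oracle over random prefixes
  set.seed(7)
  rnd <- tibble::tibble(sequence = paste0(rand_dna(500, 13), rand_dna(500, 10)),
                        quality = strrep("I", 23))
  for (mm in 0:2) {
    got <- classify_marker(rnd, marker_spec(max_mismatches = mm))$marker_flag
    want <- vapply(rnd$sequence, function(s) {
      d <- sum(strsplit(substr(s, 1, 13), "")[[1]] !=
                 strsplit("CAGTCCGACGATC", "")[[1]])
      if (d <= mm) "READ_THROUGH" else "REMAINING"
    }, character(1), USE.NAMES = FALSE)
    expect_identical(got, want)
  }
})

test_that("adapter trimming agrees with the all-offsets oracle", {
  adapter <- "AGATCGGAAGAGC"
  expect_identical(
    adapter_cut_index(paste0("GATTACA", adapter), adapter, 3, 0), 7L)
  expect_identical(adapter_cut_index("GATTACAGGG", adapter, 3, 0), 10L)
  expect_identical(
    adapter_cut_index(paste0("GATTACA", substr(adapter, 1, 4)), adapter, 3, 0),
    7L)
  set.seed(11)
  seqs <- c(rand_dna(400, 30),
            paste0(rand_dna(200, 12), adapter, rand_dna(200, 5)),
            paste0(rand_dna(200, 20), substr(adapter, 1, 6)))
  for (rate in c(0, 0.2)) {
    got <- adapter_cut_index(seqs, adapter, 3, rate)
    want <- vapply(seqs, oracle_trim, integer(1), adapter = adapter,
                   min_overlap = 3, rate = rate, USE.NAMES = FALSE)
    expect_identical(got, want)
  }
})

test_that("prepare_reads conserves counts and handles marker-only reads", {
  scheme <- tiny_scheme()
  mk <- marker_spec()
  adapter <- "AGATCGGAAGAGC"
  bc <- "ACGTTGTAA" # umi ACGAA, barcode TTGT -> s1
  reads <- tibble::tibble(
    read_id = paste0("r", 1:5),
    sequence = c(
      paste0(bc, mk$sequence, rand_dna(1, 30), adapter), # read-through
      paste0(bc, rand_dna(1, 25), adapter),              # remaining
      paste0(bc, mk$sequence),                           # marker-only
      paste0(bc, rand_dna(1, 5)),                        # too-short insert
      "ACGT"                                             # too short for barcode
    ),
    quality = NA_character_
  )
  reads$quality <- strrep("I", nchar(reads$sequence))
  prep <- prepare_reads(reads, scheme, mk, adapter = adapter)
  s <- prep$stats
  expect_identical(s$n_input, 5L)
  expect_identical(s$n_input, s$n_emitted + sum(s$discards$n))
  expect_identical(s$discards$n[s$discards$reason == "TOO_SHORT_BARCODE"], 1L)
  # marker-only read is dropped as a short insert, not emitted as empty RT
  expect_identical(s$discards$n[s$discards$reason == "TOO_SHORT_INSERT"], 2L)
  expect_identical(nrow(prep$reads), 2L)
  expect_identical(prep$reads$marker_flag, c("READ_THROUGH", "REMAINING"))
  expect_identical(prep$reads$sample, c("s1", "s1"))
  expect_identical(prep$reads$umi, c("ACGAA", "ACGAA"))
  expect_false(any(startsWith(prep$reads$insert, mk$sequence) &
                     prep$reads$marker_flag == "READ_THROUGH"))
  g <- glance(prep)
  expect_identical(g$n_emitted, 2L)
  expect_equal(g$frac_read_through, 0.5)
})

test_that("marker stripping and adapter trimming commute on library-shaped reads", {
  sim <- tiny_sim(seed = 5, n = 400)
  scheme <- barcode_scheme(sim$config$barcode_pattern, sim$config$sample_table)
  mk <- marker_spec(sim$config$marker)
  bc <- extract_barcode(sim$reads, scheme)
  bc <- bc[!bc$too_short, ]
  a <- trim_adapter(classify_marker(bc, mk), sim$config$adapter)
  b <- classify_marker(trim_adapter(bc, sim$config$adapter), mk)
  keep_a <- nchar(a$sequence) >= 15
  keep_b <- nchar(b$sequence) >= 15
  expect_identical(keep_a, keep_b)
  expect_identical(a$marker_flag[keep_a], b$marker_flag[keep_b])
  expect_identical(a$sequence[keep_a], b$sequence[keep_b])
})

test_that("marker classification equals truth on error-free simulated reads", {
  sim <- tiny_sim(seed = 9, n = 1500)
  scheme <- barcode_scheme(sim$config$barcode_pattern, sim$config$sample_table)
  prep <- prepare_reads(sim$reads, scheme, marker_spec(sim$config$marker),
                        adapter = sim$config$adapter)
  truth_marker <- sim$truth$marker_present[molecule_of(prep$reads$read_id)]
  expect_identical(prep$reads$marker_flag == "READ_THROUGH", truth_marker)
})
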