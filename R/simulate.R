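#' Simulator configuration
#'
#' Parameters of the generative model of a read-through-marking iCLIP library.
#' The model follows the library-preparation cascade: UV crosslink placement
#' with a uridine preference (`w_U`, weight multiplier at T positions in DNA
#' coordinates), RNase I cleavage upstream of the crosslink with an adenosine
#' preference at the retained 5' nucleotide (`w_A`), reverse transcription
#' that truncates at the crosslink with probability `p_trunc` (else reads
#' through to the cleavage site), 5'-marker ligation succeeding with
#' efficiency `epsilon` (only read-through cDNAs can carry the marker into
#' the read), a barcode/UMI prefix on every read, and geometric PCR
#' duplication.
#'
#' @param seed Integer seed; identical configs give byte-identical output.
#' @param n_refs,ref_length Number and length of reference sequences.
#' @param base_probs Length-4 numeric (A, C, G, T), summing to 1.
#' @param n_molecules Number of cDNA molecules before PCR.
#' @param w_U Crosslink weight multiplier at T positions (>= 1).
#' @param w_A Cleavage weight multiplier when the retained 5' base is A (>= 1).
#' @param frag_len_min,frag_len_max Uniform bounds of the 5' extent: the
#'   cleavage site lies this many nucleotides upstream of the crosslink.
#' @param downstream_min,downstream_max Uniform bounds of the 3' extent of the
#'   fragment beyond the crosslink.
#' @param p_trunc Probability reverse transcription truncates at the
#'   crosslink.
#' @param epsilon 5'-marker ligation efficiency.
#' @param pcr_geom_p Geometric parameter of the PCR copy number (support
#'   >= 1); 1 means no duplication.
#' @param barcode_pattern Barcode layout over `{N, X}`, see
#'   [barcode_scheme()].
#' @param sample_table Named character vector barcode -> sample.
#' @param read_length Sequenced read length; reads are truncated to it.
#' @param seq_error_rate Per-base substitution error rate applied per PCR
#'   copy.
#' @param truncation_offset Offset of the truncated cDNA's first nucleotide
#'   relative to the crosslink (default 0: the cDNA starts on the crosslinked
#'   nucleotide itself, putting the crosslink at logo position +1; 1 gives the
#'   crosslink-at-position--1 convention).
#' @param adapter 3'-adapter appended after the insert.
#' @param marker 5'-marker DNA sequence.
#' @return An object of class `rtm_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_refs = 2L,
                       ref_length = 50000L,
                       base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       n_molecules = 10000L,
                       w_U = 8,
                       w_A = 8,
                       frag_len_min = 20L,
                       frag_len_max = 40L,
                       downstream_min = 19L,
                       downstream_max = 35L,
                       p_trunc = 0.9,
                       epsilon = 0.5,
                       pcr_geom_p = 0.5,
                       barcode_pattern = "NNNXXXXNN",
                       sample_table = c(TTGT = "sample1"),
                       read_length = 100L,
                       seq_error_rate = 0,
                       truncation_offset = 0L,
                       adapter = "AGATCGGAAGAGC",
                       marker = "CAGTCCGACGATC") {
  cfg <- list(
    seed = as.integer(seed), n_refs = as.integer(n_refs),
    ref_length = as.integer(ref_length),
    base_probs = unname(base_probs), n_molecules = as.integer(n_molecules),
    w_U = w_U, w_A = w_A,
    frag_len_min = as.integer(frag_len_min),
    frag_len_max = as.integer(frag_len_max),
    downstream_min = as.integer(downstream_min),
    downstream_max = as.integer(downstream_max),
    p_trunc = p_trunc, epsilon = epsilon, pcr_geom_p = pcr_geom_p,
    barcode_pattern = barcode_pattern,
    sample_table = unlist(sample_table),
    read_length = as.integer(read_length),
    seq_error_rate = seq_error_rate,
    truncation_offset = as.integer(truncation_offset),
    adapter = toupper(adapter), marker = toupper(marker)
  )
  stopifnot(
    cfg$n_refs >= 1, cfg$ref_length >= 1, cfg$n_molecules >= 0,
    length(cfg$base_probs) == 4, all(cfg$base_probs >= 0),
    abs(sum(cfg$base_probs) - 1) < 1e-8,
    cfg$w_U >= 1, cfg$w_A >= 1,
    cfg$frag_len_min >= 1, cfg$frag_len_max >= cfg$frag_len_min,
    cfg$downstream_min >= 1, cfg$downstream_max >= cfg$downstream_min,
    cfg$p_trunc >= 0, cfg$p_trunc <= 1,
    cfg$epsilon >= 0, cfg$epsilon <= 1,
    cfg$pcr_geom_p > 0, cfg$pcr_geom_p <= 1,
    cfg$seq_error_rate >= 0, cfg$seq_error_rate < 1,
    cfg$truncation_offset %in% c(0L, 1L)
  )
  # the barcode scheme must validate, and reads must reach into the insert
  scheme <- barcode_scheme(cfg$barcode_pattern, cfg$sample_table)
  if (cfg$read_length <= nchar(cfg$barcode_pattern) + nchar(cfg$marker)) {
    stop("read_length must exceed barcode + marker length", call. = FALSE)
  }
  if (cfg$frag_len_max + cfg$downstream_max + 1L > cfg$ref_length) {
    stop("infeasible config: no eligible crosslink positions ",
         "(frag_len_max + downstream_max + 1 > ref_length)", call. = FALSE)
  }
  cfg$scheme <- scheme
  structure(cfg, class = "rtm_sim_config")
}

#' @export
print.rtm_sim_config <- function(x, ...) {
  cat(sprintf(paste0("<rtm_sim_config> seed %d: %d x %d nt refs, %d molecules, ",
                     "w_U %s, w_A %s, p_trunc %s, epsilon %s\n"),
              x$seed, x$n_refs, x$ref_length, x$n_molecules,
              format(x$w_U), format(x$w_A), format(x$p_trunc),
              format(x$epsilon)))
  invisible(x)
}

.sim_refs <- function(cfg) {
  seqs <- random_dna(cfg$n_refs, cfg$ref_length, cfg$base_probs)
  reference_set(setNames(seqs, sprintf("ref%02d", seq_len(cfg$n_refs))),
                mode = "genome")
}

#' Simulate reference sequences
#'
#' `n_refs` i.i.d. sequences of `ref_length` drawn from `base_probs`;
#' reproducible from `cfg$seed`.
#'
#' @param cfg An [sim_config()].
#' @return An [reference_set()] in genome mode.
#' @export
simulate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "rtm_sim_config"))
  withr::with_seed(cfg$seed, .sim_refs(cfg))
}

# 0-based eligible crosslink positions: the whole fragment (5' extent up to
# frag_len_max, 3' extent up to downstream_max) must fit in the reference.
eligible_range <- function(cfg, ref_len) {
  lo <- cfg$frag_len_max
  hi <- ref_len - 1L - cfg$downstream_max
  if (hi < lo) stop("infeasible config: no eligible crosslink positions",
                    call. = FALSE)
  c(lo, hi)
}

#' Place crosslinks with a uridine preference
#'
#' Samples `n` crosslink positions on one reference, weighting T positions
#' (the DNA proxy of uridine) by `w_U` and all others by 1, over the eligible
#' region that keeps the whole fragment inside the reference.
#'
#' @param ref_seq A single reference sequence (string).
#' @param cfg An [sim_config()].
#' @param n Number of positions to draw.
#' @return Integer vector of 0-based positions.
#' @export
place_crosslinks <- function(ref_seq, cfg, n) {
  rng <- eligible_range(cfg, stringi::stri_length(ref_seq))
  pos0 <- rng[1]:rng[2]
  base <- stringi::stri_sub(ref_seq, pos0 + 1L, length = 1L)
  wt <- ifelse(base == "T", cfg$w_U, 1)
  if (n == 0L) return(integer(0))
  pos0[sample.int(length(pos0), n, replace = TRUE, prob = wt)]
}

#' Choose RNase cleavage sites with an adenosine preference
#'
#' For each crosslink, the cleavage site (the fragment's 5' end, and therefore
#' the first nucleotide of any read-through cDNA) is drawn from the positions
#' `crosslink - frag_len_max ... crosslink - frag_len_min`, weighting
#' candidates whose retained base is A by `w_A`. Sampling uses the Gumbel-max
#' trick so all molecules are drawn in one vectorised pass.
#'
#' @param ref_seq A single reference sequence (string).
#' @param crosslink_pos Integer vector of 0-based crosslink positions.
#' @param cfg An [sim_config()].
#' @return Integer vector of 0-based cleavage positions, one per crosslink.
#' @export
choose_cleavages <- function(ref_seq, crosslink_pos, cfg) {
  n <- length(crosslink_pos)
  if (n == 0L) return(integer(0))
  offs <- seq(cfg$frag_len_max, cfg$frag_len_min)
  k <- length(offs)
  cand <- outer(crosslink_pos, offs, "-")
  if (any(cand < 0)) stop("cleavage candidates run off the reference",
                          call. = FALSE)
  base <- stringi::stri_sub(ref_seq, as.vector(cand) + 1L, length = 1L)
  wt <- ifelse(base == "A", cfg$w_A, 1)
  gumbel <- -log(-log(runif(n * k)))
  score <- matrix(log(wt) + gumbel, nrow = n, ncol = k)
  j <- max.col(score, ties.method = "first")
  cand[cbind(seq_len(n), j)]
}

# per-base substitution errors, applied per read
mutate_sequences <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- stringi::stri_length(seqs)
  n_err <- stats::rbinom(length(seqs), lens, rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) {
      old <- stringi::stri_sub(seqs[i], p, p)
      stringi::stri_sub(seqs[i], p, p) <- sample(setdiff(DNA_BASES, old), 1)
    }
  }
  seqs
}

#' Simulate a read-through-marking iCLIP library
#'
#' Draws references and per-molecule ground truth, then assembles reads as
#' `barcode (UMI + sample barcode) + [marker if ligated and read-through] +
#' insert + adapter`, truncated to `read_length`, with geometric PCR copies
#' and optional per-copy substitution errors. Truncated cDNAs never carry the
#' marker; read-through cDNAs carry it with probability `epsilon`.
#'
#' @param cfg An [sim_config()].
#' @return An object of class `rtm_sim`: list with `reads` (tibble `read_id`,
#'   `sequence`, `quality`; ids are `mol<id>/<copy>`), `truth` (one row per
#'   molecule: `molecule_id`, `ref_name`, `crosslink_pos`, `cleavage_pos`,
#'   `cdna_start_pos`, `class`, `marker_present`, `umi`, `sample`,
#'   `n_copies`), `refs` (an [reference_set()]) and `config`.
#' @export
simulate_library <- function(cfg) {
  stopifnot(inherits(cfg, "rtm_sim_config"))
  withr::with_seed(cfg$seed, {
    refs <- .sim_refs(cfg)
    n <- cfg$n_molecules
    ref_idx <- if (n > 0) sample.int(cfg$n_refs, n, replace = TRUE) else integer(0)
    crosslink <- integer(n)
    for (r in seq_len(cfg$n_refs)) {
      sel <- which(ref_idx == r)
      crosslink[sel] <- place_crosslinks(refs$seq[[r]], cfg, length(sel))
    }
    cleavage <- integer(n)
    for (r in seq_len(cfg$n_refs)) {
      sel <- which(ref_idx == r)
      cleavage[sel] <- choose_cleavages(refs$seq[[r]], crosslink[sel], cfg)
    }
    downstream <- if (cfg$downstream_max > cfg$downstream_min) {
      sample(cfg$downstream_min:cfg$downstream_max, n, replace = TRUE)
    } else {
      rep(cfg$downstream_min, n)
    }
    truncated <- runif(n) < cfg$p_trunc
    marker_present <- !truncated & (runif(n) < cfg$epsilon)
    cdna_start <- ifelse(truncated, crosslink + cfg$truncation_offset, cleavage)
    frag_end <- crosslink + downstream # 0-based inclusive
    ref_names <- names(refs)[ref_idx]
    insert <- ref_slice(refs, ref_names, cdna_start, frag_end + 1L)
    umi <- random_dna(n, length(cfg$scheme$n_pos))
    keys <- names(cfg$scheme$sample_table)
    key_idx <- if (length(keys) > 1) sample.int(length(keys), n, replace = TRUE) else
      rep(1L, n)
    barcode <- build_barcodes(cfg$scheme, umi, keys[key_idx])
    read_seq <- stringi::stri_sub(
      paste0(barcode, ifelse(marker_present, cfg$marker, ""), insert,
             cfg$adapter),
      1L, cfg$read_length
    )
    n_copies <- rgeom(n, cfg$pcr_geom_p) + 1L
    truth <- tibble::tibble(
      molecule_id = seq_len(n),
      ref_name = ref_names,
      crosslink_pos = as.integer(crosslink),
      cleavage_pos = as.integer(cleavage),
      cdna_start_pos = as.integer(cdna_start),
      class = ifelse(truncated, "TRUNCATED", FLAG_RT),
      marker_present = marker_present,
      umi = umi,
      sample = unname(cfg$scheme$sample_table[key_idx]),
      n_copies = n_copies
    )
    rep_idx <- rep(seq_len(n), n_copies)
    copy_no <- sequence(n_copies)
    seqs <- mutate_sequences(read_seq[rep_idx], cfg$seq_error_rate)
    reads <- tibble::tibble(
      read_id = sprintf("mol%07d/%d", rep_idx, copy_no),
      sequence = seqs,
      quality = strrep("I", stringi::stri_length(seqs))
    )
    structure(list(reads = reads, truth = truth, refs = refs, config = cfg),
              class = "rtm_sim")
  })
}

# fill N positions with UMI bases and X positions with the sample barcode
build_barcodes <- function(scheme, umi, expcode) {
  plen <- nchar(scheme$pattern)
  n <- length(umi)
  if (n == 0L) return(character(0))
  m <- matrix("", nrow = n, ncol = plen)
  for (j in seq_along(scheme$n_pos)) {
    m[, scheme$n_pos[j]] <- stringi::stri_sub(umi, j, j)
  }
  for (j in seq_along(scheme$x_pos)) {
    m[, scheme$x_pos[j]] <- stringi::stri_sub(expcode, j, j)
  }
  do.call(paste0, asplit(m, 2))
}

#' @export
print.rtm_sim <- function(x, ...) {
  cat(sprintf("<rtm_sim> %d molecules -> %d reads on %d reference(s)\n",
              nrow(x$truth), nrow(x$reads), length(x$refs)))
  invisible(x)
}

#' @export
tidy.rtm_sim <- function(x, ...) x$truth

#' @export
glance.rtm_sim <- function(x, ...) {
  tibble::tibble(
    n_molecules = nrow(x$truth),
    n_reads = nrow(x$reads),
    frac_read_through = mean(x$truth$class == FLAG_RT),
    frac_marker = mean(x$truth$marker_present)
  )
}

#' Write a simulated library to disk
#'
#' Emits `reads.fastq.gz`, `refs.fa`, `truth.tsv` and the configuration as
#' `sim_config.json` into `dir`.
#'
#' @param sim An `rtm_sim` from [simulate_library()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "rtm_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(sim$reads, file.path(dir, "reads.fastq.gz"))
  write_reference_fasta(sim$refs, file.path(dir, "refs.fa"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  cfg <- unclass(sim$config)
  cfg$scheme <- NULL
  jsonlite::write_json(cfg, file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
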