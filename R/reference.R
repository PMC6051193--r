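#' Reference sequence set
#'
#' A small ordered container of named uppercase DNA sequences with a mapping
#' mode. In `"genome"` mode alignments may fall on either strand; in
#' `"transcriptome"` mode only the sense strand is searched, mirroring
#' mapping against a set of mRNA sequences.
#'
#' @param sequences Named character vector of uppercase DNA sequences.
#' @param mode `"genome"` or `"transcriptome"`.
#' @return An object of class `rtm_refs`.
#' @export
#' @examples
#' refs <- reference_set(c(chrA = "ACGTACGTAC"), mode = "genome")
#' ref_slice(refs, "chrA", -3, 2)
reference_set <- function(sequences, mode = c("genome", "transcriptome")) {
  mode <- match.arg(mode)
  if (length(sequences) == 0) stop("reference set is empty", call. = FALSE)
  nm <- names(sequences)
  if (is.null(nm) || any(nm == "") || anyNA(nm)) {
    stop("all reference sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(nm)) stop("duplicate reference names", call. = FALSE)
  sequences <- toupper(as.character(sequences))
  if (any(sequences == "")) stop("empty reference sequence", call. = FALSE)
  if (!all(is_dna(sequences))) {
    stop("reference sequences must be over A/C/G/T/N", call. = FALSE)
  }
  structure(list(seq = setNames(sequences, nm), mode = mode),
            class = "rtm_refs")
}

#' @export
length.rtm_refs <- function(x) length(x$seq)

#' @export
names.rtm_refs <- function(x) names(x$seq)

#' @export
print.rtm_refs <- function(x, ...) {
  cat(sprintf("<rtm_refs> %d sequence(s), mode = %s\n", length(x), x$mode))
  info <- sprintf("  %s (%d nt)", names(x), stringi::stri_length(x$seq))
  cat(paste(head(info, 6), collapse = "\n"), "\n")
  invisible(x)
}

#' Read a reference FASTA file
#'
#' @param path FASTA file (plain or gzipped).
#' @param mode Mapping mode, see [reference_set()].
#' @return An `rtm_refs` object, record order preserved.
#' @export
read_reference_fasta <- function(path, mode = c("genome", "transcriptome")) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("no FASTA records in ", path, call. = FALSE)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("duplicate sequence names in ", path, call. = FALSE)
  }
  reference_set(setNames(as.character(ss), nm), mode = match.arg(mode))
}

#' Write a reference set to FASTA
#'
#' @param refs An `rtm_refs` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refs, path) {
  stopifnot(inherits(refs, "rtm_refs"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(refs$seq), path)
  invisible(path)
}

#' Slice a reference with N padding
#'
#' Extracts `[start, end)` (0-based, half-open) from a reference sequence.
#' Positions outside `[0, length)` yield `N` rather than an error, so windows
#' around start sites near sequence ends keep their width.
#'
#' @param refs An `rtm_refs` object.
#' @param ref_name Character vector of reference names (recycled with
#'   `start`/`end`).
#' @param start,end Integer vectors, 0-based half-open coordinates.
#' @return Character vector of slices, each of length `end - start`.
#' @export
ref_slice <- function(refs, ref_name, start, end) {
  stopifnot(inherits(refs, "rtm_refs"))
  n <- max(length(ref_name), length(start), length(end))
  ref_name <- rep_len(ref_name, n)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  unknown <- !(ref_name %in% names(refs))
  if (any(unknown)) {
    stop("unknown reference name(s): ",
         paste(unique(ref_name[unknown]), collapse = ", "), call. = FALSE)
  }
  if (any(end < start)) stop("end < start in ref_slice", call. = FALSE)
  seqs <- unname(refs$seq[ref_name])
  len <- stringi::stri_length(seqs)
  left <- pmax(0L, pmin(end, 0L) - start)
  right <- pmax(0L, end - pmax(start, len))
  from <- pmax(start, 0L) + 1L
  to <- pmin(end, len)
  core <- ifelse(to >= from, stringi::stri_sub(seqs, from, to), "")
  paste0(strrep("N", left), core, strrep("N", right))
}
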