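# In-silico reproduction of the computable parts of the rDNA ITS clone
# discrimination assay: primer handling, GC-clamp construction, amplicon
# prediction and pairwise sequence divergence. Coordinates are 1-based
# inclusive throughout (the R/Bioconductor convention); an amplicon of length
# L therefore satisfies end - start + 1 = L and spans both primer footprints.

IUPAC_CODES <- names(Biostrings::IUPAC_CODE_MAP)

clean_seq <- function(seq, what = "seq") {
  s <- toupper(gsub("[[:space:]]", "", seq))
  bad <- setdiff(unique(strsplit(s, "")[[1]]), IUPAC_CODES)
  if (length(bad) > 0) {
    abort(sprintf("`%s` contains non-IUPAC character(s): %s.",
                  what, paste(bad, collapse = ", ")),
          class = "chemocomp_parse_error")
  }
  if (nchar(s) == 0) {
    abort(sprintf("`%s` is empty.", what), class = "chemocomp_domain_error")
  }
  s
}

#' Reverse complement of a nucleotide sequence
#'
#' Handles the full IUPAC ambiguity alphabet; whitespace is stripped and the
#' result is upper case. An involution: applying it twice returns the input.
#'
#' @param seq A nucleotide string (IUPAC codes, whitespace allowed).
#' @return The reverse complement as a character string.
#' @examples
#' reverse_complement("GATC CGGT") # "ACCGGATC"
#' @export
reverse_complement <- function(seq) {
  s <- clean_seq(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Locate primer binding sites on a template
#'
#' Finds matches of the primer on the forward strand and of its reverse
#' complement on the template (reverse-strand sites), allowing up to
#' `max_mismatches` mismatches. IUPAC ambiguity codes in the primer match any
#' of their expansions; template letters are taken literally (an `N` in the
#' template is not a wildcard), appropriate for primers designed on known
#' templates.
#'
#' @param template Template sequence (string).
#' @param primer Primer sequence, 5'->3' as synthesised.
#' @param max_mismatches Maximum mismatches allowed; default 0 (exact).
#' @return A tibble with `start`, `end` (1-based inclusive template
#'   coordinates of the footprint) and `strand` (`"+"` or `"-"`); zero rows
#'   when there is no site or the primer is longer than the template.
#' @export
find_primer_sites <- function(template, primer, max_mismatches = 0) {
  tpl <- clean_seq(template, "template")
  prm <- clean_seq(primer, "primer")
  if (nchar(prm) > nchar(tpl)) {
    return(tibble(start = integer(), end = integer(), strand = character()))
  }
  subject <- Biostrings::DNAString(tpl)
  hits_for <- function(pat, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                  max.mismatch = max_mismatches,
                                  fixed = "subject")
    tibble(start = Biostrings::start(m), end = Biostrings::end(m),
           strand = rep(strand, length(m)))
  }
  bind_rows(
    hits_for(prm, "+"),
    hits_for(reverse_complement(prm), "-")
  ) %>% arrange(.data$start)
}

#' Predict PCR amplicons in silico
#'
#' For every forward-primer site on the plus strand lying upstream of a
#' reverse-primer site on the minus strand, within `max_len`, emits the
#' amplicon spanning both primer footprints inclusive (the length convention
#' under which Sanger-verified product sizes are reported).
#'
#' @param templates A named character vector of template sequences (or a
#'   single unnamed string).
#' @param forward,reverse Primer sequences, 5'->3' as synthesised.
#' @param max_len Maximum product length in bp; default 5000.
#' @param max_mismatches Mismatches allowed per primer site; default 0.
#' @return A tibble with `template_id`, `start`, `end` (1-based inclusive),
#'   `length_bp` and `sequence`; zero rows when no product forms.
#' @examples
#' tpl <- paste0("GATCCGGTGAACCTTCTGGAC", strrep("A", 100),
#'               reverse_complement("CGGCGCTTTATCCTATTTTGGC"))
#' in_silico_pcr(tpl, "GATCCGGTGAACCTTCTGGAC", "CGGCGCTTTATCCTATTTTGGC")
#' @export
in_silico_pcr <- function(templates, forward, reverse, max_len = 5000,
                          max_mismatches = 0) {
  if (is.null(names(templates))) {
    names(templates) <- if (length(templates) == 1) "template" else
      paste0("template_", seq_along(templates))
  }
  fwd <- clean_seq(forward, "forward")
  rev <- clean_seq(reverse, "reverse")
  min_len <- nchar(fwd) + nchar(rev)
  purrr::imap_dfr(templates, function(tpl, id) {
    tpl <- clean_seq(tpl, "template")
    f_sites <- find_primer_sites(tpl, fwd, max_mismatches) %>%
      filter(.data$strand == "+")
    r_sites <- find_primer_sites(tpl, rev, max_mismatches) %>%
      filter(.data$strand == "-")
    empty <- tibble(template_id = character(), start = integer(),
                    end = integer(), length_bp = integer(),
                    sequence = character())
    if (nrow(f_sites) == 0 || nrow(r_sites) == 0) return(empty)
    cand <- tidyr::expand_grid(fs = f_sites$start, re = r_sites$end) %>%
      mutate(length_bp = .data$re - .data$fs + 1L) %>%
      filter(.data$length_bp >= min_len, .data$length_bp <= max_len)
    if (nrow(cand) == 0) return(empty)
    transmute(
      cand,
      template_id = id,
      start = .data$fs, end = .data$re, length_bp = .data$length_bp,
      sequence = substring(tpl, .data$fs, .data$re)
    )
  })
}

#' The 40-nt GC clamp used for DGGE-compatible primers
#'
#' @return The clamp sequence (40 nt).
#' @export
gc_clamp_40 <- function() {
  "CGCCCGCCGCGCCCCGCGCCCGTCCCGCCGCCCCCGCCCG"
}

#' Attach a GC clamp to a primer's 5' end
#'
#' DGGE separates same-length products by melting behaviour; a GC-rich 5'
#' extension keeps the duplex partially annealed in the gradient. This is a
#' plain concatenation `clamp + primer`.
#'
#' @param primer Primer sequence.
#' @param clamp Clamp sequence; default the standard 40-nt clamp
#'   ([gc_clamp_40()]). May be empty (`""`), giving the identity.
#' @return The clamped primer.
#' @export
attach_gc_clamp <- function(primer, clamp = gc_clamp_40()) {
  prm <- clean_seq(primer, "primer")
  clp <- if (nchar(gsub("[[:space:]]", "", clamp)) == 0) "" else clean_seq(clamp, "clamp")
  paste0(clp, prm)
}

#' Pairwise divergence of two sequences
#'
#' Global (Needleman-Wunsch) alignment with the given scores, then the
#' p-distance over aligned columns, excluding columns containing a gap in
#' either sequence. Symmetric; 0 iff the sequences are identical.
#'
#' @param seq_a,seq_b Nucleotide strings; non-empty.
#' @param match,mismatch Alignment match/mismatch scores; defaults +1 / -1.
#' @param gap Per-position gap penalty; default -2 (linear gap cost).
#' @return Fraction of differing sites among gap-free aligned columns.
#' @export
pairwise_divergence <- function(seq_a, seq_b, match = 1, mismatch = -1, gap = -2) {
  a <- clean_seq(seq_a, "seq_a")
  b <- clean_seq(seq_b, "seq_b")
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = sub, gapOpening = 0, gapExtension = abs(gap))
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  keep <- pa != "-" & pb != "-"
  if (!any(keep)) return(NA_real_)
  mean(pa[keep] != pb[keep])
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width; default 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  x <- Biostrings::DNAStringSet(vapply(seqs, clean_seq, character(1)))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Bundled marker primers
#'
#' The primer set of the clone-discrimination assay: the ITS F/R pair
#' amplifying the ~2.8 kb 18S-ITS1-5.8S-ITS2-partial-28S fragment, the
#' DGGE-scale 3770F/2104R pair targeting the conserved regions flanking the
#' hypervariable ITS regions, and 3770F with the 40-nt GC clamp attached.
#'
#' @return A tibble with `name` and `sequence` (5'->3' as synthesised).
#' @export
default_primers <- function() {
  path <- system.file("extdata", "marker_primers.fasta", package = "chemocomp",
                      mustWork = TRUE)
  seqs <- read_fasta(path)
  tibble(name = names(seqs), sequence = unname(seqs))
}
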