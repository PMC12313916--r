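# Packaged study fixtures: the canonical EGFP coding sequence, the
# stop-codon mutant derived from it, and the printed oligos of the assay.

#' Built-in EGFP fixtures
#'
#' Returns the canonical 720-nt EGFP coding sequence, the premature-stop
#' mutant derived from it by the CBE installation edit, and the table of
#' printed assay oligos (guide spacers as synthesized RNA, normalized to
#' DNA; ddPCR primers and probe).
#'
#' The mutant is not stored: it is constructed at call time by locating the
#' installation spacer on the WT CDS and applying C->T at spacer position
#' \code{install_target_position}. The edited CDS coordinate and codon
#' index are reported alongside, in both coding-strand (c.241C>T) and
#' antisense (G>A) representations, since the substitution is a G>A change
#' when numbered on the opposite strand.
#'
#' @return List with elements \code{wt_cds}, \code{q81x_cds} (character
#'   sequences), \code{oligos} (data.frame: name, sequence as DNA, role,
#'   orientation_note), \code{install_spacer},
#'   \code{install_target_position} (5), \code{edit_cds_position} (1-based
#'   coding-strand coordinate), \code{stop_codon_index}, and
#'   \code{edit_label} (both strand representations).
#' @examples
#' fx <- egfp_fixtures()
#' substr(fx$q81x_cds, fx$edit_cds_position, fx$edit_cds_position)
#' @export
egfp_fixtures <- function() {
  fa <- system.file("extdata", "egfp_wt_cds.fa", package = "stopswitch")
  wt <- unname(read_fasta(fa)[1])
  oligos <- utils::read.delim(
    system.file("extdata", "printed_oligos.tsv", package = "stopswitch"),
    stringsAsFactors = FALSE)
  oligos$sequence <- vapply(oligos$sequence, dna, "", USE.NAMES = FALSE)

  install_spacer <- oligos$sequence[oligos$name == "install_spacer"]
  target_pos <- 5L
  loc <- .locate_unique(install_spacer, wt)
  edit_pos <- loc + target_pos - 1L  # 1-based CDS coordinate
  mut <- apply_edit(wt, edit_pos, "C", "T", "+")
  codon_index <- (edit_pos - 1L) %/% 3L + 1L

  list(
    wt_cds = wt,
    q81x_cds = mut,
    oligos = oligos,
    install_spacer = install_spacer,
    install_target_position = target_pos,
    edit_cds_position = edit_pos,
    stop_codon_index = codon_index,
    edit_label = sprintf("c.%dC>T (coding strand) / c.G%dA (antisense numbering)",
                         edit_pos, edit_pos)
  )
}

# 1-based start of the unique occurrence of `pattern` in `subject`.
.locate_unique <- function(pattern, subject) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                Biostrings::DNAString(subject))
  if (length(m) != 1L)
    stop("pattern ", pattern, " occurs ", length(m),
         " times in subject; expected exactly one")
  Biostrings::start(m)[1]
}

#' Count occurrences of an oligo on either strand
#'
#' @param oligo Oligo sequence (RNA accepted).
#' @param subject Subject sequence.
#' @return Integer: occurrences of the oligo or its reverse complement.
#' @export
count_oligo_hits <- function(oligo, subject) {
  o <- dna(oligo); s <- Biostrings::DNAString(dna(subject))
  length(Biostrings::matchPattern(Biostrings::DNAString(o), s)) +
    length(Biostrings::matchPattern(Biostrings::DNAString(revcomp(o)), s))
}
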