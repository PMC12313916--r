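#' @keywords internal
#' @useDynLib stopswitch, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Coordinate conventions used throughout:
#  - protospacer positions are 1-based from the PAM-distal (5') end of the
#    spacer, so "A7" means the adenine at spacer position 7;
#  - positions on an input sequence's plus strand are 0-based half-open
#    where a field is named *_start (so they round-trip with protospacer
#    positions without off-by-one ambiguity), and 1-based where a field or
#    argument is a CDS coordinate (cds_position, apply_edit()).

#' Normalize a nucleotide sequence
#'
#' Uppercases, converts RNA U to DNA T, and validates that only A, C, G, T
#' and N remain. All package functions accept sequences that have passed
#' through this normalization; they call it on ingest themselves.
#'
#' @param x Character scalar, the sequence.
#' @return Character scalar over \code{{A,C,G,T,N}}.
#' @examples
#' dna("gaagcagcacgacuucuuca")
#' @export
dna <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("sequence must be a single character string")
  s <- chartr("u", "t", toupper(x))
  s <- chartr("U", "T", s)
  bad <- gsub("[ACGTN]", "", s)
  if (nzchar(bad))
    stop("non-nucleotide characters in sequence: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  s
}

#' Reverse complement
#'
#' @param seq Sequence (character scalar; U accepted and normalized to T).
#' @return Reverse-complemented sequence. N maps to N.
#' @examples
#' revcomp("GAAGCAGCACGACTTCTTCA")
#' @export
revcomp <- function(seq) {
  s <- dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.complement_base <- function(b) {
  chartr("ACGTN", "TGCAN", b)
}

#' Translate a coding sequence
#'
#' Standard genetic code; stop codons render as \code{"*"}; codons
#' containing N render as \code{"X"}.
#'
#' @param cds Coding sequence, length divisible by 3.
#' @return Protein string, one letter per codon.
#' @examples
#' translate_cds("ATGTAA")
#' @export
translate_cds <- function(cds) {
  s <- dna(cds)
  if (nchar(s) %% 3L != 0L)
    stop("CDS length (", nchar(s), ") is not divisible by 3")
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "X"))
}

# IUPAC code -> base set. Implemented directly (not via fixed=FALSE pattern
# matching) because an N in the *candidate window* must be treated as
# non-matching, a conservative rule stricter than set intersection.
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Match a degenerate IUPAC pattern against a sequence window
#'
#' Position-wise set membership: the window matches iff each of its bases
#' belongs to the set encoded by the pattern symbol at that position. An N
#' in the window never matches (conservatively treated as unknown, not
#' wildcard).
#'
#' @param pattern IUPAC pattern, e.g. \code{"NGG"}, \code{"NNGRRT"}.
#' @param window Concrete sequence of the same length.
#' @return Logical scalar.
#' @examples
#' iupac_match("NNGRRT", "CGGGGT")
#' @export
iupac_match <- function(pattern, window) {
  p <- toupper(pattern)
  w <- dna(window)
  if (nchar(p) != nchar(w))
    stop("pattern and window lengths differ (", nchar(p), " vs ", nchar(w), ")")
  pc <- strsplit(p, "")[[1]]
  wc <- strsplit(w, "")[[1]]
  if (!all(pc %in% names(.IUPAC_SETS)))
    stop("invalid IUPAC symbol in pattern: ", pattern)
  for (i in seq_along(pc)) {
    if (wc[i] == "N") return(FALSE)
    if (!(wc[i] %in% .IUPAC_SETS[[pc[i]]])) return(FALSE)
  }
  TRUE
}

#' Construct an editor profile
#'
#' Describes one base-editor/Cas-orthologue combination: which base it
#' converts, where in the protospacer it acts, and which PAM the Cas domain
#' requires immediately 3' of the protospacer on the protospacer strand.
#'
#' @param name Label.
#' @param base_from,base_to Single bases (C/T for CBEs, A/G for ABEs).
#' @param window_start,window_end Editing window, 1-based inclusive
#'   protospacer positions counted from the PAM-distal end.
#' @param pam IUPAC PAM pattern.
#' @param spacer_length Spacer length in nt.
#' @param window_default Logical; \code{TRUE} when the window is a package
#'   default rather than an experimentally established value (flagged in
#'   reports).
#' @return An object of class \code{editor_profile}.
#' @seealso [editor_profiles()] for the shipped profiles.
#' @export
editor_profile <- function(name, base_from, base_to, window_start, window_end,
                           pam, spacer_length, window_default = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  base_from <- dna(base_from); base_to <- dna(base_to)
  if (nchar(base_from) != 1L || nchar(base_to) != 1L)
    stop("base_from/base_to must be single nucleotides")
  window_start <- as.integer(window_start)
  window_end <- as.integer(window_end)
  spacer_length <- as.integer(spacer_length)
  if (!(1L <= window_start && window_start <= window_end &&
        window_end <= spacer_length))
    stop("require 1 <= window_start <= window_end <= spacer_length")
  pc <- strsplit(toupper(pam), "")[[1]]
  if (!all(pc %in% names(.IUPAC_SETS)))
    stop("invalid IUPAC symbol in PAM: ", pam)
  structure(
    list(name = name, base_from = base_from, base_to = base_to,
         window_start = window_start, window_end = window_end,
         pam = toupper(pam), spacer_length = spacer_length,
         window_default = isTRUE(window_default)),
    class = "editor_profile")
}

#' @export
print.editor_profile <- function(x, ...) {
  cat(sprintf("<editor_profile> %s: %s->%s, window %d-%d of %d-mer, PAM %s%s\n",
              x$name, x$base_from, x$base_to, x$window_start, x$window_end,
              x$spacer_length, x$pam,
              if (x$window_default) " (default window)" else ""))
  invisible(x)
}

#' Shipped editor profiles
#'
#' The profile set used throughout the workflow:
#' \describe{
#'   \item{abe8e_sp}{SpCas9 ABE8e, A->G, window 3-10, PAM NGG, 20-mer.}
#'   \item{be4max_sp_ng}{SpCas9-NG BE4max, C->T, window 4-8, PAM NG, 20-mer.
#'     Window 4-8 encodes "target 12-16 bases upstream of the PAM" of a
#'     20-mer under the intervening-bases distance convention (see
#'     vignette).}
#'   \item{be4max_sp_ngg}{As above with the canonical NGG PAM.}
#'   \item{sa_abe8e}{SaCas9 ABE8e, A->G, PAM NNGRRT, 21-mer; window
#'     defaults to 4-12 (configurable; flagged as a default).}
#'   \item{sauri_abe}{S. auricularis Cas9 ABE, A->G, PAM NNGG, 21-mer;
#'     window defaults to 4-12 (configurable; flagged as a default).}
#' }
#'
#' @param name Optional profile name; when given, that single profile is
#'   returned.
#' @return A named list of [editor_profile()] objects, or one profile.
#' @export
editor_profiles <- function(name = NULL) {
  profs <- list(
    abe8e_sp = editor_profile("abe8e_sp", "A", "G", 3, 10, "NGG", 20),
    be4max_sp_ng = editor_profile("be4max_sp_ng", "C", "T", 4, 8, "NG", 20),
    be4max_sp_ngg = editor_profile("be4max_sp_ngg", "C", "T", 4, 8, "NGG", 20),
    sa_abe8e = editor_profile("sa_abe8e", "A", "G", 4, 12, "NNGRRT", 21,
                              window_default = TRUE),
    sauri_abe = editor_profile("sauri_abe", "A", "G", 4, 12, "NNGG", 21,
                               window_default = TRUE)
  )
  if (is.null(name)) return(profs)
  if (!name %in% names(profs))
    stop("unknown profile '", name, "'; shipped: ",
         paste(names(profs), collapse = ", "))
  profs[[name]]
}

#' Load editor profiles from a YAML config
#'
#' Each top-level key names a profile; fields follow [editor_profile()]
#' arguments. Missing fields fall back to the shipped profile of the same
#' name, so a config can override just a window.
#'
#' @param path YAML file path.
#' @return Named list of [editor_profile()] objects.
#' @export
load_editor_profiles <- function(path) {
  cfg <- yaml::read_yaml(path)
  shipped <- editor_profiles()
  out <- lapply(names(cfg), function(nm) {
    base <- if (nm %in% names(shipped)) unclass(shipped[[nm]]) else list()
    fields <- utils::modifyList(base, cfg[[nm]])
    fields$name <- nm
    do.call(editor_profile, fields[c("name", "base_from", "base_to",
                                     "window_start", "window_end",
                                     "pam", "spacer_length")])
  })
  names(out) <- names(cfg)
  out
}

#' Construct a guide design
#'
#' A concrete protospacer placement on an input sequence. Usually produced
#' by [find_protospacers()] rather than called directly.
#'
#' @param spacer Spacer sequence (protospacer-strand, 5'->3').
#' @param strand \code{"+"} or \code{"-"} relative to the input sequence.
#' @param protospacer_start 0-based start of the covered interval on the
#'   input sequence's plus strand (half-open).
#' @param pam_seq Observed PAM on the protospacer strand.
#' @param target_position 1-based protospacer position of the target base.
#' @param bystander_positions Integer vector of additional editable-base
#'   positions inside the editing window.
#' @param profile_name Name of the profile the design was made under.
#' @return An object of class \code{guide_design}.
#' @export
guide_design <- function(spacer, strand, protospacer_start, pam_seq,
                         target_position, bystander_positions = integer(),
                         profile_name = NA_character_) {
  strand <- match.arg(strand, c("+", "-"))
  spacer <- dna(spacer)
  target_position <- as.integer(target_position)
  bystander_positions <- as.integer(bystander_positions)
  if (target_position %in% bystander_positions)
    stop("target_position must not appear among bystander_positions")
  structure(
    list(spacer = spacer, strand = strand,
         protospacer_start = as.integer(protospacer_start),
         pam_seq = dna(pam_seq), target_position = target_position,
         bystander_positions = sort(bystander_positions),
         profile_name = profile_name),
    class = "guide_design")
}

#' @export
print.guide_design <- function(x, ...) {
  cat(sprintf(
    "<guide_design> %s (%s) strand %s start %d PAM %s target pos %d bystanders [%s]\n",
    x$spacer, x$profile_name, x$strand, x$protospacer_start, x$pam_seq,
    x$target_position, paste(x$bystander_positions, collapse = ",")))
  invisible(x)
}

# Map a 1-based protospacer position of a guide to the 0-based plus-strand
# coordinate it covers on the input sequence.
.guide_pos_to_coord <- function(guide, pos) {
  L <- nchar(guide$spacer)
  if (guide$strand == "+") guide$protospacer_start + pos - 1L
  else guide$protospacer_start + L - pos
}

#' Enumerate protospacers covering an editable site
#'
#' Finds every protospacer placement, on either strand of \code{seq}, in
#' which the base at \code{site} (i) is the profile's editable base on the
#' protospacer strand, (ii) falls at a protospacer position inside the
#' profile's editing window, and (iii) is followed 3' (on the protospacer
#' strand) by a matching PAM. Bystander positions are the other in-window
#' occurrences of the editable base.
#'
#' @param seq Input sequence (plus strand).
#' @param site 0-based position of the editable base on the plus strand.
#' @param profile An [editor_profile()].
#' @return List of [guide_design()] objects, sorted by (strand, start);
#'   empty when no strand carries the editable base at \code{site}.
#' @examples
#' fx <- egfp_fixtures()
#' find_protospacers(fx$wt_cds, 240, editor_profiles("be4max_sp_ng"))
#' @export
find_protospacers <- function(seq, site, profile) {
  s <- dna(seq)
  M <- nchar(s)
  site <- as.integer(site)
  if (site < 0L || site >= M)
    stop("site ", site, " out of bounds for sequence of length ", M)
  L <- profile$spacer_length
  P <- nchar(profile$pam)
  w1 <- profile$window_start; w2 <- profile$window_end
  base_plus <- substr(s, site + 1L, site + 1L)
  out <- list()

  if (base_plus == profile$base_from) {
    for (a in seq.int(site - w2 + 1L, site - w1 + 1L)) {
      if (a < 0L || a + L + P > M) next
      pam_seq <- substr(s, a + L + 1L, a + L + P)
      if (!iupac_match(profile$pam, pam_seq)) next
      spacer <- substr(s, a + 1L, a + L)
      p <- site - a + 1L
      out[[length(out) + 1L]] <- .make_guide(spacer, "+", a, pam_seq, p, profile)
    }
  }
  if (.complement_base(base_plus) == profile$base_from) {
    starts <- sort(seq.int(site - L + w1, site - L + w2))
    for (a in starts) {
      if (a - P < 0L || a + L > M) next
      pam_seq <- revcomp(substr(s, a - P + 1L, a))
      if (!iupac_match(profile$pam, pam_seq)) next
      spacer <- revcomp(substr(s, a + 1L, a + L))
      p <- a + L - site
      out[[length(out) + 1L]] <- .make_guide(spacer, "-", a, pam_seq, p, profile)
    }
  }
  ord <- order(vapply(out, function(g) g$strand, ""),
               vapply(out, function(g) g$protospacer_start, 0L))
  out[ord]
}

.make_guide <- function(spacer, strand, start0, pam_seq, target_position,
                        profile) {
  win <- seq.int(profile$window_start, profile$window_end)
  chars <- strsplit(spacer, "")[[1]]
  bys <- win[chars[win] == profile$base_from & win != target_position]
  guide_design(spacer, strand, start0, pam_seq, target_position, bys,
               profile_name = profile$name)
}

#' Read a FASTA file
#'
#' @param path FASTA path (single- or multi-record).
#' @return Named character vector of normalized sequences; names are the
#'   full description lines.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- vapply(as.character(x), dna, "", USE.NAMES = FALSE)
  names(out) <- names(x)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(vapply(seqs, dna, "", USE.NAMES = FALSE))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
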