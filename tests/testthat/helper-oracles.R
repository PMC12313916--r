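# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive: exhaustive enumeration and textbook DP, sharing no
# code with the implementation they check.

# Base-wise complement + reversal, written without Biostrings.
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# IUPAC symbol -> regex character class.
.iupac_regex <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
                  W = "[AT]", S = "[CG]", K = "[GT]", M = "[AC]",
                  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
                  N = "[ACGT]")
iupac_to_regex <- function(pattern) {
  paste(.iupac_regex[strsplit(pattern, "")[[1]]], collapse = "")
}

# Brute-force protospacer enumeration: slide a spacer+PAM window over both
# strands and keep placements where the site is the editable base inside
# the editing window and the PAM matches (regex on concrete ACGT; windows
# containing N never match, mirroring the conservative rule).
oracle_protospacers <- function(seq, site, profile) {
  M <- nchar(seq)
  L <- profile$spacer_length
  P <- nchar(profile$pam)
  pam_re <- paste0("^", iupac_to_regex(profile$pam), "$")
  hits <- list()
  for (strand in c("+", "-")) {
    for (a in 0:(M - L - P)) {
      if (strand == "+") {
        spacer <- substr(seq, a + 1, a + L)
        pam <- substr(seq, a + L + 1, a + L + P)
        start0 <- a
        pos <- site - start0 + 1
      } else {
        # protospacer on the minus strand occupying plus interval
        # [a+P, a+P+L), PAM at plus interval [a, a+P)
        spacer <- oracle_revcomp(substr(seq, a + P + 1, a + P + L))
        pam <- oracle_revcomp(substr(seq, a + 1, a + P))
        start0 <- a + P
        pos <- start0 + L - site
      }
      if (pos < profile$window_start || pos > profile$window_end) next
      if (grepl("N", pam, fixed = TRUE)) next
      if (!grepl(pam_re, pam)) next
      if (substr(spacer, pos, pos) != profile$base_from) next
      hits[[length(hits) + 1]] <- list(strand = strand, start = start0,
                                       spacer = spacer, pam = pam,
                                       target_position = pos)
    }
  }
  hits
}

guide_key <- function(g) paste(g$strand, g$protospacer_start %||% g$start,
                               sep = ":")
`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force stop-switch screen: try every single C->T edit (either
# strand) at every CDS position, keep those that create an in-frame stop
# without touching other codons and that admit at least one install guide
# (by the brute-force protospacer oracle).
oracle_stop_switch <- function(cds, profile) {
  n <- nchar(cds)
  prot <- sapply(seq_len(n / 3), function(k)
    oracle_translate(substr(cds, 3 * k - 2, 3 * k)))
  out <- list()
  for (pos in seq_len(n)) {
    for (strand in c("+", "-")) {
      plus_from <- if (strand == "+") "C" else "G"
      plus_to <- if (strand == "+") "T" else "A"
      if (substr(cds, pos, pos) != plus_from) next
      edited <- cds
      substr(edited, pos, pos) <- plus_to
      k <- (pos - 1) %/% 3 + 1
      codon_new <- substr(edited, 3 * k - 2, 3 * k)
      if (!codon_new %in% c("TAA", "TAG", "TGA")) next
      if (prot[k] == "*") next
      if (length(oracle_protospacers(cds, pos - 1, profile)) == 0) next
      out[[length(out) + 1]] <- list(codon_index = k,
                                     wt_codon = substr(cds, 3 * k - 2, 3 * k),
                                     installed_codon = codon_new,
                                     edit_cds_position = pos,
                                     edit_strand = strand)
    }
  }
  out
}

.CODON_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- sort(codons)
  aa <- vapply(codons, function(cd)
    as.character(Biostrings::GENETIC_CODE[[cd]]), "")
  stats::setNames(aa, codons)
})
oracle_translate <- function(codon) unname(.CODON_TABLE[codon])

# Textbook Gotoh affine-gap DP, read globally aligned, free end gaps on
# the subject; gap of length k costs open + k * extend. Returns the best
# score.
oracle_align_score <- function(read, subject, match = 2, mismatch = -3,
                               gap_open = -5, gap_extend = -2) {
  r <- strsplit(read, "")[[1]]; s <- strsplit(subject, "")[[1]]
  n <- length(r); m <- length(s)
  NEG <- -1e9
  H <- matrix(NEG, n + 1, m + 1)  # best ending in match/mismatch or free
  E <- matrix(NEG, n + 1, m + 1)  # gap in subject (read base unmatched)
  F <- matrix(NEG, n + 1, m + 1)  # gap in read (subject base skipped)
  H[1, ] <- 0                     # free leading subject gap
  for (i in 2:(n + 1)) {
    E[i, 1] <- gap_open + gap_extend * (i - 1)
    H[i, 1] <- E[i, 1]
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (r[i - 1] == s[j - 1]) match else mismatch
      diag <- max(H[i - 1, j - 1], E[i - 1, j - 1], F[i - 1, j - 1]) + sub
      E[i, j] <- max(H[i - 1, j] + gap_open + gap_extend,
                     E[i - 1, j] + gap_extend)
      F[i, j] <- max(H[i, j - 1] + gap_open + gap_extend,
                     F[i, j - 1] + gap_extend)
      H[i, j] <- max(diag, NEG)
    }
  }
  max(H[n + 1, ], E[n + 1, ], F[n + 1, ])  # free trailing subject gap
}

# Random open reading frame: ATG, n_codons-2 random non-stop codons, TAA.
random_orf <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- setdiff(names(.CODON_TABLE), c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                      collapse = ""), "TAA")
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Build a QualityScaledDNAStringSet from sequences and per-read constant
# Phred scores.
make_reads <- function(seqs, phred = 37, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%04d", seq_along(seqs))
  phred <- rep_len(phred, length(seqs))
  quals <- vapply(seq_along(seqs), function(i)
    intToUtf8(rep(phred[i] + 33L, nchar(seqs[i]))), "")
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(seqs, ids)),
    Biostrings::PhredQuality(quals))
}
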