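# Editing quantification from single-end amplicon sequencing: mean-quality
# read filter, orientation-aware semi-global alignment to the amplicon
# reference, and per-position substitution tallies inside a quantification
# window anchored on the guide.

#' Read a FASTQ file
#'
#' @param path FASTQ path (Sanger/phred+33 qualities; .gz accepted).
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @export
read_fastq <- function(path) {
  Biostrings::readQualityScaledDNAStringSet(path)
}

#' Write reads to a FASTQ file
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @param path Output path (".gz" suffix compresses).
#' @export
write_fastq <- function(reads, path) {
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              compress = grepl("\\.gz$", path),
                              qualities = Biostrings::quality(reads))
  invisible(path)
}

#' Per-read mean Phred score
#'
#' Arithmetic mean of the integer Phred scores of each read (not
#' error-probability averaging).
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @return Numeric vector.
#' @export
mean_phred <- function(reads) {
  q <- Biostrings::quality(reads)
  if (!methods::is(q, "PhredQuality"))
    q <- methods::as(q, "PhredQuality")
  vapply(as.character(q), function(s) mean(utf8ToInt(s)) - 33, 0,
         USE.NAMES = FALSE)
}

#' Filter reads by mean Phred score
#'
#' Keeps reads whose arithmetic-mean Phred score is strictly greater than
#' the threshold (a read at exactly the threshold is removed).
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @param min_mean_phred Threshold (default 30).
#' @return Filtered reads.
#' @export
filter_by_mean_quality <- function(reads, min_mean_phred = 30) {
  reads[mean_phred(reads) > min_mean_phred]
}

#' Quantification configuration
#'
#' @param min_mean_phred Mean-quality threshold, strict inequality
#'   (default 30).
#' @param window_center Protospacer position at the centre of the
#'   quantification window (default 10).
#' @param window_halfwidth Half-width in nt (default 20); the window is
#'   protospacer positions \code{center - halfwidth .. center + halfwidth}
#'   mapped to amplicon coordinates and clipped to the amplicon. The
#'   defaults always cover a 20-mer protospacer.
#' @param indel_policy \code{"exclude_window_indels"} (default) drops reads
#'   with an insertion or deletion overlapping the window from the
#'   substitution tally; \code{"count_all"} keeps them.
#' @return List of class \code{quant_config}.
#' @export
quant_config <- function(min_mean_phred = 30, window_center = 10,
                         window_halfwidth = 20,
                         indel_policy = c("exclude_window_indels", "count_all")) {
  stopifnot(min_mean_phred > 0, window_halfwidth >= 0)
  structure(list(min_mean_phred = min_mean_phred,
                 window_center = as.integer(window_center),
                 window_halfwidth = as.integer(window_halfwidth),
                 indel_policy = match.arg(indel_policy)),
            class = "quant_config")
}

# Alignment scoring, fixed and echoed into result metadata. A gap of
# length k costs open + k * extend.
.ALIGN_SCORING <- list(match = 2, mismatch = -3, gap_open = -5,
                       gap_extend = -2, floor_frac = 0.4)

# ---- alignment core -------------------------------------------------------

# k-mer index of the amplicon: named list kmer -> 1-based start positions.
.kmer_index <- function(amplicon, k) {
  M <- nchar(amplicon)
  if (M < k) return(list())
  starts <- seq_len(M - k + 1L)
  kmers <- substring(amplicon, starts, starts + k - 1L)
  split(starts, kmers)
}

# Ungapped comparison of `read` placed at 0-based `off` on `amplicon`.
.ungapped_mismatches <- function(read_int, amp_int, off) {
  sum(read_int != amp_int[(off + 1L):(off + length(read_int))])
}

# Base-R reverse complement of a utf8ToInt-encoded sequence (hot path).
.COMP_MAP <- local({
  m <- integer(128)
  m[utf8ToInt("A")] <- utf8ToInt("T"); m[utf8ToInt("T")] <- utf8ToInt("A")
  m[utf8ToInt("C")] <- utf8ToInt("G"); m[utf8ToInt("G")] <- utf8ToInt("C")
  m[utf8ToInt("N")] <- utf8ToInt("N")
  m
})
.revcomp_int <- function(ri) rev(.COMP_MAP[ri])

# Placement of reads on the amplicon. Exact-anchor ungapped fast path with
# an optimality certificate; compiled affine semi-global DP (read fully
# aligned, free end gaps on the amplicon) as fallback and general path.
# Returns a list of per-read records.
.align_reads <- function(seqs, amplicon, scoring = .ALIGN_SCORING) {
  M <- nchar(amplicon)
  k <- max(8L, min(18L, min(nchar(seqs))))
  idx_f <- .kmer_index(amplicon, k)
  amp_int <- utf8ToInt(amplicon)

  n <- length(seqs)
  out <- vector("list", n)

  # Unique-offset lookup: 0-based offset implied by an exact k-mer at read
  # position a, or NA when the k-mer is absent or repeated in the amplicon.
  unique_off <- function(read_int, a) {
    hit <- idx_f[[intToUtf8(read_int[a:(a + k - 1L)])]]
    if (is.null(hit) || length(hit) != 1L) NA_integer_ else hit - a
  }

  fast_one <- function(read_int, target_int) {
    len <- length(read_int)
    if (len < k || len > M) return(NULL)
    anchors <- unique(c(1L, (len - k) %/% 2L + 1L, len - k + 1L))
    offs <- integer(0)
    for (a in anchors) {
      hit <- idx_f[[intToUtf8(read_int[a:(a + k - 1L)])]]
      if (!is.null(hit)) offs <- c(offs, hit - a)
    }
    offs <- unique(offs)
    offs <- offs[offs >= 0L & offs + len <= M]
    if (length(offs) == 0L) return(NULL)
    mm <- vapply(offs, function(o) .ungapped_mismatches(read_int, target_int, o), 0L)
    best <- which.min(mm)
    off <- offs[best]
    mmb <- mm[best]
    # Certificate that the ungapped placement is the orientation's global
    # optimum without running the DP:
    #  - mm <= 1: a gap costs >= 7, repairing one mismatch gains at most 5.
    #  - mm == 2: a better alignment needs one 0-mismatch gap, so the read
    #    splits into two segments matching the amplicon exactly. Take an
    #    intact anchor near each read end whose k-mer occurs exactly once
    #    in the amplicon, both implying this placement: a split between
    #    them would put one anchor in each exact segment, forcing the two
    #    segments onto the same offset -- impossible for a gapped
    #    alignment. Splits outside the anchor span are only viable when
    #    both mismatches sit out there too, which is checked explicitly.
    certified <- mmb <= 1L
    if (!certified && mmb == 2L && len >= 2L * k) {
      mm_pos <- which(read_int != target_int[(off + 1L):(off + len)])
      l <- NA_integer_
      for (a in c(1L, k + 1L, 2L * k + 1L)) {
        if (a + k - 1L > len) break
        o <- unique_off(read_int, a)
        if (!is.na(o) && o == off) { l <- a; break }
      }
      r <- NA_integer_
      for (a in c(len - k + 1L, len - 2L * k + 1L, len - 3L * k + 1L)) {
        if (a < 1L) break
        o <- unique_off(read_int, a)
        if (!is.na(o) && o == off) { r <- a + k - 1L; break }
      }
      # margins widened by the maximal competitive gap length (2) so that
      # unaligned read bases flanking an insertion are covered
      certified <- !is.na(l) && !is.na(r) && (r - l) >= 2L * k &&
        !all(mm_pos <= l + k) && !all(mm_pos >= r - k)
    }
    list(off = off, mm = mmb, certified = certified,
         score = scoring$match * (len - mmb) + scoring$mismatch * mmb)
  }

  # Certified ungapped placements are accepted outright. Other reads get a
  # score-only affine DP per orientation; when the DP score equals the
  # ungapped candidate's score that placement is optimal and kept, and
  # only reads the DP genuinely improves (indels, anchor misses) pay for a
  # traceback.
  dp_score <- function(q) .gotoh_align(q, amplicon, scoring$match,
                                       scoring$mismatch, scoring$gap_open,
                                       scoring$gap_extend, FALSE)$score
  dp_full <- function(q) .gotoh_align(q, amplicon, scoring$match,
                                      scoring$mismatch, scoring$gap_open,
                                      scoring$gap_extend, TRUE)

  ungapped_rec <- function(strand, hit, oriented) {
    list(strand = strand, score = hit$score, offset = hit$off,
         oriented = oriented, gapped = FALSE,
         aln_pattern = NA_character_, aln_subject = NA_character_)
  }

  for (i in seq_len(n)) {
    read <- seqs[i]
    ri <- utf8ToInt(read)
    f <- fast_one(ri, amp_int)
    if (!is.null(f) && f$certified) {
      out[[i]] <- ungapped_rec("+", f, read)
      next
    }
    # reverse-complement orientation: align revcomp(read) to the forward
    # amplicon (equivalent to aligning the read to the minus strand)
    rci <- .revcomp_int(ri)
    rc_ok <- !any(rci == 0L)
    rc <- if (rc_ok) intToUtf8(rci) else revcomp(read)
    r <- if (rc_ok) fast_one(rci, amp_int) else NULL
    if (!is.null(r) && r$certified && (is.null(f) || r$score > f$score)) {
      out[[i]] <- ungapped_rec("-", r, rc)
      next
    }
    sc_f <- dp_score(read)
    sc_r <- dp_score(rc)
    floor_score <- scoring$floor_frac * scoring$match * nchar(read)
    if (max(sc_f, sc_r) < floor_score) {
      out[[i]] <- list(strand = if (sc_r > sc_f) "-" else "+",
                       score = max(sc_f, sc_r), offset = NA_integer_,
                       oriented = if (sc_r > sc_f) rc else read,
                       gapped = FALSE, aln_pattern = NA_character_,
                       aln_subject = NA_character_)
      next
    }
    if (sc_f >= sc_r) {  # tie keeps the plus strand
      if (!is.null(f) && f$score == sc_f) {
        out[[i]] <- ungapped_rec("+", f, read)
      } else {
        d <- dp_full(read)
        out[[i]] <- list(strand = "+", score = d$score, offset = d$offset,
                         oriented = read,
                         gapped = grepl("-", d$aln_pattern, fixed = TRUE) ||
                           grepl("-", d$aln_subject, fixed = TRUE),
                         aln_pattern = d$aln_pattern,
                         aln_subject = d$aln_subject)
      }
    } else {
      if (!is.null(r) && r$score == sc_r) {
        out[[i]] <- ungapped_rec("-", r, rc)
      } else {
        d <- dp_full(rc)
        out[[i]] <- list(strand = "-", score = d$score, offset = d$offset,
                         oriented = rc,
                         gapped = grepl("-", d$aln_pattern, fixed = TRUE) ||
                           grepl("-", d$aln_subject, fixed = TRUE),
                         aln_pattern = d$aln_pattern,
                         aln_subject = d$aln_subject)
      }
    }
  }
  out
}

# Subject-position -> read-base map for a gapped alignment record.
# Returns list(bases = named character (names = 1-based subject coords),
# del_positions, ins_flanks).
.gapped_map <- function(rec) {
  pc <- strsplit(rec$aln_pattern, "")[[1]]
  sc <- strsplit(rec$aln_subject, "")[[1]]
  spos <- rec$offset  # 0-based, incremented before use
  bases <- character(0)
  dels <- integer(0)
  ins <- integer(0)
  for (j in seq_along(pc)) {
    if (sc[j] != "-") {
      spos <- spos + 1L
      if (pc[j] == "-") {
        dels <- c(dels, spos)
      } else {
        bases[as.character(spos)] <- pc[j]
      }
    } else {
      ins <- c(ins, spos)  # insertion sits after subject position spos
    }
  }
  list(bases = bases, del_positions = dels, ins_flanks = ins,
       cover = c(rec$offset + 1L, spos))
}

#' Align one read to an amplicon reference
#'
#' Semi-global alignment with the read fully aligned and free end gaps on
#' the amplicon, scored match +2 / mismatch -3 / gap open -5 / gap extend
#' -2 per gap base. Both orientations are tried and the higher-scoring one
#' kept (ties resolve to the plus strand). A read whose best score falls
#' below 0.4 x 2 x read length is flagged unalignable.
#'
#' @param read Read sequence (character scalar).
#' @param amplicon Amplicon reference sequence.
#' @return List: \code{strand}, \code{score}, \code{offset} (0-based
#'   subject start), \code{oriented} (read expressed on the plus strand),
#'   \code{gapped}, \code{unalignable}, and for gapped alignments the
#'   aligned pattern/subject strings.
#' @export
align_to_amplicon <- function(read, amplicon) {
  if (!nzchar(read) || !nzchar(amplicon)) stop("empty read or amplicon")
  rec <- .align_reads(dna(read), dna(amplicon))[[1]]
  rec$unalignable <-
    rec$score < .ALIGN_SCORING$floor_frac * .ALIGN_SCORING$match * nchar(read)
  rec$scoring <- .ALIGN_SCORING
  rec
}

# ---- quantification -------------------------------------------------------

# Locate a guide's protospacer on the amplicon; 0-based start or error.
.locate_guide <- function(guide, amplicon) {
  probe <- if (guide$strand == "+") guide$spacer else revcomp(guide$spacer)
  m <- Biostrings::matchPattern(Biostrings::DNAString(probe),
                                Biostrings::DNAString(amplicon))
  if (length(m) == 0L)
    stop("guide protospacer not found on amplicon")
  if (length(m) > 1L)
    stop("guide protospacer occurs ", length(m), " times on amplicon")
  Biostrings::start(m)[1] - 1L
}

# 1-based amplicon coordinate of protospacer position p for a guide whose
# covered interval starts at 0-based loc0 (extrapolates beyond the spacer).
.proto_to_amplicon <- function(p, loc0, L, strand) {
  if (strand == "+") loc0 + p else loc0 + L - p + 1L
}

#' Quantify base-editing outcomes in an amplicon read set
#'
#' Pipeline: mean-quality filter (strict Q > threshold), orientation-aware
#' semi-global alignment, exclusion of unalignable reads and (by default)
#' of reads with an indel overlapping the quantification window, then
#' per-position substitution tallies. The editing percentage is the
#' percentage of quantified reads carrying the editor's converted base at
#' the guide's target position.
#'
#' @param reads FASTQ path or [Biostrings::QualityScaledDNAStringSet].
#' @param amplicon Amplicon reference sequence (or single-record FASTA
#'   path).
#' @param guide [guide_design()] locating the protospacer and target on
#'   the amplicon; its strand determines the sense of the conversion.
#' @param config [quant_config()].
#' @param base_from,base_to The conversion, on the protospacer strand
#'   (defaults A -> G).
#' @return Object of class \code{quant_result}: read accounting
#'   (\code{n_total}, \code{n_pass_quality}, \code{n_removed_quality},
#'   \code{n_unalignable}, \code{n_window_indel},
#'   \code{n_window_not_covered}, \code{n_quantified}),
#'   \code{editing_percent} (NA when no reads quantified),
#'   \code{per_position_conversion}, \code{substitution_table}, window and
#'   target coordinates, and alignment-scoring metadata.
#' @export
quantify_sample <- function(reads, amplicon, guide, config = quant_config(),
                            base_from = "A", base_to = "G") {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  if (is.character(amplicon) && file.exists(amplicon))
    amplicon <- read_fasta(amplicon)[1]
  amplicon <- dna(amplicon)
  M <- nchar(amplicon)
  L <- nchar(guide$spacer)
  loc0 <- .locate_guide(guide, amplicon)

  # conversion expressed on the amplicon plus strand
  conv_from <- if (guide$strand == "+") dna(base_from) else .complement_base(dna(base_from))
  conv_to <- if (guide$strand == "+") dna(base_to) else .complement_base(dna(base_to))
  target_coord <- .proto_to_amplicon(guide$target_position, loc0, L, guide$strand)

  pp <- seq.int(config$window_center - config$window_halfwidth,
                config$window_center + config$window_halfwidth)
  W <- sort(vapply(pp, .proto_to_amplicon, 0L, loc0 = loc0, L = L,
                   strand = guide$strand))
  W <- W[W >= 1L & W <= M]
  if (length(W) == 0L) stop("quantification window empty after clipping")
  wlo <- min(W); whi <- max(W)
  if (target_coord < wlo || target_coord > whi)
    stop("target position falls outside the quantification window")

  n_total <- length(reads)
  passed <- filter_by_mean_quality(reads, config$min_mean_phred)
  n_pass <- length(passed)

  if (n_pass == 0L)
    return(.quant_result(n_total, n_pass, 0L, 0L, 0L, 0L, NULL, NULL,
                         amplicon, W, target_coord, conv_from, conv_to,
                         guide, config))

  seqs <- as.character(passed)
  lens <- nchar(seqs)
  recs <- .align_reads(seqs, amplicon)
  score <- vapply(recs, function(r) r$score, 0)
  unalignable <- score < .ALIGN_SCORING$floor_frac * .ALIGN_SCORING$match * lens
  gapped <- vapply(recs, function(r) r$gapped, TRUE)

  keep <- !unalignable
  win_indel <- logical(n_pass)
  not_covered <- logical(n_pass)
  gap_maps <- vector("list", n_pass)
  for (i in which(keep)) {
    r <- recs[[i]]
    if (!gapped[i]) {
      cover <- c(r$offset + 1L, r$offset + nchar(r$oriented))
    } else {
      gm <- .gapped_map(r)
      gap_maps[[i]] <- gm
      cover <- gm$cover
      overlaps <- any(gm$del_positions >= wlo & gm$del_positions <= whi) ||
        any(gm$ins_flanks >= wlo & gm$ins_flanks < whi)
      if (overlaps && config$indel_policy == "exclude_window_indels")
        win_indel[i] <- TRUE
    }
    if (cover[1] > wlo || cover[2] < whi) not_covered[i] <- TRUE
  }
  quant <- keep & !win_indel & !not_covered
  n_quant <- sum(quant)

  if (n_quant == 0L)
    return(.quant_result(n_total, n_pass, sum(unalignable), sum(win_indel),
                         sum(not_covered), 0L, NULL, NULL, amplicon, W,
                         target_coord, conv_from, conv_to, guide, config))

  qi <- which(quant)
  ug <- qi[!gapped[qi]]
  gp <- qi[gapped[qi]]
  oriented <- vapply(recs, function(r) r$oriented, "")
  offsets <- vapply(recs, function(r) r$offset, 0L)

  ref_bases <- substring(amplicon, W, W)
  tab_list <- vector("list", length(W))
  conv_pct <- rep(NA_real_, length(W))
  conv_n <- integer(length(W))
  for (j in seq_along(W)) {
    wp <- W[j]
    b <- character(0)
    if (length(ug))
      b <- substring(oriented[ug], wp - offsets[ug], wp - offsets[ug])
    if (length(gp))
      b <- c(b, vapply(gp, function(i) {
        x <- gap_maps[[i]]$bases[as.character(wp)]
        if (is.na(x)) "-" else x
      }, ""))
    b <- b[b != "-"]  # deletion under count_all policy: no base to tally
    counts <- table(b)
    tab_list[[j]] <- data.frame(position = wp, ref_base = ref_bases[j],
                                read_base = names(counts),
                                count = as.integer(counts),
                                stringsAsFactors = FALSE)
    conv_n[j] <- length(b)
    if (ref_bases[j] == conv_from && length(b) > 0L)
      conv_pct[j] <- 100 * sum(b == conv_to) / length(b)
  }
  substitution_table <- do.call(rbind, tab_list)
  jt <- match(target_coord, W)
  editing_percent <- conv_pct[jt]
  if (ref_bases[jt] != conv_from)
    stop("amplicon base at the target coordinate is ", ref_bases[jt],
         ", not the editable base ", conv_from)

  per_position <- data.frame(
    position = W,
    protospacer_position = if (guide$strand == "+") W - loc0 else loc0 + L - W + 1L,
    ref_base = ref_bases, n_covering = conv_n,
    percent_converted = conv_pct, stringsAsFactors = FALSE)

  .quant_result(n_total, n_pass, sum(unalignable), sum(win_indel),
                sum(not_covered), n_quant, substitution_table, per_position,
                amplicon, W, target_coord, conv_from, conv_to, guide, config,
                editing_percent)
}

.quant_result <- function(n_total, n_pass, n_unalignable, n_window_indel,
                          n_window_not_covered, n_quantified,
                          substitution_table, per_position, amplicon, W,
                          target_coord, conv_from, conv_to, guide, config,
                          editing_percent = NA_real_) {
  structure(list(
    n_total = n_total, n_pass_quality = n_pass,
    n_removed_quality = n_total - n_pass,
    n_unalignable = n_unalignable, n_window_indel = n_window_indel,
    n_window_not_covered = n_window_not_covered, n_quantified = n_quantified,
    editing_percent = editing_percent,
    substitution_table = substitution_table,
    per_position_conversion = per_position,
    window = range(W), target_amplicon_position = target_coord,
    conversion = sprintf("%s>%s (plus strand)", conv_from, conv_to),
    guide = guide, config = config, alignment_scoring = .ALIGN_SCORING),
    class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf(
    "<quant_result> %d reads: %d passed Q filter, %d quantified (%d unalignable, %d window-indel, %d window-incomplete)\n",
    x$n_total, x$n_pass_quality, x$n_quantified, x$n_unalignable,
    x$n_window_indel, x$n_window_not_covered))
  cat(sprintf("  editing at amplicon position %d (%s): %s\n",
              x$target_amplicon_position, x$conversion,
              if (is.na(x$editing_percent)) "NA (no quantified reads)"
              else sprintf("%.1f%%", x$editing_percent)))
  invisible(x)
}
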