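# Ground-truthed simulators emulating the study's data-generating
# processes: single-end amplicon reads with a known edited fraction, ddPCR
# partition counts, and multi-copy cell populations. All are
# byte-reproducible under a fixed seed.

#' Amplicon read-simulation configuration
#'
#' Emulates single-end amplicon sequencing of 220-280 cycles over a locus
#' carrying a target conversion at a known per-read fraction, optional
#' bystander co-edits, uniform per-base sequencing error, and normal
#' per-base Phred qualities. Read start positions are uniform subject to
#' the read covering the full quantification window implied by
#' \code{quant}.
#'
#' @param amplicon Amplicon reference sequence.
#' @param guide [guide_design()] locating the target on the amplicon.
#' @param edit_fraction Per-read probability q of carrying the target
#'   conversion.
#' @param bystander_fractions Named numeric: protospacer position ->
#'   co-edit probability (default none).
#' @param bystander_linked If \code{TRUE}, bystander co-edits occur only on
#'   reads carrying the target edit (deaminase action is processive on one
#'   molecule); default \code{FALSE}, independent.
#' @param per_base_error Uniform substitution error rate per base (default
#'   0.001).
#' @param read_length Read length in nt; \code{NULL} (default) draws
#'   uniformly from 220-280 per read, clipped to the amplicon length.
#' @param n_reads Number of reads.
#' @param phred_mean,phred_sd Per-base quality model, Normal truncated to
#'   [2, 41] and rounded (defaults 37, 3).
#' @param fraction_low_quality Fraction of reads drawn with mean quality 25
#'   to exercise the Q > 30 filter (default 0.05).
#' @param base_from,base_to The conversion on the protospacer strand
#'   (defaults A -> G).
#' @param quant [quant_config()] defining the window reads must cover.
#' @param seed Integer seed.
#' @return List of class \code{amplicon_sim_config}.
#' @export
amplicon_sim_config <- function(amplicon, guide, edit_fraction,
                                bystander_fractions = numeric(),
                                bystander_linked = FALSE,
                                per_base_error = 0.001,
                                read_length = NULL, n_reads = 1000L,
                                phred_mean = 37, phred_sd = 3,
                                fraction_low_quality = 0.05,
                                base_from = "A", base_to = "G",
                                quant = quant_config(), seed = 1L) {
  stopifnot(edit_fraction >= 0, edit_fraction <= 1,
            per_base_error >= 0, per_base_error <= 1,
            fraction_low_quality >= 0, fraction_low_quality <= 1,
            all(bystander_fractions >= 0), all(bystander_fractions <= 1))
  if (!is.null(read_length) && read_length > nchar(dna(amplicon)))
    stop("read_length exceeds amplicon length")
  structure(list(amplicon = dna(amplicon), guide = guide,
                 edit_fraction = edit_fraction,
                 bystander_fractions = bystander_fractions,
                 bystander_linked = isTRUE(bystander_linked),
                 per_base_error = per_base_error,
                 read_length = read_length, n_reads = as.integer(n_reads),
                 phred_mean = phred_mean, phred_sd = phred_sd,
                 fraction_low_quality = fraction_low_quality,
                 base_from = dna(base_from), base_to = dna(base_to),
                 quant = quant, seed = as.integer(seed)),
            class = "amplicon_sim_config")
}

.trunc_phred <- function(n, mean, sd) {
  pmin(41L, pmax(2L, as.integer(round(stats::rnorm(n, mean, sd)))))
}

.OTHER_BASES <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                     G = c("A", "C", "T"), T = c("A", "C", "G"))

#' Simulate single-end amplicon reads with ground truth
#'
#' Draws reads from plus-strand substrings of the amplicon covering the
#' quantification window; labels a Bernoulli(q) subset as edited and
#' installs the target conversion on those before applying bystander
#' co-edits and uniform per-base errors; assigns Phred qualities from the
#' configured model. Deterministic under the config seed.
#'
#' @param config [amplicon_sim_config()].
#' @param fastq_path Optional path; when given the reads are also written
#'   as FASTQ (".gz" compresses) and the manifest as JSON alongside
#'   (\code{<path>.manifest.json}).
#' @return List: \code{reads}
#'   ([Biostrings::QualityScaledDNAStringSet]) and \code{manifest} (list
#'   with per-read truth labels, realized edit fraction, seed and config
#'   echo).
#' @export
simulate_amplicon_reads <- function(config, fastq_path = NULL) {
  amp <- config$amplicon
  M <- nchar(amp)
  g <- config$guide
  L <- nchar(g$spacer)
  loc0 <- .locate_guide(g, amp)
  conv_from <- if (g$strand == "+") config$base_from else .complement_base(config$base_from)
  conv_to <- if (g$strand == "+") config$base_to else .complement_base(config$base_to)
  target_coord <- .proto_to_amplicon(g$target_position, loc0, L, g$strand)

  qc <- config$quant
  pp <- seq.int(qc$window_center - qc$window_halfwidth,
                qc$window_center + qc$window_halfwidth)
  W <- vapply(pp, .proto_to_amplicon, 0L, loc0 = loc0, L = L, strand = g$strand)
  W <- W[W >= 1L & W <= M]
  wlo <- min(W); whi <- max(W)

  by_pos <- as.integer(names(config$bystander_fractions))
  by_coord <- vapply(by_pos, .proto_to_amplicon, 0L, loc0 = loc0, L = L,
                     strand = g$strand)
  by_to <- conv_to  # bystander co-edits are the same conversion chemistry

  withr::with_seed(config$seed, {
    n <- config$n_reads
    lens <- if (is.null(config$read_length))
      pmin(M, sample(220:280, n, replace = TRUE))
    else rep(as.integer(config$read_length), n)
    if (any(lens < whi - wlo + 1L))
      stop("read length shorter than the quantification window")
    start_lo <- pmax(1L, whi - lens + 1L)
    start_hi <- pmin(wlo, M - lens + 1L)
    if (any(start_hi < start_lo))
      stop("amplicon too short for reads to cover the quantification window")
    starts <- start_lo +
      floor(stats::runif(n) * (start_hi - start_lo + 1L))
    edited <- stats::runif(n) < config$edit_fraction
    low_q <- stats::runif(n) < config$fraction_low_quality

    seqs <- character(n)
    quals <- character(n)
    by_table <- matrix(FALSE, n, length(by_pos))
    for (i in seq_len(n)) {
      ri <- utf8ToInt(substr(amp, starts[i], starts[i] + lens[i] - 1L))
      tpos <- target_coord - starts[i] + 1L
      if (edited[i]) ri[tpos] <- utf8ToInt(conv_to)
      if (length(by_pos)) {
        eligible <- if (config$bystander_linked) edited[i] else TRUE
        for (bj in seq_along(by_pos)) {
          bp <- by_coord[bj] - starts[i] + 1L
          if (eligible && bp >= 1L && bp <= lens[i] &&
              stats::runif(1) < config$bystander_fractions[bj]) {
            ri[bp] <- utf8ToInt(by_to)
            by_table[i, bj] <- TRUE
          }
        }
      }
      if (config$per_base_error > 0) {
        err <- which(stats::runif(lens[i]) < config$per_base_error)
        for (e in err) {
          b <- intToUtf8(ri[e])
          ri[e] <- utf8ToInt(sample(.OTHER_BASES[[b]], 1L))
        }
      }
      seqs[i] <- intToUtf8(ri)
      qm <- if (low_q[i]) 25 else config$phred_mean
      quals[i] <- intToUtf8(.trunc_phred(lens[i], qm, config$phred_sd) + 33L)
    }
  })

  ids <- sprintf("read_%06d", seq_len(config$n_reads))
  reads <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(seqs, ids)),
    Biostrings::PhredQuality(quals))
  manifest <- list(
    seed = config$seed,
    n_reads = config$n_reads,
    realized_edit_fraction = sum(edited) / config$n_reads,
    target_amplicon_position = target_coord,
    conversion = sprintf("%s>%s (plus strand)", conv_from, conv_to),
    per_read = data.frame(id = ids, edited = edited,
                          intended_low_quality = low_q,
                          start = starts, length = lens,
                          stringsAsFactors = FALSE),
    bystander_labels = if (length(by_pos)) {
      colnames(by_table) <- as.character(by_pos); by_table
    } else NULL,
    config = config[setdiff(names(config), c("amplicon", "guide", "quant"))],
    amplicon_nchar = M)
  if (!is.null(fastq_path)) {
    write_fastq(reads, fastq_path)
    jsonlite::write_json(
      manifest[c("seed", "n_reads", "realized_edit_fraction",
                 "target_amplicon_position", "conversion", "config")],
      paste0(fastq_path, ".manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  list(reads = reads, manifest = manifest)
}

#' Simulate ddPCR partition counts
#'
#' Each partition's occupancy is Poisson with the channel's mean; a
#' partition is positive when occupancy is at least 1. Channels are
#' independent.
#'
#' @param lambda_target,lambda_reference Mean copies per partition.
#' @param n_partitions Number of accepted partitions.
#' @param seed Integer seed.
#' @return List: \code{n_partitions}, \code{n_positive_target},
#'   \code{n_positive_reference}, \code{truth} (the input lambdas and
#'   ratio), \code{seed}.
#' @export
simulate_ddpcr <- function(lambda_target, lambda_reference, n_partitions,
                           seed = 1L) {
  if (lambda_target < 0 || lambda_reference < 0)
    stop("lambda must be non-negative")
  withr::with_seed(seed, {
    pos_t <- sum(stats::rpois(n_partitions, lambda_target) >= 1L)
    pos_r <- sum(stats::rpois(n_partitions, lambda_reference) >= 1L)
  })
  list(n_partitions = as.integer(n_partitions),
       n_positive_target = pos_t, n_positive_reference = pos_r,
       truth = list(lambda_target = lambda_target,
                    lambda_reference = lambda_reference,
                    ratio = if (lambda_reference > 0)
                      lambda_target / lambda_reference else NA_real_),
       seed = as.integer(seed))
}

#' Simulate a multi-copy cell population
#'
#' Each cell carries \code{n_copies} independently edited copies
#' (Bernoulli(q)); a cell is reporter-positive when at least one copy is
#' edited.
#'
#' @param q Per-copy edited fraction.
#' @param n_copies Copies per cell (default 6).
#' @param n_cells Number of cells.
#' @param seed Integer seed.
#' @return List: \code{allele_fraction} (empirical per-copy fraction),
#'   \code{cell_positive_fraction}, \code{n_cells}, \code{n_copies},
#'   \code{seed}.
#' @export
simulate_cell_population <- function(q, n_copies = 6L, n_cells = 1e5,
                                     seed = 1L) {
  stopifnot(q >= 0, q <= 1, n_copies >= 1)
  withr::with_seed(seed, {
    edited_per_cell <- stats::rbinom(n_cells, n_copies, q)
  })
  list(allele_fraction = sum(edited_per_cell) / (n_cells * n_copies),
       cell_positive_fraction = mean(edited_per_cell >= 1L),
       n_cells = as.integer(n_cells), n_copies = as.integer(n_copies),
       seed = as.integer(seed))
}
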