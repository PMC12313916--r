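# Stop-switch design: enumerate CBE-installable premature termination
# codons in an ORF, design ABE reversion guides, annotate bystanders and
# rank candidates.

# Single C->T edits (on either strand) that convert a sense codon into a
# stop. Offsets are 1-based within the codon; strand is the strand carrying
# the C->T change ("-" means the coding-strand base is G and changes to A).
.STOP_SWITCH_RULES <- data.frame(
  wt_codon        = c("CGA", "CAA", "CAG", "TGG", "TGG"),
  installed_codon = c("TGA", "TAA", "TAG", "TAG", "TGA"),
  offset          = c(1L, 1L, 1L, 2L, 3L),
  strand          = c("+", "+", "+", "-", "-"),
  stringsAsFactors = FALSE
)

#' Apply a single-base edit
#'
#' @param seq Input sequence (plus strand).
#' @param position 1-based position of the edited base on the plus strand.
#' @param from_base,to_base The substitution, expressed on \code{strand}.
#' @param strand Strand carrying the edit; a minus-strand C->T is applied
#'   as G->A on the stored plus strand.
#' @return The edited sequence (plus strand).
#' @examples
#' apply_edit("ATGCAG", 4, "C", "T", "+")
#' @export
apply_edit <- function(seq, position, from_base, to_base, strand = "+") {
  s <- dna(seq)
  strand <- match.arg(strand, c("+", "-"))
  position <- as.integer(position)
  if (position < 1L || position > nchar(s))
    stop("position ", position, " out of bounds")
  from_base <- dna(from_base); to_base <- dna(to_base)
  f <- if (strand == "+") from_base else .complement_base(from_base)
  t <- if (strand == "+") to_base else .complement_base(to_base)
  have <- substr(s, position, position)
  if (have != f)
    stop("base at position ", position, " is ", have, " on the plus strand, ",
         "expected ", f, " (", from_base, " on strand ", strand, ")")
  substr(s, position, position) <- t
  s
}

#' Enumerate CBE-installable stop codons in a coding sequence
#'
#' Screens every codon of the CDS for the four sense codons one C->T edit
#' away from a stop (CGA, CAA, CAG on the coding strand; TGG via the
#' antisense C). A codon becomes a candidate when at least one install
#' guide exists under \code{install_profile}, i.e. the edited base sits in
#' the editing window of a protospacer with a matching PAM. When
#' \code{revert_profiles} are supplied, reversion guides are designed on
#' the edited CDS for each, and \code{min_reversion_bystanders} is the
#' minimum in-window bystander count over the guides of the first (default)
#' reversion profile.
#'
#' @param cds Coding sequence (length divisible by 3).
#' @param install_profile A CBE-type [editor_profile()] (C->T).
#' @param revert_profiles List of ABE-type profiles (first = default used
#'   for bystander ranking); \code{NULL} to skip reversion design.
#' @param max_codon Optional cap on codon index (the screen itself applies
#'   no 5'-proximity filter; reports carry codon_index so callers can).
#' @return List of \code{stop_switch_candidate} objects sorted by
#'   (codon_index, edit_cds_position).
#' @examples
#' fx <- egfp_fixtures()
#' cands <- enumerate_stop_switch_sites(fx$wt_cds,
#'   editor_profiles("be4max_sp_ng"), list(editor_profiles("abe8e_sp")))
#' @export
enumerate_stop_switch_sites <- function(cds, install_profile,
                                        revert_profiles = NULL,
                                        max_codon = NULL) {
  s <- dna(cds)
  if (nchar(s) %% 3L != 0L) stop("CDS length not divisible by 3")
  if (install_profile$base_from != "C" || install_profile$base_to != "T")
    stop("install profile must be CBE-type (C->T); got ",
         install_profile$base_from, "->", install_profile$base_to)
  n_codons <- nchar(s) %/% 3L
  out <- list()
  for (k in seq_len(n_codons)) {
    codon <- substr(s, 3L * k - 2L, 3L * k)
    rules <- .STOP_SWITCH_RULES[.STOP_SWITCH_RULES$wt_codon == codon, ]
    if (nrow(rules) == 0L) next
    if (!is.null(max_codon) && k > max_codon) next
    for (r in seq_len(nrow(rules))) {
      pos <- 3L * (k - 1L) + rules$offset[r]  # 1-based CDS coordinate
      guides <- find_protospacers(s, pos - 1L, install_profile)
      if (length(guides) == 0L) next
      cand <- structure(
        list(codon_index = k, wt_codon = codon,
             installed_codon = rules$installed_codon[r],
             edit_cds_position = pos, edit_strand = rules$strand[r],
             install_profile = install_profile$name,
             install_guides = guides,
             reversion_guides = list(),
             min_reversion_bystanders = NA_integer_),
        class = "stop_switch_candidate")
      if (!is.null(revert_profiles)) {
        mut <- apply_edit(s, pos, "C", "T", rules$strand[r])
        rg <- lapply(revert_profiles, function(p)
          design_reversion_guides(mut, cand, p))
        names(rg) <- vapply(revert_profiles, function(p) p$name, "")
        cand$reversion_guides <- rg
        g0 <- rg[[1]]
        cand$min_reversion_bystanders <-
          if (length(g0) == 0L) NA_integer_
          else min(vapply(g0, function(g) length(g$bystander_positions), 0L))
      }
      out[[length(out) + 1L]] <- cand
    }
  }
  ord <- order(vapply(out, function(x) x$codon_index, 0L),
               vapply(out, function(x) x$edit_cds_position, 0L))
  out[ord]
}

#' @export
print.stop_switch_candidate <- function(x, ...) {
  cat(sprintf(
    "<stop_switch_candidate> codon %d %s->%s, edit c.%d (%s strand), %d install / %s reversion guides, min bystanders %s\n",
    x$codon_index, x$wt_codon, x$installed_codon, x$edit_cds_position,
    x$edit_strand, length(x$install_guides),
    paste(vapply(x$reversion_guides, length, 0L), collapse = "+"),
    x$min_reversion_bystanders))
  invisible(x)
}

#' Design ABE reversion guides for an installed stop codon
#'
#' On the mutant CDS, enumerates every protospacer (both strands) that
#' places the revertible adenine -- the A created by, or base-paired with,
#' the installed T -- inside the ABE profile's editing window with a
#' matching PAM.
#'
#' @param mutant Mutant CDS carrying the installed stop.
#' @param candidate A \code{stop_switch_candidate}.
#' @param revert_profile An ABE-type [editor_profile()] (A->G).
#' @return List of [guide_design()] objects.
#' @export
design_reversion_guides <- function(mutant, candidate, revert_profile) {
  s <- dna(mutant)
  if (revert_profile$base_from != "A" || revert_profile$base_to != "G")
    stop("reversion profile must be ABE-type (A->G); got ",
         revert_profile$base_from, "->", revert_profile$base_to)
  k <- candidate$codon_index
  have <- substr(s, 3L * k - 2L, 3L * k)
  if (have != candidate$installed_codon)
    stop("mutant codon ", k, " is ", have, ", expected installed codon ",
         candidate$installed_codon)
  find_protospacers(s, candidate$edit_cds_position - 1L, revert_profile)
}

#' Count and annotate bystander bases of a guide
#'
#' Counts the editable bases inside the profile window other than the
#' target, and annotates each (and the target) with the coding consequence
#' of its single-base conversion, recomputed by translation of the edited
#' context.
#'
#' @param guide A [guide_design()] placed on \code{context}.
#' @param profile The [editor_profile()] the guide was designed under.
#' @param context The sequence the guide is placed on; consequence
#'   annotation assumes it is a CDS in frame from position 1.
#' @return List with \code{n_bystanders} (integer) and \code{annotations}
#'   (data.frame: protospacer_position, cds_position, codon_index,
#'   is_target, consequence, residue_change).
#' @export
count_bystanders <- function(guide, profile, context) {
  s <- dna(context)
  L <- nchar(guide$spacer)
  a <- guide$protospacer_start
  covered <- substr(s, a + 1L, a + L)
  observed <- if (guide$strand == "+") covered else revcomp(covered)
  if (observed != guide$spacer)
    stop("guide does not match context at protospacer_start ", a)
  win <- seq.int(profile$window_start, profile$window_end)
  chars <- strsplit(guide$spacer, "")[[1]]
  editable <- win[chars[win] == profile$base_from]
  bys <- setdiff(editable, guide$target_position)

  ann <- do.call(rbind, lapply(editable, function(p) {
    coord <- .guide_pos_to_coord(guide, p) + 1L  # 1-based
    k <- (coord - 1L) %/% 3L + 1L
    edited <- apply_edit(s, coord, profile$base_from, profile$base_to,
                         guide$strand)
    cons <- .codon_consequence(s, edited, k)
    data.frame(protospacer_position = p, cds_position = coord,
               codon_index = k, is_target = p == guide$target_position,
               consequence = cons$consequence,
               residue_change = cons$residue_change,
               stringsAsFactors = FALSE)
  }))
  if (is.null(ann))
    ann <- data.frame(protospacer_position = integer(), cds_position = integer(),
                      codon_index = integer(), is_target = logical(),
                      consequence = character(), residue_change = character(),
                      stringsAsFactors = FALSE)
  list(n_bystanders = length(bys), annotations = ann)
}

.codon_consequence <- function(ref, edited, codon_index) {
  lo <- 3L * codon_index - 2L; hi <- 3L * codon_index
  if (hi > nchar(ref))  # edit outside the in-frame part of the context
    return(list(consequence = "non_coding", residue_change = NA_character_))
  aa_ref <- translate_cds(substr(ref, lo, hi))
  aa_new <- translate_cds(substr(edited, lo, hi))
  cons <-
    if (aa_ref == aa_new) "synonymous"
    else if (aa_new == "*") "nonsense"
    else if (aa_ref == "*") "stop_loss"
    else "missense"
  list(consequence = cons,
       residue_change = sprintf("%s%d%s", aa_ref, codon_index, aa_new))
}

#' Rank stop-switch candidates
#'
#' Ascending by \code{min_reversion_bystanders}; ties broken by the number
#' of orthologue profiles with at least one valid reversion guide (more is
#' better), then by smaller codon index. Candidates with no reversion
#' guide under any profile rank last, flagged.
#'
#' @param candidates List of \code{stop_switch_candidate} objects.
#' @return The list, reordered; each element gains \code{no_reversion}.
#' @export
rank_candidates <- function(candidates) {
  if (length(candidates) == 0L) return(candidates)
  bys <- vapply(candidates, function(x)
    ifelse(is.na(x$min_reversion_bystanders), Inf,
           as.numeric(x$min_reversion_bystanders)), 0)
  northo <- vapply(candidates, function(x)
    sum(vapply(x$reversion_guides, length, 0L) > 0L), 0L)
  idx <- vapply(candidates, function(x) as.numeric(x$codon_index), 0)
  ord <- order(is.infinite(bys), bys, -northo, idx)
  out <- candidates[ord]
  lapply(out, function(x) { x$no_reversion <- is.na(x$min_reversion_bystanders); x })
}

#' Candidate list as a data frame
#'
#' One row per candidate with its best reversion guide under the default
#' profile, suitable for TSV reports.
#'
#' @param candidates List of \code{stop_switch_candidate} objects.
#' @return data.frame.
#' @export
candidates_table <- function(candidates) {
  do.call(rbind, lapply(candidates, function(x) {
    ig <- x$install_guides[[1]]
    g0 <- if (length(x$reversion_guides)) x$reversion_guides[[1]] else list()
    best <- if (length(g0)) g0[[which.min(vapply(g0, function(g)
      length(g$bystander_positions), 0L))]] else NULL
    ortho <- names(x$reversion_guides)[vapply(x$reversion_guides, length, 0L) > 0L]
    data.frame(
      codon_index = x$codon_index, wt_codon = x$wt_codon,
      installed_codon = x$installed_codon,
      edit_cds_position = x$edit_cds_position, edit_strand = x$edit_strand,
      install_profile = x$install_profile,
      install_spacer = ig$spacer, install_pam = ig$pam_seq,
      revert_spacer = if (is.null(best)) NA_character_ else best$spacer,
      revert_target_position = if (is.null(best)) NA_integer_ else best$target_position,
      min_reversion_bystanders = x$min_reversion_bystanders,
      orthologue_flags = paste(ortho, collapse = ","),
      stringsAsFactors = FALSE)
  }))
}
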