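#!/usr/bin/env Rscript
# Stop-switch design screen on the EGFP coding sequence: enumerate every
# codon a single C->T edit away from a premature termination codon that a
# CBE can reach, design ABE reversion guides, and rank by bystander load.

suppressPackageStartupMessages(library(stopswitch))
dir.create("results", showWarnings = FALSE)

fx <- egfp_fixtures()
revert_profiles <- list(editor_profiles("abe8e_sp"), editor_profiles("sa_abe8e"),
                        editor_profiles("sauri_abe"))

cands <- enumerate_stop_switch_sites(fx$wt_cds, editor_profiles("be4max_sp_ng"),
                                     revert_profiles)
ranked <- rank_candidates(cands)
tab <- candidates_table(ranked)
write.table(tab, "results/candidates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("screened %d codons; %d installable stop-switch candidates\n",
            nchar(fx$wt_cds) / 3, length(ranked)))
top <- ranked[[1]]
cat(sprintf(
  "top candidate: codon %d (%s->%s), edit c.%d, install spacer %s, %d reversion bystanders\n",
  top$codon_index, top$wt_codon, top$installed_codon, top$edit_cds_position,
  top$install_guides[[1]]$spacer, top$min_reversion_bystanders))
ortho <- names(top$reversion_guides)[vapply(top$reversion_guides, length, 0L) > 0]
cat("orthologues with a valid reversion guide:", paste(ortho, collapse = ", "), "\n")
cat("full table in results/candidates.tsv\n")
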