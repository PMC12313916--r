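#!/usr/bin/env Rscript
# Reversion-guide design for the installed stop codon: every ABE
# protospacer placing the revertible adenine in the editing window, with
# per-position bystander annotation, across Cas9 orthologues.

suppressPackageStartupMessages(library(stopswitch))
dir.create("results", showWarnings = FALSE)

fx <- egfp_fixtures()
cands <- enumerate_stop_switch_sites(fx$wt_cds, editor_profiles("be4max_sp_ng"))
c81 <- Filter(function(x) x$codon_index == fx$stop_codon_index, cands)[[1]]

rows <- list()
for (pname in c("abe8e_sp", "sa_abe8e", "sauri_abe")) {
  prof <- editor_profiles(pname)
  for (g in design_reversion_guides(fx$q81x_cds, c81, prof)) {
    b <- count_bystanders(g, prof, fx$q81x_cds)
    rows[[length(rows) + 1]] <- data.frame(
      profile = pname, spacer = g$spacer, strand = g$strand,
      pam = g$pam_seq, target_position = g$target_position,
      n_bystanders = b$n_bystanders,
      bystander_consequences = paste(
        b$annotations$residue_change[!b$annotations$is_target], collapse = ","),
      window_is_default = prof$window_default)
  }
}
tab <- do.call(rbind, rows)
write.table(tab, "results/reversion_guides.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("designed %d reversion guides for the codon-%d stop\n",
            nrow(tab), c81$codon_index))
print(tab[, c("profile", "spacer", "target_position", "n_bystanders")])
cat("guides with zero in-window bystanders:",
    sum(tab$n_bystanders == 0), "\n")
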