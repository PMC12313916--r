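#!/usr/bin/env Rscript
# Multi-copy reporter activation model: with six EGFP copies per diploid
# genome, the fraction of fluorescent cells exceeds the edited-allele
# fraction (f = 1 - (1-q)^6 under independent editing). Tabulates the
# model curve, verifies it against simulated cell populations, and
# inverts measured cell fractions back to allele fractions.

suppressPackageStartupMessages(library(stopswitch))
dir.create("results", showWarnings = FALSE)

n_copies <- 6L
qs <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5)
rows <- lapply(seq_along(qs), function(i) {
  q <- qs[i]
  pop <- simulate_cell_population(q, n_copies = n_copies, n_cells = 1e5,
                                  seed = 100 + i)
  data.frame(
    allele_fraction = q,
    model_cell_fraction = cell_positive_fraction(q, n_copies),
    simulated_cell_fraction = pop$cell_positive_fraction,
    recovered_allele_fraction =
      allele_fraction_from_cells(pop$cell_positive_fraction, n_copies))
})
tab <- do.call(rbind, rows)
write.table(format(tab, digits = 4), "results/activation_model.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("activation model, %d copies per cell (100,000 simulated cells per row):\n",
            n_copies))
print(tab, digits = 3, row.names = FALSE)
cat(sprintf("max |recovered - true| allele fraction: %.4f\n",
            max(abs(tab$recovered_allele_fraction - tab$allele_fraction))))
cat("the cell-positive fraction always exceeds the allele fraction:",
    all(tab$model_cell_fraction > tab$allele_fraction), "\n")
cat("table in results/activation_model.tsv\n")
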