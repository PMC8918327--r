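#!/usr/bin/env Rscript
# Step 2 -- generate the synthetic ortholog family used downstream.
#
# Simulates the reference study conditions: 8 orthologs of length 800,
# two compositionally biased disordered spans, per-site background
# substitution 0.2, six conserved motif implants inside the disordered
# spans and four decoy implants in the ordered spans. Emits FASTA, the
# trivial alignment, the disorder annotation and the recomputed truth
# table under results/family/.

suppressMessages(library(sydescan))
out <- "results/family"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

params <- family_params(seed = 1)
fam <- simulate_family(params)

write_fasta(fam$records, file.path(out, "family.fasta"))
write_alignment(fam$msa, file.path(out, "family.aln.fasta"))
spans <- fam$truth$disordered_spans
write_region_table(
  data.frame(protein_id = "ortho1", label = "disorder",
             start = spans$start, end = spans$end, source = "generator"),
  file.path(out, "disorder.tsv"))
write.table(fam$truth$implants, file.path(out, "truth_implants.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(fam$truth$incidental, file.path(out, "truth_incidental.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "family of %d orthologs, length %d; %d implants (%d in disordered spans),\n",
  params$n_orthologs, params$length, nrow(fam$truth$implants),
  sum(fam$truth$implants$in_disordered_span)),
  sprintf("%d incidental background matches recorded; inputs in %s/\n",
          nrow(fam$truth$incidental), out))
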