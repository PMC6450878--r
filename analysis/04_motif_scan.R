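#!/usr/bin/env Rscript
# Scan the packaged integrin beta cytoplasmic tails for the
# membrane-proximal NPxY/F and membrane-distal NxxY/F motifs, and show
# that the point mutations Y783A (human beta-1) and the protozoan NPxF->A
# substitution erase the proximal hit.

library(opticr)

tails <- optic_tail_fixtures()
tab <- motif_presence_table(tails)
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/motif_presence.csv", row.names = FALSE)
print(tab, row.names = FALSE)

b1 <- tails$ITGB1
prox <- subset(find_motifs(b1), motif_class == "membrane_proximal")
message(sprintf("beta-1 proximal motif %s at %d-%d (terminal %s%d)",
                prox$sequence, prox$start, prox$end,
                prox$terminal_residue, prox$end))
mut <- apply_mutation(b1, "Y783A")
message(sprintf("after Y783A: %d membrane-proximal hit(s)",
                sum(find_motifs(mut)$motif_class == "membrane_proximal")))
cow <- apply_mutation(tails$ITGB2_Cow, "F22A")
message(sprintf("Capsaspora ITGB2 NPxF->NPxA: %d membrane-proximal hit(s)",
                sum(find_motifs(cow)$motif_class == "membrane_proximal")))
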