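#!/usr/bin/env Rscript
# The layered membrane-protein mimic: negative unit charges stacked in the
# 5 A slabs near one surface, positive near the other (the charge
# architecture type-II reaction centers show), with buried redox probes
# along the membrane normal.  The probes' Em must rise monotonically toward
# the positively charged side, and the shift decomposes into a
# depth-independent solvation-loss term plus the protein-charge term that
# carries the gradient.
suppressPackageStartupMessages(library(redoxpb))
dir.create("results", showWarnings = FALSE)

fx <- make_layered_protein(seed = 3)
en <- intrinsic_values(fx$structure, fx$sites, levels = c(2.5, 1.0))
prof <- em_profile(fx$structure, en)
write.csv(prof, "results/em_profile.csv", row.names = FALSE)
print(prof, row.names = FALSE)
cat(sprintf("Em rises monotonically with z: %s\n",
            all(diff(prof$Em_mV[order(prof$z)]) > 0)))
cat(sprintf("solvation term is flat (spread %.1f mV); the protein-charge term\n",
            diff(range(prof$solvation_shift_mV))))
cat(sprintf("carries the gradient (spread %.0f mV)\n",
            diff(range(prof$charge_shift_mV))))

# per-residue breakdown for the probe nearest the positive layers
top <- prof$site_id[which.max(prof$z)]
tab <- per_residue_contributions(en, top)
write.csv(tab, "results/per_residue_contributions.csv", row.names = FALSE)
cat(sprintf("\nlargest contributors to %s charge shift:\n", top))
print(head(tab, 5), row.names = FALSE)

# unit-charge bookkeeping in the 5 A surface slabs
tal <- region_charge_tally(fx$structure, fx$sites, interfaces = c(-20, 20))
write.csv(tal, "results/region_tally.csv", row.names = FALSE)
cat("\ncharged-group tally per 5 A layer (regions from each surface):\n")
print(tal, row.names = FALSE)

# control: with slab charges removed the probes are equivalent
fx0 <- make_layered_protein(seed = 3, slab_charges = rep(0, 8))
en0 <- intrinsic_values(fx0$structure, fx0$sites, levels = c(2.5, 1.0))
prof0 <- em_profile(fx0$structure, en0)
cat(sprintf("\ncontrol (no slab charges): Em spread %.1f mV -> the gradient\n",
            diff(range(prof0$Em_mV))))
cat("is carried entirely by the layered charges, not by burial depth.\n")
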