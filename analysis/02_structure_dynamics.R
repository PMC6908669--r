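#!/usr/bin/env Rscript
# Stage 2: structure-based dynamics of the synthetic module. Builds the ANM,
# reports per-residue RMSF and the cross-correlation map of the ten slowest
# modes, and annotates disulfide bridges and ion-contact residues. Also runs
# the ensemble (trajectory-like) route and compares the two RMSF profiles.

suppressMessages(library(reelmech))
outdir <- "results/structure"
res <- run_structure_pipeline("results/data/module_synthetic.pdb", outdir)

cat("ANM:", sum(res$modes$rigid), "rigid modes (connected network)\n")
cat("disulfide bridges detected:",
    paste(res$bridges$residue_a, "-", res$bridges$residue_b), "\n")

cmap <- res$correlation$matrix
cat(sprintf("correlation map: %.1f%% of pairs |C| > 0.5\n",
            100 * mean(abs(cmap[upper.tri(cmap)]) > 0.5)))

## ensemble route on the simulated trajectory
ens <- read_ensemble_pdb("results/data/ensemble_synthetic.pdb")
ens <- superpose_ensemble(ens)
r_ens <- rmsf_from_ensemble(ens)
r_mode <- rmsf_from_modes(pca_modes(ens, k = "all"))
write.table(data.frame(residue = ens$reference$residues$key,
                       rmsf_ensemble_A = signif(r_ens, 9),
                       rmsf_pca_A = signif(r_mode, 9)),
            file.path(outdir, "rmsf_ensemble.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("ensemble vs PCA-mode RMSF: max relative gap %.2g (identity)\n",
            max(abs(r_ens - r_mode) / pmax(r_ens, 1e-12))))
gt <- jsonlite::read_json("results/data/module_synthetic.json",
                          simplifyVector = TRUE)
inside <- unlist(lapply(seq_len(nrow(gt$crosslinks)), function(k)
  gt$crosslinks[k, 1]:gt$crosslinks[k, 2]))
cat(sprintf(paste0("mean ensemble RMSF %.2f A; interior (bridged) regions ",
                   "%.2f A vs %.2f A elsewhere — the slow modes concentrate ",
                   "motion at the free termini\n"),
            mean(r_ens), mean(r_ens[inside]), mean(r_ens[-inside])))
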