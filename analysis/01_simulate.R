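#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input the downstream analyses consume,
# with JSON ground-truth sidecars. Stand-ins for: a crystal-derived BEB
# module (bead chain with disulfide-like crosslinks and a Zn site), MD
# trajectories (Gaussian mode ensembles), AFM recordings (piecewise-WLC
# curves, incl. parallel-stretched dimers), and a cross-species alignment.

suppressMessages(library(reelmech))
seed <- 20260918
outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

## BEB-like module: 100 beads, two BNR-like crosslinked regions, one ion site
st <- make_bead_chain(100, "helix",
                      crosslinks = rbind(c(10, 35), c(60, 85)),
                      ions = data.frame(element = "ZN", residue = 50),
                      seed = seed)
write_structure_pdb(st, file.path(outdir, "module_synthetic.pdb"))
write_ground_truth(st, file.path(outdir, "module_synthetic.json"))

## trajectory stand-in: 500 frames over the 10 slowest ANM modes + rigid jitter
ms <- decompose_hessian(build_anm_hessian(st))
vars <- 1 / ms$values[!ms$rigid][1:10]
vars <- vars / max(vars) * 4
ens <- sample_ensemble(ms, vars, 500, st, rigid_jitter = TRUE, seed = seed + 1)
write_ensemble_pdb(ens, file.path(outdir, "ensemble_synthetic.pdb"))

## AFM stand-ins: 40 monomer curves (increments 20/40/60 nm, noise 8.5 pN)
## and 20 parallel-dimer curves (true increment 40 nm)
for (i in 1:40) {
  cv <- simulate_force_curve(seed = seed + 100 + i)
  write_force_curve(cv, file.path(outdir, sprintf("curve_mono_%02d.txt", i)))
}
for (i in 1:20) {
  cv <- simulate_force_curve(lc_schedule = c(30, 70), dimer_parallel = TRUE,
                             seed = seed + 200 + i)
  write_force_curve(cv, file.path(outdir, sprintf("curve_dimer_%02d.txt", i)))
}

## 67-sequence alignment with a conserved core and variable loops
length_aln <- 360
conservation <- rep(0.92, length_aln)
conservation[sample(length_aln, 60)] <- 0.6   # variable columns
m <- simulate_msa(n_seqs = 67, length = length_aln,
                  conservation = conservation, seed = seed + 300)
write_msa_fasta(m, file.path(outdir, "alignment_synthetic.fasta"))

cat("wrote synthetic inputs to", outdir, ":\n ",
    paste(list.files(outdir)[1:6], collapse = "\n  "), "\n  ...",
    length(list.files(outdir)), "files total\n")
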