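#!/usr/bin/env Rscript
## Stage 1: biased sampling.
## (a) Validation system: standard metadynamics on the 1-D double well
##     (barrier 20 kJ/mol) with production-style hills (1.0 kJ/mol every
##     0.5 ps), three independent seeds.
## (b) Study system: the 2-CV synthetic unbinding landscape (bound basin,
##     transition state, intermediate, exit channel), run until the
##     distance CV passes the 4.0 nm unbinding reference.
## Outputs PLUMED-style HILLS and COLVAR files under results/sim/.

suppressPackageStartupMessages(library(metafes))
seed <- if (length(commandArgs(TRUE)) >= 1) as.integer(commandArgs(TRUE)[1]) else 1L
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)

## (a) double well, three seeds -------------------------------------------
pot_dw <- make_double_well(barrier = 20, well_separation = 2)
prm_dw <- meta_params(height = 1.0, widths = 0.1, pace = 0.5)
for (s in 1:3) {
  run <- run_metadynamics(pot_dw, prm_dw, dt = 0.002, friction = 50,
                          temperature = 300, n_steps = 20000L * 250L,
                          seed = seed + s, x0 = -1)
  write_hills(run$hills, sprintf("results/sim/dw_hills_seed%d.dat", s))
  write_colvar(run$colvar, sprintf("results/sim/dw_colvar_seed%d.dat", s))
  cat(sprintf("double well seed %d: %d hills over %.1f ns\n",
              s, nrow(run$hills), max(run$hills$time) / 1000))
}

## (b) 2-CV unbinding landscape -------------------------------------------
pot <- make_unbinding_landscape(barrier_BTs = 20)
prm <- meta_params(height = 1.0, widths = c(0.05, 50), pace = 0.5)
run <- run_metadynamics(pot, prm, dt = 0.002, friction = 20,
                        temperature = 100, n_steps = 4e6,
                        seed = seed, x0 = pot$minima$B$cv,
                        mass = c(5, 1e-4))
write_hills(run$hills, "results/sim/unbind_hills.dat")
write_colvar(run$colvar, "results/sim/unbind_colvar.dat")
esc <- which(run$colvar$cv_1 >= 4.0)[1]
cat(sprintf("unbinding run: %d hills; 4.0 nm reference reached at %s ps\n",
            nrow(run$hills),
            if (is.na(esc)) "never" else format(run$colvar$time[esc])))
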