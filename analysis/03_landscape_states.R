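#!/usr/bin/env Rscript
## Stage 3: basins, states and the minimum-energy path.
## Minima are counted on the surface smoothed at the hill-width resolution
## and filtered by topographic prominence; shallow deposition dips merge
## into their parent basins.  Frames within 20 kJ/mol of their basin
## minimum are assigned to it; the B -> I minimax path gives the
## activation energy and the reaction-coordinate profile.

suppressPackageStartupMessages(library(metafes))
dir.create("results/landscape", showWarnings = FALSE, recursive = TRUE)

fes <- read_fes("results/fes/unbind_fes.tsv")
colvar <- read_colvar("results/sim/unbind_colvar.dat")
names(colvar) <- c("time", "cv_1", "cv_2")

fes_s <- fes_smooth(fes, c(0.05, 50))
raw <- suppressWarnings(find_minima(fes_s))
sig <- significant_minima(fes_s)
cat(sprintf("%d raw minima -> %d deep minima (prominence >= 4 kJ/mol):\n",
            nrow(raw), nrow(sig)))
print(sig[, c("label", "cv1", "cv2", "energy", "prominence")])

basins <- merge_basins(fes_s, suppressWarnings(basin_assign(fes_s, raw)), sig)
states <- assign_frames(colvar, fes_s, basins, cutoff = 20)
write.table(states, "results/landscape/states.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(table(states$state, useNA = "ifany"))

mep <- minimum_energy_path(fes_s, basins, "B", "I")
prof <- profile_along_path(mep)
write.table(mep$path[, c("s", "cv1", "cv2", "energy")],
            "results/landscape/mep_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("dG*(B -> Ts) = %.2f kJ/mol (saddle at s = %.3f); generator barrier 20\n",
            mep$activation, mep$path$s[mep$saddle_index]))
esc <- escape_barrier(fes_s)
cat(sprintf("minimax escape barrier from B: %.2f kJ/mol\n", esc$activation))
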