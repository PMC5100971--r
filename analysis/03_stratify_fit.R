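#!/usr/bin/env Rscript
# Step 3 -- stratify patients and fit per-type parameter deregulations.
#
# Classifies every patient by the Th1/Th2 sign rule (T-bet and GATA-3
# relative to healthy means) and then solves the inverse problem: which
# fractional changes of the ten varied production/activation rates move
# the healthy equilibrium to each type's observed fold-change pattern.
# With the Treg production pair tied, the 7-target problem is identifiable
# and the fits land on the published deregulation table's sign pattern for
# every type (near-exact magnitudes for Types 1, 2 and 4; Type 3 matches
# its targets equally well at a different nu_gamma_1/sigma_21 trade-off,
# the expected underdetermination).

library(ibdimmune)
outdir <- "results"

run_pipeline(pipeline_config(outdir = outdir,
                             stages = c("cohort", "classify", "fit_types"),
                             seed = 1))

cat("\nAssigned type counts:\n")
print(utils::read.csv(file.path(outdir, "type_counts.csv")))
cat("\nFitted per-type parameter variations:\n")
fits <- utils::read.csv(file.path(outdir, "type_parameter_fits.csv"))
print(cbind(fits["type"], round(fits[setdiff(names(fits), c("type", "loss"))], 3),
            loss = signif(fits$loss, 2)))
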