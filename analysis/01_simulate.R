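#!/usr/bin/env Rscript
# Stage 1: generate the synthetic hominid-like craniometric sample that the
# rest of the workflow analyses, and write it out with its latent sizes.
# Four extant species (adults + juveniles) share one ontogenetic allometry;
# a human-like group is laterally transposed toward a larger relative
# neurocranium; two fossil groups differ in how endocranial volume couples
# to cranial size.

library(craniomod)

seed <- 1L
dir.create("results", showWarnings = FALSE)

ds <- simulate_hominid_sample(seed = seed)
write_craniometric_csv(ds, "results/synthetic_sample.csv")
write.csv(attr(ds, "latent"), "results/synthetic_latent_sizes.csv",
          row.names = FALSE)

cat(sprintf("wrote %d specimens (%d adults, %d juveniles) in %d groups\n",
            nrow(ds), sum(ds$age_class == "adult"),
            sum(ds$age_class == "juvenile"), length(unique(ds$group))))
cat("seed:", seed, "\n")
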