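#!/usr/bin/env Rscript
# Stage 1: generate the synthetic herd that stands in for the study
# population: 739 offspring of 101 dams x 72 sires, 199 genotyped (one male
# and one female per litter), 707 with gut-microbiota profiles, two birth
# batches, two diets.  Marker and ASV panels are desk-scale stand-ins.

library(microgblup)

seed <- 2024L
out <- "results/simdata"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

truth <- true_params(var_a = 0.5, var_m = 0.05, var_p = 0.1, var_e = 0.35,
                     mu = 10)
herd <- simulate_herd(herd_design(), truth, n_snps = 3000, n_asvs = 400,
                      depth = 5000, seed = seed)

write_pedigree(herd$ped, file.path(out, "pedigree.csv"))
write_genotypes(herd$geno, file.path(out, "genotypes.tsv"))
write_counts(herd$counts, file.path(out, "asv_counts.tsv"))
write.csv(herd$pheno, file.path(out, "phenotypes.csv"), row.names = FALSE)
jsonlite::write_json(
  list(seed = seed, var_a = truth$var_a, var_m = truth$var_m,
       var_p = truth$var_p, var_e = truth$var_e, mu = truth$mu,
       fixed_effects = as.list(truth$fixed_effects)),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

message("herd: ", nrow(herd$ped), " animals (",
        sum(!herd$ped$founder), " phenotyped offspring), ",
        nrow(herd$geno), " genotyped, ", nrow(herd$counts),
        " with microbiota")
message("true variance fractions: h2 = ",
        round(truth$var_a / (truth$var_a + truth$var_p + truth$var_e), 3),
        ", m2 = ",
        round(truth$var_m / (truth$var_m + truth$var_p + truth$var_e), 3))
message("wrote ", out)
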