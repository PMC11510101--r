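#!/usr/bin/env Rscript
# Stage 3: build the relationship matrices from stage-1 files: pedigree A,
# its genotyped submatrix A22, the VanRaden genomic matrix G (5% blended
# with A22 so it is invertible), the single-step H-inverse, and the
# microbial matrix O from the ASV counts.

library(microgblup)

ind <- "results/simdata"
out <- "results/matrices"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ped <- read_pedigree(file.path(ind, "pedigree.csv"))
geno <- read_genotypes(file.path(ind, "genotypes.tsv"))
counts <- read_counts(file.path(ind, "asv_counts.tsv"))

hh <- build_H(ped, geno, blend_weight = 0.05)
mb <- microbiome_pipeline(counts, depth = min(rowSums(counts)),
                          min_prevalence = 0.20, pseudocount = 1, seed = 1)

message(sprintf("A: %d animals, mean diagonal %.4f", nrow(hh$A),
                mean(diag(hh$A))))
message(sprintf("G: %d genotyped, mean diagonal %.4f", nrow(hh$G),
                mean(diag(hh$G))))
message(sprintf("O: %d animals x %d retained ASVs, trace/n = %.6f",
                nrow(mb$O), ncol(mb$M), sum(diag(mb$O)) / nrow(mb$O)))

write_matrix(hh$A22, file.path(out, "A22.tsv"))
write_matrix(hh$G, file.path(out, "G.tsv"))
write_matrix(hh$H_inv, file.path(out, "H_inv.tsv"))
write_matrix(hh$H, file.path(out, "H.tsv"))
write_matrix(mb$O, file.path(out, "O.tsv"))
message("wrote ", out)
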