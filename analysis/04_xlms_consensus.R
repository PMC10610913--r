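#!/usr/bin/env Rscript
# Stage 4: cross-link filtering, replicate consensus and structural
# compatibility.
#
# Generates five replicate cross-link identification tables with planted
# residue pairs and decoys, applies the post-search filter and the 5-of-5
# consensus rule, counts N-terminal links, then scores the consensus map's
# geometric compatibility (<30 A Calpha-Calpha) against a planted
# four-conformer ensemble clustered by k-medoids on superposed RMSD.

suppressMessages(library(aggscan))
dir.create("results/xlms", showWarnings = FALSE, recursive = TRUE)

xl <- simulate_xlms(seed = 0L)
write_xlinks_tsv(xl$ids, "results/xlms/identifications.tsv")
filt <- filter_xlinks(xl$ids)
cat(sprintf("filter: %d of %d identifications pass\n", nrow(filt),
            nrow(xl$ids)))
cons <- consensus_links(filt)
print(cons)
write.table(cons$pairs, "results/xlms/consensus_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

nterm <- region_link_count(cons, c(1L, 35L))
cat(sprintf("N-terminal (1-35) links: mean frequency %.1f over %d pairs\n",
            nterm, attr(nterm, "n_pairs")))

ens_sim <- simulate_ensemble(seed = 0L)
write_ensemble_pdb(ens_sim$ensemble, "scratch/ensemble_synthetic.pdb",
                   aa = asyn_cds()$aa)
ens <- read_ensemble_pdb("scratch/ensemble_synthetic.pdb")
cl <- cluster_region(ens, region = c(1L, 35L), k = 4L)
cat("cluster occupancies:", sprintf("%.1f%%", 100 * cl$occupancy), "\n")

comp <- lapply(cl$medoids, function(m)
  xlink_compatibility(cons, ens$models[[m]], cutoff = 30))
comp_tab <- data.frame(cluster = seq_along(cl$medoids),
                       occupancy = cl$occupancy,
                       medoid_model = cl$medoids,
                       n_compatible = vapply(comp, `[[`, integer(1L),
                                             "n_compatible"),
                       n_total = vapply(comp, `[[`, integer(1L), "n_total"))
write.table(comp_tab, "results/xlms/cluster_compatibility.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(comp_tab)
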