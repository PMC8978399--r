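#!/usr/bin/env Rscript
# Build the reference set of synthetic contigs used by the downstream
# analyses: one contig carrying reconstructions of the five described Jozin
# element families (complete ends) and one contig carrying the
# satellite-bearing, subTIR-only element. Each element is embedded in
# random background with a 3-bp target-site duplication, and exact ground
# truth (GFF3 + DANTE-style hit table) is written alongside the FASTA.

library(cactascan)

out <- file.path("results", "simulation")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

families <- c("pamiricum", "sosnowskyi", "iljinii", "vulvaria",
              "quinoa_scaffold3500")
elements <- lapply(seq_along(families), function(i)
  build_element(jozin_element_spec(families[i], seed = 100 + i)))
emb1 <- embed_in_background(elements, bg_len = 120000, gc = 0.37, seed = 11,
                            contig_id = "synth_families")

sat_el <- build_element(jozin_element_spec("quinoa_scaffold3389", seed = 200))
emb2 <- embed_in_background(list(sat_el), bg_len = 40000, gc = 0.37,
                            seed = 12, contig_id = "synth_satellite")

write_fasta(c(stats::setNames(emb1$seq, emb1$id),
              stats::setNames(emb2$seq, emb2$id)),
            file.path(out, "contigs.fa"))
write_truth_gff3(emb1, file.path(out, "truth_families.gff3"))
write_truth_gff3(emb2, file.path(out, "truth_satellite.gff3"))

hits1 <- file.path(out, "hits_families.tsv")
write_truth_hits(emb1, hits1)
write_truth_hits(emb2, file.path(out, "hits_satellite.tsv"))
# single merged hit table for the scan step
h <- rbind(utils::read.delim(hits1),
           utils::read.delim(file.path(out, "hits_satellite.tsv")))
utils::write.table(h, file.path(out, "hits.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("Simulated", length(families), "complete-end family elements",
    "(lengths", paste(vapply(elements, function(e) e$truth$length,
                             integer(1)), collapse = ", "), "bp)\n")
cat("plus one satellite-bearing subTIR-only element of",
    sat_el$truth$length, "bp carrying a",
    sat_el$truth$sat_copy_number, "copy array of a",
    sat_el$truth$sat_monomer_len, "bp monomer.\n")
cat("Outputs in", out, "\n")
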