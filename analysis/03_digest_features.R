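# Derive the per-digest characteristics from the match results: size-class
# abundance fractions, total abundance, unique ions, and the two overlap
# percentages. Also exports tile-plot and abundance-comparison tables for
# the highest-overlap digest (AWPC).

source("analysis/00_setup.R")
dir.create(file.path(OUT_DIR, "features"), recursive = TRUE,
           showWarnings = FALSE)

bench <- read_benchmark()
blank <- read_blank()
digests <- read_digests()

pipe <- run_matching_pipeline(digests, blank, bench)
features <- do.call(rbind, lapply(pipe$digests, function(res) {
  compute_features(res$table, res$match)
}))
rownames(features) <- NULL
write.csv(features, file.path(OUT_DIR, "features", "digest_features.csv"),
          row.names = FALSE)

awpc <- pipe$digests[["AWPC/R1"]]
tabs <- export_overlap_tables(awpc$match, awpc$table, pipe$benchmark)
write.csv(tabs$tile, file.path(OUT_DIR, "features", "AWPC_R1_tile.csv"),
          row.names = FALSE)
write.csv(tabs$comparison,
          file.path(OUT_DIR, "features", "AWPC_R1_abundance_comparison.csv"),
          row.names = FALSE)

by_src <- aggregate(cbind(pct_overlap, pct_abundance_overlap, n_unique,
                          total_abundance) ~ source_id, features, mean)
cat("replicate-mean digest characteristics:\n")
print(by_src, digits = 3)
cat(sprintf("overlap range: %.1f%% to %.1f%% of retained ions\n",
            min(by_src$pct_overlap), max(by_src$pct_overlap)))
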