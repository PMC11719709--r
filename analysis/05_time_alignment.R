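#!/usr/bin/env Rscript
# Cross-species developmental time alignment: per terminal lineage, cells at
# every time point are weighted by their fate probability toward that
# lineage and compared across species by exact earth mover distance in a
# joint ortholog embedding. With species B specified 3 h later, the aligned
# pairs should sit above the diagonal.
suppressPackageStartupMessages(library(devoalign))

dir.create("results", showWarnings = FALSE)
cfg <- sim_config(seed = 1L)          # default conditions: +3 h delay in B
res <- run_pipeline(cfg, pipeline_config(),
                    outdir = file.path(tempdir(), "run05"),
                    stages = c("simulate", "preprocess", "transport",
                               "fates", "align"))
align <- res$state$align

offsets <- do.call(rbind, lapply(align, function(ar)
  data.frame(lineage = ar$cell_lineage,
             n_pairs = nrow(ar$best_pairs),
             median_offset_h = median(ar$offsets),
             pairs_above_diagonal = pairs_above_diagonal(ar))))
write.csv(offsets, "results/05_alignment_offsets.csv", row.names = FALSE)

pairs <- do.call(rbind, lapply(align, function(ar)
  cbind(lineage = ar$cell_lineage, ar$best_pairs)))
write.csv(pairs, "results/05_alignment_best_pairs.csv", row.names = FALSE)

spacing <- max(diff(cfg$timepoints_A))
message("Per-lineage median alignment offsets (species B minus species A, hours):")
print(offsets)
message(sum(abs(offsets$median_offset_h - 3) <= spacing), " of ",
        nrow(offsets), " lineages recover the 3 h delay to within one ",
        "inter-sample spacing (", spacing, " h).")
message("Wrote results/05_alignment_offsets.csv and results/05_alignment_best_pairs.csv")
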