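#!/usr/bin/env Rscript
# Position-scanning imaging of a synthetic fingertip: ridge pattern,
# secretion blobs growing after hand washing, blob segmentation and
# probe-site selection.
# Writes: results/pa_image_t2.csv/.png, results/pa_image_t60.csv/.png,
#         results/blobs_t60.csv, results/site_selection.json

library(paglucose)
dir.create("results", showWarnings = FALSE)
seed <- 42

map <- generate_skin_map(seed = seed)
cat(sprintf("skin map: %d pores over %.2f mm^2 (350 glands/cm^2 nominal)\n",
            nrow(map$pores), (map$extent / 1000)^2))

config <- instrument_config()
img2 <- raster_scan(map, t = 2, config = config, seed = seed + 1)
img60 <- raster_scan(map, t = 60, config = config, seed = seed + 2)
write_pa_image_csv(img2, "results/pa_image_t2.csv")
write_pa_image_csv(img60, "results/pa_image_t60.csv")
write_pa_image_png(img2, "results/pa_image_t2.png")
write_pa_image_png(img60, "results/pa_image_t60.png")

blobs <- segment_blobs(img60)
write.csv(blobs$summaries, "results/blobs_t60.csv", row.names = FALSE)
cat(sprintf("t = 2 min (right after washing): %d blob(s); t = 60 min: %d blob(s)\n",
            nrow(segment_blobs(img2)$summaries), nrow(blobs$summaries)))
for (k in seq_len(nrow(blobs$summaries))) {
  d <- min(sqrt((map$pores$x - blobs$summaries$centroid_x_um[k])^2 +
                  (map$pores$y - blobs$summaries$centroid_y_um[k])^2))
  cat(sprintf("  blob %d: centroid (%.0f, %.0f) um, %.0f um from nearest pore\n",
              k, blobs$summaries$centroid_x_um[k],
              blobs$summaries$centroid_y_um[k], d))
}

sel <- select_probe_sites(img60)
write_site_selection_json(sel, "results/site_selection.json")
cat(sprintf("dark valley site (%g, %g) um: ridge height %.2f (valley floor)\n",
            sel$dark_site$x_um, sel$dark_site$y_um,
            ridge_at(map, sel$dark_site$x_um, sel$dark_site$y_um)))
cat(sprintf("bright ridge site (%g, %g) um: inside a secretion blob\n",
            sel$bright_site$x_um, sel$bright_site$y_um))
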