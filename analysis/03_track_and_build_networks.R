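#!/usr/bin/env Rscript
# Run TEND tractography on the phantoms, summarize termination behavior, and
# build the connectivity networks at connection thresholds m = 1, 3, 5.

library(iscn)

out <- "results/networks"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
gt <- default_gradient_table()

track_rows <- list()
net_rows <- list()
for (nm in c("straight", "arc", "sharp_bend")) {
  spec <- switch(nm,
    straight = bundle_phantom_spec(),
    arc = bundle_phantom_spec(grid_shape = c(30, 30, 14), geometry = "arc"),
    sharp_bend = bundle_phantom_spec(grid_shape = c(30, 30, 14),
                                     geometry = "sharp_bend"))
  ph <- make_bundle_phantom(spec, gt)
  field <- fit_tensor(ph$dwi, gt)
  tract <- track_whole_volume(field)
  write_tck(tract, file.path(out, paste0(nm, ".tck")))
  reasons <- termination_summary(tract)
  ep <- assign_endpoints(tract, ph$labels)
  track_rows[[nm]] <- data.frame(
    phantom = nm,
    n_streamlines = length(tract$streamlines),
    hit_rate_cap1_cap2 = mean(ep[, 1] == 1 & ep[, 2] == 2),
    t(as.matrix(reasons)))
  for (m in c(1, 3, 5)) {
    net <- build_network(tract, ph$labels, field, m = m)
    write_network(net, file.path(out, nm, paste0("m", m)))
    ut <- upper.tri(net$density)
    net_rows[[paste(nm, m)]] <- data.frame(
      phantom = nm, m = m,
      edges = sum(net$density[ut] > 0),
      cd_12 = net$density[1, 2],
      fa_12 = net$fa[1, 2],
      md_12 = net$md[1, 2],
      density_sum = sum(net$density[ut]))
  }
}
tracks <- do.call(rbind, track_rows)
nets <- do.call(rbind, net_rows)
write.csv(tracks, file.path(out, "tracking_summary.csv"), row.names = FALSE)
write.csv(nets, file.path(out, "network_summary.csv"), row.names = FALSE)

cat("Tracking summary (termination reasons count both launch directions):\n")
print(tracks, digits = 3)
cat("\nNetworks across connection thresholds:\n")
print(nets, digits = 3)
cat("\nThe straight and arc phantoms connect caps 1-2 as a single edge with\n",
    "cd_12 = n_12/n_all; the sharp-bend phantom terminates bend-crossing\n",
    "streamlines by the 60-degree curvature rule, which removes the\n",
    "through-connection.\n", sep = "")
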