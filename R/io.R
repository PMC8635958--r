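# Plain-text output writers: trajectory, scalar series, kymographs with a
# JSON sidecar, run provenance.

#' Write simulation outputs to a directory
#'
#' Writes `trajectory.csv` (t, x, y), `scalars.csv` (cytosolic FilGAP, bound
#' FilGAP, fast-mode fraction, area, perimeter), one `kymo_<species>.csv`
#' per recorded species (node x time concentration matrices) with a
#' `kymo_meta.json` sidecar (times, arc-length coordinates), shape
#' `snapshots.csv`, `config.json` and `provenance.json`.
#'
#' @param out a `sim_output`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_output <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(t = out$times, x = out$centroid[, 1],
                       y = out$centroid[, 2]),
            file.path(dir, "trajectory.csv"), row.names = FALSE)
  write.csv(data.frame(t = out$times, filgap_c = out$filgap_c,
                       bound_filgap = out$bound_filgap,
                       fast_frac = out$fast_frac, area = out$area,
                       perimeter = out$perimeter),
            file.path(dir, "scalars.csv"), row.names = FALSE)
  for (sp in names(out$kymo))
    write.csv(out$kymo[[sp]], file.path(dir, paste0("kymo_", sp, ".csv")),
              row.names = FALSE)
  jsonlite::write_json(list(times = out$kymo_times,
                            arc = unname(out$kymo_arc)),
                       file.path(dir, "kymo_meta.json"), digits = NA)
  snaps <- do.call(rbind, lapply(seq_along(out$snapshots), function(k)
    data.frame(t = out$snapshot_times[k], node = seq_len(nrow(out$snapshots[[k]])),
               x = out$snapshots[[k]][, 1], y = out$snapshots[[k]][, 2])))
  write.csv(snaps, file.path(dir, "snapshots.csv"), row.names = FALSE)
  cfg <- out$config
  cfg$env <- out$state$env    # include sources placed during the run
  config_to_json(cfg, file.path(dir, "config.json"))
  jsonlite::write_json(list(master_seed = out$master_seed,
                            package_version = as.character(utils::packageVersion("chemomech")),
                            n_capped = out$counters$n_capped,
                            n_contact = out$counters$n_contact),
                       file.path(dir, "provenance.json"), auto_unbox = TRUE)
  invisible(dir)
}
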