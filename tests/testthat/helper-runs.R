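# Self-assembly runs shared by several test blocks, built once per test
# session and cached. The membrane uses the reduced desk-scale preset
# (15 x 15 x 30 rc, 225 + 225 chains, 60,000 steps); the perforated
# system runs in a smaller patch at the same leaflet packing (one chain
# per rc^2) to keep the suite fast.

.run_cache <- new.env(parent = emptyenv())

desk_run <- function(name) {
  if (!is.null(.run_cache[[name]])) return(.run_cache[[name]])
  cfg <- switch(name,
    membrane = reduced_preset(nt1 = 9, nt2 = 9),
    perforated = reduced_preset(nt1 = 5, nt2 = 6, n1 = 144, n2 = 144,
                                box = c(12, 12, 24), n_steps = 40000),
    stop("unknown desk run: ", name))
  run <- simulate(cfg, seed = if (name == "membrane") 1 else 202)
  .run_cache[[name]] <- run
  run
}

# stable-stage frames + segmentation of a cached run
desk_stable <- function(name) {
  run <- desk_run(name)
  seg <- stage_segmentation(run)
  frames <- run_frames(run)
  f_times <- vapply(frames, function(s) s$time, numeric(1))
  stable <- frames[f_times > seg$t_adjust_end]
  if (length(stable) == 0) stable <- frames[length(frames)]
  list(run = run, seg = seg, stable = stable)
}

# stable-stage thickness: mean of per-frame measurements (see
# thickness_timeseries); NA-robust
stable_thickness <- function(stable) {
  tt <- thickness_timeseries(stable)
  mean(tt$thickness, na.rm = TRUE)
}
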