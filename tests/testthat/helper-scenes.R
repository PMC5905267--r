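# shared fixture builders (all scenes are generated in code, seeded)

# cap + pit on a tilted, mildly noisy background -- the standard
# convex/concave segmentation fixture
cap_pit_scene <- function(seed = 11) {
  sp <- background_spec(tilt = c(0.05, 0.08), noise_sd = 0.3)
  add_features(make_background(c(128, 128), sp, seed = seed),
               list(cap_feature(c(42, 40), 14, 20),
                    pit_feature(c(90, 88), 14, 18)),
               noise = 0.3)
}

# crossed sinusoids + tilt: background too complex for a single global
# polynomial (the sliding-window methods' use case)
complex_bg_spec <- function(noise_sd = 0) {
  background_spec(tilt = c(0.05, 0.1),
                  sinusoids = data.frame(amplitude = c(30, 25),
                                         period = c(96, 80),
                                         phase = c(0.4, 1.1),
                                         axis = c("col", "row")),
                  noise_sd = noise_sd)
}

# one scene of the two-pass evaluation suite: strong tilt, bow, per-row
# drift, pixel noise, 20 caps
twopass_scene <- function(i, base_seed = 1) {
  sp <- background_spec(tilt = c(0.15 + 0.02 * i, 0.6 - 0.04 * i),
                        bow = c(u2 = 12 + 2 * i, v2 = -10 - i),
                        drift_sd = 0.4, noise_sd = 0.3)
  make_cap_field(c(192, 192), 20, spec = sp, seed = base_seed + i)
}

# per-feature detection bookkeeping against scene ground truth
detection_stats <- function(fm, scene) {
  tm <- scene$truth_mask
  nfp <- 0L
  for (k in seq_len(max(fm$components))) {
    sel <- fm$components == k
    if (sum(sel & tm$included) == 0L) nfp <- nfp + 1L
  }
  centers <- t(vapply(scene$features, function(f) f$center, numeric(2)))
  hit <- vapply(seq_len(nrow(centers)), function(i)
    fm$included[round(centers[i, 1]), round(centers[i, 2])], logical(1))
  list(found = sum(hit), n = nrow(centers), false_pos = nfp)
}

# best truth-component IoU for one detected component
component_best_iou <- function(fm, k, tm) {
  sel <- fm$components == k
  best <- 0
  for (j in seq_len(max(tm$components))) {
    tsel <- tm$components == j
    best <- max(best, sum(sel & tsel) / sum(sel | tsel))
  }
  best
}
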