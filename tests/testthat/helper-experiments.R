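# Shared experiment drivers for the heavier planted-effect checks.
# Reduced problem sizes (N = 60 parcels, Louvain restarts 20, control grid
# 251) keep the experiments fast; the quantities compared are group-level
# directions, which are insensitive to these settings.

small_atlas <- function(seed = 1) make_atlas(52, 8, 7, seed = seed)

# One planted-cohort replicate: 12 VH-like vs 12 control-like subjects,
# 220-timepoint runs (longer than the default geometry so transition-count
# contrasts can exist: a 101-timepoint run supports at most one
# window-majority transition), "both_states" conditioning so every subject
# expresses both states without conditioning away the stay-probability
# contrasts. Returns the five headline direction indicators.
planted_cohort_directions <- function(seed, atlas = small_atlas(),
                                      louvain_iter = 10, n_steps = 251) {
  coh <- make_cohort(atlas = atlas,
                     n_per_group = c(VH = 12, nonVH = 12, control = 0),
                     n_timepoints = 220, conditioning = "both_states",
                     p_stay = c(Integrated = 0.97, Segregated = 0.97),
                     p_stay_segregated_vh = 0.995, hub_scale_vh = 0.4,
                     seed = seed)
  rows <- lapply(seq_along(coh$subjects), function(k) {
    s <- coh$subjects[[k]]
    st <- subject_states(s$bold, window_len = 63, louvain_iter = louvain_iter,
                         seed = derive_seed(seed, k))
    en <- suppressWarnings(
      subject_energies(s$sc, st$dfc, st$assignment, n_steps = n_steps))
    cbind(data.frame(group = s$group), st$metrics,
          if (!is.null(en)) data.frame(log_IS = en$suite$log_energy[["IS"]],
                                       log_II = en$suite$log_energy[["II"]],
                                       log_SS = en$suite$log_energy[["SS"]])
          else data.frame(log_IS = NA_real_, log_II = NA_real_,
                          log_SS = NA_real_))
  })
  df <- do.call(rbind, rows)
  gm <- function(col, grp) mean(df[[col]][df$group == grp], na.rm = TRUE)
  list(frac = gm("fraction_integrated", "VH") < gm("fraction_integrated", "nonVH"),
       trans = gm("n_transitions", "VH") < gm("n_transitions", "nonVH"),
       dwell = gm("dwell_segregated", "VH") > gm("dwell_segregated", "nonVH"),
       energy = gm("log_IS", "VH") < gm("log_IS", "nonVH"),
       persist = mean(df$log_II - df$log_SS, na.rm = TRUE) > 0)
}

derive_seed <- dynstates:::derive_seed
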