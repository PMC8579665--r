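# Shared helpers: independent EFM oracle for signed models and seeded
# random signed-model generation. The oracle path is split -> brute-force
# minimal-support search -> two-cycle filter -> signed merge; it never
# touches the double description or reverse search code.

oracle_efms <- function(model) {
  sp <- split_reversible(model)
  fc <- flux_cone(sp$model$S, sp$model$reaction_ids)
  ms <- brute_force_efms(fc)
  ms <- filter_two_cycles(ms, sp$record)
  merge_split_pairs(ms, sp$record)
}

ddm_efms <- function(model) {
  sp <- split_reversible(model)
  fc <- flux_cone(sp$model$S, sp$model$reaction_ids)
  ms <- enumerate_efms_ddm(fc)
  ms <- filter_two_cycles(ms, sp$record)
  merge_split_pairs(ms, sp$record)
}

# seeded random signed metabolic model: sparse stoichiometry, a few
# reversible columns
random_signed_model <- function(m, n, seed, rev_frac = 0.3) {
  fc <- random_flux_cone(m, n, density = 0.5, seed = seed)
  rng_vals <- (seed * 7919 + seq_len(n) * 104729) %% 1000 / 1000
  rev <- rng_vals < rev_frac
  metabolic_model(fc$N, paste0("M", seq_len(m)), fc$reaction_ids, rev = rev)
}

# vertex count of a polytope through homogenization + double description
ddm_vertex_count <- function(rep) {
  dh <- dehomogenize(enumerate_rays_ddm(homogenize(rep)))
  sum(dh$kind == "efv")
}
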