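# Planted profile screen: compounds drawn around class centres in
# anchored-score space (planted effects |s| >= 60, noise sd 10).
planted_profiles <- function(seed, n_per_class = 8, sd = 10) {
  set.seed(seed)
  centres <- list(growth_inhibitory = c(-85, -40, 30),
                  anti_invasive = c(-5, -80, 0),
                  inactive = c(0, 0, 0))
  rows <- list(); truth <- character(0); id <- 0
  for (cl in names(centres)) {
    for (i in seq_len(n_per_class)) {
      id <- id + 1
      s <- centres[[cl]] + rnorm(3, 0, sd)
      rows[[id]] <- data.frame(compound_id = sprintf("K%02d", id),
                               concentration_uM = 1, cell_line = "PC-3",
                               role = "treatment", s_area = s[1],
                               s_complexity = s[2], s_death = s[3],
                               n_wells = 2)
      truth <- c(truth, cl)
    }
  }
  list(profiles = do.call(rbind, rows), truth = truth)
}
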