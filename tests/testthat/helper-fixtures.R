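# Shared fixtures, all built in code at test time.

# A minimal two-subject cohort with hand-chosen scores for one source.
tiny_scores <- function(cs_a = c(50, 55, 48, 47), cs_b = cs_a,
                        source = "target") {
  rbind(
    data.frame(subject = "a", source = source, phase_deg = c(0, 90, 180, 270),
               n_keywords = 130, n_correct = NA, cs = cs_a),
    data.frame(subject = "b", source = source, phase_deg = c(0, 90, 180, 270),
               n_keywords = 130, n_correct = NA, cs = cs_b))
}

# A noiseless cohort in which every subject's centered profile equals
# `delta` (values at phases 0/90/180/270).
noiseless_cohort <- function(delta, n_subjects = 6, source = "target") {
  do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    data.frame(subject = sprintf("S%02d", s), source = source,
               phase_deg = c(0, 90, 180, 270), n_keywords = 130,
               n_correct = NA, cs = 50 + delta)
  }))
}

# A theta-band test signal with slowly varying amplitude.
modulated_theta <- function(rate = 250, dur = 10, f0 = 6, mod_f = 0.3,
                            mod_depth = 0.4) {
  t <- (0:(rate * dur - 1)) / rate
  (1 + mod_depth * sin(2 * pi * mod_f * t)) * sin(2 * pi * f0 * t)
}

expect_circ_close <- function(a, b, tol) {
  expect_lt(abs(tacsphase:::circ_dist_deg(a, b)), tol)
}
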