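# Shared fixtures, all generated in code.

# 11-bp duplex with one sharp kink (roll `kink` degrees) at step 5.
kinked_profile <- function(kink = 50, n = 11, at = 5,
                           sequence = "ACGTACGTACGTACGT") {
  seqv <- substr(sequence, 1, n)
  roll <- rep(0, n - 1)
  roll[at] <- kink
  step_profile(seqv, roll = roll)
}

kinked_model <- function(...) build_duplex(kinked_profile(...))

# random physical-ish profile used by property tests
random_profile <- function(n = 8, roll_max = 60, tilt_max = 60) {
  seqv <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  step_profile(seqv,
               shift = runif(n - 1, -1.5, 1.5),
               slide = runif(n - 1, -1.5, 1.5),
               rise = runif(n - 1, 2.5, 4.5),
               tilt = runif(n - 1, -tilt_max, tilt_max),
               roll = runif(n - 1, -roll_max, roll_max),
               twist = runif(n - 1, 20, 45))
}

random_rotation <- function() {
  axis_angle_rot <- function() {
    v <- rnorm(3)
    rot <- dnakink:::rot_about(v, runif(1, 0, 360))
    rot
  }
  axis_angle_rot()
}

measure_profile <- function(model, duplex = generator_duplex(model)) {
  roll_profile(duplex, model)$steps[, c("shift", "slide", "rise",
                                        "tilt", "roll", "twist")]
}

profile_matrix <- function(profile) {
  as.matrix(profile[, c("shift", "slide", "rise", "tilt", "roll", "twist")])
}

# duplex object with strand II reinterpreted as strand I (reads the same
# helix in the opposite direction)
reverse_duplex <- function(duplex) {
  pr <- duplex$pairs[rev(seq_len(nrow(duplex$pairs))), ]
  out <- duplex
  out$pairs <- data.frame(res_I = pr$res_II, res_II = pr$res_I,
                          base_I = pr$base_II, base_II = pr$base_I,
                          n_hbonds = pr$n_hbonds, c1c1 = pr$c1c1,
                          is_watson_crick = pr$is_watson_crick)
  out$sequence_I <- rev(duplex$sequence_II)
  out$sequence_II <- rev(duplex$sequence_I)
  out$chain_I <- duplex$chain_II
  out$chain_II <- duplex$chain_I
  out
}

pdb_line <- function(eleno, name, resid, chain, resno, x, y, z,
                     occ = 1, alt = " ") {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          eleno, paste0(" ", name), alt, resid, chain, resno, x, y, z,
          occ, 0, substr(name, 1, 1))
}

minimal_pdb_text <- function() c(pdb_line(1, "C1'", "DA", "A", 1, 1, 2, 3), "END")
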