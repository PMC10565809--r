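# shared helpers: brute-force oracles and random-case generators

# independent per-group summation oracle for the HSP components: loops row
# by row instead of vectorised table arithmetic
oracle_hsp <- function(counts, table, V, polar_sum = "linear") {
  Fd <- 0; Fp_lin <- 0; Fp_sq <- 0; Eh <- 0
  for (g in names(counts)) {
    row <- table[table$name == g, ]
    for (r in seq_len(counts[[g]])) {
      Fd <- Fd + row$F_di
      Fp_lin <- Fp_lin + row$F_pi
      Fp_sq <- Fp_sq + row$F_pi^2
      Eh <- Eh + row$E_hi
    }
  }
  dd <- Fd / V
  dp <- if (polar_sum == "linear") Fp_lin / V else sqrt(Fp_sq) / V
  dh <- sqrt(Eh / V)
  c(delta_d = dd, delta_p = dp, delta_h = dh,
    delta_total = sqrt(dd^2 + dp^2 + dh^2))
}

# random count vector over non-correction groups with positive volume sum
random_counts <- function(table, max_groups = 6, max_count = 5) {
  ok <- table$name[!table$is_correction & table$V_fedors > 0]
  picked <- sample(ok, sample(2:max_groups, 1))
  stats::setNames(sample(1:max_count, length(picked), replace = TRUE), picked)
}

random_profile <- function(id = "x") {
  structure(list(molecule_id = id,
                 delta_d = runif(1, 12, 25), delta_p = runif(1, 0, 20),
                 delta_h = runif(1, 0, 15), delta_total = NA, V = 100),
            class = "hsp_profile")
}
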