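# Shared miniature fixtures built in code (no binary files).

# Classic trio: sire S, dam D, offspring O.
trio_pedigree <- function() {
  data.frame(animal = c("S", "D", "O"),
             sire = c(NA, NA, "S"),
             dam = c(NA, NA, "D"),
             stringsAsFactors = FALSE)
}

# Two full sibs O1, O2 and their mating -> inbred grandchild X.
fullsib_pedigree <- function() {
  data.frame(animal = c("S", "D", "O1", "O2", "X"),
             sire = c(NA, NA, "S", "S", "O1"),
             dam = c(NA, NA, "D", "D", "O2"),
             stringsAsFactors = FALSE)
}

# Random pedigree generator for property tests: n animals, each non-founder
# drawing parents uniformly from earlier animals (possibly unknown).
random_pedigree <- function(n, seed) {
  set.seed(seed)
  animal <- sprintf("A%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in 3:n) {
    cand <- seq_len(i - 1)
    if (runif(1) < 0.8) sire[i] <- animal[sample(cand, 1)]
    if (runif(1) < 0.8) {
      d <- animal[sample(cand, 1)]
      if (is.na(sire[i]) || d != sire[i]) dam[i] <- d
    }
  }
  data.frame(animal = animal, sire = sire, dam = dam,
             stringsAsFactors = FALSE)
}

# Small deterministic record table covering two herds, two years.
toy_records <- function() {
  data.frame(
    animal = sprintf("C%02d", 1:12),
    herd = rep(c("H1", "H2"), each = 6),
    year = rep(c(2010, 2010, 2010, 2011, 2011, 2011), 2),
    month = c(1, 2, 3, 7, 8, 9, 1, 2, 3, 10, 11, 12),
    age_months = c(40, 42, 44, 41, 43, 45, 39, 40, 41, 46, 47, 48),
    tmp_kg = c(1900, 2100, 2000, 2500, 2600, 2700,
               1800, 1850, 1950, 3000, 3100, 2900),
    ll_days = c(280, 310, 305, 290, 305, 320, 270, 305, 300, 330, 305, 310),
    sire_mf = rep(1, 12),
    dam_mf = c(rep(0.5, 6), rep(1, 6)),
    stringsAsFactors = FALSE
  )
}
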