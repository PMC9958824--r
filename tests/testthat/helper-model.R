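# Shared fixtures for the test suite.

default_model <- swell_model()

# a small consistent table with one zero-gradient permeant cation:
# both sides electro-neutral, both total 300 mM, impermeant anions 10/134
zero_gradient_ions <- function() {
  ion_table(name     = c("Na", "Cl", "A"),
            valence  = c(1L, -1L, -1L),
            permeant = c(TRUE, TRUE, FALSE),
            conc_out = c(150, 140, 10),
            conc_in  = c(150, 16, 134))
}

# random electro-neutral, isotonic five-species table (two cations, two
# permeant anions, one impermeant anion with the inside pool dominating so a
# shrinkage equilibrium exists)
random_ions <- function() {
  cat1_o <- runif(1, 60, 160)
  cat2_o <- runif(1, 2, 40)
  A_o <- runif(1, 2, 20)
  cat_tot <- cat1_o + cat2_o          # = half the total on each side
  u <- runif(1, 0.2, 0.8)
  an1_o <- u * (cat_tot - A_o)
  an2_o <- (1 - u) * (cat_tot - A_o)
  A_i <- runif(1, A_o + 20, cat_tot - 20)
  v <- runif(1, 0.2, 0.8)
  an1_i <- v * (cat_tot - A_i)
  an2_i <- (1 - v) * (cat_tot - A_i)
  s <- runif(1, 0.05, 0.95)
  ion_table(name     = c("C1", "C2", "X1", "X2", "A"),
            valence  = c(1L, 1L, -1L, -1L, -1L),
            permeant = c(TRUE, TRUE, TRUE, TRUE, FALSE),
            conc_out = c(cat1_o, cat2_o, an1_o, an2_o, A_o),
            conc_in  = c(s * cat_tot, (1 - s) * cat_tot, an1_i, an2_i, A_i))
}

# reference Donnan state rebuilt from printed, rounded concentrations (mM)
printed_donnan_out <- c(Na = 26.6, K = 61.2, Cl = 54.4, HCO3 = 23.4, A = 10)
printed_donnan_in <- c(Na = 52.5, K = 120.9, Cl = 27.5, HCO3 = 11.9, A = 134)
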