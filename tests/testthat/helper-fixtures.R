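# small shared fixtures and independent oracles

grid9 <- function() band_grid(seq(600, by = 200, length.out = 9),
                              weights = seq(24, 12, by = -1.5))

grid5 <- function(weights = NULL) band_grid(seq(600, by = 200,
                                                length.out = 5),
                                            weights = weights)

# brute-force rarefaction: average observed richness over every t-subset of
# the T sampling units, from a unit-by-species incidence matrix
rarefy_bruteforce <- function(units_by_species, t) {
  T <- nrow(units_by_species)
  subs <- utils::combn(T, t)
  mean(apply(subs, 2L, function(u) {
    sum(colSums(units_by_species[u, , drop = FALSE]) > 0)
  }))
}

# random unit-by-species incidence with no empty species column
random_unit_matrix <- function(T, S, p = 0.4) {
  repeat {
    m <- matrix(stats::rbinom(T * S, 1L, p), T, S)
    if (all(colSums(m) > 0)) return(m)
  }
}

freqs_of <- function(units_by_species)
  incidence_freqs(colSums(units_by_species), T = nrow(units_by_species))

# all four boundary policies
all_policies <- function() list(
  hh = boundary_policy("hard", "hard"),
  ss = boundary_policy("soft", "soft"),
  sh = boundary_policy("soft", "hard"),
  hs = boundary_policy("hard", "soft")
)
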