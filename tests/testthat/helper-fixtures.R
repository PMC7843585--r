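# in-code fixtures: tiny profiles and noise-free design grids

# profile with a constant size per organ (easy arithmetic)
flat_profile <- function(sizes = c(LL = 80, LW = 10, SL = 18, SW = 3, IL = 10, ID = 2),
                         density = 4.5) {
  grid <- expand.grid(rank = modeled_ranks(), organ = organ_codes(),
                      stringsAsFactors = FALSE)
  grid$size_cm <- unname(sizes[grid$organ])
  base_profile(grid, density = density)
}

# noise-free percent-change observations on the standard design grid
grouped_design <- function(A, B, C, ranks, x = c(1.5, 3, 4.5, 10.5)) {
  d <- expand.grid(x = x, rank = ranks)
  d$y <- A * log(d$x) + B * d$rank + C
  d
}

ear_design <- function(D, E, x = c(1.5, 3, 4.5, 10.5)) {
  data.frame(x = x, y = D * x + E)
}

elevated_densities <- function() c(6, 7.5, 9, 15)
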