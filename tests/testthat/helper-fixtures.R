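# reference simulation parameter set and initial counts used across tests
ref_params <- function(...) ng_params(...)
ref_state <- function(...) ng_state(...)

# draw one random parameter set in the declining-niche regime (stem pool
# declining strictly, progenitors depleting strictly faster), away from the
# equal-rate degeneracy
sample_regime_params <- function() {
  repeat {
    a1 <- runif(1, 0.5, 0.9)
    theta1 <- runif(1, 0.1, 0.95)
    p1 <- runif(1, 0.2, 2)
    if (a1 * theta1 >= 0.49) next
    a2 <- runif(1, 0.5, 0.95)
    theta2 <- runif(1, 0.1, 0.95)
    p2 <- runif(1, 0.5, 3)
    d2 <- runif(1, 0, 0.5)
    lambda1 <- (2 * a1 * theta1 - 1) * p1
    lambda2 <- (2 * a2 * theta2 - 1) * p2 - d2
    if (lambda2 - lambda1 > -0.05) next
    return(ng_params(
      a1 = a1, theta1 = theta1, p1 = p1, kappa = runif(1, 0.05, 0.95),
      a2 = a2, theta2 = theta2, p2 = p2, d2 = d2,
      p3 = runif(1, 0.5, 2), d3 = runif(1, 0, 0.5),
      d4 = runif(1, 0, 0.1), d5 = runif(1, 0, 0.1)
    ))
  }
}

# nonzero symbols of a sign sequence, e.g. c("-", "+")
nonzero_signs <- function(sq) sq$symbols[sq$symbols != "0"]

# is `x` a subsequence of `pattern`? used for pointwise lemma sign checks
# where a crossing may lie beyond the analysis horizon
is_subsequence <- function(x, pattern) {
  j <- 1L
  for (s in x) {
    while (j <= length(pattern) && pattern[j] != s) j <- j + 1L
    if (j > length(pattern)) return(FALSE)
    j <- j + 1L
  }
  TRUE
}
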