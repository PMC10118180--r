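# Shared fixtures, all built in code.

# the reference corruption experiment: five bands t=1..5, x0=1000, gamma=30,
# a=0, b=1 downshift, unit grid 901..1099, uniform factor 1.1
ref_world <- function(factor = 1.1) table1_world(factor = factor)

# small random curves on a fixed grid, deterministic given the seed
random_curve_pair <- function(n = 50, seed = 1) {
  set.seed(seed)
  g <- curve_grid(seq_len(n))
  list(s = curve_single(g, stats::rnorm(n), role = "simulated"),
       m = curve_single(g, stats::rnorm(n), role = "measured"))
}

# brute-force O(N^2) oracle for the full-matrix two-trace asynchronous sum:
# a literal double loop over Psi(j,k) = (s_j m_k - m_j s_k) / 2
brute_async_full <- function(s, m) {
  acc <- 0
  for (j in seq_along(s)) {
    for (k in seq_along(m)) {
      acc <- acc + ((s[j] * m[k] - m[j] * s[k]) / 2)^2
    }
  }
  acc
}

# brute-force oracle for the Hilbert-Noda matrix, entry by entry
brute_noda <- function(m) {
  out <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i != j) out[i, j] <- 1 / (pi * (j - i))
    }
  }
  out
}

# memoized run of the full loss-comparison experiment (used by several
# acceptance criteria; ~5 s once)
table1_results <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- reproduce_table1(world = ref_world())
    cache
  }
})

fitted_t_row <- function(tab, family) {
  as.numeric(tab[tab$family == family, paste0("t_", 1:5)])
}

# agreement to the printed precision: |x - ref| below half a unit in the
# last of `sig` significant digits of ref
expect_signif_equal <- function(x, ref, sig = 4) {
  tol <- 0.5 * 10^(floor(log10(abs(ref))) - (sig - 1))
  expect_true(all(abs(x - ref) < tol),
              label = sprintf("%s within %d significant figures of %s",
                              paste(signif(x, sig + 2), collapse = ", "),
                              sig, paste(ref, collapse = ", ")))
}
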