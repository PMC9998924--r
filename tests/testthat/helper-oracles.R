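# Independent oracles, deliberately naive: literal formula evaluation,
# term-by-term loops, no shared code with the package internals.

# Poisson probability mass written out literally (safe for k <= 30, a <= 20)
poisson_term <- function(a, k) a^k * exp(-a) / factorial(k)

# term-by-term brute-force evaluation of the published sharing formula
brute_force_paper_formula <- function(a, b, kmax = 30) {
  num <- 0
  den <- 0
  for (k in 1:kmax) {
    num <- num + poisson_term(a, k) * b * k^2
    den <- den + poisson_term(a, k) * k
  }
  100 * num / den
}

# expected positive fraction under the exact all-or-none mechanism
brute_force_exact_model <- function(a, b, kmax = 30) {
  num <- 0
  den <- 0
  for (k in 1:kmax) {
    num <- num + poisson_term(a, k) * k * (1 - (1 - b)^k)
    den <- den + poisson_term(a, k) * k
  }
  100 * num / den
}

# 4PL response used to manufacture synthetic standards in tests
fourpl <- function(x, A, D, C, B) A + (D - A) / (1 + (x / C)^(-B))

two_point_standards <- function() {
  data.frame(concentration_pg_ml = c(10, 1000), mfi = c(100, 10000))
}

grid_a <- c(0.5, 1, 2, 4, 8, 12)
grid_b <- c(0.01, 0.05, 0.1, 0.3, 0.9)
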