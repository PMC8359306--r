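# in-code fixtures shared across test files

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

counts_file <- function(rows = c("s1\t100\t10\t4")) {
  write_tsv_lines(c("SampleID\tPosition\tTotal\tMeth", rows))
}

covariates_file <- function(rows = c("s1\t1", "s2\t0"), header = "SampleID\tZ1") {
  write_tsv_lines(c(header, rows))
}

# small simulated region + fit with the error channel, reused by several
# inference tests (computed once per test run)
small_fit_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_scenario1(20, seed = 11, n_cpg = 40)
      fit <- em_fit(sim$counts, sim$covariates, error_rates(0.003, 0.9))
      cache <<- list(sim = sim, fit = fit)
    }
    cache
  }
})

# central finite-difference Hessian of a scalar function
fd_hessian <- function(f, x, h = 1e-4) {
  K <- length(x)
  H <- matrix(0, K, K)
  for (a in 1:K) for (b in a:K) {
    ea <- eb <- rep(0, K); ea[a] <- h; eb[b] <- h
    H[a, b] <- H[b, a] <-
      (f(x + ea + eb) - f(x + ea - eb) - f(x - ea + eb) + f(x - ea - eb)) /
      (4 * h^2)
  }
  H
}
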