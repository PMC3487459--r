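# Shared fixtures: canonical small landscapes built in code.

two_locus_valley <- function(s = 0.05, eps = 1) {
  build_landscape(2, s, eps, fitness_topography(2, c("01", "10")))
}

two_locus_single_lfg <- function(s = 0.05, eps = 1) {
  build_landscape(2, s, eps, fitness_topography(2, "01"))
}

two_locus_smooth <- function(s = 0.05, eps = 1) {
  build_landscape(2, s, eps)
}

four_locus_smooth <- function(s = 0.05, eps = 1) {
  build_landscape(4, s, eps)
}

standard_params <- function(...) {
  args <- list(...)
  do.call(dynamics_params, utils::modifyList(list(mu = 1e-5, r = 0.05), args))
}

random_simplex <- function(n) {
  x <- stats::runif(n)
  x / sum(x)
}

# independent brute-force subset enumerator (oracle for enumerate_topographies)
brute_force_subsets <- function(items, max_size) {
  out <- list(integer(0))
  for (sz in seq_len(max_size)) {
    if (sz > length(items)) break
    idx <- utils::combn(length(items), sz, simplify = FALSE)
    for (ii in idx) out[[length(out) + 1L]] <- items[ii]
  }
  out
}
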