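# Small fixtures shared across test files.

# tiny generator config: fast, keeps all structural features
tiny_config <- function(seed = 1L, ...) {
  defaults <- list(n_genes = 120L, n_mirnas = 40L, n_modules = 5L,
                   samples_per_group = c(30L, 30L, 12L, 12L),
                   n_3us_genes = 8L, n_3ul_genes = 4L, us_modules = 2L,
                   seed = seed)
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

# igraph from a two-column edge matrix of vertex names
graph_from_pairs <- function(...) {
  igraph::graph_from_edgelist(matrix(c(...), ncol = 2, byrow = TRUE),
                              directed = FALSE)
}

# independent Student-t tail by numerical quadrature of the density
quad_t_p2 <- function(r, n) {
  df <- n - 2
  t <- r * sqrt(df / (1 - r^2))
  dens <- function(x) gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
    (1 + x^2 / df)^(-(df + 1) / 2)
  2 * stats::integrate(dens, abs(t), Inf)$value
}

# hypergeometric upper tail by explicit PMF summation (independent of phyper)
pmf_sum_tail <- function(q, m, k, n_pop) {
  j <- seq(max(0, q), min(m, k))
  if (!length(j)) return(0)
  sum(choose(m, j) * choose(n_pop - m, k - j) / choose(n_pop, k))
}

# brute-force two-sample KS statistic: sup over all breakpoints
brute_ks_stat <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# the method's stage order on a dataset: expression filter, then backbone
filtered_backbone <- function(ds, ...) {
  expressed <- rownames(filter_expressed(do.call(cbind, ds$expression), 1, 0.8))
  keep <- intersect(rownames(ds$targets$site_count), expressed)
  build_backbone(target_site_table(ds$targets$site_count[keep, , drop = FALSE]),
                 ...)
}
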