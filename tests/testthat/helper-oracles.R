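# Independent oracles used across tests. These deliberately use brute
# force or closed forms, never the package's own computational path.

# exhaustive rarefaction: enumerate all C(N, n) unordered subsamples
enum_rarefaction <- function(counts, n) {
  counts <- counts[counts > 0]
  pool <- rep(seq_along(counts), counts)
  subsets <- utils::combn(length(pool), n)
  vals <- apply(subsets, 2, function(ix) length(unique(pool[ix])))
  list(mean = mean(vals), sd = sqrt(mean(vals^2) - mean(vals)^2))
}

# closed-form simple OLS (sum-of-products form)
ols_closed <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- sxy^2 / (sxx * sum((y - mean(y))^2))
  c(slope = slope, intercept = intercept, r2 = r2)
}

# deterministic unimodal community: Gaussian responses along a known
# gradient; noise-free expected abundances unless pois = TRUE
unimodal_table <- function(n_samples = 25, n_species = 35, seed = 7,
                           pois = FALSE) {
  set.seed(seed)
  grad <- sort(runif(n_samples, 0, 10))
  opt <- seq(-0.5, 10.5, length.out = n_species)
  tol <- runif(n_species, 1.2, 2.2)
  h <- runif(n_species, 30, 90)
  mu <- sapply(seq_len(n_species), function(j)
    h[j] * exp(-(grad - opt[j])^2 / (2 * tol[j]^2)))
  X <- if (pois) matrix(rpois(length(mu), mu), n_samples, n_species) else mu
  rownames(X) <- sprintf("s%02d", seq_len(n_samples))
  colnames(X) <- sprintf("sp%02d", seq_len(n_species))
  list(table = X, gradient = grad)
}

# build a binned_counts object directly from a long data frame
binned_from_long <- function(df) {
  seqs <- counts_from_columns(df)
  bin_sites(seqs)
}
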