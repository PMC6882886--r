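#' Analytic rarefaction: expected richness at a fixed grain sum
#'
#' The number of pollen types encountered grows with counting effort, so
#' samples are compared at a common sample size by rarefaction: the
#' expected number of distinct taxa in a random subsample of `n` grains
#' drawn without replacement from the observed counts,
#' \deqn{E[S_n] = \sum_i \left[1 - \binom{N - N_i}{n} / \binom{N}{n}\right],}
#' with `N` the grain total and `N_i` the count of taxon i. The standard
#' deviation uses the full variance of `S_n` under the hypergeometric
#' model, including the pairwise joint-absence covariance terms, not the
#' diagonal approximation.
#'
#' All combinatorial ratios are computed as log-gamma differences
#' ([lchoose]), never as raw binomial coefficients, so the computation is
#' exact in double precision with no overflow up to regional pools of 1e7
#' grains.
#'
#' @param counts Numeric vector of non-negative integer counts (zeros
#'   ignored), optionally named by taxon.
#' @param n Target grain sum (subsample size), a positive integer.
#' @return List of class `rarefaction_result` with elements
#'   `expected_richness`, `sd`, `n_target`, `n_available`, `defined`.
#'   When fewer than `n` grains are available the result is undefined
#'   (`defined = FALSE`, `NA` estimates) and is excluded from downstream
#'   analyses rather than rarefied to its own total: comparisons are only
#'   meaningful at a common size.
#' @seealso [rarefy_montecarlo] for the simulation oracle,
#'   [rarefy_table] to rarefy a whole set of bins.
#' @export
rarefy_expected <- function(counts, n) {
  if (length(counts) == 0L) stop("empty counts", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n <= 0 || n != round(n))
    stop("n must be a positive integer", call. = FALSE)
  .check_counts(counts, context = "rarefy_expected")
  counts <- as.numeric(counts[counts > 0])
  if (length(counts) == 0L) stop("empty counts", call. = FALSE)
  N <- sum(counts)
  S <- length(counts)
  if (N < n) {
    return(structure(list(expected_richness = NA_real_, sd = NA_real_,
                          n_target = n, n_available = N, defined = FALSE),
                     class = "rarefaction_result"))
  }
  lden <- lchoose(N, n)
  # P(taxon i absent from the subsample)
  la <- lchoose(N - counts, n) - lden
  la[N - counts < n] <- -Inf
  a <- exp(la)
  E <- S - sum(a)
  # Var(S_n) = sum_i a_i (1 - a_i) + sum_{i != j} (a_ij - a_i a_j),
  # a_ij = P(i and j both absent) = C(N - N_i - N_j, n) / C(N, n)
  M <- outer(counts, counts, "+")
  lA <- lchoose(N - M, n) - lden
  lA[N - M < n] <- -Inf
  A <- exp(lA)
  diag(A) <- 0
  aa <- outer(a, a)
  diag(aa) <- 0
  V <- sum(a * (1 - a)) + sum(A - aa)
  structure(list(expected_richness = E, sd = sqrt(max(V, 0)),
                 n_target = n, n_available = N, defined = TRUE),
            class = "rarefaction_result")
}

#' @export
print.rarefaction_result <- function(x, ...) {
  if (x$defined) {
    cat("E[S_", format(x$n_target), "] = ", format(x$expected_richness),
        " (sd ", format(x$sd), ") from ", format(x$n_available),
        " grains\n", sep = "")
  } else {
    cat("undefined: only ", format(x$n_available), " grains available for n = ",
        format(x$n_target), "\n", sep = "")
  }
  invisible(x)
}

# independent high-precision route: each absence probability as a direct
# log1p product, prod_j (N - N_i - j)/(N - j), j = 0..n-1
rarefy_expected_ref <- function(counts, n) {
  counts <- as.numeric(counts[counts > 0])
  N <- sum(counts)
  stopifnot(N >= n)
  j <- 0:(n - 1)
  a <- vapply(counts, function(Ni) {
    if (N - Ni < n) return(0)
    exp(sum(log1p(-Ni / (N - j))))
  }, 0.0)
  length(counts) - sum(a)
}

#' Monte-Carlo rarefaction
#'
#' Simulation oracle for [rarefy_expected]: draws `reps` subsamples of `n`
#' grains without replacement and reports the mean and standard deviation
#' of the distinct-taxon count. Sampling uses the sequential conditional
#' hypergeometric decomposition (taxon by taxon via [stats::rhyper]), so
#' no grain vector is ever materialised and 1e7-grain pools are cheap.
#'
#' @inheritParams rarefy_expected
#' @param reps Number of replicate subsamples (>= 1).
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @return List with `mean`, `sd`, `reps`.
#' @export
rarefy_montecarlo <- function(counts, n, reps, seed) {
  counts <- as.numeric(counts[counts > 0])
  if (length(counts) == 0L) stop("empty counts", call. = FALSE)
  N <- sum(counts)
  if (N < n) stop("fewer than n grains available", call. = FALSE)
  stopifnot(reps >= 1)
  distinct <- withr_seed(seed, {
    n_rem <- rep.int(n, reps)
    N_rem <- N
    d <- integer(reps)
    for (Ni in counts) {
      k <- stats::rhyper(reps, Ni, N_rem - Ni, n_rem)
      d <- d + (k > 0L)
      n_rem <- n_rem - k
      N_rem <- N_rem - Ni
    }
    d
  })
  list(mean = mean(distinct),
       sd = if (reps > 1) stats::sd(distinct) else 0,
       reps = reps)
}

# evaluate expr under a temporary RNG state; restores the caller's state
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Rarefy every bin in a set at a common grain sum
#'
#' @param binned A `binned_counts` object (site-level or regional).
#' @param n Common grain sum; by convention 500 for site-based analyses
#'   and 50,000 for regionally pooled samples.
#' @return Data frame with one row per bin: `owner`, `slice_center_bp`,
#'   `n_target`, `n_available`, `expected_richness`, `sd`, `defined`.
#'   Bins with fewer than `n` grains are reported with `defined = FALSE`.
#' @export
rarefy_table <- function(binned, n) {
  stopifnot(inherits(binned, "binned_counts"))
  meta <- binned$meta
  if (!nrow(meta)) {
    return(data.frame(owner = character(), slice_center_bp = numeric(),
                      n_target = numeric(), n_available = numeric(),
                      expected_richness = numeric(), sd = numeric(),
                      defined = logical()))
  }
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    cnt <- bin_counts(binned, meta$owner[i], meta$slice_center_bp[i])
    r <- rarefy_expected(cnt, n)
    data.frame(owner = meta$owner[i], slice_center_bp = meta$slice_center_bp[i],
               n_target = r$n_target, n_available = r$n_available,
               expected_richness = r$expected_richness, sd = r$sd,
               defined = r$defined, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
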