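#' Correspondence analysis, first non-trivial axis
#'
#' Plain correspondence analysis by generalized SVD of the
#' chi-square-standardized matrix
#' \eqn{S = D_r^{-1/2}(P - r c^T) D_c^{-1/2}} (equivalently, converged
#' reciprocal averaging). Sample scores are row principal coordinates;
#' species scores standard column coordinates. The axis sign is fixed so
#' the first sample's score does not exceed the last sample's, making
#' plots reproducible run-to-run.
#'
#' @param table Non-negative count matrix, rows = samples, columns =
#'   taxa (all-zero rows/columns are dropped).
#' @param transform `"none"` or `"sqrt"` (square-root transform of
#'   counts before analysis, the conventional variance stabilisation for
#'   pollen percentages/counts).
#' @return List of class `ordination_result`: `axis1_scores` (samples),
#'   `axis2_scores_raw`, `species_scores`, `eigenvalue1`,
#'   `gradient_length` (max - min of axis-1 scores), `constrained =
#'   FALSE`, plus the internal `table` and row weights used (for
#'   detrending/rescaling).
#' @export
ca_axis1 <- function(table, transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  X <- as.matrix(table)
  if (any(X < 0)) stop("table must be non-negative", call. = FALSE)
  if (transform == "sqrt") X <- sqrt(X)
  X <- X[rowSums(X) > 0, colSums(X) > 0, drop = FALSE]
  if (nrow(X) < 2L || ncol(X) < 2L)
    stop("rank-deficient table: need >= 2 non-empty rows and columns",
         call. = FALSE)
  P <- X / sum(X)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  dec <- svd(S)
  if (dec$d[1] < 1e-10)
    stop("no non-trivial axis (all rows proportional)", call. = FALSE)
  row1 <- dec$u[, 1] / sqrt(r) * dec$d[1]
  sgn <- if (row1[1] > row1[length(row1)]) -1 else 1
  row1 <- sgn * row1
  row2 <- if (length(dec$d) >= 2) sgn * dec$u[, 2] / sqrt(r) * dec$d[2]
          else rep(0, nrow(X))
  col1 <- sgn * dec$v[, 1] / sqrt(cc)
  structure(list(axis1_scores = stats::setNames(row1, rownames(X)),
                 axis2_scores_raw = stats::setNames(row2, rownames(X)),
                 species_scores = stats::setNames(col1, colnames(X)),
                 eigenvalue1 = dec$d[1]^2,
                 gradient_length = diff(range(row1)),
                 constrained = FALSE,
                 table = X, row_weights = r),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat("<ordination_result> ", if (x$constrained) "constrained " else "",
      "axis 1: eigenvalue ", format(x$eigenvalue1),
      ", gradient length ", format(x$gradient_length),
      ", ", length(x$axis1_scores), " samples\n", sep = "")
  invisible(x)
}

#' Detrending by segments, with nonlinear rescaling to SD units
#'
#' The classical detrending-by-segments procedure: the axis-1 range is cut
#' into `n_segments` equal-width segments and axis-2 scores are recentred
#' to zero mean within each segment, removing the arch artefact of plain
#' correspondence analysis. When the count `table` is supplied, axis 1 is
#' additionally rescaled segment-wise to units of species-turnover
#' standard deviation: within each segment the weighted within-sample
#' dispersion of (shrinkage-expanded) species scores is estimated and the
#' segment stretched by its inverse square root, so the gradient length
#' comes out in SD. Segment dispersions are smoothed and clamped around
#' their weighted mean for numerical stability on low-turnover series.
#' The piecewise-linear stretching is strictly monotone, hence sample
#' rank order along axis 1 is preserved.
#'
#' Segments holding no sample inherit the global mean dispersion; few
#' samples per segment are tolerated.
#'
#' @param scores_axis1 Axis-1 sample scores.
#' @param scores_axis2_raw Raw axis-2 sample scores.
#' @param n_segments Number of segments (default 26, the conventional
#'   default of the original algorithm).
#' @param table Optional count matrix (as used in the ordination); if
#'   `NULL`, axis 1 is returned unchanged (detrending only).
#' @return List: `axis1` (rescaled to SD units if `table` given, origin
#'   at 0), `axis2_detrended`, `gradient_length`.
#' @export
detrend_by_segments <- function(scores_axis1, scores_axis2_raw,
                                n_segments = 26, table = NULL) {
  x <- as.numeric(scores_axis1)
  y <- as.numeric(scores_axis2_raw)
  stopifnot(length(x) == length(y), n_segments >= 1)
  seg <- .axis_segments(x, n_segments)
  y_det <- y - stats::ave(y, seg)
  x_out <- if (is.null(table)) x else
    .rescale_axis_sd(x, as.matrix(table), n_segments)
  x_out <- x_out - min(x_out)
  list(axis1 = stats::setNames(x_out, names(scores_axis1)),
       axis2_detrended = stats::setNames(y_det, names(scores_axis2_raw)),
       gradient_length = diff(range(x_out)))
}

.axis_segments <- function(x, n_segments) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(1L, length(x)))
  br <- seq(rng[1], rng[2], length.out = n_segments + 1)
  pmin(pmax(findInterval(x, br, rightmost.closed = TRUE), 1L), n_segments)
}

# Hill-style nonlinear rescaling, applied in a single pass to the
# converged correspondence-analysis solution (where the shrinkage of
# weighted-average species scores equals the eigenvalue, so they can be
# expanded consistently). The within-sample dispersion of the expanded
# species scores defines the local SD unit; per-segment dispersions are
# smoothed over neighbouring segments and clamped around their weighted
# mean, so near-empty segments of low-turnover series cannot stretch the
# axis without bound.
.rescale_axis_sd <- function(x, X, n_segments) {
  rs <- rowSums(X)
  cs <- colSums(X)
  rng <- range(x)
  if (diff(rng) == 0) return(x)
  y <- colSums(X * x) / cs
  xb <- as.numeric(X %*% y) / rs
  denom <- sum(rs * x * x)
  if (denom <= 0) return(x)
  beta <- sum(rs * x * xb) / denom       # shrinkage ~ eigenvalue
  if (!is.finite(beta) || beta <= 0) return(x)
  ye <- y / beta
  xp <- as.numeric(X %*% ye) / rs
  disp <- vapply(seq_len(nrow(X)), function(i)
    sum(X[i, ] * (ye - xp[i])^2) / rs[i], 0.0)
  br <- seq(rng[1], rng[2], length.out = n_segments + 1)
  seg <- pmin(pmax(findInterval(x, br, rightmost.closed = TRUE), 1L),
              n_segments)
  D <- rep(NA_real_, n_segments)
  for (s in unique(seg)) D[s] <- stats::weighted.mean(disp[seg == s], rs[seg == s])
  Dbar <- stats::weighted.mean(disp, rs)
  D[is.na(D)] <- Dbar
  # smooth over neighbours, then clamp to one order of magnitude
  Ds <- vapply(seq_len(n_segments), function(s)
    mean(D[max(1, s - 1):min(n_segments, s + 1)]), 0.0)
  Ds <- pmin(pmax(Ds, Dbar / 5), Dbar * 5)
  w <- 1 / sqrt(pmax(Ds, 1e-12))
  width <- diff(br) * w
  newbr <- c(0, cumsum(width))
  newbr[seg] + (x - br[seg]) * w[seg]
}

#' Detrended correspondence analysis, first axis
#'
#' Convenience wrapper: [ca_axis1] followed by [detrend_by_segments] with
#' the table supplied, so axis-1 sample scores and the gradient length are
#' in SD units. Optionally drops taxa below a presence threshold first
#' (rare-taxon sensitivity).
#'
#' @inheritParams ca_axis1
#' @inheritParams detrend_by_segments
#' @param threshold_pct Drop taxa never exceeding this percentage of any
#'   sample's total before ordination (0 = keep all).
#' @return An `ordination_result` with rescaled `axis1_scores`,
#'   `axis2_scores_raw` replaced by the detrended scores, and
#'   `gradient_length` in SD units.
#' @export
dca_axis1 <- function(table, transform = c("none", "sqrt"),
                      n_segments = 26, threshold_pct = 0) {
  X <- as.matrix(table)
  if (threshold_pct > 0) {
    pct <- 100 * sweep(X, 1, pmax(rowSums(X), 1), "/")
    X <- X[, apply(pct, 2, max) > threshold_pct, drop = FALSE]
  }
  ca <- ca_axis1(X, transform = transform)
  det <- detrend_by_segments(ca$axis1_scores, ca$axis2_scores_raw,
                             n_segments = n_segments, table = ca$table)
  ca$axis1_scores <- det$axis1
  ca$axis2_scores_raw <- det$axis2_detrended
  ca$gradient_length <- det$gradient_length
  ca
}

#' Time-constrained correspondence analysis, first axis
#'
#' Canonical correspondence analysis with a single continuous constraint
#' (sample age): sample scores are restricted to linear functions of the
#' covariate, and the first (only) constrained axis summarises the
#' component of compositional change that is linear in time in the
#' chi-square metric. Between-consecutive-sample score differences are
#' returned, indexing the rate of compositional change.
#'
#' Both raw canonical scores and a rescaled (SD-unit) version are
#' reported, since detrending conventions for constrained axes vary.
#'
#' @inheritParams ca_axis1
#' @param constraint Numeric covariate, one value per row of `table`
#'   (e.g. slice age); must not be constant.
#' @return An `ordination_result` with `constrained = TRUE` and extra
#'   elements `axis1_scores_sd` (rescaled) and `score_diffs` (data frame
#'   of consecutive-sample differences of the raw scores, in the row
#'   order of `table`).
#' @export
constrained_axis1 <- function(table, constraint, transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  X <- as.matrix(table)
  if (any(X < 0)) stop("table must be non-negative", call. = FALSE)
  if (transform == "sqrt") X <- sqrt(X)
  stopifnot(length(constraint) == nrow(X))
  keep_r <- rowSums(X) > 0
  X <- X[keep_r, colSums(X) > 0, drop = FALSE]
  z <- as.numeric(constraint)[keep_r]
  if (nrow(X) < 2L || ncol(X) < 2L)
    stop("rank-deficient table", call. = FALSE)
  if (stats::var(z) == 0)
    stop("constraint is constant", call. = FALSE)
  if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(nrow(X)))
  P <- X / sum(X)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  B <- sqrt(r) * cbind(1, z)
  Sfit <- B %*% solve(crossprod(B), crossprod(B, S))
  dec <- svd(Sfit)
  u1 <- dec$u[, 1] / sqrt(r) * dec$d[1]   # LC scores, linear in z
  sgn <- if (u1[1] > u1[length(u1)]) -1 else 1
  u1 <- sgn * u1
  x_sd <- .rescale_axis_sd(u1, X, n_segments = 26)
  x_sd <- x_sd - min(x_sd)
  sd_diffs <- if (length(u1) > 1)
    data.frame(from = rownames(X)[-nrow(X)], to = rownames(X)[-1],
               diff = diff(u1), stringsAsFactors = FALSE)
  else data.frame(from = character(), to = character(), diff = numeric())
  structure(list(axis1_scores = stats::setNames(u1, rownames(X)),
                 axis1_scores_sd = stats::setNames(x_sd, rownames(X)),
                 axis2_scores_raw = NULL,
                 species_scores = stats::setNames(sgn * dec$v[, 1] / sqrt(cc),
                                                  colnames(X)),
                 eigenvalue1 = dec$d[1]^2,
                 gradient_length = diff(range(u1)),
                 score_diffs = sd_diffs,
                 constrained = TRUE,
                 table = X, row_weights = r),
            class = "ordination_result")
}
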