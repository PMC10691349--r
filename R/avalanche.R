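#' Bin a spike raster into 1-ms population counts
#'
#' @param spikes tibble with a `time_ms` column (e.g. the `spikes` of a
#'   `"network_sim"` or [read_raster()] output).
#' @param bin_ms bin width (ms); 1 ms is the canonical width matching
#'   the avalanche silence criterion.
#' @param t_range `c(start, end)`; default spans the data.
#' @return Tibble `bin_start_ms, count`.
#' @export
bin_raster <- function(spikes, bin_ms = 1, t_range = NULL) {
  if (is.null(t_range))
    t_range <- c(0, max(spikes$time_ms, 0))
  edges <- seq(t_range[1], t_range[2] + bin_ms, by = bin_ms)
  tibble::tibble(
    bin_start_ms = head(edges, -1),
    count = as.integer(tabulate(
      findInterval(spikes$time_ms, edges, rightmost.closed = TRUE),
      nbins = length(edges) - 1)))
}

#' Detect avalanches in binned population activity
#'
#' An avalanche is a maximal run of consecutive nonempty bins, bounded
#' on both sides by at least one empty bin (one bin of silence at the
#' canonical 1-ms width). Its duration is the run length times the bin
#' width and its size the total spike count in the run, so every spike
#' belongs to exactly one avalanche and `size >= duration` in bins.
#'
#' @param counts integer vector of per-bin spike counts, or a tibble
#'   with a `count` column as returned by [bin_raster()].
#' @param bin_ms bin width (ms). Widths other than 1 ms are supported
#'   but non-canonical.
#' @return Tibble of class `"avalanche_set"` with columns
#'   `start_bin` (1-based), `start_ms`, `duration_ms`, `size`.
#' @export
#' @examples
#' detect_avalanches(c(0, 2, 3, 0, 1, 0))
detect_avalanches <- function(counts, bin_ms = 1) {
  if (is.data.frame(counts)) counts <- counts$count
  if (any(counts < 0) || any(counts != round(counts)))
    stop("detect_avalanches: counts must be non-negative integers",
         call. = FALSE)
  counts <- as.integer(counts)
  r <- rle(counts > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  act <- which(r$values)
  av <- tibble::tibble(
    start_bin = starts[act],
    start_ms = (starts[act] - 1) * bin_ms,
    duration_ms = r$lengths[act] * bin_ms,
    size = vapply(act, function(i) sum(counts[starts[i]:ends[i]]), 0L))
  class(av) <- c("avalanche_set", class(av))
  av
}

# Hurwitz zeta sum_{k>=0} (a+k)^-s by Euler-Maclaurin; vectorised over a.
hurwitz_zeta <- function(s, a, m = 64L) {
  k <- 0:(m - 1)
  direct <- colSums(outer(k, a, `+`)^(-s))
  am <- a + m
  direct + am^(1 - s) / (s - 1) + 0.5 * am^(-s) +
    s * am^(-s - 1) / 12 - s * (s + 1) * (s + 2) * am^(-s - 3) / 720
}

#' Fit a discrete power law to avalanche sizes or durations
#'
#' Clauset-style discrete maximum likelihood: for each candidate lower
#' cutoff `x_min`, the exponent maximises the zeta likelihood
#' `P(X = k) = k^-alpha / zeta(alpha, x_min)`; `x_min` is then chosen
#' to minimise the Kolmogorov-Smirnov distance between the empirical
#' and fitted tail distributions. The fit is flagged implausible when
#' the minimised KS distance exceeds `gof_cutoff` — a deliberately
#' simple screen that separates genuine power-law tails from
#' exponential-tailed controls at the sample sizes used here, not a
#' formal hypothesis test.
#'
#' @param x positive integer observations; at least `min_obs` of them.
#' @param xmin fix the lower cutoff instead of scanning.
#' @param min_obs minimum number of observations (configurable floor).
#' @param min_tail candidates keeping fewer than this many tail
#'   observations are not considered.
#' @param xmin_quantile candidates above this sample quantile are not
#'   considered, so the scan cannot retreat into an arbitrarily small
#'   far tail where any distribution looks scale-free.
#' @param gof_cutoff KS distance above which the fit is flagged.
#' @param max_candidates scan at most this many candidate cutoffs.
#' @return An object of class `"powerlaw_fit"`: `exponent`, `xmin`,
#'   `ks` (goodness-of-fit statistic), `n_tail`, `plausible`, `n`.
#' @seealso [rpowerlaw()] to generate calibration samples; [tidy()] and
#'   [glance()] methods.
#' @export
#' @examples
#' x <- rpowerlaw(2000, exponent = 1.8, seed = 1)
#' fit_power_law(x)
fit_power_law <- function(x, xmin = NULL, min_obs = 50, min_tail = 50,
                          xmin_quantile = 0.9, gof_cutoff = 0.03,
                          max_candidates = 100) {
  x <- as.numeric(x)
  if (any(x < 1) || any(x != round(x)))
    stop("fit_power_law: x must be positive integers", call. = FALSE)
  if (length(x) < min_obs)
    stop("fit_power_law: need at least ", min_obs, " observations",
         call. = FALSE)

  fit_at <- function(xm) {
    tail_x <- x[x >= xm]
    n <- length(tail_x)
    slx <- sum(log(tail_x))
    nll <- function(alpha) n * log(hurwitz_zeta(alpha, xm)) + alpha * slx
    alpha <- optimize(nll, c(1.001, 8))$minimum
    u <- sort(unique(tail_x))
    # theoretical P(X <= k) = 1 - zeta(alpha, k + 1) / zeta(alpha, xmin)
    th <- 1 - hurwitz_zeta(alpha, u + 1) / hurwitz_zeta(alpha, xm)
    # both CDFs right-continuous: compare at the observed support points
    emp <- cumsum(tabulate(match(tail_x, u))) / n
    ks <- max(abs(emp - th))
    list(alpha = alpha, ks = ks, n_tail = n)
  }

  if (is.null(xmin)) {
    cand <- sort(unique(x))
    cand <- cand[vapply(cand, function(xm) sum(x >= xm), 0) >= min_tail &
                   cand <= stats::quantile(x, xmin_quantile)]
    if (!length(cand)) cand <- min(x)
    if (length(cand) > max_candidates)
      cand <- cand[unique(round(seq(1, length(cand),
                                    length.out = max_candidates)))]
    fits <- lapply(cand, fit_at)
    best <- which.min(vapply(fits, `[[`, 0, "ks"))
    xmin <- cand[best]
    f <- fits[[best]]
  } else {
    if (xmin < min(x))
      stop("fit_power_law: xmin below the smallest observation",
           call. = FALSE)
    f <- fit_at(xmin)
  }
  structure(list(exponent = f$alpha, xmin = xmin, ks = f$ks,
                 n_tail = f$n_tail, plausible = f$ks <= gof_cutoff,
                 n = length(x), gof_cutoff = gof_cutoff),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(paste0("<powerlaw_fit> alpha = %.3f, xmin = %g, ",
                     "KS = %.4f (%s), tail n = %d of %d\n"),
              x$exponent, x$xmin, x$ks,
              if (x$plausible) "plausible" else "flagged poor",
              x$n_tail, x$n))
  invisible(x)
}

#' @rdname fit_power_law
#' @param x a `"powerlaw_fit"`.
#' @param ... unused.
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble::tibble(term = c("exponent", "xmin"),
                 estimate = c(x$exponent, x$xmin))
}

#' @rdname fit_power_law
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble::tibble(exponent = x$exponent, xmin = x$xmin, ks = x$ks,
                 n_tail = x$n_tail, n = x$n, plausible = x$plausible)
}

#' Sample a discrete power law
#'
#' Exact inverse-CDF sampling of `P(X = k) propto k^-exponent` for
#' `k >= xmin` up to an internal cap, with the (small) super-cap tail
#' drawn from the continuous Pareto approximation.
#'
#' @param n sample size.
#' @param exponent power-law exponent, `> 1`.
#' @param xmin smallest value, `>= 1`.
#' @param seed optional RNG seed.
#' @param cap tabulation cap for exact inversion.
#' @return Integer-valued numeric vector of length `n`.
#' @export
rpowerlaw <- function(n, exponent, xmin = 1, seed = NULL, cap = 1e5) {
  if (exponent <= 1) stop("exponent must be > 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  k <- xmin:cap
  w <- k^(-exponent)
  z <- hurwitz_zeta(exponent, xmin)
  p_tail <- max(0, 1 - sum(w) / z)
  u <- runif(n)
  cdf <- cumsum(w) / z
  out <- k[findInterval(u, c(0, cdf)) ]
  over <- u > cdf[length(cdf)]
  if (any(over)) {
    v <- runif(sum(over))
    out[over] <- floor(cap * (1 - v)^(-1 / (exponent - 1)))
  }
  out
}

#' Scaling of avalanche size with duration
#'
#' Groups avalanches into duration classes and returns the slope of
#' mean log-size against log-duration — the size-duration scaling
#' exponent of crackling-noise analyses.
#'
#' @param avalanches an `"avalanche_set"` tibble from
#'   [detect_avalanches()], needing at least two distinct durations.
#' @return The scaling exponent (slope) as a scalar, with the
#'   underlying per-class means in attribute `"classes"`.
#' @export
#' @examples
#' av <- detect_avalanches(c(1, 0, 2, 2, 0, 3, 3, 3, 0))
#' size_duration_scaling(av)
size_duration_scaling <- function(avalanches) {
  if (length(unique(avalanches$duration_ms)) < 2)
    stop("size_duration_scaling: need >= 2 distinct durations",
         call. = FALSE)
  classes <- avalanches |>
    dplyr::group_by(.data$duration_ms) |>
    dplyr::summarise(mean_log_size = mean(log(.data$size)),
                     n = dplyr::n(), .groups = "drop")
  slope <- coef(lm(mean_log_size ~ log(duration_ms), data = classes))[[2]]
  attr(slope, "classes") <- classes
  slope
}
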