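# Classic empirical mode decomposition (sifting with cubic-spline
# envelopes and mirrored boundaries) and the per-IMF statistical features.

# Strict interior local extrema of a signal.
find_extrema <- function(x) {
  n <- length(x)
  d <- diff(x)
  s <- sign(d)
  # collapse flat runs so plateaus count once
  nz <- which(s != 0)
  if (length(nz) < 2) return(list(max = integer(0), min = integer(0)))
  idx <- nz[-length(nz)]; nxt <- nz[-1]
  turn <- which(s[idx] != s[nxt])
  pos <- idx[turn] + 1L
  list(max = pos[s[idx[turn]] > 0], min = pos[s[idx[turn]] < 0])
}

# Cubic-spline envelope through extrema, mirror-extending `n_mirror`
# extrema beyond each end to suppress boundary swings.
envelope_spline <- function(x, ext, n_mirror = 2) {
  n <- length(x)
  xs <- ext; ys <- x[ext]
  m <- min(n_mirror, length(ext))
  left_x <- 2 * 1 - rev(ext[seq_len(m)]);  left_y <- rev(x[ext[seq_len(m)]])
  right_i <- ext[seq.int(length(ext) - m + 1L, length(ext))]
  right_x <- 2 * n - rev(right_i);         right_y <- rev(x[right_i])
  px <- c(left_x, xs, right_x); py <- c(left_y, ys, right_y)
  keep <- !duplicated(px)
  spline(px[keep], py[keep], xout = seq_len(n), method = "fmm")$y
}

#' Empirical mode decomposition by sifting
#'
#' Repeatedly subtracts the mean of the cubic-spline upper and lower
#' envelopes until the Cauchy standard-deviation criterion
#' `sum((h_prev - h)^2) / sum(h_prev^2) < sd_tol` is met (or
#' `max_sift_iter` reached), then peels the IMF off and continues on the
#' residual until it has fewer than 2 extrema or `max_imfs` IMFs have been
#' extracted. The IMFs plus the residual reconstruct the input exactly by
#' construction.
#'
#' @param x numeric signal, length >= 4, finite.
#' @param max_imfs cap on extracted IMFs (default 12).
#' @param sd_tol Cauchy criterion tolerance (default 0.2).
#' @param max_sift_iter sifting iteration cap per IMF (default 100).
#' @return An `imf_set`: `imfs` (list, highest frequency first), `residual`.
#' @export
sift <- function(x, max_imfs = 12, sd_tol = 0.2, max_sift_iter = 100) {
  if (length(x) < 4) abort_invalid("signal too short for EMD")
  if (any(!is.finite(x))) abort_invalid("signal must be finite")
  imfs <- list()
  resid <- as.numeric(x)
  while (length(imfs) < max_imfs) {
    ext <- find_extrema(resid)
    if (length(ext$max) + length(ext$min) < 2 ||
        length(ext$max) < 1 || length(ext$min) < 1) break
    h <- resid
    for (it in seq_len(max_sift_iter)) {
      e <- find_extrema(h)
      if (length(e$max) < 2 || length(e$min) < 2) break
      upper <- envelope_spline(h, e$max)
      lower <- envelope_spline(h, e$min)
      m <- (upper + lower) / 2
      h_new <- h - m
      sd_c <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
      h <- h_new
      if (sd_c < sd_tol) break
    }
    imfs[[length(imfs) + 1L]] <- h
    resid <- resid - h
  }
  structure(list(imfs = imfs, residual = resid), class = "imf_set")
}

#' Standardize an IMF set to a fixed count
#'
#' Keeps the first `m_target` IMFs (highest frequency first); if fewer are
#' available, pads with zero signals and emits a notice. The residual is
#' untouched.
#'
#' @param s an `imf_set`.
#' @param m_target target IMF count (default 9).
#' @return The standardized `imf_set`.
#' @export
standardize_imfs <- function(s, m_target = 9) {
  stopifnot(inherits(s, "imf_set"))
  if (!is_count(m_target)) abort_invalid("m_target must be a count >= 1")
  m <- length(s$imfs)
  n <- length(s$residual)
  if (m >= m_target) {
    s$imfs <- s$imfs[seq_len(m_target)]
  } else {
    notice("only %d IMFs extracted; padding to %d with zero signals", m, m_target)
    s$imfs <- c(s$imfs, replicate(m_target - m, numeric(n), simplify = FALSE))
  }
  s
}

#' The 14 per-IMF statistical features
#'
#' Fixed ordered set: mean, maximum, minimum, first quartile, third
#' quartile, interquartile range, median, population variance, population
#' standard deviation, excess kurtosis, skewness, root mean square, Hjorth
#' activity (the signal variance, listed separately by convention), and
#' peak-to-peak range. Skewness and kurtosis of a zero-variance signal are
#' defined as 0.
#'
#' @param imf numeric signal, length >= 2.
#' @return Named numeric vector of length 14.
#' @export
imf_statistics <- function(imf) {
  if (length(imf) < 2) abort_invalid("signal too short")
  n <- length(imf)
  mu <- mean(imf)
  m2 <- mean((imf - mu)^2)
  q <- quantile(imf, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (m2 > 0) {
    skew <- mean((imf - mu)^3) / m2^1.5
    kurt <- mean((imf - mu)^4) / m2^2 - 3
  } else skew <- kurt <- 0
  c(mean = mu, max = max(imf), min = min(imf), q1 = q[1], q3 = q[3],
    iqr = q[3] - q[1], median = q[2], variance = m2, sd = sqrt(m2),
    kurtosis = kurt, skewness = skew, rms = sqrt(mean(imf^2)),
    activity = m2, ptp = max(imf) - min(imf))
}

emd_stat_names <- function() names(imf_statistics(c(0, 1)))

#' Channels x IMFs x statistics EMD feature tensor
#'
#' Each channel of the recording is decomposed by [sift()], standardized to
#' `m_target` IMFs, and summarized by the 14 statistics — an N x M x C
#' block whose flattened length is `channels * 9 * 14` (2142 for the
#' 17-channel montage).
#'
#' @param rec a preprocessed [recording()].
#' @param m_target IMF count after standardization (default 9).
#' @param max_imfs,sd_tol,max_sift_iter passed to [sift()].
#' @return 3-d array with dimnames (channel, imf, statistic) and class
#'   `emd_tensor`.
#' @export
emd_feature_tensor <- function(rec, m_target = 9, max_imfs = 12,
                               sd_tol = 0.2, max_sift_iter = 100) {
  stopifnot(inherits(rec, "recording"))
  nch <- nrow(rec$data)
  stats_n <- emd_stat_names()
  out <- array(0, dim = c(nch, m_target, length(stats_n)),
               dimnames = list(rec$channel_names,
                               paste0("imf", seq_len(m_target)), stats_n))
  for (i in seq_len(nch)) {
    s <- standardize_imfs(sift(rec$data[i, ], max_imfs = max_imfs,
                               sd_tol = sd_tol,
                               max_sift_iter = max_sift_iter), m_target)
    for (j in seq_len(m_target)) out[i, j, ] <- imf_statistics(s$imfs[[j]])
  }
  class(out) <- c("emd_tensor", class(out))
  out
}
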