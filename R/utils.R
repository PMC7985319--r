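#' Weighted mean and weighted median
#'
#' The weighted median is the 0.5 quantile of the weight CDF, using the
#' midpoint-CDF convention with linear interpolation between adjacent values:
#' with equal weights it reproduces `median()` for both odd and even `n`.
#'
#' @param x numeric values.
#' @param w positive weights, recycled to `length(x)`.
#' @param p quantile level (default 0.5, the weighted median).
#' @return a single numeric value, `NA` if no complete observations.
#' @export
weighted_quantile <- function(x, w = rep(1, length(x)), p = 0.5) {
  stopifnot(length(p) == 1L, p >= 0, p <= 1)
  w <- rep_len(w, length(x))
  keep <- !is.na(x) & !is.na(w)
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L) return(NA_real_)
  if (any(w <= 0)) stop("weights must be positive")
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  # midpoint-CDF positions: (c_k - w_k / 2) / W
  pos <- (cw - w / 2) / cw[length(cw)]
  if (p <= pos[1L]) return(x[1L])
  if (p >= pos[length(pos)]) return(x[length(x)])
  stats::approx(pos, x, xout = p, ties = "ordered")$y
}

#' @rdname weighted_quantile
#' @export
weighted_median <- function(x, w = rep(1, length(x))) {
  weighted_quantile(x, w, p = 0.5)
}

#' @rdname weighted_quantile
#' @export
weighted_mean <- function(x, w = rep(1, length(x))) {
  w <- rep_len(w, length(x))
  keep <- !is.na(x) & !is.na(w)
  if (!any(keep)) return(NA_real_)
  sum(x[keep] * w[keep]) / sum(w[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_missing_cols <- function(df, cols, where = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 where, paste(miss, collapse = ", ")), call. = FALSE)
  }
}
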