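# Shared internal helpers: window inventory, shift/rolling primitives.

# Rolling windows shared by the glucose feature space. Labels are part of the
# public column-naming scheme (<base>_<window>_<sum|mean>).
.windows_min <- c("30m" = 30, "60m" = 60, "90m" = 90,
                  "2h" = 120, "3h" = 180, "8h" = 480, "24h" = 1440)

# Windows of <= 3 h count as short-term, 8 h and 24 h as long-term, when
# grouping feature importance.
.short_windows <- c("30m", "60m", "90m", "2h", "3h")
.long_windows <- c("8h", "24h")

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Shift a vector by k samples: k > 0 is a lag (values from the past),
# k < 0 a lead. Out-of-range positions become NA.
#' @noRd
shift_vec <- function(x, k) {
  n <- length(x)
  if (k == 0L || n == 0L) return(x)
  if (abs(k) >= n) return(rep(NA_real_, n))
  if (k > 0L) c(rep(NA_real_, k), x[seq_len(n - k)])
  else c(x[seq_len(n + k) - k], rep(NA_real_, -k))
}

# Trailing rolling sum over windows of exactly `w` samples ending at the
# current sample. Positions with fewer than `w` samples of history are NA:
# windows never extend past the start of a stretch.
#' @noRd
roll_sum <- function(x, w) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (w <= n) {
    cs <- c(0, cumsum(x))
    idx <- seq.int(w, n)
    out[idx] <- cs[idx + 1L] - cs[idx + 1L - w]
  }
  out
}

#' @noRd
roll_mean <- function(x, w) roll_sum(x, w) / w

# Rolling mean of x over only those in-window samples where `mask` is TRUE
# (e.g. meal fractions averaged over meal-carrying rows). A full window with
# no masked support yields 0 by convention.
#' @noRd
roll_mean_masked <- function(x, mask, w) {
  mask <- as.numeric(mask)
  num <- roll_sum(x * mask, w)
  den <- roll_sum(mask, w)
  out <- ifelse(den > 0, num / den, 0)
  out[is.na(num)] <- NA_real_
  out
}

# Row-wise sd of a matrix without na.rm: any NA in the row propagates,
# matching the never-impute rule at stretch boundaries.
#' @noRd
row_sd <- function(m) {
  k <- ncol(m)
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (k - 1))
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Derive a stream-specific child seed from a run seed, staying within the
# 32-bit integer range R requires.
#' @noRd
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 101 + offset) %% .Machine$integer.max)
}
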