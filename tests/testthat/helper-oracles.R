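# Independent oracles used across test files.

# Exhaustive DTW: minimum over ALL admissible monotone warping paths with
# step set {(1,0),(0,1),(1,1)}, enumerated recursively (exponential; only
# for short sequences).
dtw_exhaustive <- function(a, b) {
    if (is.null(dim(a))) a <- matrix(as.numeric(a), ncol = 1)
    if (is.null(dim(b))) b <- matrix(as.numeric(b), ncol = 1)
    n <- nrow(a); m <- nrow(b)
    cost <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
    rec <- function(i, j) {
        c0 <- cost(i, j)
        if (i == n && j == m) return(c0)
        opts <- c(if (i < n) rec(i + 1, j),
                  if (j < m) rec(i, j + 1),
                  if (i < n && j < m) rec(i + 1, j + 1))
        c0 + min(opts)
    }
    rec(1, 1)
}

# Textbook Pearson correlation, written out longhand.
pcc_textbook <- function(x, y) {
    x <- as.numeric(x); y <- as.numeric(y)
    mx <- sum(x) / length(x); my <- sum(y) / length(y)
    sum((x - mx) * (y - my)) /
        sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Strict-neighbour local-extremum counter with plateau collapsing, written
# as an explicit scan independent of the package's vectorized version.
extrema_scan <- function(x) {
    # collapse plateaus to single representatives
    y <- x[c(TRUE, diff(x) != 0)]
    if (length(y) < 3L) return(0L)
    cnt <- 0L
    for (i in 2:(length(y) - 1L)) {
        if ((y[i] > y[i - 1] && y[i] > y[i + 1]) ||
            (y[i] < y[i - 1] && y[i] < y[i + 1]))
            cnt <- cnt + 1L
    }
    cnt
}

# zero-phase gain of a 2nd-order Butterworth design at frequency f (Hz),
# via the designed filter's complex frequency response (|H|^2 because the
# filter is applied forward and backward).
butter_gain2 <- function(f, rate, band, type) {
    flt <- signal::butter(2, band / (rate / 2), type = type)
    z <- exp(-1i * 2 * pi * f / rate)
    H <- sum(flt$b * z^(seq_along(flt$b) - 1)) /
        sum(flt$a * z^(seq_along(flt$a) - 1))
    Mod(H)^2
}
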