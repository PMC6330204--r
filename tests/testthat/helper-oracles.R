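# Independent brute-force oracles and fixture builders used across tests.
# Each oracle re-derives the quantity from first principles, sharing no code
# with the implementation it checks.

# Build a gap profile with exact ring gap fractions (homogeneous cells).
make_profile <- function(p_gap, width = 5, max_zenith = 60, n_cells = 8,
                         n_pixels = 1000) {
  breaks <- seq(0, max_zenith, by = width)
  mid <- (head(breaks, -1) + breaks[-1]) / 2
  stopifnot(length(p_gap) == length(mid))
  rings <- data.frame(zenith_lo = head(breaks, -1), zenith_hi = breaks[-1],
                      theta_mid = mid, n_pixels = rep(n_pixels, length(mid)),
                      n_sky = n_pixels * p_gap, p_gap = p_gap)
  cells <- do.call(rbind, lapply(seq_along(mid), function(i)
    data.frame(ring = i, cell = seq_len(n_cells),
               n_pixels = n_pixels / n_cells,
               n_sky = n_pixels / n_cells * p_gap[i], p_gap = p_gap[i])))
  structure(list(rings = rings, cells = cells, ring_width_deg = width,
                 n_azimuth_cells = n_cells, max_zenith = max_zenith,
                 n_images = 1L),
            class = "gap_profile")
}

# Exhaustive isodata oracle: scan all 256 candidate 8-bit cut points for the
# fixed-point condition. A cut t is a fixed point when the threshold implied
# by its two class means, T = (mean(x <= t) + mean(x > t)) / 2, induces the
# same partition as t itself. Returns the implied thresholds of all fixed
# points (usually exactly one).
isodata_scan_oracle <- function(x) {
  x <- as.numeric(x)
  fixed <- c()
  for (t0 in 0:255) {
    lo <- x[x <= t0]; hi <- x[x > t0]
    if (length(lo) == 0 || length(hi) == 0) next
    T_implied <- (mean(lo) + mean(hi)) / 2
    if (sum(x <= T_implied) == sum(x <= t0)) fixed <- c(fixed, T_implied)
  }
  unique(fixed)
}

# Exact two-sided rank-sum p-value by enumeration of all C(m+n, m) labelings.
wilcoxon_enum_oracle <- function(x, y) {
  all_v <- c(x, y)
  m <- length(x)
  combs <- utils::combn(length(all_v), m)
  ranks <- rank(all_v)
  u_obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
  u_all <- apply(combs, 2, function(idx) sum(ranks[idx]) - m * (m + 1) / 2)
  mu <- m * length(y) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}

# Brute-force GLCM MEAN/DISSIMILARITY at one output pixel: double loop over
# the window's vertical pairs, explicit symmetric co-occurrence table.
glcm_brute_oracle <- function(q, row, col, window = 3) {
  half <- (window - 1) / 2
  rs <- (row - half):(row + half); cs <- (col - half):(col + half)
  if (min(rs) < 1 || min(cs) < 1 || max(rs) > nrow(q) || max(cs) > ncol(q))
    return(c(mean = NA_real_, dissimilarity = NA_real_))
  w <- q[rs, cs]
  if (any(!is.finite(w))) return(c(mean = NA_real_, dissimilarity = NA_real_))
  pairs <- list()
  for (r in 2:window) for (cc in 1:window)
    pairs[[length(pairs) + 1]] <- c(w[r, cc], w[r - 1, cc])
  entries <- do.call(rbind, c(pairs, lapply(pairs, rev)))
  p <- 1 / nrow(entries)
  c(mean = sum(entries[, 1] * p),
    dissimilarity = sum(abs(entries[, 1] - entries[, 2]) * p))
}

# Brute-force focal mean/sd at one pixel (window truncated at edges, NA
# excluded).
focal_brute_oracle <- function(m, row, col, window = 9) {
  half <- (window - 1) / 2
  rs <- max(1, row - half):min(nrow(m), row + half)
  cs <- max(1, col - half):min(ncol(m), col + half)
  v <- as.numeric(m[rs, cs])
  v <- v[is.finite(v)]
  c(mean = if (length(v) >= 1) mean(v) else NA_real_,
    sd = if (length(v) >= 2) stats::sd(v) else NA_real_)
}

# Tiny deterministic hemis_band from a plain matrix (full-frame footprint not
# needed; circular footprint centred in the matrix).
band_from_matrix <- function(m) {
  arr <- array(rep(m, 3), c(nrow(m), ncol(m), 3))
  extract_blue_band(hemis_image(arr))
}
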