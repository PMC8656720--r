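# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, BFS) so they cannot share a defect with
# the implementations they check.

# per-pixel clipped-window mean threshold, O(N * w^2)
naive_bradley <- function(channel, window_px = 41L, sensitivity = 0.15) {
  n <- nrow(channel); m <- ncol(channel)
  h <- (window_px - 1L) %/% 2L
  out <- matrix(FALSE, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      rs <- max(1L, i - h):min(n, i + h)
      cs <- max(1L, j - h):min(m, j + h)
      out[i, j] <- channel[i, j] > mean(channel[rs, cs]) * (1 - sensitivity)
    }
  }
  out
}

# all-pairs vicinity counter with reference self-exclusion by coordinates
brute_count_in_vicinity <- function(cells, refs, radius_um,
                                    reference_phenotype = "malignant") {
  phs <- unique(cells$phenotype)
  counts <- setNames(integer(length(phs)), phs)
  if (nrow(refs) == 0L) return(counts)
  for (i in seq_len(nrow(cells))) {
    best <- Inf
    for (j in seq_len(nrow(refs))) {
      if (cells$phenotype[i] == reference_phenotype &&
          cells$x_um[i] == refs$x_um[j] && cells$y_um[i] == refs$y_um[j]) next
      d <- sqrt((cells$x_um[i] - refs$x_um[j])^2 +
                (cells$y_um[i] - refs$y_um[j])^2)
      best <- min(best, d)
    }
    if (best <= radius_um)
      counts[cells$phenotype[i]] <- counts[cells$phenotype[i]] + 1L
  }
  counts
}

# 8-connected BFS flood fill from a start pixel; returns reached mask
flood_reach <- function(mask, start_row, start_col) {
  reached <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!mask[start_row, start_col]) return(reached)
  queue <- list(c(start_row, start_col))
  reached[start_row, start_col] <- TRUE
  while (length(queue)) {
    p <- queue[[1L]]; queue <- queue[-1L]
    for (di in -1:1) for (dj in -1:1) {
      qi <- p[1] + di; qj <- p[2] + dj
      if (qi >= 1 && qi <= nrow(mask) && qj >= 1 && qj <= ncol(mask) &&
          mask[qi, qj] && !reached[qi, qj]) {
        reached[qi, qj] <- TRUE
        queue[[length(queue) + 1L]] <- c(qi, qj)
      }
    }
  }
  reached
}

# binary disk raster, 1-based pixel-index coordinates
disk_mask <- function(nr, nc, ci, cj, r) {
  outer(seq_len(nr), seq_len(nc), function(i, j) (i - ci)^2 + (j - cj)^2 <= r^2)
}

# nearest-distance recall/precision between planted and detected centroids
centroid_match <- function(truth_xy, det_xy, radius_um = 5) {
  if (nrow(det_xy) == 0L || nrow(truth_xy) == 0L)
    return(list(recall = 0, precision = 0, matched_err = numeric(0)))
  d2 <- outer(truth_xy$x_um, det_xy$x_um, "-")^2 +
        outer(truth_xy$y_um, det_xy$y_um, "-")^2
  t_nn <- sqrt(apply(d2, 1L, min))
  d_nn <- sqrt(apply(d2, 2L, min))
  list(recall = mean(t_nn <= radius_um),
       precision = mean(d_nn <= radius_um),
       matched_err = d_nn[d_nn <= radius_um])
}

# Welch statistic from the textbook formulas, no stats:: machinery
formula_welch <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (length(a)^2 * (length(a) - 1)) +
                 vb^2 / (length(b)^2 * (length(b) - 1)))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# 256-bin global Otsu threshold: the test-only baseline the adaptive rule
# is compared against under illumination gradients
otsu_threshold <- function(x) {
  cnt <- hist(pmin(pmax(x, 0), 1), breaks = seq(0, 1, length.out = 257),
              plot = FALSE)$counts
  p <- cnt / sum(cnt)
  w0 <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  sb <- (mu[256] * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  which.max(sb) / 256
}

# small fast fixtures
mini_geom <- function() field_geometry(256L, 256L, 0.5)

mini_preset <- function(...) {
  stage_preset("mini", malignant_intensity = 12,
               compartment_targets = c(cd4 = 450, cd8 = 150, nk = 300),
               exhausted_fraction = 0.25, cluster_sd_um = 25, n_foci = 2, ...)
}

quiet_render <- function() render_params(noise_sd = 0,
                                         illumination_gradient_amplitude = 0)
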