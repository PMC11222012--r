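# Periodic wavelet packet transform with the db4 (8-tap) orthogonal filter
# pair. Tree nodes hold channels x coefficients matrices so all channels are
# transformed in one pass. A band signal is synthesized by zeroing every
# terminal node outside the band and inverting; the transform is orthogonal,
# so synthesis is the transpose of analysis and reconstruction from all
# nodes is exact. Terminal nodes are indexed in natural (filter-path) order
# internally; the sequency (frequency) rank of each node follows the
# standard rule that children of a node sitting at an odd frequency
# position have their low/high spectral halves swapped by the decimation.

# db4 decomposition lowpass filter (reversed scaling coefficients).
DB4_DEC_LO <- c(-0.010597401784997278, 0.032883011666982945,
                0.030841381835986965, -0.187034811718881140,
                -0.027983769416983849, 0.630880767929590360,
                0.714846570552541500, 0.230377813308855230)
DB4_DEC_HI <- rev(DB4_DEC_LO) * c(1, -1, 1, -1, 1, -1, 1, -1)

# One analysis step on a channels x n matrix: correlate rows with the
# filter and keep even phases (periodic boundary).
wpt_step_down <- function(v, h) {
  n <- ncol(v)
  k <- seq(0, n / 2 - 1)
  out <- matrix(0, nrow(v), n / 2)
  for (j in seq_along(h))
    out <- out + h[j] * v[, ((2 * k + j - 1) %% n) + 1, drop = FALSE]
  out
}

# Transpose (synthesis) of the analysis step applied to one child.
wpt_step_up <- function(a, h, n) {
  v <- matrix(0, nrow(a), n)
  k <- seq(0, n / 2 - 1)
  for (j in seq_along(h)) {
    idx <- ((2 * k + j - 1) %% n) + 1   # distinct columns for fixed j
    v[, idx] <- v[, idx] + h[j] * a
  }
  v
}

# Full packet analysis of a channels x n matrix: list of terminal-node
# coefficient matrices in natural order.
wpt_analyze <- function(X, level) {
  cur <- list(rbind(X))
  for (l in seq_len(level)) {
    nxt <- vector("list", 2 * length(cur))
    for (p in seq_along(cur)) {
      nxt[[2 * p - 1]] <- wpt_step_down(cur[[p]], DB4_DEC_LO)
      nxt[[2 * p]] <- wpt_step_down(cur[[p]], DB4_DEC_HI)
    }
    cur <- nxt
  }
  cur
}

# Synthesize channels x n signals from terminal-node matrices (natural
# order); NULL entries are treated as zero.
wpt_synthesize <- function(nodes, level, n) {
  cur <- nodes
  for (l in seq(level, 1)) {
    len <- n / 2^(l - 1)
    nxt <- vector("list", length(cur) / 2)
    for (p in seq_along(nxt)) {
      a <- cur[[2 * p - 1]]
      d <- cur[[2 * p]]
      v <- if (!is.null(a)) wpt_step_up(a, DB4_DEC_LO, len)
      if (!is.null(d)) {
        u <- wpt_step_up(d, DB4_DEC_HI, len)
        v <- if (is.null(v)) u else v + u
      }
      nxt[p] <- list(v)
    }
    cur <- nxt
  }
  if (is.null(cur[[1]])) stop("no terminal nodes selected")
  cur[[1]]
}

# Frequency (sequency) rank of each natural-order terminal node, 0-based.
wpt_freq_order <- function(level) {
  ranks <- 0L
  for (l in seq_len(level)) {
    nxt <- integer(2 * length(ranks))
    for (p in seq_along(ranks)) {
      fr <- ranks[p]
      if (fr %% 2L == 0L) {
        nxt[2 * p - 1] <- 2L * fr
        nxt[2 * p] <- 2L * fr + 1L
      } else {
        nxt[2 * p - 1] <- 2L * fr + 1L
        nxt[2 * p] <- 2L * fr
      }
    }
    ranks <- nxt
  }
  ranks
}

# Assign each terminal node to the band with the largest overlap of its
# nominal support (ties to the lower band); nodes overlapping no band stay
# unassigned. Returns data.frame(node = natural index, band).
wpt_band_assignment <- function(bands, fs, level) {
  nnodes <- 2^level
  width <- (fs / 2) / nnodes
  fr <- wpt_freq_order(level)
  f0 <- fr * width
  f1 <- f0 + width
  band <- rep(NA_character_, nnodes)
  for (i in seq_len(nnodes)) {
    ov <- pmax(0, pmin(f1[i], bands$hi) - pmax(f0[i], bands$lo))
    if (max(ov) > 0) band[i] <- bands$band[which.max(ov)]
  }
  data.frame(node = seq_len(nnodes), band = band, stringsAsFactors = FALSE)
}

# Band-limited reconstruction of one channel vector from selected terminal
# nodes (used by tests; decompose_bands works on whole matrices).
wpt_band_signal <- function(x, level, nodes) {
  terms <- wpt_analyze(rbind(x), level)
  keep <- vector("list", length(terms))
  keep[nodes] <- terms[nodes]
  drop(wpt_synthesize(keep, level, length(x)))
}
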