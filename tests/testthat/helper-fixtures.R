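# Small design: 2 runs x 8 trials, 2 repetitions per setting, 102
# volumes (3 lead-in + 8 x 12 trial volumes + 3 trailing), 2 participants.
tiny_design <- function(overrides = list()) {
  base <- list(
    n_runs = 2L, trials_per_run = 8L, repetitions_per_setting = 2L,
    volumes_per_run = 102L, n_participants = 2L
  )
  base[names(overrides)] <- overrides
  build_design(base)
}

tiny_truth <- function(scenario = "null", seed = 1, rois = c("V1", "V2"),
                       n_voxels = c(V1 = 40L, V2 = 30L), ...) {
  make_ground_truth(
    scenario = scenario, seed = seed, rois = rois, n_voxels = n_voxels, ...
  )
}

# Pattern sets with planted antisymmetric orientation structure, for
# decoding tests that bypass the simulator.
toy_pattern_set <- function(n_runs = 4, per_run = 4, n_feat = 20,
                            amplitude = 0, noise = 1, seed = 1,
                            pattern = NULL, condition = "DG",
                            phase = "action", participant = 1L) {
  set.seed(seed)
  if (is.null(pattern)) {
    pattern <- stats::rnorm(n_feat)
    pattern <- pattern / sqrt(sum(pattern^2))
  }
  n <- n_runs * per_run
  orientation <- rep(c("+45", "-45"), length.out = n)
  sign <- ifelse(orientation == "+45", 1, -1)
  x <- matrix(stats::rnorm(n * n_feat, sd = noise), n, n_feat) +
    amplitude * outer(sign, pattern)
  structure(
    list(
      x = x,
      meta = tibble::tibble(
        participant = participant,
        run = rep(seq_len(n_runs), each = per_run),
        trial = rep(seq_len(per_run), n_runs),
        condition = condition, orientation = orientation, phase = phase
      ),
      roi = "toy"
    ),
    class = "pattern_set"
  )
}

# Brute-force maximum-margin separator for 2-D separable data. The
# optimal hard-margin hyperplane is supported by either one point of
# each class (perpendicular bisector of the closest pair) or an edge of
# one class's hull plus a point of the other; enumerate all candidates,
# keep feasible ones, pick the widest margin. Independent of libsvm.
max_margin_oracle <- function(x, y) {
  lv <- unique(y)
  stopifnot(length(lv) == 2, ncol(x) == 2)
  pos <- x[y == lv[1], , drop = FALSE]
  neg <- x[y == lv[2], , drop = FALSE]
  candidates <- list()
  for (i in seq_len(nrow(pos))) {
    for (j in seq_len(nrow(neg))) {
      w <- pos[i, ] - neg[j, ]
      if (sum(w^2) < 1e-12) next
      candidates[[length(candidates) + 1]] <-
        list(w = w, c = sum(w * (pos[i, ] + neg[j, ])) / 2)
    }
  }
  edge_candidates <- function(a, b) {
    # hyperplane parallel to edge (a1, a2), supported by point b
    out <- list()
    if (nrow(a) < 2) return(out)
    pairs <- utils::combn(nrow(a), 2)
    for (k in seq_len(ncol(pairs))) {
      a1 <- a[pairs[1, k], ]
      d <- a[pairs[2, k], ] - a1
      if (sum(d^2) < 1e-12) next
      for (j in seq_len(nrow(b))) {
        proj <- a1 + sum((b[j, ] - a1) * d) / sum(d^2) * d
        w <- b[j, ] - proj
        if (sum(w^2) < 1e-12) next
        out[[length(out) + 1]] <- list(w = w, c = sum(w * (b[j, ] + proj)) / 2)
      }
    }
    out
  }
  candidates <- c(candidates, edge_candidates(pos, neg),
                  edge_candidates(neg, pos))
  best <- NULL
  best_margin <- -Inf
  for (cand in candidates) {
    wn <- sqrt(sum(cand$w^2))
    d_pos <- (pos %*% cand$w - cand$c) / wn
    d_neg <- (neg %*% cand$w - cand$c) / wn
    s <- if (all(d_pos > -1e-9) && all(d_neg < 1e-9)) 1 else
      if (all(d_pos < 1e-9) && all(d_neg > -1e-9)) -1 else next
    margin <- min(c(s * d_pos, -s * d_neg))
    if (margin > best_margin) {
      best_margin <- margin
      best <- list(w = s * cand$w / wn, c = s * cand$c / wn,
                   margin = margin, labels = lv)
    }
  }
  best
}

oracle_predict <- function(oracle, x) {
  d <- as.numeric(x %*% oracle$w - oracle$c)
  ifelse(d >= 0, oracle$labels[1], oracle$labels[2])
}

# Step-up FDR oracle by direct enumeration of the BH definition.
fdr_stepup_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(m)) {
    if (ps[i] <= i / m * q) k <- i
  }
  sig <- logical(m)
  if (k > 0) sig[ord[seq_len(k)]] <- TRUE
  sig
}
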