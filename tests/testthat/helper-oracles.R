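# Independent straight-line transcription of the encircling/hunting
# equations, sharing the engine's random draw order (q1 then q2 per
# leader, leaders best-to-third, wolves in index order). Used as the
# oracle for full-update equivalence.
gwo_transcription <- function(objective, lower, upper, n_wolves,
                              n_iterations, seed) {
  set.seed(seed)
  n <- length(lower)
  pos <- matrix(0, n_wolves, n)
  for (i in seq_len(n_wolves)) {
    pos[i, ] <- lower + runif(n) * (upper - lower)
  }
  fit <- apply(pos, 1, objective)
  best_fit <- min(fit)
  best_pos <- pos[which.min(fit), ]
  hist <- best_fit
  for (t in seq_len(n_iterations)) {
    p <- 2 * (1 - t / n_iterations)
    ord <- order(fit)
    Ta <- pos[ord[1], ]; Tb <- pos[ord[2], ]; Td <- pos[ord[3], ]
    for (i in seq_len(n_wolves)) {
      Ti <- pos[i, ]
      q1 <- runif(n); q2 <- runif(n)
      U1 <- 2 * p * q1 - p; S1 <- 2 * q2
      Va <- abs(S1 * Ta - Ti); T1 <- Ta - U1 * Va
      q1 <- runif(n); q2 <- runif(n)
      U2 <- 2 * p * q1 - p; S2 <- 2 * q2
      Vb <- abs(S2 * Tb - Ti); T2 <- Tb - U2 * Vb
      q1 <- runif(n); q2 <- runif(n)
      U3 <- 2 * p * q1 - p; S3 <- 2 * q2
      Vd <- abs(S3 * Td - Ti); T3 <- Td - U3 * Vd
      pos[i, ] <- pmin(pmax((T1 + T2 + T3) / 3, lower), upper)
      fit[i] <- objective(pos[i, ])
      if (fit[i] < best_fit) {
        best_fit <- fit[i]
        best_pos <- pos[i, ]
      }
    }
    hist <- c(hist, best_fit)
  }
  list(best_fitness = best_fit, best_position = best_pos, history = hist)
}


# Brute-force per-pair tally, the oracle for confusion counts.
tally_oracle <- function(labels, predictions, positive) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(labels)) {
    a <- labels[i] == positive
    p <- predictions[i] == positive
    if (a && p) tp <- tp + 1L
    else if (!a && !p) tn <- tn + 1L
    else if (!a && p) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Mann-Whitney pair-counting AUC: P(score_pos > score_neg) + 0.5 ties.
auc_oracle <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (sp in pos) total <- total + sum(sp > neg) + 0.5 * sum(sp == neg)
  total / (length(pos) * length(neg))
}


# Reference convolution/pool output-size arithmetic, kept independent of
# the package's implementation: valid -> floor((n - k)/s) + 1, same ->
# ceiling(n/s).
ref_axis <- function(n, k, s, padding) {
  if (padding == "same") ceiling(n / s) else floor((n - k) / s) + 1
}

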