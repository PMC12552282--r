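# Independent oracles: deliberately naive reimplementations (explicit
# loops, no shared code paths with the package internals).

# Sample STD of the residual in every full circular window, by direct
# enumeration.
brute_std_filter <- function(M, mask, radius) {
  n <- nrow(M); m <- ncol(M)
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    vals <- c()
    ok <- TRUE
    for (di in -ceiling(radius):ceiling(radius)) {
      for (dj in -ceiling(radius):ceiling(radius)) {
        if (di^2 + dj^2 > radius^2 + 1e-9) next
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > n || jj < 1 || jj > m || !mask[ii, jj]) {
          ok <- FALSE; break
        }
        vals <- c(vals, M[ii, jj])
      }
      if (!ok) break
    }
    if (ok) out[i, j] <- stats::sd(vals)
  }
  out
}

# Mean of the k lowest circle-averaged noise-map values, by direct
# enumeration of every candidate circle.
brute_std_min <- function(L, mask, diameter, k) {
  n <- nrow(L); m <- ncol(L)
  rad <- diameter / 2
  scores <- c(); rows <- c(); cols <- c()
  for (i in seq_len(n)) for (j in seq_len(m)) {
    vals <- c()
    ok <- TRUE
    for (di in -ceiling(rad):ceiling(rad)) {
      for (dj in -ceiling(rad):ceiling(rad)) {
        if (di^2 + dj^2 > rad^2 + 1e-9) next
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > n || jj < 1 || jj > m || !mask[ii, jj] ||
            !is.finite(L[ii, jj])) {
          ok <- FALSE; break
        }
        vals <- c(vals, L[ii, jj])
      }
      if (!ok) break
    }
    if (ok) {
      scores <- c(scores, mean(vals)); rows <- c(rows, i); cols <- c(cols, j)
    }
  }
  if (length(scores) < k) stop("oracle: not enough candidates")
  ord <- order(scores, rows, cols)
  mean(scores[ord[seq_len(k)]])
}

# Line-by-line transcription of the weighted multi-rater AC2 estimator,
# built from explicit rater-pair loops rather than count-matrix algebra.
gwet_oracle <- function(scores, categories, w) {
  K <- length(categories)
  n_all <- nrow(scores)
  ri <- integer(0); keep <- integer(0)
  for (i in seq_len(n_all)) {
    r <- sum(!is.na(scores[i, ]))
    if (r >= 1) { keep <- c(keep, i); ri <- c(ri, r) }
  }
  scores <- scores[keep, , drop = FALSE]
  n <- length(keep)
  # per-item pairwise weighted agreement
  pa_i <- numeric(n)
  for (i in seq_len(n)) {
    x <- scores[i, ]; x <- x[!is.na(x)]
    if (length(x) < 2) { pa_i[i] <- 0; next }
    s <- 0
    for (g in seq_along(x)) for (h in seq_along(x)) {
      if (g == h) next
      s <- s + w[match(x[g], categories), match(x[h], categories)]
    }
    pa_i[i] <- s / (length(x) * (length(x) - 1))
  }
  two <- ri >= 2
  n2 <- sum(two)
  pa <- sum(pa_i[two]) / n2
  pik <- numeric(K)
  for (k in seq_len(K)) {
    for (i in seq_len(n)) {
      pik[k] <- pik[k] + sum(scores[i, ] == categories[k], na.rm = TRUE) / ri[i]
    }
    pik[k] <- pik[k] / n
  }
  Tw <- sum(w)
  pe <- Tw / (K * (K - 1)) * sum(pik * (1 - pik))
  ac2 <- (pa - pe) / (1 - pe)
  # item-level linearization
  gi <- numeric(n); pe_i <- numeric(n)
  for (i in seq_len(n)) {
    gi[i] <- (n / n2) * (pa_i[i] - pe * two[i]) / (1 - pe)
    s <- 0
    for (k in seq_len(K)) {
      s <- s + sum(scores[i, ] == categories[k], na.rm = TRUE) * (1 - pik[k])
    }
    pe_i[i] <- Tw / (K * (K - 1)) * s / ri[i]
  }
  gix <- gi - 2 * (1 - ac2) * (pe_i - pe) / (1 - pe)
  variance <- sum((gix - ac2)^2) / (n * (n - 1))
  list(ac2 = ac2, pa = pa, pe = pe, variance = variance)
}

# Seeded ratings table: rater 1 draws uniformly, the others copy rater 1
# with probability `copy_prob`, otherwise draw uniformly.
make_ratings <- function(n_items, n_raters, copy_prob = 0.8, seed = 1,
                         categories = 1:5, missing_frac = 0) {
  set.seed(seed)
  base <- sample(categories, n_items, replace = TRUE)
  sc <- matrix(NA_real_, n_items, n_raters)
  sc[, 1] <- base
  for (r in 2:n_raters) {
    copy <- stats::runif(n_items) < copy_prob
    sc[, r] <- ifelse(copy, base, sample(categories, n_items, replace = TRUE))
  }
  if (missing_frac > 0) {
    drop <- which(stats::runif(length(sc)) < missing_frac)
    sc[drop] <- NA
  }
  sc
}
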