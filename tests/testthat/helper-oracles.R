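# Independent brute-force oracles used to check the package's analytical
# code paths. These are deliberately slow, literal implementations.

# Three-factor balanced ANOVA sums of squares straight from the textbook
# definitions (deviations of marginal cell means), no model fitting.
oracle_factorial_ss <- function(df) {
  y <- df$value
  gm <- mean(y)
  A <- df$genotype; B <- df$regime; C <- df$harvest
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean); mC <- tapply(y, C, mean)
  mAB <- tapply(y, list(A, B), mean); mAC <- tapply(y, list(A, C), mean)
  mBC <- tapply(y, list(B, C), mean)
  mABC <- tapply(y, list(A, B, C), mean)
  nA <- length(mA); nB <- length(mB); nC <- length(mC)
  r <- length(y) / (nA * nB * nC)
  ssA <- nB * nC * r * sum((mA - gm)^2)
  ssB <- nA * nC * r * sum((mB - gm)^2)
  ssC <- nA * nB * r * sum((mC - gm)^2)
  ssAB <- nC * r * sum((mAB - outer(mA, rep(1, nB)) -
                          outer(rep(1, nA), mB) + gm)^2)
  ssAC <- nB * r * sum((mAC - outer(mA, rep(1, nC)) -
                          outer(rep(1, nA), mC) + gm)^2)
  ssBC <- nA * r * sum((mBC - outer(mB, rep(1, nC)) -
                          outer(rep(1, nB), mC) + gm)^2)
  dev3 <- array(0, dim = c(nA, nB, nC))
  for (a in seq_len(nA)) for (b in seq_len(nB)) for (cc in seq_len(nC)) {
    dev3[a, b, cc] <- mABC[a, b, cc] - mAB[a, b] - mAC[a, cc] - mBC[b, cc] +
      mA[a] + mB[b] + mC[cc] - gm
  }
  ssABC <- r * sum(dev3^2)
  fit3 <- mABC[cbind(match(A, names(mA)), match(B, names(mB)),
                     match(C, names(mC)))]
  list(G = ssA, T = ssB, H = ssC, `G:T` = ssAB, `G:H` = ssAC, `T:H` = ssBC,
       `G:T:H` = ssABC, Residuals = sum((y - fit3)^2),
       total = sum((y - gm)^2))
}

# O(n^3) average-linkage agglomeration under Manhattan distance, tracking
# cluster membership explicitly. Returns merge heights and the cophenetic
# distance matrix.
oracle_average_linkage <- function(x) {
  n <- nrow(x)
  d <- as.matrix(dist(x, method = "manhattan"))
  clusters <- as.list(seq_len(n))
  active <- seq_len(n)
  coph <- matrix(0, n, n)
  heights <- numeric(n - 1)
  cd <- d
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(active)) for (j in seq_len(i - 1)) {
      h <- cd[active[j], active[i]]
      if (h < best_h) { best_h <- h; best <- c(active[j], active[i]) }
    }
    a <- best[1]; b <- best[2]
    heights[step] <- best_h
    for (p in clusters[[a]]) for (q in clusters[[b]]) {
      coph[p, q] <- coph[q, p] <- best_h
    }
    na <- length(clusters[[a]]); nb <- length(clusters[[b]])
    for (k in active) {
      if (k == a || k == b) next
      cd[a, k] <- cd[k, a] <- (na * cd[a, k] + nb * cd[b, k]) / (na + nb)
    }
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    active <- setdiff(active, b)
  }
  list(heights = sort(heights), cophenetic = coph)
}

# ASV recomputed literally from the printed formula.
oracle_asv <- function(ipc1, ipc2, ss1, ss2) {
  vapply(seq_along(ipc1), function(i) {
    sqrt((ss1 / ss2 * ipc1[i])^2 + ipc2[i]^2)
  }, numeric(1))
}

# Rank-and-sum yield stability oracle on raw yield and ASV vectors.
oracle_ysi <- function(mean_yield, asv_values) {
  rank(asv_values, ties.method = "average") +
    rank(-mean_yield, ties.method = "average")
}

make_records <- function(genotype, regime, harvest, replicate, trait, value) {
  tibble::tibble(genotype = genotype, regime = regime,
                 harvest = as.integer(harvest),
                 replicate = as.integer(replicate),
                 trait = trait, value = value)
}
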