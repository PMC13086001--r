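# Independent oracles used to freeze expected values. Each is written as a
# direct, definition-level computation so it shares no code path with the
# package implementation it checks.

# Brute-force SSR scanner: for every (start, unit_size) pair, count whole
# repeat units by explicit comparison, then apply threshold, primitivity and
# run-maximality checks.
oracle_detect_ssrs <- function(sequence, thresholds = ssr_thresholds()) {
  L <- nchar(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  res <- list()
  for (k in 1:6) {
    thr <- thresholds[[k]]
    if (L < k * thr) next
    idx <- seq_len(L - 2 * k + 1L)
    first_unit <- substring(sequence, idx, idx + k - 1L)
    second_unit <- substring(sequence, idx + k, idx + 2L * k - 1L)
    candidates <- idx[first_unit == second_unit &
                        !grepl("N", first_unit, fixed = TRUE)]
    for (i in candidates) {
      motif <- substr(sequence, i, i + k - 1L)
      # primitivity: motif must not be a power of a shorter string
      primitive <- TRUE
      for (d in seq_len(k - 1L)) {
        if (k %% d == 0L &&
            motif == strrep(substr(motif, 1L, d), k / d)) {
          primitive <- FALSE
          break
        }
      }
      if (!primitive) next
      # left run-maximality: the periodicity must not extend one char left
      if (i > 1L && ch[i - 1L] == ch[i - 1L + k] && ch[i - 1L] != "N") next
      # count whole units to the right
      count <- 1L
      while (i + (count + 1L) * k - 1L <= L &&
               substr(sequence, i + count * k, i + (count + 1L) * k - 1L) ==
                 motif) {
        count <- count + 1L
      }
      if (count < thr) next
      res[[length(res) + 1L]] <- data.frame(
        motif = motif, unit_size = k, repeats = count,
        start = i, end = i + count * k - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) {
    return(data.frame(motif = character(), unit_size = integer(),
                      repeats = integer(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$unit_size), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_test_dna <- function(n, gc = 0.35) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Exact half-up rounding of the rational p/q at `digits` decimals, by
# integer arithmetic on the decimal expansion (p, q, 10^digits small enough
# that all intermediates are exact doubles).
oracle_round_rational <- function(p, q, digits) {
  s <- sign(p / q)
  p <- abs(p); q <- abs(q)
  scaled <- p * 10^digits
  s * ((2 * scaled + q) %/% (2 * q)) / 10^digits
}

# Definition-level Pi: explicit double loop over pairs and columns,
# complete deletion.
oracle_pi <- function(alignment) {
  rows <- strsplit(alignment$sequence, "", fixed = TRUE)
  n <- length(rows)
  L <- length(rows[[1]])
  ok <- rep(TRUE, L)
  for (r in rows) ok <- ok & r %in% c("A", "C", "G", "T")
  stopifnot(any(ok))
  total <- 0
  npairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      diffs <- 0
      for (c in which(ok)) {
        if (rows[[i]][c] != rows[[j]][c]) diffs <- diffs + 1
      }
      total <- total + diffs / sum(ok)
      npairs <- npairs + 1
    }
  }
  total / npairs
}

# Ward.D2 oracle through an explicit Euclidean route: classical MDS
# embedding, then greedy merging by the Ward cost computed from cluster
# centroids (2 |A||B| / (|A|+|B|) * ||cA - cB||^2), heights on the
# unsquared scale. Returns merge heights and the cophenetic matrix.
oracle_ward <- function(d) {
  m <- as.matrix(d)
  n <- nrow(m)
  x <- cmdscale(d, k = n - 1)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- NULL
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        ca <- colMeans(x[clusters[[a]], , drop = FALSE])
        cb <- colMeans(x[clusters[[b]], , drop = FALSE])
        na <- length(clusters[[a]]); nb <- length(clusters[[b]])
        cost <- 2 * na * nb / (na + nb) * sum((ca - cb)^2)
        if (is.null(best) || cost < best$cost) {
          best <- list(a = a, b = b, cost = cost)
        }
      }
    }
    h <- sqrt(best$cost)
    heights <- c(heights, h)
    for (i in clusters[[best$a]]) {
      for (j in clusters[[best$b]]) {
        coph[i, j] <- coph[j, i] <- h
      }
    }
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$b]] <- NULL
  }
  list(heights = heights, cophenetic = coph)
}

# Exhaustive search for the longest pair of disjoint exact
# reverse-complement substrings: every antidiagonal is enumerated.
oracle_longest_ir <- function(sequence) {
  L <- nchar(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  comp <- chartr("ACGTN", "TGCAN", ch)
  best <- list(len = 0L)
  for (D in 3:(2L * L - 1L)) {
    a_idx <- max(1L, D - L):min(L, D - 1L)
    ok <- ch[a_idx] == comp[D - a_idx] & ch[a_idx] != "N"
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (h in which(r$values)) {
      u <- a_idx[starts[h]]
      v <- min(a_idx[ends[h]], (D - 1L) %/% 2L)
      if (v < u) next
      len <- v - u + 1L
      if (len > best$len || (len == best$len && u < best$u)) {
        best <- list(len = len, u = u, v = v,
                     a1 = D - v, a2 = D - u)
      }
    }
  }
  best
}

# All r statistics over the full permutation group of one matrix's
# rows/columns (feasible at n = 4).
oracle_mantel_exact_r <- function(d1, d2) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  n <- nrow(m1)
  perms <- gtools_permutations(n)
  ut <- upper.tri(m1)
  apply(perms, 1L, function(p) {
    cor(m1[ut], m2[p, p][ut])
  })
}

# Minimal permutation enumerator (avoids a gtools dependency).
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    for (s in seq_len(nrow(sub))) {
      rest <- setdiff(seq_len(n), k)[sub[s, ]]
      out[row, ] <- c(k, rest)
      row <- row + 1L
    }
  }
  out
}

expect_same_loci <- function(found, truth) {
  key <- function(df) {
    paste(df$motif, df$unit_size, df$repeats, df$start, df$end)
  }
  expect_setequal(key(found), key(truth))
}
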