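# Brute-force reference implementations, kept deliberately independent of
# the package's algorithms: set-based reachability instead of regex for the
# G4 pattern, triple loops instead of vectorised cumulative sums for mirror
# repeats, all-pairs scans instead of interval trees, and exhaustive
# enumeration for the statistics.

# ---- G4 oracle -------------------------------------------------------------

# ends reachable from 0-based position i by run-loop-...-run decomposition;
# returns the longest valid match length at i, or 0
oracleG4LongestAt <- function(ch, i, gMin, gMax, loopMin, loopMax) {
  n <- length(ch)
  positions <- i                               # 0-based starts of next piece
  for (piece in 1:7) {
    isRun <- piece %% 2L == 1L
    lens <- if (isRun) gMin:gMax else loopMin:loopMax
    nxt <- integer(0)
    for (p in positions) {
      for (L in lens) {
        if (p + L > n) next
        seg <- ch[(p + 1):(p + L)]
        okSeg <- if (isRun) all(seg == "G") else all(seg != "N")
        if (okSeg) nxt <- c(nxt, p + L)
      }
    }
    positions <- unique(nxt)
    if (!length(positions)) return(0L)
  }
  max(positions) - i
}

# leftmost-then-longest non-overlapping G4 matches on the forward strand;
# returns data.frame of 0-based half-open intervals
oracleG4Scan <- function(seq, gMin = 3L, gMax = 5L, loopMin = 1L,
                         loopMax = 7L) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  res <- list(); i <- 0L
  while (i < n) {
    if (ch[i + 1] != "G") { i <- i + 1L; next }   # a match must begin a G-run
    L <- oracleG4LongestAt(ch, i, gMin, gMax, loopMin, loopMax)
    if (L > 0L) {
      res[[length(res) + 1L]] <- c(i, i + L)
      i <- i + L
    } else i <- i + 1L
  }
  if (!length(res)) return(data.frame(start = integer(0), end = integer(0)))
  m <- do.call(rbind, res)
  data.frame(start = m[, 1], end = m[, 2])
}

revcompChar <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(seq), "")[[1]]),
                                 collapse = ""))
}

# both-strand G4 oracle in forward 0-based coordinates
oracleG4Both <- function(seq, ...) {
  fwd <- oracleG4Scan(seq, ...)
  fwd$strand <- rep("+", nrow(fwd))
  rc <- oracleG4Scan(revcompChar(seq), ...)
  n <- nchar(seq)
  rev <- data.frame(start = n - rc$end, end = n - rc$start,
                    strand = rep("-", nrow(rc)))
  out <- rbind(fwd, rev)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# ---- H-DNA oracle ----------------------------------------------------------

# exhaustive (start, armLen, spacer) enumeration with direct string checks
oracleHdnaCandidates <- function(seq, minArm = 6L, maxSpacer = 8L,
                                 maxMismatch = 1L, minPurity = 0.9,
                                 maxArm = 25L, penalty = 3) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  rows <- list()
  for (s0 in 0:(n - 1)) {                     # 0-based start of arm1
    for (a in minArm:maxArm) {
      for (d in 0:maxSpacer) {
        e0 <- s0 + 2 * a + d                  # 0-based half-open end
        if (e0 > n) next
        span <- ch[(s0 + 1):e0]
        if (any(span == "N")) next
        arm1 <- ch[(s0 + 1):(s0 + a)]
        arm2 <- ch[(s0 + a + d + 1):e0]
        mism <- sum(arm1 != rev(arm2))
        if (mism > maxMismatch) next
        arms <- c(arm1, arm2)
        pur <- mean(arms %in% c("A", "G"))
        pyr <- mean(arms %in% c("C", "T"))
        if (pur + 1e-9 < minPurity && pyr + 1e-9 < minPurity) next
        rows[[length(rows) + 1L]] <- c(s0, e0, 2 * a - penalty * mism)
      }
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      score = numeric(0)))
  m <- do.call(rbind, rows)
  data.frame(start = m[, 1], end = m[, 2], score = m[, 3])
}

# greedy best-score-first non-overlap selection (ties: leftmost, shortest)
oracleSelect <- function(cand) {
  sel <- list()
  cand <- cand[order(-cand$score, cand$start, cand$end), , drop = FALSE]
  taken <- rep(FALSE, max(c(0, cand$end)))
  for (i in seq_len(nrow(cand))) {
    idx <- (cand$start[i] + 1):cand$end[i]
    if (!any(taken[idx])) {
      taken[idx] <- TRUE
      sel[[length(sel) + 1L]] <- cand[i, ]
    }
  }
  if (!length(sel))
    return(data.frame(start = integer(0), end = integer(0),
                      score = numeric(0)))
  out <- do.call(rbind, sel)
  out[order(out$start), , drop = FALSE]
}

oracleHdnaScan <- function(seq, ...) oracleSelect(oracleHdnaCandidates(seq, ...))

# ---- interval matching oracle ----------------------------------------------

# all-pairs one-to-one nearest matching on 1-based closed intervals
oracleMatch <- function(a, b, mode = "overlap", maxGap = 1000) {
  pairs <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) + 1
    gp <- if (ov > 0) 0 else -ov
    if (ov > 0 || (mode == "proximity" && gp <= maxGap))
      pairs[[length(pairs) + 1L]] <- c(i, j, max(ov, 0), gp)
  }
  if (!length(pairs))
    return(data.frame(indexA = integer(0), indexB = integer(0),
                      overlapBp = integer(0), gapBp = integer(0)))
  m <- do.call(rbind, pairs)
  ord <- order(m[, 4], -m[, 3], a$start[m[, 1]], b$start[m[, 2]])
  usedA <- rep(FALSE, nrow(a)); usedB <- rep(FALSE, nrow(b))
  keep <- c()
  for (r in ord) {
    if (!usedA[m[r, 1]] && !usedB[m[r, 2]]) {
      usedA[m[r, 1]] <- TRUE; usedB[m[r, 2]] <- TRUE
      keep <- c(keep, r)
    }
  }
  m <- m[keep, , drop = FALSE]
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(indexA = m[, 1], indexB = m[, 2], overlapBp = m[, 3],
             gapBp = m[, 4])
}

# ---- exact statistics oracles ----------------------------------------------

# two-sided Mann-Whitney p by enumeration, U via direct pair counting
oracleMannWhitney <- function(x, y) {
  pool <- c(x, y); nA <- length(x); n <- length(pool)
  uOf <- function(idx) {
    a <- pool[idx]; b <- pool[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  uObs <- uOf(seq_len(nA))
  mu <- nA * (n - nA) / 2
  us <- apply(combn(n, nA), 2, uOf)
  list(u = uObs, p = mean(abs(us - mu) >= abs(uObs - mu) - 1e-9))
}

# upper-tail hypergeometric by enumerating every draw of n from N
oracleHyper <- function(N, K, n, k) {
  marked <- seq_len(K)
  draws <- combn(N, n)
  mean(apply(draws, 2, function(d) sum(d %in% marked)) >= k)
}

# Kruskal-Wallis H, tie-corrected, straight from the rank formula
oracleKruskalH <- function(groups) {
  x <- unlist(groups); n <- length(x); r <- rank(x)
  sizes <- lengths(groups)
  idx <- split(seq_len(n), rep(seq_along(groups), sizes))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(idx, function(i) sum(r[i])^2 / length(i), numeric(1))) -
    3 * (n + 1)
  ties <- table(r)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# draw-enumeration counts for one (N, n): number of marked elements in
# every possible draw, for all K at once via the marked set {1..K}
oracleHyperCounts <- function(N, n, K) {
  if (n == 0) return(integer(1))
  draws <- combn(N, n)
  colSums(matrix(draws <= K, nrow = n))
}
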