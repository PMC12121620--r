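# Independent brute-force oracles used to check the fast implementations.

# Per-position fragment depth by interval stabbing over retained pairs.
# Each pair is a list(fspan, rspan, clips = list of spans) in 0-based
# half-open window coordinates; single reads are list(span, clips).
depthOracle <- function(pairs, windowLength) {
  depth <- integer(windowLength)
  stab <- function(span) {
    lo <- max(0L, span[1]); hi <- min(windowLength, span[2])
    if (lo < hi) depth[(lo + 1L):hi] <<- depth[(lo + 1L):hi] + 1L
  }
  for (p in pairs) {
    if (!is.null(p$fspan)) {
      stab(c(p$fspan[1], p$rspan[2]))
      for (cs in p$clips) stab(cs)
    } else {
      stab(p$span)
      for (cs in p$clips) stab(cs)
    }
  }
  depth
}

# Literal-rules peak scanner: O(n * w) reference implementation of summit
# detection, monotone/zero-band extension, and upstream valley assignment.
peakOracle <- function(v, zeroBand = 0.1) {
  n <- length(v)
  res <- NULL
  isSummit <- function(i) {
    if (abs(v[i]) < zeroBand) return(FALSE)
    # previous distinct value
    j <- i - 1L
    while (j >= 1L && v[j] == v[i]) j <- j - 1L
    if (j == i - 1L) {
      prevLower <- j < 1L || sign(v[j]) != sign(v[i]) ||
        abs(v[j]) < abs(v[i])
    } else {
      return(FALSE)  # not leftmost of its plateau
    }
    k <- i + 1L
    while (k <= n && v[k] == v[i]) k <- k + 1L
    nextLower <- k > n || sign(v[k]) != sign(v[i]) || abs(v[k]) < abs(v[i])
    prevLower && nextLower
  }
  for (i in seq_len(n)) {
    if (!isSummit(i)) next
    lb <- i
    repeat {
      cand <- lb - 1L
      if (cand < 1L) break
      if (abs(v[cand]) > abs(v[lb])) break
      if (abs(v[cand]) < zeroBand) break
      if (sign(v[cand]) != sign(v[i])) break
      lb <- cand
    }
    rb <- i
    repeat {
      cand <- rb + 1L
      if (cand > n) break
      if (abs(v[cand]) > abs(v[rb])) break
      if (abs(v[cand]) < zeroBand) break
      if (sign(v[cand]) != sign(v[i])) break
      rb <- cand
    }
    res <- rbind(res, c(summit = i - 1L, lb = lb - 1L, rbExcl = rb))
  }
  if (is.null(res)) {
    return(data.frame(summit = integer(0), left_bound = integer(0),
                      right_bound = integer(0)))
  }
  res <- as.data.frame(res)
  if (nrow(res) > 1L) {
    for (i in 2:nrow(res)) {
      if (res$lb[i] < res$rbExcl[i - 1L]) res$lb[i] <- res$rbExcl[i - 1L]
    }
  }
  data.frame(summit = res$summit, left_bound = res$lb,
             right_bound = res$rbExcl)
}

# Exact one-tailed Mann-Whitney p-value by enumeration of all group
# assignments (alternative: x stochastically smaller than y).
mwExactOracle <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  combos <- utils::combn(length(vals), n1)
  uStat <- function(a, b) sum(outer(a, b, "<")) + 0.5 * sum(outer(a, b, "=="))
  obs <- uStat(vals[seq_len(n1)], vals[-seq_len(n1)])
  us <- apply(combos, 2, function(idx) uStat(vals[idx], vals[-idx]))
  # smaller-than-y alternative: large U of (x < y) counts support it; the
  # p-value is the probability of an assignment at least as extreme
  mean(us >= obs)
}

# Brute-force complete-linkage flat clustering: merge the closest pair of
# clusters (by maximum pairwise distance) while the merge height stays at or
# below the threshold.
completeLinkageOracle <- function(x, threshold) {
  clusters <- as.list(seq_along(x))
  repeat {
    if (length(clusters) == 1L) break
    best <- NULL
    bestD <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- max(abs(outer(x[clusters[[i]]], x[clusters[[j]]], "-")))
        if (d < bestD) { bestD <- d; best <- c(i, j) }
      }
    }
    if (bestD > threshold) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  out <- integer(length(x))
  for (k in seq_along(clusters)) out[clusters[[k]]] <- k
  out
}

# Simple reverse-complement oracle, independent of Biostrings.
revCompOracle <- function(s) {
  comp <- chartr("ACGTacgt", "TGCAtgca", s)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# Random EQ/FR pair generator for partition properties.
randomPairs <- function(n, windowLength, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    kind <- sample(c("EQ", "FR_gap", "FR_overlap"), 1L)
    if (kind == "EQ") {
      len <- sample(30:120, 1L)
      s <- sample(0:(windowLength - len - 1L), 1L)
      list(fspan = c(s, s + len), rspan = c(s, s + len), clips = list())
    } else if (kind == "FR_gap") {
      fl <- sample(30:100, 1L); rl <- sample(30:100, 1L)
      gap <- sample(1:80, 1L)
      s <- sample(0:(windowLength - fl - rl - gap - 1L), 1L)
      list(fspan = c(s, s + fl), rspan = c(s + fl + gap, s + fl + gap + rl),
           clips = list())
    } else {
      fl <- sample(40:100, 1L); rl <- sample(40:100, 1L)
      ov <- sample(1:(min(fl, rl) - 1L), 1L)
      s <- sample(0:(windowLength - fl - rl + ov - 1L), 1L)
      list(fspan = c(s, s + fl), rspan = c(s + fl - ov, s + fl - ov + rl),
           clips = list())
    }
  })
}

# Write a SAM file for a list of EQ/FR pairs against one reference.
pairsToSam <- function(pairs, refName, refLen, path) {
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", refName, refLen))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    fl <- p$fspan[2] - p$fspan[1]
    rl <- p$rspan[2] - p$rspan[1]
    tlen <- p$rspan[2] - p$fspan[1]
    q <- sprintf("pair%05d", i)
    lines <- c(lines,
      sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s", q, refName,
              p$fspan[1] + 1L, fl, p$rspan[1] + 1L, tlen,
              strrep("A", fl), strrep("I", fl)),
      sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s", q, refName,
              p$rspan[1] + 1L, rl, p$fspan[1] + 1L, -tlen,
              strrep("A", rl), strrep("I", rl)))
  }
  writeLines(lines, path)
  path
}

# A minimal reference window for ingest tests.
testWindow <- function(windowLength = 600L, rsStart = 200L, rsEnd = 300L,
                       locusId = "testlocus") {
  loci <- data.frame(locus_id = locusId, contig_id = locusId,
                     family = "test", source_start = rsStart,
                     source_end = rsEnd, strand = "+",
                     model_score = NA_real_, e_value = NA_real_,
                     stringsAsFactors = FALSE)
  seq <- paste(rep("ACGT", ceiling(windowLength / 4)), collapse = "")
  buildReferenceWindow(loci[1, ], substr(seq, 1, windowLength),
                       flank = windowLength)
}
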