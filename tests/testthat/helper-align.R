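# Independent brute-force oracle for the alignment DP: enumerates every
# monotone one-to-one mapping and scores it as (sum of S over matched
# pairs) + gap_open per internal gap opening, query-side and target-side
# openings counted separately, end gaps free. Exponential, so only for
# tiny score matrices.

brute_dp_score <- function(S, gap_open = -0.6) {
  n <- nrow(S); m <- ncol(S)
  best <- -Inf
  rec <- function(li, lj, sc) {
    if (li < n && lj < m) {
      for (i in (li + 1):n) {
        for (j in (lj + 1):m) {
          pen <- if (li == 0) 0 else
            gap_open * ((i > li + 1) + (j > lj + 1))
          s2 <- sc + S[i, j] + pen
          if (s2 > best) best <<- s2
          rec(i, j, s2)
        }
      }
    }
    invisible(NULL)
  }
  rec(0L, 0L, 0)
  best
}
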