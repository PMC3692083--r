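# independent exhaustive oracle for the piecewise-alignment DP: enumerates
# every offset path and scores it with the stated objective (sum of window
# Pearson correlations minus lambda * |d - d'| transitions)
pw_oracle <- function(profile, reference, window, offsets, lambda, roi) {
  idx <- roi$start:roi$end
  n_win <- length(idx) %/% window
  starts <- idx[1] + (seq_len(n_win) - 1L) * window
  ends <- c(starts[-1] - 1L, idx[length(idx)])
  n <- length(profile)
  win_score <- function(w, d) {
    src <- (starts[w]:ends[w]) + d
    pw <- ifelse(src >= 1 & src <= n, profile[pmin(pmax(src, 1), n)], 0)
    ref_w <- reference[starts[w]:ends[w]]
    if (sd(pw) == 0 || sd(ref_w) == 0) 0 else cor(pw, ref_w)
  }
  grid <- as.matrix(do.call(expand.grid, rep(list(offsets), n_win)))
  best <- -Inf; best_path <- NULL
  for (row in seq_len(nrow(grid))) {
    d <- grid[row, ]
    obj <- sum(vapply(seq_len(n_win), function(w) win_score(w, d[w]), 0)) -
      lambda * sum(abs(diff(d)))
    if (obj > best + 1e-12) { best <- obj; best_path <- d }
  }
  list(objective = best, path = unname(best_path))
}
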