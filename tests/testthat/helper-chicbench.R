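# shared fixture builders; everything is generated in code

# minimal scored table from bare score / log_p vectors
make_scored <- function(score, log_p = -score, bait_bait = FALSE,
                        distance_bp = 50000) {
  n <- length(score)
  out <- tibble::tibble(
    bait_id = seq_len(n), other_id = seq_len(n) + 10000L,
    distance_bp = rep_len(distance_bp, n), count = 1L, mu = 1,
    log_p = rep_len(log_p, n), weight = 1, score = score,
    bait_bait = rep_len(bait_bait, n))
  class(out) <- c("chic_scored", class(out))
  out
}

# directed bait-bait scored table from forward/reverse score pairs
make_bb_scored <- function(fwd, rev) {
  n <- length(fwd)
  out <- tibble::tibble(
    bait_id = c(seq_len(n), seq_len(n) + 100L),
    other_id = c(seq_len(n) + 100L, seq_len(n)),
    distance_bp = 50000, count = 1L, mu = 1,
    log_p = -c(fwd, rev), weight = 1, score = c(fwd, rev),
    bait_bait = TRUE)
  class(out) <- c("chic_scored", class(out))
  out
}

# tiny 3-fragment rmap + 1-bait baitmap written to temp files
write_toy_maps <- function(dir = tempfile("toy")) {
  dir.create(dir, showWarnings = FALSE)
  rmap <- file.path(dir, "toy.rmap")
  baitmap <- file.path(dir, "toy.baitmap")
  writeLines(c("chr1\t1\t4000\t1",
               "chr1\t4001\t9000\t2",
               "chr1\t9001\t12000\t3"), rmap)
  writeLines("chr1\t4001\t9000\t2\tpromA", baitmap)
  list(rmap = rmap, baitmap = baitmap, dir = dir)
}

# brute-force Delaporte pmf oracle: truncated linear-space convolution
delaporte_oracle <- function(k, mu, r, lam) {
  sum(vapply(0:k, function(j) {
    stats::dpois(j, lam) * stats::dnbinom(k - j, size = r, mu = mu)
  }, numeric(1)))
}

# exhaustive integer-scan oracle for the FDR-minimising threshold
fdr_scan_oracle <- function(replicate_scores, ts = 0:100) {
  fdr <- vapply(ts, function(t) {
    sets <- lapply(replicate_scores, function(df) {
      df$bait_id[df$score > t]
    })
    u <- unique(unlist(sets))
    if (length(u) == 0) return(1)
    1 - length(Reduce(intersect, sets)) / length(u)
  }, numeric(1))
  list(ts = ts, fdr = fdr, argmin = ts[which.min(fdr)], min = min(fdr))
}
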