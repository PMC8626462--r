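# Shared fixture builders. All fixtures are constructed in code; the
# brute-force interval oracle here is independent of the indexed
# implementation under test.

ps <- function(factor, start, end, chrom = "chr1", ...) {
  peak_set(factor, rep_len(chrom, length(start)), start, end, ...)
}

# O(n*m) all-pairs overlap oracle: for every peak of A, every peak of B
# is tested with the half-open overlap-length arithmetic directly.
brute_force_intersect <- function(A, B, min_bp = 1L) {
  a <- as.data.frame(A); b <- as.data.frame(B)
  res <- lapply(seq_len(nrow(a)), function(i) {
    ov <- pmin(a$end[i], b$end) - pmax(a$start[i], b$start)
    b$name[b$chrom == a$chrom[i] & ov >= min_bp]
  })
  names(res) <- a$name
  res
}

random_peakset <- function(factor, n, chrom_len = 1e6, width_max = 5000) {
  start <- sample.int(chrom_len - width_max, n, replace = TRUE)
  width <- sample.int(width_max, n, replace = TRUE)
  suppressWarnings(
    peak_set(factor, rep("chrT", n), start, start + width,
             name = sprintf("%s_%d", factor, seq_len(n))))
}

write_lines_tmp <- function(lines, ext = ".bed") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
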