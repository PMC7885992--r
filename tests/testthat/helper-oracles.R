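# Brute-force oracle for the label cleanup: drop positive runs shorter
# than k, then fill gaps shorter than k between the surviving runs.
runlength_oracle <- function(x, k = 5L) {
  r <- rle(as.integer(x))
  r$values[r$values == 1L & r$lengths < k] <- 0L
  x <- inverse.rle(r)
  r <- rle(x)
  if (length(r$lengths) >= 3) {
    interior <- seq(2, length(r$lengths) - 1)
    fill <- interior[r$values[interior] == 0L & r$lengths[interior] < k]
    r$values[fill] <- 1L
  }
  inverse.rle(r)
}

# All binary sequences of length n, one per row.
all_sequences <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  storage.mode(m) <- "integer"
  m
}
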