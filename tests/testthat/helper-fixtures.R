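## Fixture builders shared across test files.

randMatrix <- function(nGenes, nSamples, seed, mean = 8, sd = 1.5) {
  set.seed(seed)
  matrix(rnorm(nGenes * nSamples, mean, sd), nGenes, nSamples,
         dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                         sprintf("s%03d", seq_len(nSamples))))
}

sigFor <- function(m, k = nrow(m), name = "test") {
  GeneSignature(name, rownames(m)[seq_len(k)])
}

randPrototypes <- function(m, seed) {
  set.seed(seed)
  n <- ncol(m)
  hi <- sample(colnames(m), floor(n / 2))
  buildPrototypes(m, sigFor(m),
                  list(high = hi, low = setdiff(colnames(m), hi)))
}

## Matrix with two sharply separated sample clusters: two profile shapes,
## the first shifted up so its cluster is the "high" one.
twoBlobMatrix <- function(nPerGroup = 10, nGenes = 12, seed = 1,
                          shift = 5, noiseSd = 0.2) {
  set.seed(seed)
  shapeA <- seq_len(nGenes)
  shapeB <- rev(shapeA)
  a <- replicate(nPerGroup, shapeA + shift + rnorm(nGenes, 0, noiseSd))
  b <- replicate(nPerGroup, shapeB + rnorm(nGenes, 0, noiseSd))
  m <- cbind(a, b)
  dimnames(m) <- list(sprintf("g%02d", seq_len(nGenes)),
                      c(sprintf("hi%02d", seq_len(nPerGroup)),
                        sprintf("lo%02d", seq_len(nPerGroup))))
  m
}

writeLinesTo <- function(lines, file = tempfile()) {
  writeLines(lines, file)
  file
}
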