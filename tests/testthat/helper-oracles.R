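## Independent brute-force oracles, written from first principles so they
## share no code path with the package (or with the stats functions the
## package delegates to).

bfMean <- function(v) sum(v) / length(v)

bfMedian <- function(v) {
  s <- sort(unname(v))
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

bfMad <- function(v) bfMedian(abs(v - bfMedian(v)))

bfPearson <- function(x, y) {
  xm <- x - bfMean(x)
  ym <- y - bfMean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

## average ranks, by counting
bfRank <- function(v) {
  vapply(seq_along(v), function(i)
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, 0)
}

bfSpearman <- function(x, y) bfPearson(bfRank(x), bfRank(y))

## Mann-Whitney U for sample a (ties count 1/2), by direct pair counting
bfU <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

## Exact two-sided signed-rank p by enumerating all 2^n sign assignments
bfWilcoxonExact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- bfRank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  pLess <- mean(Ws <= W + 1e-9)
  pGreater <- mean(Ws >= W - 1e-9)
  list(statistic = W, p.value = min(1, 2 * min(pLess, pGreater)))
}
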