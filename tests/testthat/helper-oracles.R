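# Brute-force oracles for the rank statistics, shared across test files.
aucByCounting <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  s <- 0
  for (xi in x) for (yj in y) s <- s + (xi > yj) + 0.5 * (xi == yj)
  s / (length(x) * length(y))
}

delongOracle <- function(scoresA, scoresB, labels) {
  comp <- function(scores) {
    x <- scores[labels == 1]
    y <- scores[labels == 0]
    V10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
    V01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
    list(V10 = V10, V01 = V01, auc = mean(V10))
  }
  a <- comp(scoresA)
  b <- comp(scoresB)
  v <- var(a$V10 - b$V10) / length(a$V10) + var(a$V01 - b$V01) / length(a$V01)
  z <- (a$auc - b$auc) / sqrt(v)
  list(p = 2 * pnorm(-abs(z)), z = z, aucA = a$auc, aucB = b$auc)
}

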