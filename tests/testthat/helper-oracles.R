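# Independent brute-force oracles and small fixture builders. The oracles
# deliberately share no code with the package internals: explicit loops over
# the 21 x 21 alphabet, string subsetting instead of integer encodings.

ORACLE_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                     "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")

# per-contact MI, joint entropy and I/H by direct summation over all 441 cells
oracleInterfaceMI <- function(seqsA, seqsB, colA, colB, permv, lambda) {
  M <- length(seqsA)
  Q <- length(ORACLE_ALPHABET)
  N <- length(colA)
  I <- H <- numeric(N)
  for (i in seq_len(N)) {
    xs <- substring(seqsA, colA[i], colA[i])
    ys <- substring(seqsB[permv], colB[i], colB[i])
    ysAll <- substring(seqsB, colB[i], colB[i])
    mi <- 0; ent <- 0
    for (a in ORACLE_ALPHABET) {
      fa <- (1 - lambda) * sum(xs == a) / M + lambda / Q
      for (b in ORACLE_ALPHABET) {
        fb <- (1 - lambda) * sum(ysAll == b) / M + lambda / Q
        fab <- (1 - lambda) * sum(xs == a & ys == b) / M + lambda / Q^2
        if (fab > 0) {
          mi <- mi + fab * log(fab / (fa * fb))
          ent <- ent - fab * log(fab)
        }
      }
    }
    I[i] <- mi; H[i] <- ent
  }
  list(I = I, H = H, iHat = mean(I), total = sum(I),
       regularized = sum(ifelse(H > 0, I / H, 0)))
}

# random tiny alignment pair over a 4-letter alphabet
randomTinyPair <- function(M, LA, LB, seed) {
  set.seed(seed)
  syms <- c("A", "C", "D", "E")
  mk <- function(L) vapply(seq_len(M), function(i)
    paste(sample(syms, L, replace = TRUE), collapse = ""), character(1))
  alignmentPair(mk(LA), mk(LB))
}

# brute-force KNN majority vote (self included), ties to first class in
# sorted label order -- mirrors the training-score convention
oracleKnn <- function(X, y, k) {
  classes <- sort(unique(y))
  pred <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    d <- sqrt(rowSums((X - matrix(X[i, ], nrow(X), ncol(X), byrow = TRUE))^2))
    nb <- y[order(d)[seq_len(k)]]
    cnt <- vapply(classes, function(cl) sum(nb == cl), numeric(1))
    pred[i] <- classes[which.max(cnt)]
  }
  pred
}

# minimal PDB writer for synthetic toy structures (fixed-format ATOM records)
writeToyPDB <- function(atoms, path) {
  # atoms: data.frame(serial, name, resn, chain, resno, x, y, z, occ)
  lines <- sprintf(
    "ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
    atoms$serial, sprintf(" %-3s", atoms$name), atoms$resn, atoms$chain,
    atoms$resno, atoms$x, atoms$y, atoms$z,
    if (is.null(atoms$occ)) rep(1, nrow(atoms)) else atoms$occ,
    rep(0, nrow(atoms)), substr(atoms$name, 1, 1))
  writeLines(c(lines, "END"), path)
  path
}
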