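# Independent brute-force oracles and tiny fixture builders used across the
# suite. Oracles deliberately share no code with the implementation.

# O(L^2) run enumeration: every maximal run of values >= thr, checked for
# maximality explicitly.
bruteRegions <- function(v, thr, minLen = 1L) {
  ok <- !is.na(v) & v >= thr
  n <- length(v)
  out <- NULL
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (all(ok[s:e]) &&
          (s == 1L || !ok[s - 1L]) &&
          (e == n || !ok[e + 1L]) &&
          (e - s + 1L) >= minLen)
        out <- rbind(out, c(s, e))
    }
  }
  out
}

# O(n^3) triangle enumeration for the average local clustering coefficient.
bruteAvgClustering <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    d <- length(nb)
    if (d < 2) { cc[v] <- 0; next }
    links <- 0
    for (i in seq_along(nb)) for (j in seq_along(nb)) {
      if (i < j && adj[nb[i], nb[j]] == 1) links <- links + 1
    }
    cc[v] <- 2 * links / (d * (d - 1))
  }
  mean(cc)
}

# direct windowed averaging under the package's stated offset convention
bruteMovingMean <- function(v, w) {
  n <- length(v)
  lo <- -ceiling(w / 2) + 1
  hi <- floor(w / 2)
  sapply(seq_len(n), function(i) {
    win <- v[max(1, i + lo):min(n, i + hi)]
    win <- win[!is.na(win)]
    if (!length(win)) NA_real_ else sum(win) / length(win)
  })
}

# minimal valid PDB: one CA and one CB atom per residue, chain A
writeToyPdb <- function(path, bfactors, chain = "A", resname = "ALA",
                        serialStart = 0L) {
  ser <- serialStart
  lines <- character()
  for (i in seq_along(bfactors)) {
    for (atom in c("CA", "CB")) {
      ser <- ser + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        ser, atom, resname, chain, i, i * 1.5, 0, 0, 1.00, bfactors[i]))
    }
  }
  writeLines(c(lines, "TER", "END"), path)
  path
}

randomTrack <- function(n, pid = "p", name = "t", naFrac = 0) {
  v <- runif(n)
  if (naFrac > 0) v[sample(n, ceiling(naFrac * n))] <- NA
  perResidueTrack(pid, name, v)
}
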