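# Independent brute-force oracles, deliberately implemented by direct string
# scanning over a character vector rather than via the package's substring
# machinery.

# ID83 classification oracle
oracle_classify_indel <- function(chars, pos, ref, alt) {
  if (nchar(ref) > nchar(alt)) {
    type <- "Del"
    seqv <- strsplit(substring(ref, nchar(alt) + 1L), "")[[1]]
  } else {
    type <- "Ins"
    seqv <- strsplit(substring(alt, nchar(ref) + 1L), "")[[1]]
  }
  n <- length(seqv)
  # left-align: shift while the anchor base equals the event's last base
  while (pos >= 1L && chars[pos] == seqv[n]) {
    seqv <- c(chars[pos], seqv[-n])
    pos <- pos - 1L
  }
  L <- length(chars)
  size <- if (n >= 5L) "5+" else as.character(n)
  if (n == 1L) {
    b <- seqv
    cb <- if (b %in% c("A", "T")) "T" else "C"
    left <- 0L; i <- pos
    while (i >= 1L && chars[i] == b) { left <- left + 1L; i <- i - 1L }
    i <- if (type == "Del") pos + 2L else pos + 1L
    right <- 0L
    while (i <= L && chars[i] == b) { right <- right + 1L; i <- i + 1L }
    if (type == "Del") {
      len <- left + 1L + right
      return(paste0("1:Del:", cb, ":", if (len >= 6L) "6+" else len))
    }
    adj <- left + right
    return(paste0("1:Ins:", cb, ":", if (adj >= 5L) "5+" else adj))
  }
  unit <- paste(seqv, collapse = "")
  # full copies 3' of the event
  i <- if (type == "Del") pos + n + 1L else pos + 1L
  copies <- 0L
  while (i + n - 1L <= L &&
         paste(chars[i:(i + n - 1L)], collapse = "") == unit) {
    copies <- copies + 1L
    i <- i + n
  }
  # full copies 5' of the event
  j <- pos
  while (j - n + 1L >= 1L &&
         paste(chars[(j - n + 1L):j], collapse = "") == unit) {
    copies <- copies + 1L
    j <- j - n
  }
  if (type == "Ins") {
    return(paste0(size, ":Ins:R:", if (copies >= 5L) "5+" else copies))
  }
  units <- copies + 1L
  if (units >= 2L) {
    return(paste0(size, ":Del:R:", if (units >= 6L) "6+" else units))
  }
  # microhomology: longest shared prefix 3', longest shared suffix 5'
  mh3 <- 0L
  while (mh3 < n && pos + n + mh3 + 1L <= L &&
         chars[pos + n + mh3 + 1L] == seqv[mh3 + 1L]) mh3 <- mh3 + 1L
  mh5 <- 0L
  while (mh5 < n && pos - mh5 >= 1L &&
         chars[pos - mh5] == seqv[n - mh5]) mh5 <- mh5 + 1L
  mh <- max(mh3, mh5)
  if (mh >= 1L) {
    lab <- if (n >= 5L && mh >= 5L) "5+" else as.character(min(mh, n - 1L))
    return(paste0(size, ":Del:M:", lab))
  }
  paste0(size, ":Del:R:1")
}

# Spearman rho by explicit rank-then-Pearson
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# unconstrained least-squares exposures (valid oracle when truth is interior)
oracle_lsq <- function(S, m) {
  as.numeric(solve(crossprod(S), crossprod(S, m)))
}

# random anchored indel against a reference char vector, for the oracle suite
random_indel <- function(chars, rng_pos, tracts = NULL) {
  L <- length(chars)
  kind <- sample(c("del1", "ins1", "del", "ins", "tract"), 1,
                 prob = c(0.25, 0.2, 0.25, 0.15, 0.15))
  if (kind == "tract" && !is.null(tracts) && nrow(tracts) > 0) {
    tr <- tracts[sample.int(nrow(tracts), 1), ]
    if (tr$kind == "homopolymer") {
      p <- tr$start + sample.int(tr$len, 1) - 1L   # delete inside the run
      return(list(pos = p - 1L, ref = paste0(chars[p - 1L], chars[p]),
                  alt = chars[p - 1L]))
    }
    p <- tr$start - 1L                              # delete the first unit
    return(list(pos = p, ref = paste(c(chars[p], strsplit(tr$unit, "")[[1]]),
                                     collapse = ""), alt = chars[p]))
  }
  p <- sample(rng_pos, 1)
  if (kind == "del1") {
    list(pos = p, ref = paste0(chars[p], chars[p + 1L]), alt = chars[p])
  } else if (kind == "ins1") {
    list(pos = p, ref = chars[p],
         alt = paste0(chars[p], sample(c("A", "C", "G", "T"), 1)))
  } else if (kind == "del") {
    n <- sample(2:6, 1)
    list(pos = p, ref = paste(chars[p:(p + n)], collapse = ""),
         alt = chars[p])
  } else {
    n <- sample(2:4, 1)
    list(pos = p, ref = chars[p],
         alt = paste(c(chars[p], sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE)), collapse = ""))
  }
}
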