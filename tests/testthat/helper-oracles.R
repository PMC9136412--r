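# Independent oracles used by the property and acceptance tests. These
# re-derive expected values from first principles and deliberately share
# no code with the package implementation.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n, letters = AA20) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# --- full-matrix alignment oracle (plain R, same scoring contract) -----

align_oracle <- function(a, b, match = 1, mismatch = 0, go = 10,
                         ge = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  tM <- tX <- tY <- matrix(0L, n + 1, m + 1)
  M[1, 1] <- 0
  X[2:(n + 1), 1] <- 0
  Y[1, 2:(m + 1)] <- 0
  open <- go + ge
  for (i in 2:(n + 1)) {
    ai <- A[i - 1]
    for (j in 2:(m + 1)) {
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- which.max(cand)  # first max: prefer M, then X, then Y
      M[i, j] <- cand[k] + if (ai == B[j - 1]) match else mismatch
      tM[i, j] <- k
      cand <- c(M[i - 1, j] - open, X[i - 1, j] - ge, Y[i - 1, j] - open)
      k <- which.max(cand); X[i, j] <- cand[k]; tX[i, j] <- k
      cand <- c(M[i, j - 1] - open, X[i, j - 1] - open, Y[i, j - 1] - ge)
      k <- which.max(cand); Y[i, j] <- cand[k]; tY[i, j] <- k
    }
  }
  best <- -Inf; bi <- 0L; bj <- 0L; bs <- 1L
  consider <- function(i, j) {
    vals <- c(M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
    for (s in 1:3) if (vals[s] > best) {
      best <<- vals[s]; bi <<- i; bj <<- j; bs <<- s
    }
  }
  consider(n, m)
  for (i in seq(n - 1, 0)) consider(i, m)
  for (j in seq(m - 1, 0)) consider(n, j)
  matches <- 0L; columns <- 0L
  i <- bi; j <- bj; s <- bs
  while (i > 0 && j > 0) {
    if (s == 1) {
      columns <- columns + 1L
      if (A[i] == B[j]) matches <- matches + 1L
      s <- tM[i + 1, j + 1]; i <- i - 1L; j <- j - 1L
    } else if (s == 2) {
      columns <- columns + 1L
      s <- tX[i + 1, j + 1]; i <- i - 1L
    } else {
      columns <- columns + 1L
      s <- tY[i + 1, j + 1]; j <- j - 1L
    }
  }
  list(score = best,
       identity = if (columns) 100 * matches / columns else 0)
}

# --- digestion / trypticity oracle (substring enumeration) -------------

cleavage_sites_oracle <- function(seq) {
  ch <- strsplit(seq, "")[[1]]; n <- length(ch)
  i <- which(ch == "K" | ch == "R")
  i[i == n | ch[pmin(i + 1L, n)] != "P"]
}

digest_oracle <- function(seq, max_missed = 1, min_len = 8,
                          max_len = 30) {
  n <- nchar(seq)
  sites <- cleavage_sites_oracle(seq)
  starts <- c(1L, sites + 1L); starts <- starts[starts <= n]
  ends <- unique(c(sites, n))
  grid <- expand.grid(s = unique(starts), e = ends)
  grid <- grid[grid$s <= grid$e, , drop = FALSE]
  grid$len <- grid$e - grid$s + 1L
  grid$mc <- vapply(seq_len(nrow(grid)), function(r)
    sum(sites >= grid$s[r] & sites < grid$e[r]), integer(1))
  grid <- grid[grid$mc <= max_missed & grid$len >= min_len &
                 grid$len <= max_len, , drop = FALSE]
  if (nrow(grid) == 0)
    return(data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), missed_cleavages = integer(0)))
  data.frame(sequence = substring(seq, grid$s, grid$e),
             start = grid$s, end = grid$e, missed_cleavages = grid$mc,
             stringsAsFactors = FALSE)
}

tryptic_oracle <- function(peptide, parent) {
  d <- digest_oracle(parent, max_missed = nchar(parent), min_len = 1,
                     max_len = nchar(parent))
  peptide %in% d$sequence
}

# --- cysteine-pattern regex oracle -------------------------------------

cys_regex <- function(pattern) {
  rx <- gsub("Xn", "[^C]+", pattern, fixed = TRUE)
  gsub("X(?!n)", "[^C]", rx, perl = TRUE)
}

cys_oracle <- function(sequence, pattern, windowed = TRUE) {
  rx <- cys_regex(pattern)
  if (windowed) grepl(rx, sequence, perl = TRUE)
  else grepl(paste0("^[^C]*", rx, "[^C]*$"), sequence, perl = TRUE)
}

# --- six-frame ORF oracle ----------------------------------------------

revcomp_oracle <- function(s)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]),
                                 collapse = ""))

orf_oracle <- function(seq, min_nt = 150) {
  code <- Biostrings::GENETIC_CODE
  peps <- character(0)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp_oracle(seq)
    for (off in 0:2) {
      ncod <- (nchar(s) - off) %/% 3
      if (ncod < 2) next
      codons <- substring(s, off + 1 + 3 * (0:(ncod - 1)),
                          off + 3 * (1:ncod))
      aa <- unname(code[codons]); aa[is.na(aa)] <- "X"
      stops <- which(aa == "*")
      prev <- 0
      for (st in stops) {
        cand <- which(codons == "ATG")
        cand <- cand[cand > prev & cand < st]
        if (length(cand)) {
          a <- min(cand)  # longest ORF per stop
          if (3 * (st - a) >= min_nt) {
            p <- paste(aa[a:(st - 1)], collapse = "")
            if (!grepl("X", p, fixed = TRUE)) peps <- c(peps, p)
          }
        }
        prev <- st
      }
    }
  }
  sort(peps)
}

random_transcript <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
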