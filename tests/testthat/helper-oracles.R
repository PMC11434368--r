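# Independent oracles used to freeze expected values. These deliberately
# share no code with the package implementations.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Brute-force heme-motif oracle: enumerate every window, apply the stated
# precedence/consumption rules by walking positions.
oracle_scan <- function(seq, policy = "nonoverlap_greedy") {
  n <- nchar(seq)
  ch <- if (n) strsplit(seq, "")[[1]] else character(0)
  win_ok <- function(s, w) {
    if (s + w - 1 > n) return(FALSE)
    if (w == 5) {
      ch[s] == "C" && ch[s + 3] == "C" && ch[s + 4] == "H"
    } else {
      ch[s] == "C" && ch[s + 4] == "C" && ch[s + 5] == "H"
    }
  }
  out <- data.frame(start = integer(), pattern = character(),
                    stringsAsFactors = FALSE)
  if (policy == "all_matches") {
    for (s in seq_len(max(0, n - 4))) {
      if (win_ok(s, 5)) out <- rbind(out, data.frame(
        start = s - 1L, pattern = "CXXCH", stringsAsFactors = FALSE))
      if (win_ok(s, 6)) out <- rbind(out, data.frame(
        start = s - 1L, pattern = "CXXXCH", stringsAsFactors = FALSE))
    }
  } else {
    s <- 1L
    while (s <= n - 4L) {
      if (win_ok(s, 5)) {
        out <- rbind(out, data.frame(start = s - 1L, pattern = "CXXCH",
                                     stringsAsFactors = FALSE))
        s <- s + 5L
      } else if (win_ok(s, 6)) {
        out <- rbind(out, data.frame(start = s - 1L, pattern = "CXXXCH",
                                     stringsAsFactors = FALSE))
        s <- s + 6L
      } else {
        s <- s + 1L
      }
    }
  }
  rownames(out) <- NULL
  out
}

# Quadratic Gotoh DP, score only. Gap of length L costs open + L * ext.
oracle_sw_score <- function(a, b, submat = blosum62(), open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e30
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - ext, H[i, j - 1] - open - ext)
      F[i, j] <- max(F[i - 1, j] - ext, H[i - 1, j] - open - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + submat[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Modularity from a plain edge list (each undirected edge once).
oracle_modularity <- function(edges, weights, membership, gamma = 1) {
  m <- sum(weights)
  if (m == 0) return(0)
  deg <- tapply(c(weights, weights), c(edges[, 1], edges[, 2]), sum)
  intra <- membership[edges[, 1]] == membership[edges[, 2]]
  W <- tapply(weights[intra], membership[edges[intra, 1]], sum)
  K <- tapply(as.numeric(deg), membership[names(deg)], sum)
  sum(W) / m - gamma * sum((K / (2 * m))^2)
}

# All set partitions of 1..n as lists of membership vectors (Bell(n) many).
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (k in seq_len(max(p) + 1L)) {
      out[[length(out) + 1L]] <- c(p, k)
    }
  }
  out
}

rand_seq <- function(len, alphabet = c(AA20, "X")) {
  # C and H enriched so motif windows actually occur
  prob <- ifelse(alphabet == "C", 4, ifelse(alphabet == "H", 3, 1))
  paste(sample(alphabet, len, replace = TRUE, prob = prob / sum(prob)),
        collapse = "")
}
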