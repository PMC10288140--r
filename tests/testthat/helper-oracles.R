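# Independent brute-force oracles, deliberately written with full dynamic-
# programming matrices and plain R loops so they share no code with the
# package's banded/rolling C++ kernels.

# Ends-free ("overlap") affine-gap alignment score: zero first row/column,
# best over last row and last column; gap of length L costs open + (L-1)*ext.
oracle_align_score <- function(a, b, match = 1, mismatch = -0.5,
                               open = -1, ext = -0.1, wildcard = "-") {
  m <- nchar(a); n <- nchar(b)
  if (m == 0 || n == 0) return(0)
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  FF <- matrix(-Inf, m + 1, n + 1)
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i - 1, j] + open, E[i - 1, j] + ext)
      FF[i, j] <- max(H[i, j - 1] + open, FF[i, j - 1] + ext)
      s <- if (B[j - 1] == wildcard) 0
           else if (A[i - 1] == B[j - 1]) match else mismatch
      H[i, j] <- max(H[i - 1, j - 1] + s, E[i, j], FF[i, j])
    }
  }
  max(H[m + 1, ], H[, n + 1])
}

# Same alignment with traceback: identity fraction = matches / aligned
# columns on the optimal path (free end overhangs excluded).
oracle_align_identity <- function(a, b, match = 1, mismatch = -0.5,
                                  open = -1, ext = -0.1) {
  m <- nchar(a); n <- nchar(b)
  if (m == 0 && n == 0) return(1)
  if (m == 0 || n == 0) return(0)
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  FF <- matrix(-Inf, m + 1, n + 1)
  tbH <- matrix(3L, m + 1, n + 1)  # 0 diag, 1 E, 2 F, 3 start
  tbE <- matrix(0L, m + 1, n + 1)  # 1 = opened from H
  tbF <- matrix(0L, m + 1, n + 1)
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      eh <- H[i - 1, j] + open; ee <- E[i - 1, j] + ext
      E[i, j] <- max(eh, ee); tbE[i, j] <- as.integer(eh >= ee)
      fh <- H[i, j - 1] + open; ff <- FF[i, j - 1] + ext
      FF[i, j] <- max(fh, ff); tbF[i, j] <- as.integer(fh >= ff)
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      d <- H[i - 1, j - 1] + s
      H[i, j] <- max(d, E[i, j], FF[i, j])
      tbH[i, j] <- if (H[i, j] == d) 0L
                   else if (H[i, j] == E[i, j]) 1L else 2L
    }
  }
  ends <- rbind(cbind(m + 1, seq_len(n + 1)), cbind(seq_len(m + 1), n + 1))
  vals <- H[ends]
  best <- ends[which.max(vals), ]
  i <- best[1]; j <- best[2]; state <- 0L
  matches <- 0L; columns <- 0L
  while (i > 1 && j > 1) {
    if (state == 0L) {
      t <- tbH[i, j]
      if (t == 3L) break
      if (t == 0L) {
        columns <- columns + 1L
        if (A[i - 1] == B[j - 1]) matches <- matches + 1L
        i <- i - 1L; j <- j - 1L
      } else state <- t
    } else if (state == 1L) {
      columns <- columns + 1L
      state <- if (tbE[i, j] == 1L) 0L else 1L
      i <- i - 1L
    } else {
      columns <- columns + 1L
      state <- if (tbF[i, j] == 1L) 0L else 2L
      j <- j - 1L
    }
  }
  if (columns == 0L) 0 else matches / columns
}

# Exhaustive-offset binding oracle: best ungapped tally over every relative
# shift of the two charge-coded strings.
oracle_binding_tally <- function(a, b, positive = c("K", "R"),
                                 negative = c("D", "E")) {
  code <- function(s) {
    ch <- strsplit(s, "")[[1]]
    ifelse(ch %in% positive, 1L, ifelse(ch %in% negative, -1L, 0L))
  }
  ca <- code(a); cb <- code(b)
  m <- length(ca); n <- length(cb)
  if (m == 0 || n == 0) return(0L)
  best <- -Inf
  for (s in (-(n - 1)):(m - 1)) {
    i <- max(1, s + 1):min(m, s + n)
    p <- ca[i] * cb[i - s]
    best <- max(best, sum(p == -1L) - sum(p == 1L))
  }
  as.integer(best)
}

random_protein_str <- function(n, letters = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# deliberately small configuration for engine tests
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(mu = 30, lambda = 10, generations = 5, toxin_length = 300,
         antidote_length = 150, seed = 99),
    list(...)
  )
  do.call(ea_config, args)
}
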