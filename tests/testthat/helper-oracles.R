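# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_seq_fixed <- function(n) {
  withr::with_seed(41, random_seq(n))
}

count_gap_runs <- function(s) {
  r <- rle(strsplit(s, "", fixed = TRUE)[[1]] == "-")
  sum(r$values)
}

# ends-free affine-gap alignment score by plain dynamic programming.
# Conventions mirror the package scoring: a gap of length L costs
# gap_open + L * gap_ext; terminal gaps are free in both sequences.
oracle_align_score <- function(a, b, match = 2, mismatch = -3,
                               gap_open = 5, gap_ext = 1) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  # M: a[i] aligned to b[j]; X: gap in b (a consumed); Y: gap in a
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  X[2:(n + 1L), 1] <- 0   # free leading gap in b
  Y[1, 2:(m + 1L)] <- 0   # free leading gap in a
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      s <- if (av[i - 1L] == bv[j - 1L]) match else mismatch
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L]) + s
      X[i, j] <- max(M[i - 1L, j] - gap_open - gap_ext, X[i - 1L, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1L] - gap_open - gap_ext, Y[i, j - 1L] - gap_ext)
    }
  }
  # free trailing gaps: best over last row and last column
  best <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  for (i in 1:(n + 1L)) best <- max(best, M[i, m + 1L], X[i, m + 1L], Y[i, m + 1L])
  for (j in 1:(m + 1L)) best <- max(best, M[n + 1L, j], X[n + 1L, j], Y[n + 1L, j])
  best
}

# every start offset where the adapter matches with <= mm Hamming mismatches
oracle_find_adapter <- function(seq, adapter, mm = 0L) {
  n <- nchar(seq); k <- nchar(adapter)
  if (k > n) return(integer(0))
  sv <- strsplit(seq, "", fixed = TRUE)[[1]]
  av <- strsplit(adapter, "", fixed = TRUE)[[1]]
  hits <- integer(0)
  for (i in seq_len(n - k + 1L)) {
    if (sum(sv[i:(i + k - 1L)] != av) <= mm) hits <- c(hits, i)
  }
  hits
}

# maximal perfect tandem repeats by testing every (start, unit length) and
# extending right; keeps minimal units, leftmost whole-unit phase
oracle_scan_ssrs <- function(s, min_repeats) {
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(sv)
  is_minimal <- function(m) {
    l <- nchar(m)
    for (d in seq_len(l - 1L)) {
      if (l %% d == 0L && strrep(substr(m, 1L, d), l %/% d) == m) return(FALSE)
    }
    TRUE
  }
  out <- list()
  for (l in 1:6) {
    minr <- min_repeats[[as.character(l)]]
    i <- 1L
    while (i + l * minr - 1L <= n) {
      # count matching continuation bases after the first unit
      j <- i + l
      while (j <= n && sv[j] == sv[j - l]) j <- j + 1L
      region_len <- j - i
      repeats <- region_len %/% l
      motif <- paste(sv[i:(i + l - 1L)], collapse = "")
      if (repeats >= minr && is_minimal(motif)) {
        out[[length(out) + 1L]] <- data.frame(
          motif = motif, repeats = repeats,
          start = i - 1L, end = i - 1L + repeats * l,
          stringsAsFactors = FALSE
        )
        i <- j - l + 1L  # next window beyond this maximal region
      } else if (repeats >= minr) {
        i <- j - l + 1L  # reducible unit: the shorter unit length reports it
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(motif = character(0), repeats = integer(0),
                      start = integer(0), end = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

# all (frame, first ATG after a stop, next in-frame stop) candidates plus
# ATG-anchored candidates running off the 3' end
oracle_orf_triples <- function(seq, min_len) {
  n <- nchar(seq)
  out <- list()
  for (frame in 0:2) {
    if (n - frame < 3L) next
    starts <- seq(frame + 1L, by = 3L, length.out = (n - frame) %/% 3L)
    codons <- substring(seq, starts, starts + 2L)
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    atgs <- which(codons == "ATG")
    bounds <- c(0L, stops, length(codons) + 1L)
    for (k in seq_len(length(bounds) - 1L)) {
      lo <- bounds[k] + 1L
      hi_stop <- bounds[k + 1L]
      open3 <- hi_stop > length(codons)
      hi <- if (open3) length(codons) else hi_stop
      seg_atgs <- atgs[atgs >= lo & atgs <= hi]
      if (length(seg_atgs) == 0L) next
      first_atg <- seg_atgs[1]
      ncod <- hi - first_atg + 1L
      if (ncod < min_len) next
      out[[length(out) + 1L]] <- data.frame(
        frame = frame,
        start = starts[first_atg] - 1L,
        end = starts[hi] + 2L,
        completeness = if (open3) "PARTIAL3" else "COMPLETE",
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(frame = integer(0), start = integer(0),
                      end = integer(0), completeness = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$frame), , drop = FALSE]
}
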