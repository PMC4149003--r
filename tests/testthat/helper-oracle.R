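# Plain-R recursive enumeration of all global alignments of two short
# sequences. Independent of the package's DP kernel (and of the compiled
# enumeration scorer): explores every monotone alignment path and charges
# each maximal gap run open + length * extend.
r_enum_global <- function(a, b, match = 5, mismatch = -4,
                          open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  rec <- function(i, j, last, acc) {
    if (i > length(A) && j > length(B)) return(acc)
    best <- -Inf
    if (i <= length(A) && j <= length(B))
      best <- max(best, rec(i + 1, j + 1, 0,
                            acc + if (A[i] == B[j]) match else mismatch))
    if (i <= length(A))
      best <- max(best, rec(i + 1, j, 1,
                            acc - if (last == 1) ext else open + ext))
    if (j <= length(B))
      best <- max(best, rec(i, j + 1, 2,
                            acc - if (last == 2) ext else open + ext))
    best
  }
  rec(1, 1, 0, 0)
}

# All sequences of length 1..max_len over the given letters.
all_seqs <- function(max_len, letters = c("A", "C")) {
  unlist(lapply(seq_len(max_len), function(L)
    apply(expand.grid(rep(list(letters), L)), 1, paste, collapse = "")))
}

random_seq <- function(len, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}
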