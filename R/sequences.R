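# Low-level nucleotide coding shared by all modules.
#
# Sequences are stored as upper-case character strings over {A,C,G,T,N}.
# Internally bases are encoded 1..4 in the order A,C,G,T (NA for N), and a
# full A/C/G/T 5-mer centred on 0-based position x maps to an index in
# 1..1024 by base-4 positional coding (leftmost base most significant).

encode_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  v <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], NUC)
  v
}

decode_seq <- function(code) paste(c(NUC, "N")[replace(code, is.na(code), 5L)],
                                   collapse = "")

#' All 1024 5-mer strings in index order
#'
#' Index order is base-4 positional coding of (A,C,G,T) with the leftmost
#' base most significant, so `all_fivemers()[1] == "AAAAA"` and
#' `all_fivemers()[1024] == "TTTTT"`.
#' @return Character vector of length 1024.
#' @export
all_fivemers <- function() {
  g <- expand.grid(p5 = NUC, p4 = NUC, p3 = NUC, p2 = NUC, p1 = NUC,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3, g$p4, g$p5)
}

#' Index of a 5-mer string in 1..1024
#' @param w character vector of 5-mer strings (A/C/G/T only).
#' @return Integer vector; NA for strings containing other characters.
#' @export
fivemer_index <- function(w) {
  m <- do.call(rbind, strsplit(toupper(w), "", fixed = TRUE))
  stopifnot(ncol(m) == 5L)
  code <- matrix(match(m, NUC) - 1L, nrow = nrow(m))
  idx <- code %*% c(256L, 64L, 16L, 4L, 1L) + 1L
  as.integer(idx)
}

# Per-position 5-mer indices for an encoded sequence.  Positions are 0-based;
# entry i of the result corresponds to x = i - 1.  NA where the window runs
# off the sequence or contains a non-ACGT base.
context_indices <- function(enc) {
  n <- length(enc)
  idx <- rep(NA_integer_, n)
  if (n < 5L) return(idx)
  c0 <- enc - 1L
  core <- 256L * c0[1:(n - 4L)] + 64L * c0[2:(n - 3L)] + 16L * c0[3:(n - 2L)] +
    4L * c0[4:(n - 1L)] + c0[5:n] + 1L
  idx[3:(n - 2L)] <- as.integer(core)
  idx
}

# Hamming distance between two equal-length sequences; N against anything is
# counted per `n_policy`: "mismatch" (clustering convention) or "skip".
hamming <- function(a, b, n_policy = c("mismatch", "skip")) {
  n_policy <- match.arg(n_policy)
  ea <- encode_seq(a); eb <- encode_seq(b)
  stopifnot(length(ea) == length(eb))
  if (n_policy == "mismatch") {
    ea[is.na(ea)] <- -1L
    eb[is.na(eb)] <- -2L
    sum(ea != eb)
  } else {
    ok <- !is.na(ea) & !is.na(eb)
    sum(ea[ok] != eb[ok])
  }
}

random_sequence <- function(n) paste(sample(NUC, n, replace = TRUE),
                                     collapse = "")
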