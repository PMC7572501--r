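# Centred-spectrum bookkeeping. The DC bin of an n-point DFT sits at
# centred index floor(n/2) + 1 (1-based), matching the usual fftshift.

circshift1 <- function(v, s) {
  n <- length(v)
  v[((seq_len(n) - 1L - s) %% n) + 1L]
}

shift_matrix <- function(m, sy, sx) {
  m[circshift1(seq_len(nrow(m)), sy), circshift1(seq_len(ncol(m)), sx)]
}

fftshift2 <- function(m) shift_matrix(m, nrow(m) %/% 2L, ncol(m) %/% 2L)

ifftshift2 <- function(m) shift_matrix(m, -(nrow(m) %/% 2L), -(ncol(m) %/% 2L))

# centred frequency coordinates in frequency-pixels; uy varies along rows
freq_coords <- function(shape) {
  cy <- shape[1L] %/% 2L + 1L
  cx <- shape[2L] %/% 2L + 1L
  list(uy = matrix(seq_len(shape[1L]) - cy, shape[1L], shape[2L]),
       ux = matrix(seq_len(shape[2L]) - cx, shape[1L], shape[2L], byrow = TRUE),
       center = c(cy, cx))
}

# index permutation that point-mirrors a centred spectrum about DC;
# for even axes the unmatched Nyquist row/column maps to itself
mirror_indices <- function(n) {
  c_ <- n %/% 2L + 1L
  ((2L * c_ - seq_len(n) - 1L) %% n) + 1L
}
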