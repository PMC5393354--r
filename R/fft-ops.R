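# FFT-based convolution / deconvolution plumbing shared by the glare and
# pencil-beam stages. All kernels are (2h+1) x (2h+1) with the peak at the
# centre bin; images are padded before the transform so the long glare
# tails never wrap around.

# Reflect- or zero-pad a matrix by `w` pixels on every side.
pad_matrix <- function(m, w, policy = c("reflect", "zero")) {
  policy <- match.arg(policy)
  if (w == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (policy == "zero") {
    out <- matrix(0, nr + 2 * w, nc + 2 * w)
    out[w + seq_len(nr), w + seq_len(nc)] <- m
    return(out)
  }
  if (w > nr || w > nc)
    stop("reflect padding width ", w, " exceeds image size ", nr, "x", nc)
  ridx <- c(rev(seq_len(w)), seq_len(nr), nr - seq_len(w) + 1L)
  cidx <- c(rev(seq_len(w)), seq_len(nc), nc - seq_len(w) + 1L)
  m[ridx, cidx]
}

crop_matrix <- function(m, w, nr, nc) m[w + seq_len(nr), w + seq_len(nc)]

# Embed a centred (2h+1)^2 kernel into an nr x nc array with its peak at
# element [1, 1], wrapped circularly, ready for FFT.
embed_kernel <- function(k, nr, nc) {
  kh <- (nrow(k) - 1L) %/% 2L
  if (nrow(k) > nr || ncol(k) > nc)
    stop("kernel (", nrow(k), "px) larger than the padded image (",
         nr, "x", nc, ")")
  out <- matrix(0, nr, nc)
  ri <- ((seq_len(nrow(k)) - kh - 1L) %% nr) + 1L
  ci <- ((seq_len(ncol(k)) - kh - 1L) %% nc) + 1L
  out[ri, ci] <- out[ri, ci] + k
  out
}

# Linear convolution of image with centred kernel; output same size as img.
fft_convolve <- function(img, k, pad = c("zero", "reflect"), pad_width = NULL) {
  pad <- match.arg(pad)
  kh <- (nrow(k) - 1L) %/% 2L
  w <- if (is.null(pad_width)) kh else max(pad_width, 0L)
  nr <- nrow(img); nc <- ncol(img)
  p <- pad_matrix(img, w, pad)
  kf <- stats::fft(embed_kernel(k, nrow(p), ncol(p)))
  out <- Re(stats::fft(stats::fft(p) * kf, inverse = TRUE)) / length(p)
  crop_matrix(out, w, nr, nc)
}

# Wiener-regularised inverse filter: spectral floor eps is relative to the
# kernel's peak spectral magnitude.
fft_deconvolve <- function(img, k, eps, pad = c("reflect", "zero"),
                           pad_width = NULL) {
  pad <- match.arg(pad)
  kh <- (nrow(k) - 1L) %/% 2L
  w <- if (is.null(pad_width)) kh else max(pad_width, kh)
  nr <- nrow(img); nc <- ncol(img)
  p <- pad_matrix(img, w, pad)
  kf <- stats::fft(embed_kernel(k, nrow(p), ncol(p)))
  floor2 <- (eps * max(Mod(kf)))^2
  wf <- Conj(kf) / (Mod(kf)^2 + floor2)
  out <- Re(stats::fft(stats::fft(p) * wf, inverse = TRUE)) / length(p)
  crop_matrix(out, w, nr, nc)
}

# Sampled, sum-normalised 2D Gaussian kernel (sigma in pixels).
gaussian_kernel_px <- function(sigma_px, half_size_px) {
  x <- -half_size_px:half_size_px
  g <- exp(-x^2 / (2 * sigma_px^2))
  k <- outer(g, g)
  k / sum(k)
}

# Bilinear interpolation of matrix `m` (pixel-centre coordinates in mm,
# package centre convention) at arbitrary points; NA outside the grid.
interp_bilinear <- function(m, pitch, x_row_mm, y_col_mm) {
  nr <- nrow(m); nc <- ncol(m)
  # continuous index: pos = (i - (n+1)/2) * pitch  =>  i = pos/pitch + (n+1)/2
  ri <- x_row_mm / pitch + (nr + 1) / 2
  ci <- y_col_mm / pitch + (nc + 1) / 2
  out <- rep(NA_real_, length(ri))
  ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  r0 <- pmin(pmax(floor(ri[ok]), 1L), nr - 1L)
  c0 <- pmin(pmax(floor(ci[ok]), 1L), nc - 1L)
  fr <- ri[ok] - r0
  fc <- ci[ok] - c0
  v00 <- m[cbind(r0, c0)]
  v10 <- m[cbind(r0 + 1L, c0)]
  v01 <- m[cbind(r0, c0 + 1L)]
  v11 <- m[cbind(r0 + 1L, c0 + 1L)]
  out[ok] <- v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
  out
}
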