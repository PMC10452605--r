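# Independent brute-force oracles used across the suite. These share no
# code with the package implementation beyond base R.

# textbook sRGB (D65) -> XYZ -> CIELAB for one pixel in [0,255]
oracle_srgb_to_lab <- function(rgb255) {
  v <- rgb255 / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, byrow = TRUE)
  xyz <- as.vector(M %*% lin)
  wp <- c(0.95047, 1, 1.08883) # D65
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz[1] / wp[1]); fy <- f(xyz[2] / wp[2]); fz <- f(xyz[3] / wp[3])
  c(L = 116 * fy - 16, A = 500 * (fx - fy), B = 200 * (fy - fz))
}

# naive circular binary-pattern code: own trig, own bilinear sampling, bit
# string built as characters and converted with strtoi
oracle_glpp_code <- function(gray, row, col, radius, P,
                             direction = "cw", interpolation = "bilinear") {
  sample_at <- function(r, c) {
    if (interpolation == "nearest") return(gray[round(r), round(c)])
    r0 <- floor(r); c0 <- floor(c)
    fr <- r - r0; fc <- c - c0
    r1 <- min(r0 + 1, nrow(gray)); c1 <- min(c0 + 1, ncol(gray))
    (1 - fr) * (1 - fc) * gray[r0, c0] + (1 - fr) * fc * gray[r0, c1] +
      fr * (1 - fc) * gray[r1, c0] + fr * fc * gray[r1, c1]
  }
  ks <- 0:(P - 1)
  if (direction == "ccw") ks <- rev(ks)
  bits <- vapply(ks, function(k) {
    ang <- 2 * pi * k / P
    r <- row + radius * sin(ang)
    c <- col + radius * cos(ang)
    r <- ifelse(abs(r - round(r)) < 1e-9, round(r), r)
    c <- ifelse(abs(c - round(c)) < 1e-9, round(c), c)
    if (sample_at(r, c) >= gray[row, col]) "1" else "0"
  }, character(1))
  strtoi(paste(bits, collapse = ""), base = 2L)
}

oracle_glpp_code_image <- function(gray, radius, P, interpolation = "bilinear") {
  m <- ceiling(radius)
  out <- matrix(NA_real_, nrow(gray), ncol(gray))
  for (i in (m + 1):(nrow(gray) - m)) {
    for (j in (m + 1):(ncol(gray) - m)) {
      cw <- oracle_glpp_code(gray, i, j, radius, P, "cw", interpolation)
      ccw <- oracle_glpp_code(gray, i, j, radius, P, "ccw", interpolation)
      out[i, j] <- max(cw, ccw)
    }
  }
  out
}

# quadruple-loop depthwise-separable convolution, stride 1, 'same' padding
oracle_sepconv <- function(x, dw, pw, b) {
  k <- dim(dw)[1]; h <- dim(x)[1]; w <- dim(x)[2]; C <- dim(x)[3]
  pad <- (k - 1) %/% 2
  xp <- array(0, c(h + 2 * pad + (k %% 2 == 0), w + 2 * pad + (k %% 2 == 0), C))
  xp[pad + seq_len(h), pad + seq_len(w), ] <- x
  mid <- array(0, c(h, w, C))
  for (c in seq_len(C)) for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (u in seq_len(k)) for (v in seq_len(k)) {
      acc <- acc + dw[u, v, c] * xp[i + u - 1, j + v - 1, c]
    }
    mid[i, j, c] <- acc
  }
  Ct <- ncol(pw)
  out <- array(0, c(h, w, Ct))
  for (t in seq_len(Ct)) for (i in seq_len(h)) for (j in seq_len(w)) {
    out[i, j, t] <- sum(mid[i, j, ] * pw[, t]) + b[t]
  }
  out
}

# AUC as exhaustive pairwise concordance (ties count 1/2)
oracle_auc_concordance <- function(scores, positive) {
  pos <- scores[as.logical(positive)]
  neg <- scores[!as.logical(positive)]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# render a tile directly from known concentration fields and stain vectors
# (Beer-Lambert), independent of the generator internals
oracle_render <- function(c1, c2, sm, i0 = 255, eps = 1) {
  od <- cbind(as.vector(c1), as.vector(c2)) %*% sm
  ints <- (i0 + eps) * 10^(-od) - eps
  array(round(pmin(pmax(ints, 0), 255)), c(dim(c1), 3L))
}
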