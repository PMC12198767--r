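# Maximal-overlap discrete wavelet transform (MODWT), periodic boundary.
# Implemented from the standard pyramid algorithm; used by wavelet_band() to
# isolate a dyadic frequency sub-band as a multiresolution detail series.

# Unit-norm DWT scaling filters; the wavelet filter follows by the QMF
# relation h_l = (-1)^l g_{L-1-l}.
wavelet_filters <- function(name) {
  g <- switch(name,
    haar = c(0.7071067811865476, 0.7071067811865476),
    d4 = c(0.4829629131445341, 0.8365163037378079,
           0.2241438680420134, -0.1294095225512604),
    la8 = c(-0.0757657147893407, -0.0296355276459541, 0.4976186676324578,
            0.8037387518052163, 0.2978577956055422, -0.0992195435769354,
            -0.0126039672622612, 0.0322231006040713),
    la16 = c(-0.0033824159513594, -0.0005421323316355, 0.0316950878103452,
             0.0076074873252848, -0.1432942383510542, -0.0612733590679088,
             0.4813596512592012, 0.7771857516997478, 0.3644418948359564,
             -0.0519458381078751, -0.0272190299168137, 0.0491371796734768,
             0.0038087520140601, -0.0149522583367926, -0.0003029205145516,
             0.0018899503329007),
    stop(sprintf("unknown wavelet `%s` (use haar, d4, la8 or la16)", name), call. = FALSE)
  )
  l <- length(g)
  h <- (-1)^(seq_len(l) - 1) * rev(g)
  # MODWT rescaling
  list(g = g / sqrt(2), h = h / sqrt(2))
}

# y_t = sum_l f_l x_{(t - s l) mod N}  (analysis step, filter upsampled by s)
circ_filter <- function(x, f, s) {
  n <- length(x)
  y <- numeric(n)
  idx <- seq_len(n) - 1L
  for (l in seq_along(f)) {
    y <- y + f[l] * x[((idx - s * (l - 1L)) %% n) + 1L]
  }
  y
}

# Adjoint: y_t = sum_l f_l x_{(t + s l) mod N}  (synthesis step)
circ_filter_adj <- function(x, f, s) {
  n <- length(x)
  y <- numeric(n)
  idx <- seq_len(n) - 1L
  for (l in seq_along(f)) {
    y <- y + f[l] * x[((idx + s * (l - 1L)) %% n) + 1L]
  }
  y
}

# Pyramid: wavelet (W_1..W_J) and scaling (V_J) coefficient vectors.
modwt_pyramid <- function(x, levels, wavelet = "la16") {
  flt <- wavelet_filters(wavelet)
  v <- x
  w <- vector("list", levels)
  for (k in seq_len(levels)) {
    s <- 2L^(k - 1L)
    w[[k]] <- circ_filter(v, flt$h, s)
    v <- circ_filter(v, flt$g, s)
  }
  list(w = w, v = v)
}

# Multiresolution detail series of one level: synthesize W_j back to the
# time domain through the adjoint cascade.
modwt_detail <- function(x, level, wavelet = "la16") {
  pyr <- modwt_pyramid(x, level, wavelet)
  flt <- wavelet_filters(wavelet)
  d <- circ_filter_adj(pyr$w[[level]], flt$h, 2L^(level - 1L))
  for (k in rev(seq_len(level - 1L))) {
    d <- circ_filter_adj(d, flt$g, 2L^(k - 1L))
  }
  d
}

# Full multiresolution analysis: details D_1..D_J plus smooth S_J.
# The components sum to the input exactly (used as a correctness check).
modwt_mra <- function(x, levels, wavelet = "la16") {
  pyr <- modwt_pyramid(x, levels, wavelet)
  flt <- wavelet_filters(wavelet)
  details <- lapply(seq_len(levels), function(j) {
    d <- circ_filter_adj(pyr$w[[j]], flt$h, 2L^(j - 1L))
    for (k in rev(seq_len(j - 1L))) {
      d <- circ_filter_adj(d, flt$g, 2L^(k - 1L))
    }
    d
  })
  smooth <- pyr$v
  for (k in rev(seq_len(levels))) {
    smooth <- circ_filter_adj(smooth, flt$g, 2L^(k - 1L))
  }
  list(details = details, smooth = smooth)
}
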