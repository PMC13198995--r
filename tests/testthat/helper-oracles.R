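# Independent oracles and small fixtures shared across tests.

# Naive direct convolution in plain R (double precision) -- the reference
# for the im2col/GEMM kernel.
naive_conv <- function(x, w, stride = 1, pad = c(0, 0, 0, 0), dil = 1,
                       groups = 1) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]; N <- dim(x)[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; cing <- dim(w)[3]; cout <- dim(w)[4]
  Ho <- (H + pad[1] + pad[2] - ((kh - 1) * dil + 1)) %/% stride + 1
  Wo <- (W + pad[3] + pad[4] - ((kw - 1) * dil + 1)) %/% stride + 1
  xp <- array(0, c(H + pad[1] + pad[2], W + pad[3] + pad[4], C, N))
  xp[pad[1] + (1:H), pad[3] + (1:W), , ] <- x
  y <- array(0, c(Ho, Wo, cout, N))
  cpg <- C %/% groups; copg <- cout %/% groups
  for (n in 1:N) for (co in 1:cout) {
    g <- (co - 1) %/% copg
    for (ho in 1:Ho) for (wo in 1:Wo) {
      acc <- 0
      for (ci in 1:cing) for (ki in 1:kh) for (kj in 1:kw) {
        acc <- acc + xp[(ho - 1) * stride + (ki - 1) * dil + 1,
                        (wo - 1) * stride + (kj - 1) * dil + 1,
                        g * cpg + ci, n] * w[ki, kj, ci, co]
      }
      y[ho, wo, co, n] <- acc
    }
  }
  y
}

# Brute-force all-pairs surface distances (O(|SA| * |SB|)), the oracle for
# the distance-transform implementation.
brute_surface_distances <- function(a, b) {
  pa <- boundary_points(a)
  pb <- boundary_points(b)
  if (nrow(pa) == 0L || nrow(pb) == 0L)
    return(list(hd95 = NA_real_, assd = NA_real_, valid = FALSE))
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  da <- sqrt(apply(d2, 1, min))
  db <- sqrt(apply(d2, 2, min))
  list(hd95 = max(quantile(da, 0.95, type = 7, names = FALSE),
                  quantile(db, 0.95, type = 7, names = FALSE)),
       assd = (sum(da) + sum(db)) / (length(da) + length(db)),
       hd = max(max(da), max(db)),
       valid = TRUE)
}

random_mask <- function(n = 32, p = 0.2) {
  m <- matrix(0, n, n)
  k <- sample(1:3, 1)
  for (i in seq_len(k)) {
    cx <- runif(1, 4, n - 4); cy <- runif(1, 4, n - 4)
    r <- runif(1, 2, n / 4)
    xs <- matrix(seq_len(n), n, n); ys <- t(xs)
    m[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- 1
  }
  m
}

# Closed-form FLOPs recomputation written directly from the architecture
# constants (independent of the build-time layer registry).
oracle_flops <- function(variant, S) {
  mac2 <- function(cin, k, cout, hw) 2 * cin * k * k * cout * hw * hw
  total <- mac2(3, 3, 32, S / 2)                      # stem
  blocks <- list(
    list(e = 1, k = 3, s = 1, cin = 32, cout = 16, rep = 1),
    list(e = 6, k = 3, s = 2, cin = 16, cout = 24, rep = 2),
    list(e = 6, k = 5, s = 2, cin = 24, cout = 40, rep = 2),
    list(e = 6, k = 3, s = 2, cin = 40, cout = 80, rep = 3),
    list(e = 6, k = 5, s = 1, cin = 80, cout = 112, rep = 3),
    list(e = 6, k = 5, s = 2, cin = 112, cout = 192, rep = 4),
    list(e = 6, k = 3, s = 1, cin = 192, cout = 320, rep = 1))
  hw <- S / 2
  for (b in blocks) {
    cin <- b$cin
    for (r in seq_len(b$rep)) {
      stride <- if (r == 1) b$s else 1
      hw_out <- hw / stride
      cexp <- cin * b$e
      if (b$e != 1) total <- total + mac2(cin, 1, cexp, hw)
      total <- total + 2 * 1 * b$k^2 * cexp * hw_out^2          # depthwise
      se <- max(1, cin %/% 4)
      total <- total + 2 * cexp * se + 2 * se * cexp            # SE at 1x1
      total <- total + mac2(cexp, 1, b$cout, hw_out)            # project
      cin <- b$cout
      hw <- hw_out
    }
  }
  total <- total + mac2(320, 1, 1280, S / 32)                   # head conv
  bins <- c(1, 2, 3, 6)
  total <- total + sum(2 * 1280 * 128 * bins^2)                 # PPM branches
  total <- total + mac2(1280 + 4 * 128, 1, 512, S / 32)         # PPM reduce
  skip_ch <- c(96, 144, 240, 672)
  if (variant == "full_msff") {
    for (i in 1:4) {
      C <- skip_ch[i]; hwi <- S / 2^i
      att <- max(1, (3 * C) %/% 8)
      total <- total + mac2(C, 1, C, hwi) + 2 * mac2(C, 3, C, hwi) +
        mac2(3 * C, 1, C, hwi) + mac2(C, 1, C, hwi) +
        2 * 3 * C * att + 2 * att * 3 * C
    }
  }
  dch <- c(512, 256, 128, 64, 32)
  prev <- 512
  for (i in 1:5) {
    hwi <- S / 2^(5 - i)
    skip <- if (i <= 4 && variant != "no_skip") skip_ch[5 - i] else 0
    total <- total + mac2(prev + skip, 3, dch[i], hwi)
    prev <- dch[i]
  }
  total + mac2(32, 1, 1, S)                                     # head
}

tiny_model <- function(input_size = 32L, variant = "full_msff", seed = 42L) {
  suppressWarnings(build_model(model_config(variant = variant,
                                            input_size = input_size,
                                            seed = seed)))
}

tiny_samples <- function(n = 4L, size = 32L, seed = 9L, img_size = 64L,
                         bg = 0) {
  spec <- phantom_spec(n_patients = 1L, slices_per_patient = n,
                       image_size = img_size,
                       background_slice_fraction = bg, seed = seed)
  phantom_samples(list(make_phantom_volume(spec, 1L)), size = size)
}
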