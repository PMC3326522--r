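# Shared fixtures, built in code and cached for the session.

.fx <- new.env(parent = emptyenv())

fixModel <- function(top = "T", bottom = "T") {
  key <- paste0("m_", top, "_", bottom)
  if (is.null(.fx[[key]])) .fx[[key]] <- buildStateModel(top, bottom)
  .fx[[key]]
}

fixMap <- function(state = "T", voxelA = 4, boxVox = 64, resolutionA = 8) {
  key <- paste("v", state, voxelA, boxVox, resolutionA, sep = "_")
  if (is.null(.fx[[key]]))
    .fx[[key]] <- synthesizeDensity(fixModel(state), voxelA, boxVox, resolutionA)
  .fx[[key]]
}

# independent rigid-superposition oracle: Horn's quaternion method
hornSuperpose <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  M <- t(A) %*% B
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  Nq <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  q <- eigen(Nq, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
  list(R = R, t = cb - as.numeric(R %*% ca))
}

# planted two-pattern image stack for classification tests
plantedStack <- function(n, N = 32, snrPlant = 0.3, seed = 42,
                         nStates = 2) {
  set.seed(seed)
  base <- matrix(0, N, N)
  base[N / 2 + (-6:6), N / 2 + (-6:6)] <- 1
  r <- sqrt(outer((seq_len(N) - 1 - N / 2)^2, (seq_len(N) - 1 - N / 2)^2, `+`))
  patterns <- lapply(seq_len(nStates), function(k) {
    p <- base
    ang <- 2 * pi * (k - 1) / nStates
    cx <- round(N / 2 + 11 * cos(ang)); cy <- round(N / 2 + 11 * sin(ang))
    p[cx + (-2:2), cy + (-2:2)] <- p[cx + (-2:2), cy + (-2:2)] + 2
    p
  })
  state <- rep(seq_len(nStates), length.out = n)
  sigma <- sqrt(var(as.numeric(patterns[[1]])) / snrPlant)
  imgs <- array(0, c(N, N, n))
  for (i in seq_len(n))
    imgs[, , i] <- patterns[[state[i]]] + rnorm(N * N, sd = sigma)
  list(images = imgs, state = state, patterns = patterns)
}
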