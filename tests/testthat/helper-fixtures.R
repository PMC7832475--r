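# Shared fixtures and independent brute-force oracles.

# one-vertebra phantom on a small grid; sd 0 by default for exact checks
smallPhantom <- function(mean_hu = 100, sd_hu = 0, seed = 1, level = "L1",
                         degenerated = FALSE, kvp = 120) {
  generateVolume(
    list(vertebraSpec(level, center = c(24, 20, 20),
                      trabecular_mean_hu = mean_hu, trabecular_sd_hu = sd_hu,
                      degenerated = degenerated)),
    grid = list(dim = c(48, 64, 40), spacing = c(1, 1, 1)),
    kvp = kvp, seed = seed)
}

identityEq <- function(kvp = 120) CalibrationEquation(kvp, 1, 0)

# brute-force metric erosion: keep voxel iff min world distance to any
# complement voxel exceeds depth (exhaustive scan; independent of the
# package's distance transform)
erodeBrute <- function(mask, spacing, depth) {
  d <- dim(mask)
  comp <- which(!mask, arr.ind = TRUE)
  out <- array(FALSE, d)
  if (nrow(comp) == 0) return(mask)
  cw <- sweep(comp - 1, 2, spacing, "*")
  for (v in which(mask)) {
    w <- (arrayInd(v, d) - 1) * spacing
    d2 <- min(rowSums(sweep(cw, 2, as.numeric(w))^2))
    out[v] <- d2 > depth^2
  }
  out
}

# brute-force AUC: pairwise concordance with ties counting one half
aucBrute <- function(cases, controls, lower_is_positive = TRUE) {
  conc <- outer(cases, controls, function(a, b)
    if (lower_is_positive) (a < b) + 0.5 * (a == b)
    else (a > b) + 0.5 * (a == b))
  mean(conc)
}

# exhaustive Youden scan over 2(n1+n2)+1 candidates: every observed value
# offset by +/- eps, plus one extreme sentinel
youdenBrute <- function(cases, controls, lower_is_positive = TRUE) {
  v <- c(cases, controls)
  eps <- if (diff(range(v)) > 0) diff(range(v)) * 1e-9 else 1e-9
  cuts <- c(min(v) - 1, as.vector(rbind(v - eps, v + eps)))
  best <- -Inf
  for (ct in cuts) {
    if (lower_is_positive) {
      sens <- mean(cases < ct); spec <- mean(controls >= ct)
    } else {
      sens <- mean(cases > ct); spec <- mean(controls <= ct)
    }
    best <- max(best, sens + spec - 1)
  }
  best
}
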