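# Independent oracles and small fixture builders shared across tests.

# Brute-force Phansalkar: per-pixel double loop with explicit symmetric
# (edge-repeating) mirror reflection, population SD. Deliberately written
# without integral images so it checks the fast implementation.
phansalkar_oracle <- function(px, window = 15L, p = 2, q = 10, k = 0.25,
                              r = 0.5) {
  n <- nrow(px); m <- ncol(px)
  pad <- (window - 1L) %/% 2L
  reflect <- function(x, lim) {
    if (x < 1L) 1L - x else if (x > lim) 2L * lim + 1L - x else x
  }
  out <- matrix(FALSE, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      vals <- numeric(window^2)
      idx <- 1L
      for (di in -pad:pad) {
        for (dj in -pad:pad) {
          vals[idx] <- px[reflect(i + di, n), reflect(j + dj, m)]
          idx <- idx + 1L
        }
      }
      mu <- mean(vals)
      s <- sqrt(mean(vals^2) - mu^2)
      t <- mu * (1 + p * exp(-q * mu) + k * ((s / r) - 1))
      out[i, j] <- px[i, j] > t
    }
  }
  out
}

# Exhaustive Shanbhag criterion scan, plain double loops over candidate
# bins and histogram entries.
shanbhag_oracle_bin <- function(counts) {
  nb <- length(counts)
  norm <- counts / sum(counts)
  P1 <- cumsum(norm)
  P2 <- 1 - P1
  eps <- .Machine$double.eps
  first <- which(P1 >= eps)[1L]
  last <- max(which(abs(P2) >= eps))
  best <- first; best_val <- Inf
  for (it in first:last) {
    eb <- 0
    tb <- 0.5 / P1[it]
    if (it >= 2L) {
      for (ih in 2:it) eb <- eb - norm[ih] * log(1 - tb * P1[ih - 1L])
    }
    eb <- eb * tb
    eo <- 0
    to <- 0.5 / P2[it]
    for (ih in (it + 1L):nb) {
      eo <- eo - norm[ih] * log(max(1 - to * P2[ih], eps))
    }
    eo <- eo * to
    val <- abs(eb - eo)
    if (val < best_val) {
      best_val <- val
      best <- it
    }
  }
  best - 1L
}

# All permutations of 1..n (n small), one per row.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Exact Spearman permutation p-value: proportion of permutations with
# |rho| >= |rho observed|.
spearman_perm_p <- function(x, y) {
  rho_obs <- cor(x, y, method = "spearman")
  perms <- all_perms(length(y))
  rhos <- apply(perms, 1L, function(pp) cor(x, y[pp], method = "spearman"))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# ICC via R's ANOVA machinery as an independent mean-squares route.
icc_aov_oracle <- function(ratings, mode) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(y = as.vector(ratings),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  if (mode == "consistency") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  }
}

# TRUE where a pixel's full 3x3 neighbourhood is foreground (used to
# check the 1-px-wide skeleton property).
window_full3 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  out <- matrix(FALSE, n, k)
  if (n < 3 || k < 3) return(out)
  inner <- m[2:(n - 1), 2:(k - 1)] &
    m[1:(n - 2), 2:(k - 1)] & m[3:n, 2:(k - 1)] &
    m[2:(n - 1), 1:(k - 2)] & m[2:(n - 1), 3:k] &
    m[1:(n - 2), 1:(k - 2)] & m[1:(n - 2), 3:k] &
    m[3:n, 1:(k - 2)] & m[3:n, 3:k]
  out[2:(n - 1), 2:(k - 1)] <- inner
  out
}

# 90-degree counter-clockwise rotation of a matrix.
rot_ccw <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

# Minimal valid cohort rows for eye-selection tests.
make_eye_row <- function(id, eye, sq_mac = 8, ssi_mac = 60, sq_disc = 8,
                         ssi_disc = 55, group = "aMCI", scp_vd = 40) {
  data.frame(id = id, group = group, age = 73, gender = "F",
             race = "Caucasian", eye = eye,
             sq_macula = sq_mac, ssi_macula = ssi_mac,
             sq_disc = sq_disc, ssi_disc = ssi_disc,
             moca = 25, cdr = 0.5, craft_imm = 10, craft_del = 8,
             ravlt_del = 5, iop = 15, education_years = 16,
             test_imaging_interval_years = 0.4, scp_vd = scp_vd,
             stringsAsFactors = FALSE)
}

# A small macular angiogram with a known constructed vessel mask: grid
# lines at `spacing`, avascular disc of radius `faz_mm` at the centre.
constructed_macula <- function(n = 152L, vessel_value = 0.6,
                               noise_mean = 0.1, noise_sd = 0.02,
                               spacing = 8L, faz_mm = 0.25,
                               field_mm = 1.5, seed = 1L) {
  set.seed(seed)
  px <- matrix(pmin(pmax(rnorm(n * n, noise_mean, noise_sd), 0), 1), n, n)
  vessel <- matrix(FALSE, n, n)
  vessel[seq(4L, n, by = spacing), ] <- TRUE
  vessel[, seq(4L, n, by = spacing)] <- TRUE
  ctr <- (n + 1) / 2
  um <- 1000 * field_mm / n
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  r_faz <- faz_mm * 1000 / um
  vessel[d < r_faz] <- FALSE
  ring <- d >= r_faz & d < r_faz + 2
  vessel <- vessel | ring
  px[vessel] <- vessel_value
  list(image = en_face_angiogram(px, field_mm, "macula"),
       vessel = vessel, faz_analytic_mm2 = pi * faz_mm^2)
}
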