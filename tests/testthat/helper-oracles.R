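# Independent oracles used across the suite. These re-derive the model
# quantities with plain loops and no shared code with the package
# internals (beyond the documented conventions: unit squares [ix, ix+1),
# Gaussian density profile with peak 1 truncated at the disc).

# per-square density map of one terminal: list of (ix, iy, w)
oracle_footprint <- function(x, y, radius = 3.5, sigma = 0.5 * 3.5) {
  sq <- list()
  wmax <- 0
  for (ix in floor(x - radius - 2):ceiling(x + radius + 2)) {
    for (iy in floor(y - radius - 2):ceiling(y + radius + 2)) {
      d2 <- (ix + 0.5 - x)^2 + (iy + 0.5 - y)^2
      if (d2 <= radius^2) {
        w <- exp(-d2 / (2 * sigma^2))
        sq[[length(sq) + 1]] <- c(ix = ix, iy = iy, w = w)
        wmax <- max(wmax, w)
      }
    }
  }
  lapply(sq, function(s) unname(c(s["ix"], s["iy"], s["w"] / wmax)))
}

# brute-force Eq. 1: term-by-term over the focal terminal's footprint,
# with the other terminals' densities accumulated square by square
oracle_potential <- function(terminals, which, field, C = 0, radius = 3.5,
                             sigma_frac = 0.5) {
  sigma <- sigma_frac * radius
  W <- field$width; H <- field$height
  Lf <- field$resident_L; Rf <- field$resident_R
  for (i in seq_len(nrow(terminals))) {
    if (i == which) next
    for (s in oracle_footprint(terminals$x[i], terminals$y[i], radius,
                               sigma)) {
      if (s[1] >= 0 && s[1] < W && s[2] >= 0 && s[2] < H) {
        Lf[s[1] + 1, s[2] + 1] <- Lf[s[1] + 1, s[2] + 1] +
          s[3] * terminals$L_F[i]
        Rf[s[1] + 1, s[2] + 1] <- Rf[s[1] + 1, s[2] + 1] +
          s[3] * terminals$R_F[i]
      }
    }
  }
  num <- 0; den <- 0
  any_in <- FALSE
  for (s in oracle_footprint(terminals$x[which], terminals$y[which],
                             radius, sigma)) {
    if (s[1] < 0 || s[1] >= W || s[2] < 0 || s[2] >= H) next
    any_in <- TRUE
    lf <- s[3] * terminals$L_F[which]
    rf <- s[3] * terminals$R_F[which]
    num <- num + lf * (field$R_T[s[1] + 1, s[2] + 1] + rf +
                         C * Rf[s[1] + 1, s[2] + 1])
    den <- den + rf * (field$L_T[s[1] + 1, s[2] + 1] + lf +
                         C * Lf[s[1] + 1, s[2] + 1])
  }
  if (!any_in) return(NA_real_)
  unname(abs(log(num / den)))
}

# reference sensor dynamics for immobile terminals: the documented
# per-iteration algorithm (compute D, push history, common coefficient,
# resetting force), with sequential within-iteration updates in terminal
# order, composed from the exported R operations
oracle_immobile_dynamics <- function(terminals, field, n_iter, params) {
  n <- nrow(terminals)
  hist <- matrix(0, params$h, n)
  Dlog <- matrix(NA_real_, n_iter, n)
  for (it in seq_len(n_iter)) {
    C <- fiber_weight(it - 1, params)
    for (t in seq_len(n)) {
      D <- guidance_potential(terminals[t, ], field, terminals[-t, ], C,
                              params)
      hist[, t] <- c(hist[-1, t], D)
      a <- adaptation_coefficient(hist[, t], params)
      terminals[t, ] <- apply_coadaptation(terminals[t, ], a, params)
      Dlog[it, t] <- D
    }
  }
  list(terminals = terminals, D = Dlog)
}

# fake simulation result for metric unit tests
fake_sim <- function(u, x, y = rep(1, length(u)), max_x = x,
                     class = rep("wt", length(u)),
                     mobile = rep(TRUE, length(u)), hints = list()) {
  structure(list(
    final = data.frame(terminal_id = seq_along(u), origin_u = u, x = x,
                       y = y, R_F = 1, L_F = 1, D = 0, class = class,
                       mobile = mobile, stringsAsFactors = FALSE),
    max_x = max_x, max_ratio_dev = rep(0, length(u)), trace = NULL,
    params = as.list(model_params()), hints = hints, tag = "fake"),
    class = "coadapt_sim")
}
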