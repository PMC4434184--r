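# Independent brute-force transcription of the elastic forced-bending
# model, written step by step from the defining relations and kept free
# of any code shared with the package: parameters are looked up straight
# from the canonical ten-row table, the accumulated twist is built by
# literal summation, and all sums are explicit loops over the signed
# step indices.

oracle_canonical <- data.frame(
  step  = c("AA", "AT", "AG", "AC", "TA", "TG", "TC", "GG", "GC", "CG"),
  k_rho = c(0.2, 0.124, 0.077, 0.085, 0.064, 0.059, 0.097, 0.075, 0.057, 0.04),
  k_tau = c(0.406, 0.641, 0.28, 0.302, 0.365, 0.393, 0.408, 0.218, 0.256, 0.255),
  rho0  = c(0.76, -1.39, 3.15, 0.91, 5.25, 5.95, 3.87, 3.86, 0.67, 4.25),
  tau0  = c(-1.84, 0, -1.48, -0.64, 0, -0.05, -1.52, 0.4, 0, 0),
  stringsAsFactors = FALSE)

oracle_rc_step <- function(step) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste0(comp[substr(step, 2, 2)], comp[substr(step, 1, 1)])
}

oracle_params <- function(step) {
  k <- match(step, oracle_canonical$step)
  if (!is.na(k)) return(oracle_canonical[k, ])
  k <- match(oracle_rc_step(step), oracle_canonical$step)
  if (is.na(k)) stop("unknown step ", step)
  p <- oracle_canonical[k, ]
  p$tau0 <- -p$tau0
  p
}

# accumulated twist at signed step i, by literal summation of omega
oracle_Omega <- function(i, omega) {
  if (i > 0) {
    om <- 0.5 * omega
    if (i >= 2) for (k in 2:i) om <- om + omega
    om
  } else {
    om <- -0.5 * omega
    if (i <= -2) for (k in -2:i) om <- om - omega
    om
  }
}

# full per-placement evaluation on a 129-bp window (dyad at base 65)
oracle_placement <- function(window, alpha = 579, omega = 34.8) {
  stopifnot(nchar(window) == 129)
  b <- strsplit(window, "")[[1]]
  dyad <- 65
  idx <- c(-64:-1, 1:64)
  # torque from the total-bend constraint
  sum_r0c <- 0; sum_t0s <- 0; sum_c2k <- 0; sum_s2k <- 0
  for (i in idx) {
    first <- if (i > 0) dyad + i - 1 else dyad + i
    p <- oracle_params(paste0(b[first], b[first + 1]))
    Om <- oracle_Omega(i, omega) * pi / 180
    sum_r0c <- sum_r0c + p$rho0 * cos(Om)
    sum_t0s <- sum_t0s + p$tau0 * sin(Om)
    sum_c2k <- sum_c2k + cos(Om)^2 / p$k_rho
    sum_s2k <- sum_s2k + sin(Om)^2 / p$k_tau
  }
  Fb <- (alpha - sum_r0c - sum_t0s) / (sum_c2k + sum_s2k)
  # per-step deformation energies under that torque, and the realised
  # bend angle from the deformed roll/tilt
  E <- 0; bend <- 0
  for (i in idx) {
    first <- if (i > 0) dyad + i - 1 else dyad + i
    p <- oracle_params(paste0(b[first], b[first + 1]))
    Om <- oracle_Omega(i, omega) * pi / 180
    E <- E + Fb^2 / (2 * p$k_rho) * cos(Om)^2 +
             Fb^2 / (2 * p$k_tau) * sin(Om)^2
    rho <- p$rho0 + Fb * cos(Om) / p$k_rho
    tau <- p$tau0 + Fb * sin(Om) / p$k_tau
    bend <- bend + rho * cos(Om) + tau * sin(Om)
  }
  list(F_b = Fb, E = E, bend = bend)
}

# literal sliding-window occupancy: S at every dyad with a full contact
# window, then the mean of defined S over the l-bp window at each base
oracle_occupancy <- function(sequence, beta = 1, l = 51) {
  L <- nchar(sequence)
  S <- rep(NA_real_, L)
  for (d in 65:(L - 64)) {
    win <- substr(sequence, d - 64, d + 64)
    if (grepl("[^ACGT]", win)) next
    S[d] <- exp(-beta * oracle_placement(win)$E)
  }
  h <- (l - 1) / 2
  O <- rep(NA_real_, L)
  for (j in 1:L) {
    w <- S[max(1, j - h):min(L, j + h)]
    w <- w[!is.na(w)]
    if (length(w)) O[j] <- sum(w) / length(w)
  }
  O
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
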