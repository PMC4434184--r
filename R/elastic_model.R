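#' Dinucleotide-step mechanical parameters
#'
#' Loads the ten canonical dinucleotide-step rows (force constants
#' `k_rho`, `k_tau` for roll and tilt, and torque-free equilibrium angles
#' `rho0`, `tau0`, angles in degrees, energies in the arbitrary units the
#' constants imply) and expands them to all 16 steps.  A step and its
#' reverse complement describe the same physical stack read from opposite
#' strands: roll is symmetric under strand reversal while tilt changes
#' sign, so the complementary step inherits `k_rho`, `k_tau` and `rho0`
#' unchanged and takes `-tau0`.  Self-complementary steps (AT, TA, GC,
#' CG) must therefore have `tau0 = 0`, which is validated at load.
#'
#' @param path optional TSV with columns `step`, `k_rho`, `k_tau`,
#'   `rho0`, `tau0`; one row per complementary pair (either orientation).
#'   Defaults to the table shipped with the package.
#' @return a `step_param_table`: data frame with one row per dinucleotide
#'   step (all 16), row names the step strings.
#' @export
step_param_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "step_params.tsv",
                        package = "nucelastic", mustWork = TRUE)
  }
  canon <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("step", "k_rho", "k_tau", "rho0", "tau0")
  if (!all(need %in% names(canon))) {
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  }
  canon$step <- toupper(canon$step)
  if (any(nchar(canon$step) != 2L) || any(!grepl("^[ACGT]{2}$", canon$step))) {
    stop("steps must be dinucleotides over A/C/G/T")
  }
  if (any(canon$k_rho <= 0) || any(canon$k_tau <= 0)) {
    stop("force constants k_rho and k_tau must be positive")
  }
  pal <- canon$step == vapply(canon$step, revcomp, "")
  if (any(pal & canon$tau0 != 0)) {
    stop("self-complementary steps must have tau0 = 0: ",
         paste(canon$step[pal & canon$tau0 != 0], collapse = ", "))
  }

  # row order matters: step (b1, b2) must sit at row (b1 - 1) * 4 + b2
  # for the integer dinucleotide indexing used throughout
  steps <- paste0(rep(DNA_BASES, each = 4L), rep(DNA_BASES, times = 4L))
  idx <- match(steps, canon$step)
  out <- data.frame(step = steps,
                    k_rho = NA_real_, k_tau = NA_real_,
                    rho0 = NA_real_, tau0 = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(steps)) {
    if (!is.na(idx[j])) {
      out[j, -1L] <- canon[idx[j], c("k_rho", "k_tau", "rho0", "tau0")]
    } else {
      k <- match(revcomp(steps[j]), canon$step)
      if (is.na(k)) stop("no parameters for step ", steps[j],
                         " or its reverse complement")
      out[j, -1L] <- canon[k, c("k_rho", "k_tau", "rho0", "tau0")]
      out$tau0[j] <- -canon$tau0[k]
    }
  }
  rownames(out) <- out$step
  class(out) <- c("step_param_table", "data.frame")
  out
}

#' Nucleosome bending geometry
#'
#' Constants of the forced-bending description of nucleosomal DNA: the
#' core particle wraps `core_len` bp, of which only the central
#' `contact_len` bp are in contact with the histone octamer and bend by a
#' total angle `alpha_total` under a uniform torque; helical twist is
#' fixed at `omega` per step.  Steps are indexed from the dyad as
#' i = +/-1 ... +/-max_step (no step 0); step +/-1 sits half a step from
#' the dyad.
#'
#' @param alpha_total total bend of the contacted DNA, degrees.
#' @param omega uniform twist per dinucleotide step, degrees.
#' @param core_len nucleosome footprint, bp (odd).
#' @param contact_len histone-contacted stretch scored by the model, bp
#'   (odd, at most `core_len`).
#' @return an `elastic_geometry` list; `$max_step` is
#'   `(contact_len - 1) / 2`.
#' @export
elastic_geometry <- function(alpha_total = 579, omega = 34.8,
                             core_len = 147L, contact_len = 129L) {
  stopifnot(is.numeric(alpha_total), length(alpha_total) == 1L,
            is.numeric(omega), length(omega) == 1L, omega > 0)
  core_len <- as.integer(core_len)
  contact_len <- as.integer(contact_len)
  if (contact_len %% 2L != 1L) stop("contact_len must be odd")
  if (core_len %% 2L != 1L) stop("core_len must be odd")
  if (contact_len > core_len) stop("contact_len must not exceed core_len")
  if (contact_len < 3L) stop("contact_len must be at least 3")
  structure(list(alpha_total = alpha_total, omega = omega,
                 core_len = core_len, contact_len = contact_len,
                 max_step = (contact_len - 1L) %/% 2L),
            class = "elastic_geometry")
}

#' Accumulated twist at a dinucleotide step
#'
#' Helical phase of step `i` counted from the dyad: step +/-1 lies half a
#' step away, each further step adds a full twist, and the sign follows
#' the direction from the dyad, so the result is antisymmetric in `i`.
#'
#' @param i signed step index (vectorised); 0 is not a step.
#' @param omega twist per step, degrees.
#' @param max_step largest admissible `|i|`.
#' @return accumulated twist in degrees.
#' @export
accumulated_twist <- function(i, omega = 34.8, max_step = 64L) {
  if (any(i == 0L) || any(abs(i) > max_step)) {
    stop("invalid step index: i must satisfy 1 <= |i| <= ", max_step)
  }
  sign(i) * (0.5 + (abs(i) - 1)) * omega
}

# Per-dyad sums of the elastic model over steps i = +/-1 ... +/-max_step.
# codes: integer base codes for the full sequence.  Returns the dyad
# positions (1-based index into the sequence) and the four sums
#   A = sum cos^2(Om_i)/k_rho(i)    B = sum sin^2(Om_i)/k_tau(i)
#   C = sum rho0(i) cos(Om_i)      D = sum tau0(i) sin(Om_i)
# from which torque and energy follow in closed form.  NA bases propagate
# to NA sums for every dyad whose contact window touches them.
elastic_sums <- function(codes, table, geom) {
  L <- length(codes)
  m <- geom$max_step
  if (L < geom$contact_len) {
    stop("sequence shorter than contact_len (", geom$contact_len, " bp)")
  }
  # per-step-position parameter vectors; position p covers bases p, p+1
  din <- (codes[-L] - 1L) * 4L + codes[-1L]
  inv_kr <- (1 / table$k_rho)[din]
  inv_kt <- (1 / table$k_tau)[din]
  r0 <- table$rho0[din]
  t0 <- table$tau0[din]

  Om <- deg2rad(accumulated_twist(seq_len(m), geom$omega, m))
  c1 <- cos(Om); s1 <- sin(Om)
  c2 <- c1^2;   s2 <- s1^2

  dyads <- (m + 1L):(L - m)          # 1-based dyad base positions
  nd <- length(dyads)
  A <- numeric(nd); B <- numeric(nd); C <- numeric(nd); D <- numeric(nd)
  for (i in seq_len(m)) {
    up <- dyads + i - 1L             # step +i starts at dyad + i - 1
    dn <- dyads - i                  # step -i starts at dyad - i
    A <- A + c2[i] * (inv_kr[up] + inv_kr[dn])
    B <- B + s2[i] * (inv_kt[up] + inv_kt[dn])
    C <- C + c1[i] * (r0[up] + r0[dn])
    D <- D + s1[i] * (t0[up] - t0[dn])   # sin(Om_{-i}) = -sin(Om_i)
  }
  list(dyads = dyads, A = A, B = B, C = C, D = D)
}

#' Deformation-energy landscape of a sequence
#'
#' Scores every candidate dyad placement whose full contact window lies
#' within the sequence.  For each dyad the torque is the bending load
#' that makes the contacted stretch bend by `alpha_total` in total,
#'   F_b = (alpha - sum rho0 cos(Om) - sum tau0 sin(Om)) /
#'         (sum cos^2(Om)/k_rho + sum sin^2(Om)/k_tau),
#' and the deformation energy is the harmonic roll/tilt energy under
#' that torque, which reduces to
#'   E = (alpha - sum rho0 cos(Om) - sum tau0 sin(Om))^2 / (2 (A + B)).
#' Placements whose contact window contains an ambiguous base get NA.
#'
#' @param sequence DNA string.
#' @param table a [step_param_table()].
#' @param geom an [elastic_geometry()].
#' @return data frame with columns `dyad` (0-based position of the dyad
#'   base), `F_b` and `energy`.
#' @export
energy_landscape <- function(sequence, table = step_param_table(),
                             geom = elastic_geometry()) {
  codes <- encode_bases(sequence)
  s <- elastic_sums(codes, table, geom)
  num <- geom$alpha_total - s$C - s$D
  den <- s$A + s$B
  data.frame(dyad = s$dyads - 1L,
             F_b = num / den,
             energy = num^2 / (2 * den))
}

# central contact window of an odd-length placement window
contact_codes <- function(window, geom) {
  codes <- encode_bases(window)
  L <- length(codes)
  if (L < geom$contact_len) {
    stop("window shorter than contact_len (", geom$contact_len, " bp)")
  }
  if (L %% 2L != 1L) stop("placement window must have odd length")
  mid <- (L + 1L) %/% 2L
  codes[(mid - geom$max_step):(mid + geom$max_step)]
}

#' Torque of a single nucleosome placement
#'
#' The uniform bending load the histone octamer must exert so that the
#' contacted stretch centred on the window's midpoint bends by
#' `alpha_total` degrees in total.  Only the central `contact_len` bp
#' enter; an ambiguous base inside them makes the placement undefined
#' (returns `NA`).
#'
#' @inheritParams energy_landscape
#' @param window DNA string of odd length at least `contact_len`,
#'   centred on the candidate dyad.
#' @return torque `F_b` (degree-energy units), or `NA` if undefined.
#' @export
torque <- function(window, table = step_param_table(),
                   geom = elastic_geometry()) {
  codes <- contact_codes(window, geom)
  s <- elastic_sums(codes, table, geom)
  (geom$alpha_total - s$C - s$D) / (s$A + s$B)
}

#' Deformation energy of a single nucleosome placement
#'
#' Sums the per-step harmonic roll/tilt energy of the contacted stretch
#' under the placement's torque.  With `per_step = TRUE` the per-step
#' decomposition (step index, accumulated twist, energy) is attached.
#'
#' @inheritParams torque
#' @param per_step return the per-step energy decomposition.
#' @return list with `F_b`, `E_total`, and (optionally) `per_step`, a
#'   data frame with columns `i`, `Omega`, `E`.
#' @export
placement_energy <- function(window, table = step_param_table(),
                             geom = elastic_geometry(), per_step = FALSE) {
  codes <- contact_codes(window, geom)
  s <- elastic_sums(codes, table, geom)
  fb <- (geom$alpha_total - s$C - s$D) / (s$A + s$B)
  out <- list(F_b = fb, E_total = fb^2 / 2 * (s$A + s$B))
  if (per_step) {
    m <- geom$max_step
    i <- c(-m:-1L, 1L:m)
    Om <- accumulated_twist(i, geom$omega, m)
    din <- (codes[-length(codes)] - 1L) * 4L + codes[-1L]
    # step +i starts at base m + i (1-based in the contact window), step -i at m + 1 - i
    p <- ifelse(i > 0L, m + i, m + 1L + i)
    kr <- table$k_rho[din[p]]
    kt <- table$k_tau[din[p]]
    Omr <- deg2rad(Om)
    out$per_step <- data.frame(
      i = i, Omega = Om,
      E = fb^2 / 2 * (cos(Omr)^2 / kr + sin(Omr)^2 / kt))
  }
  out
}

#' Total bend angle realised by a placement
#'
#' Deforms roll and tilt at every contacted step under the placement's
#' torque and sums their projections on the bending plane.  By the
#' construction of the torque this returns `alpha_total` for every
#' well-defined placement; the function exists as an explicit
#' conservation check.
#'
#' @inheritParams torque
#' @return realised bend angle in degrees (`NA` if the placement is
#'   undefined).
#' @export
total_bend_angle <- function(window, table = step_param_table(),
                             geom = elastic_geometry()) {
  codes <- contact_codes(window, geom)
  fb <- torque(window, table, geom)
  if (is.na(fb)) return(NA_real_)
  m <- geom$max_step
  total <- 0
  for (i in c(-m:-1L, 1L:m)) {
    p <- if (i > 0L) m + i else m + 1L + i
    din <- (codes[p] - 1L) * 4L + codes[p + 1L]
    Om <- deg2rad(accumulated_twist(i, geom$omega, m))
    rho <- table$rho0[din] + fb * cos(Om) / table$k_rho[din]
    tau <- table$tau0[din] + fb * sin(Om) / table$k_tau[din]
    total <- total + rho * cos(Om) + tau * sin(Om)
  }
  total
}
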