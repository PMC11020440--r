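## Synthetic generators: every input the pipeline consumes (alignments,
## structures, external feature tables, training sets) can be produced
## with known ground truth.  All generators take an explicit seed and
## restore the caller's RNG state, so one call never shifts another's
## stream.

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Sample an alignment from independent column profiles
#'
#' Each column gets an amino-acid profile drawn from a symmetric
#' Dirichlet; rows are sampled independently from the profiles, with an
#' optional per-cell gap probability.  The query row is drawn last (from
#' the same profiles, without gaps) and placed first.  Large
#' concentrations give near-uniform columns (conservation index near 0);
#' small concentrations give near-single-residue columns (high
#' conservation).
#'
#' @param m number of homolog rows (the query is added on top).
#' @param N alignment length.
#' @param concentration Dirichlet concentration per amino acid (> 0).
#' @param gap_fraction per-cell gap probability in homolog rows.
#' @param seed integer seed.
#' @return an [`msa`][read_msa] with `m + 1` rows; attribute `profiles`
#'   carries the generating N x 20 profile matrix.
#' @export
sample_profile_msa <- function(m, N, concentration = 1, gap_fraction = 0,
                               seed = 1L) {
  if (m < 1L || N < 1L) stop_varfit("m and N must be >= 1")
  if (!is.finite(concentration) || concentration <= 0)
    stop_varfit("concentration must be a positive number")
  if (gap_fraction < 0 || gap_fraction >= 1)
    stop_varfit("gap_fraction must be in [0, 1)")
  with_seed(seed, {
    profiles <- t(vapply(seq_len(N),
                         function(i) rdirichlet1(rep(concentration, 20L)),
                         numeric(20L)))
    colnames(profiles) <- AA20
    rows <- matrix(GAP, m, N)
    for (i in seq_len(N))
      rows[, i] <- sample(AA20, m, replace = TRUE, prob = profiles[i, ])
    if (gap_fraction > 0) {
      gaps <- matrix(stats::runif(m * N) < gap_fraction, m, N)
      rows[gaps] <- GAP
    }
    query <- vapply(seq_len(N),
                    function(i) sample(AA20, 1L, prob = profiles[i, ]),
                    character(1L))
    mat <- rbind(query, rows, deparse.level = 0)
    base::structure(new_msa(mat, query_id = "synthetic_query"),
                    profiles = profiles)
  })
}

#' Sample an alignment from a known Potts model
#'
#' Draws a random Potts model (Gaussian fields and couplings, reported in
#' the zero-sum gauge) and samples sequences from its Boltzmann
#' distribution.  In `"exact"` mode the full state space is enumerated
#' (requires `q^N <= 1e6`) and samples are exact draws from the
#' normalized distribution — the oracle mode for inference tests.
#' `"gibbs"` mode runs a single-site Gibbs sampler with stated burn-in
#' and thinning and is approximate.
#'
#' @param m number of sequences.
#' @param N positions; @param q states (uses the first `q` letters of the
#'   21-state alphabet).
#' @param h_sd,J_sd standard deviations of the generating fields and
#'   couplings.
#' @param seed integer seed.
#' @param mode `"exact"` or `"gibbs"`.
#' @param burn_in,thin Gibbs parameters (sweeps).
#' @return list with `msa` and the generating `model` (class
#'   `potts_model`, zero-sum gauge); in exact mode also `probs`, the full
#'   Boltzmann distribution, and `states`, the enumerated state matrix.
#' @export
sample_potts_msa <- function(m, N, q = 3L, h_sd = 0.5, J_sd = 0.5,
                             seed = 1L, mode = c("exact", "gibbs"),
                             burn_in = 200L, thin = 10L) {
  mode <- match.arg(mode)
  with_seed(seed, {
    h <- matrix(stats::rnorm(N * q, sd = h_sd), N, q)
    J <- array(0, dim = c(q, q, N, N))
    for (i in seq_len(N - 1L)) for (j in seq(i + 1L, N)) {
      Jij <- matrix(stats::rnorm(q * q, sd = J_sd), q, q)
      J[, , i, j] <- Jij
      J[, , j, i] <- t(Jij)
    }
    model <- zero_sum_gauge(new_potts_model(h, J))
    if (mode == "exact") {
      if (q^N > 1e6)
        stop_varfit("state space q^N = ", q^N, " exceeds the exact-",
                    "enumeration limit (1e6); use mode = \"gibbs\"")
      states <- as.matrix(expand.grid(rep(list(seq_len(q)), N)))[, N:1,
                                                                 drop = FALSE]
      E <- potts_energy_all(model, states)
      p <- exp(-(E - min(E)))
      p <- p / sum(p)
      idx <- sample.int(nrow(states), m, replace = TRUE, prob = p)
      mat <- matrix(model$alphabet[states[idx, , drop = FALSE]], m, N)
      msa <- new_msa(mat, query_id = "potts_query")
      list(msa = msa, model = model, probs = p, states = states)
    } else {
      s <- sample.int(q, N, replace = TRUE)
      keep <- matrix(0L, m, N)
      n_kept <- 0L
      sweep_count <- 0L
      while (n_kept < m) {
        for (i in seq_len(N)) {
          e <- model$h[i, ]
          for (j in seq_len(N)) if (j != i) e <- e + model$J[, s[j], i, j]
          p <- exp(e - max(e)); p <- p / sum(p)
          s[i] <- sample.int(q, 1L, prob = p)
        }
        sweep_count <- sweep_count + 1L
        if (sweep_count > burn_in && (sweep_count - burn_in) %% thin == 0L) {
          n_kept <- n_kept + 1L
          keep[n_kept, ] <- s
        }
      }
      mat <- matrix(model$alphabet[keep], m, N)
      list(msa = new_msa(mat, query_id = "potts_query"), model = model)
    }
  })
}

# energies of an integer state matrix (rows = states) under a Potts model
potts_energy_all <- function(model, states) {
  N <- model$N
  E <- numeric(nrow(states))
  for (i in seq_len(N)) E <- E - model$h[i, states[, i]]
  for (i in seq_len(N - 1L)) for (j in seq(i + 1L, N))
    E <- E - model$J[, , i, j][cbind(states[, i], states[, j])]
  E
}

# ---- toy structures ------------------------------------------------------

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resname, chain, resno, x, y, z, 1.00, 0.00, element)
}

# backbone + CB offsets for one residue in a given conformation
residue_atoms <- function(conformation, i, resname) {
  if (conformation == "helix") {
    # ideal alpha-helix: 100 deg twist, 1.5 A rise, CA radius 2.28 A
    th <- (i - 1L) * 100 * pi / 180
    z0 <- (i - 1L) * 1.5
    cyl <- function(r, dth, dz) c(r * cos(th + dth), r * sin(th + dth),
                                  z0 + dz)
    pos <- list(N = cyl(1.50, -25 * pi / 180, -0.50),
                CA = cyl(2.28, 0, 0),
                C = cyl(1.65, 21 * pi / 180, 0.50),
                O = cyl(2.00, 23 * pi / 180, 1.55),
                CB = cyl(3.45, -6 * pi / 180, -0.65))
  } else {
    # extended chain: CA every 3.8 A along x, alternating pucker in y
    s <- if (i %% 2L == 0L) 1 else -1
    x0 <- (i - 1L) * 3.8
    pos <- list(N = c(x0 - 1.20, s * 0.60, 0),
                CA = c(x0, 0, 0),
                C = c(x0 + 1.20, s * 0.60, 0),
                O = c(x0 + 1.20, s * 0.60, 1.23),
                CB = c(x0, -s * 1.10, -1.10))
  }
  if (resname == "GLY") pos$CB <- NULL
  pos
}

#' Write a toy protein structure as PDB text
#'
#' Emits an ideal poly-alanine alpha-helix or extended chain (backbone
#' N, CA, C, O plus CB), optionally replicated into several rigidly
#' translated chains for occlusion tests.  Geometry is idealized: 3.8 A
#' consecutive CA-CA distances in both conformations.
#'
#' @param n_res residues per chain.
#' @param conformation `"helix"` or `"extended"`.
#' @param chains chain identifiers; each after the first is translated by
#'   successive multiples of `offset`.
#' @param offset xyz translation between chains (Angstrom).
#' @param resname residue type for all positions (three-letter).
#' @param sequence optional one-letter sequence overriding `resname`
#'   (and `n_res`) with one residue type per position.
#' @param path optional output file; when NULL the PDB text is returned.
#' @return character vector of PDB lines (invisibly if written to
#'   `path`).
#' @export
make_toy_structure <- function(n_res, conformation = c("helix", "extended"),
                               chains = "A", offset = c(0, 5.5, 0),
                               resname = "ALA", sequence = NULL,
                               path = NULL) {
  conformation <- match.arg(conformation)
  if (!is.null(sequence)) {
    if (length(sequence) == 1L && nchar(sequence) > 1L)
      sequence <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    if (!all(sequence %in% AA20)) stop_varfit("unknown residue in sequence")
    n_res <- length(sequence)
    resnames <- AA1TO3[sequence]
  } else {
    resnames <- rep(resname, n_res)
  }
  if (n_res < 1L) stop_varfit("n_res must be >= 1")
  lines <- character(0)
  serial <- 0L
  for (ci in seq_along(chains)) {
    shift <- (ci - 1L) * offset
    for (i in seq_len(n_res)) {
      pos <- residue_atoms(conformation, i, resnames[i])
      for (nm in names(pos)) {
        serial <- serial + 1L
        xyz <- pos[[nm]] + shift
        lines <- c(lines, pdb_atom_line(serial, nm, resnames[i], chains[ci],
                                        i, xyz[1], xyz[2], xyz[3],
                                        substr(nm, 1L, 1L)))
      }
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Extended Gly-X-Gly tripeptide as PDB text
#'
#' The reference conformation used for RSA normalization: an extended
#' tripeptide with glycines flanking the residue of interest.
#'
#' @param x one-letter code of the central residue.
#' @param path optional output file.
#' @return character vector of PDB lines.
#' @export
make_gxg_tripeptide <- function(x, path = NULL) {
  if (!(x %in% AA20)) stop_varfit("unknown residue '", x, "'")
  res3 <- c("GLY", AA1TO3[[x]], "GLY")
  lines <- character(0)
  serial <- 0L
  for (i in 1:3) {
    pos <- residue_atoms("extended", i, res3[i])
    for (nm in names(pos)) {
      serial <- serial + 1L
      xyz <- pos[[nm]]
      lines <- c(lines, pdb_atom_line(serial, nm, res3[i], "A", i,
                                      xyz[1], xyz[2], xyz[3],
                                      substr(nm, 1L, 1L)))
    }
  }
  lines <- c(lines, "TER", "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# ---- synthetic training sets ---------------------------------------------

#' Default generating coefficients of the synthetic training data
#'
#' Chosen so that, in feature-sd units, the evolutionary block (PVS, CI,
#' LOR, PYF) carries about three times the weight of the structural block
#' (PoP, MAE, SNP), the balance the model is designed to exhibit on real
#' deep-mutational-scanning data.
#'
#' @return a [varfit_coefficients()] object.
#' @export
default_true_alpha <- function() {
  varfit_coefficients(
    c(RSA = 0.002, PoP = -0.04, MAE = -0.03, SNP = -0.03,
      PVS = 0.06, CI = -0.40, LOR = 0.06, PYF = 0.06,
      `(Intercept)` = 0.90),
    provenance = "synthetic ground truth")
}

#' Generate a synthetic deep-mutational-scanning training set
#'
#' Draws per-variant feature vectors with realistic ranges (RSA in
#' percent, stability scores in kcal/mol-like units, alignment scores on
#' their natural scales) and computes fitness as the linear model plus
#' Gaussian noise.  The generating coefficients are recorded in the
#' `true_alpha` attribute, so fits can be checked against ground truth.
#'
#' @param n number of variants.
#' @param true_alpha generating coefficients
#'   ([varfit_coefficients()] or named 9-vector); default
#'   [default_true_alpha()].
#' @param noise_sd fitness noise standard deviation (default 0.1).
#' @param L protein length used for variant positions.
#' @param seed integer seed.
#' @return data.frame (a training set) with `protein`, `position`, `wt`,
#'   `mt`, the eight features and `fitness`; attribute `true_alpha`.
#' @export
make_synthetic_dms <- function(n, true_alpha = default_true_alpha(),
                               noise_sd = 0.1, L = 200L, seed = 1L) {
  if (inherits(true_alpha, "varfit_coefficients"))
    true_alpha <- true_alpha$alpha
  with_seed(seed, {
    position <- sample.int(L, n, replace = TRUE)
    wt <- sample(AA20, n, replace = TRUE)
    mt <- vapply(wt, function(a) sample(setdiff(AA20, a), 1L), character(1L))
    df <- data.frame(
      protein = "synthetic", position = position, wt = wt, mt = mt,
      RSA = stats::runif(n, 0, 100),
      PoP = stats::rnorm(n, 1.0, 1.5),
      MAE = stats::rnorm(n, 0.5, 1.0),
      SNP = stats::rnorm(n, 0.0, 1.0),
      PVS = stats::rnorm(n, -2.0, 2.0),
      CI = pmin(abs(stats::rnorm(n, 0.25, 0.15)), 1),
      LOR = stats::rnorm(n, -3.0, 2.0),
      PYF = stats::rnorm(n, -0.5, 1.0),
      stringsAsFactors = FALSE)
    X <- as.matrix(df[, FEATURE_NAMES])
    df$fitness <- unname(drop(X %*% true_alpha[FEATURE_NAMES])) +
      true_alpha[["(Intercept)"]] + stats::rnorm(n, sd = noise_sd)
    base::structure(df, true_alpha = true_alpha)
  })
}
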