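## Structures are stored as a plain atom table (one row per heavy atom)
## with class "pdb_structure"; parsing is delegated to bio3d and the
## altloc / hydrogen / water policy is applied on top.

# van der Waals radii (Angstrom) by element, Bondi set; fallback 1.70
ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                   H = 1.20, SE = 1.90)

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records, strips hydrogens and waters, and resolves
#' alternate locations by highest occupancy (ties broken by lexicographic
#' altloc id).  All chains are retained.
#'
#' @param path path to a PDB-format file.
#' @return object of class `pdb_structure`: a data.frame with columns
#'   `chain`, `resno`, `insert`, `resname`, `atom`, `element`, `x`, `y`,
#'   `z`, `occupancy`, plus attribute `chains`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop_varfit("structure file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop_varfit("cannot parse PDB file ", path, ": ",
                                conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop_varfit("no ATOM records in ", path)
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  elem <- at$elesy
  missing_elem <- is.na(elem) | !nzchar(trimws(elem))
  # infer element from the atom name when the element column is blank
  elem[missing_elem] <- substr(gsub("[0-9'\"]", "", at$elety[missing_elem]), 1L, 1L)
  elem <- toupper(trimws(elem))
  at$element <- elem
  at <- at[elem != "H" & elem != "D", , drop = FALSE]
  if (nrow(at) == 0L) stop_varfit("no heavy protein atoms in ", path)
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
    stop_varfit("non-finite coordinates in ", path)
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc: keep highest occupancy, then lexicographically first id;
  # file order is restored afterwards
  at$.idx <- seq_len(nrow(at))
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(at$.idx), , drop = FALSE]
  out <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                    resname = at$resid, atom = at$elety,
                    element = at$element, x = at$x, y = at$y, z = at$z,
                    occupancy = at$o, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("pdb_structure", "data.frame"),
            chains = unique(out$chain))
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("Structure: %d heavy atoms, chains %s\n", nrow(x),
              paste(attr(x, "chains"), collapse = ", ")))
  invisible(x)
}

# deterministic near-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent accessible surface area by Shrake-Rupley quadrature
#'
#' Places `n_points` quadrature points on each heavy atom's solvent-
#' expanded sphere (atom radius + probe radius) and counts the points not
#' buried inside any neighbouring atom's expanded sphere.  All chains in
#' the structure occlude each other, so a multimeric input yields the
#' complex accessibility; compute chains separately for isolated-chain
#' values.
#'
#' @param structure a [`pdb_structure`][read_structure], or a data.frame
#'   with columns `x`, `y`, `z` and either `element` or `radius`.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4).
#' @param n_points quadrature points per atom (default 960; minimum 100).
#' @param radii named vector of per-element radii in Angstrom.
#' @return data.frame keyed by (`chain`, `resno`, `insert`, `resname`)
#'   with per-residue `asa` in square Angstrom, plus attribute
#'   `atom_asa` carrying the per-atom values.
#' @export
compute_sasa <- function(structure, probe_radius = 1.4, n_points = 960L,
                         radii = ELEMENT_RADII) {
  if (probe_radius <= 0) stop_varfit("probe_radius must be > 0")
  if (n_points < 100L) stop_varfit("n_points must be >= 100")
  xyz <- cbind(structure$x, structure$y, structure$z)
  n <- nrow(xyz)
  if ("radius" %in% names(structure)) {
    r <- structure$radius
  } else {
    r <- radii[structure$element]
    r[is.na(r)] <- 1.70
  }
  R <- r + probe_radius
  pts <- sphere_points(n_points)
  atom_asa <- numeric(n)
  # neighbour cutoff: spheres can only intersect within R_i + max(R_j)
  maxR <- max(R)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (R[i] + maxR)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (R[i] + R[nb])^2]
    p <- pts * R[i]
    p <- sweep(p, 2L, xyz[i, ], "+")
    if (length(nb) > 0L) {
      exposed <- rep(TRUE, n_points)
      for (j in nb) {
        dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
          (p[, 3] - xyz[j, 3])^2
        exposed <- exposed & (dj >= R[j]^2)
        if (!any(exposed)) break
      }
      frac <- sum(exposed) / n_points
    } else {
      frac <- 1
    }
    atom_asa[i] <- frac * 4 * pi * R[i]^2
  }
  if (!all(c("chain", "resno", "resname") %in% names(structure))) {
    return(base::structure(data.frame(asa = sum(atom_asa)), atom_asa = atom_asa))
  }
  ins <- structure$insert %||% rep("", n)
  key <- paste(structure$chain, structure$resno, ins, sep = "|")
  idx <- !duplicated(key)
  res <- data.frame(chain = structure$chain[idx], resno = structure$resno[idx],
                    insert = ins[idx], resname = structure$resname[idx],
                    stringsAsFactors = FALSE)
  res$asa <- as.numeric(tapply(atom_asa, factor(key, levels = key[idx]), sum))
  rownames(res) <- NULL
  base::structure(res, atom_asa = atom_asa)
}

#' Relative solvent accessibility
#'
#' RSA(%) is the residue's accessible surface area as a percentage of its
#' reference area in an extended Gly-X-Gly tripeptide.  The bundled
#' reference table uses the Tien et al. (2013) theoretical maxima; a
#' custom table (data.frame with `resname` and `max_asa`) may be supplied.
#' Values slightly above 100% can occur for exposed conformations and are
#' deliberately not clamped, so a linear model sees the raw feature.
#'
#' @param asa per-residue ASA table from [compute_sasa()].
#' @param reference reference table; default the bundled Gly-X-Gly set.
#' @return `asa` with an `rsa` column added.
#' @export
relative_solvent_accessibility <- function(asa, reference = max_asa_reference()) {
  unknown <- setdiff(unique(asa$resname), reference$resname)
  if (length(unknown) > 0L)
    stop_varfit("no reference ASA for residue type(s): ",
                paste(unknown, collapse = ", "))
  ref <- stats::setNames(reference$max_asa, reference$resname)
  asa$rsa <- 100 * asa$asa / ref[asa$resname]
  asa
}

#' Bundled Gly-X-Gly maximum-ASA reference table
#'
#' @return data.frame with columns `resname`, `aa`, `max_asa` (Angstrom^2).
#' @export
max_asa_reference <- function() {
  utils::read.csv(system.file("extdata", "max_asa_gxg.csv",
                              package = "varfit"),
                  stringsAsFactors = FALSE)
}

#' One-letter sequence of a structure chain
#'
#' @param structure a [`pdb_structure`][read_structure].
#' @param chain chain id.
#' @return character vector of one-letter residues in chain order, with
#'   attribute `resno` (author residue numbers) and `insert`.
#' @export
chain_sequence <- function(structure, chain) {
  if (!(chain %in% attr(structure, "chains")))
    stop_varfit("chain '", chain, "' not in structure (available: ",
                paste(attr(structure, "chains"), collapse = ", "), ")")
  at <- structure[structure$chain == chain, , drop = FALSE]
  key <- paste(at$resno, at$insert, sep = "|")
  idx <- !duplicated(key)
  aa <- AA3TO1[at$resname[idx]]
  aa[is.na(aa)] <- "X"
  base::structure(unname(aa), resno = at$resno[idx], insert = at$insert[idx])
}

#' Map query sequence positions to structure residues
#'
#' Aligns the chain's observed residues to the query sequence (global
#' alignment, so unresolved loops are tolerated as gaps) and returns, for
#' each 1-based query position, the matching structure residue.  The
#' mapping is sequence-based: author residue numbering never enters it.
#'
#' @param structure a [`pdb_structure`][read_structure].
#' @param chain chain id.
#' @param query query sequence (character vector or single string).
#' @return data.frame with one row per query position: `position`, `aa`,
#'   `resno`, `insert`, `mapped` (FALSE for query positions without a
#'   resolved residue).  Errors if fewer than half the query maps.
#' @export
map_structure_to_sequence <- function(structure, chain, query) {
  if (length(query) == 1L && nchar(query) > 1L)
    query <- strsplit(query, "", fixed = TRUE)[[1L]]
  sseq <- chain_sequence(structure, chain)
  al <- Biostrings::pairwiseAlignment(
    paste(sseq, collapse = ""), paste(query, collapse = ""),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  qpos <- 0L; spos <- 0L
  map <- rep(NA_integer_, length(query))
  same <- rep(NA, length(query))
  for (k in seq_along(p)) {
    if (s[k] != "-") qpos <- qpos + 1L
    if (p[k] != "-") spos <- spos + 1L
    if (s[k] != "-" && p[k] != "-") {
      map[qpos] <- spos
      same[qpos] <- s[k] == p[k]
    }
  }
  mapped <- !is.na(map) & same %in% TRUE
  if (mean(mapped) < 0.5)
    stop_varfit("fewer than 50% of query positions map to chain '", chain,
                "': wrong chain or wrong structure?")
  data.frame(position = seq_along(query), aa = query,
             resno = ifelse(mapped, attr(sseq, "resno")[map], NA_integer_),
             insert = ifelse(mapped, attr(sseq, "insert")[map], NA_character_),
             mapped = mapped,
             mismatch = !is.na(map) & same %in% FALSE,
             stringsAsFactors = FALSE)
}
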