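## Synthetic ensembles with controlled motion structure, and toy mmCIF files
## with declared-but-unresolved residues. All generators are
## seed-deterministic and return the ground truth (modes, amplitudes,
## angles) alongside the data, enabling parameter-recovery tests without
## any downloaded structures.

## Self-avoiding random walk of Calpha positions: 3.8 A steps with
## directional persistence, rejecting steps closer than 3.5 A to any
## non-adjacent previous position.
random_ca_trace <- function(m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- matrix(0, m, 3L)
  dir <- unitv(stats::rnorm(3))
  for (i in 2:m) {
    for (try in 1:100) {
      cand_dir <- unitv(dir + 0.6 * stats::rnorm(3))
      cand <- pos[i - 1L, ] + 3.8 * cand_dir
      if (i <= 3L) break
      d <- sqrt(rowSums(sweep(pos[1:(i - 2L), , drop = FALSE], 2L, cand)^2))
      if (min(d) > 3.5) break
    }
    pos[i, ] <- cand
    dir <- cand_dir
  }
  pos
}

## Expand a Calpha trace to an idealised N/CA/C/O backbone: N and C placed
## at canonical bond lengths in a local frame built from the chain tangent;
## O reconstructed from the peptide geometry. Good enough for format
## validity; not stereochemically scored.
expand_backbone <- function(ca) {
  m <- nrow(ca)
  tangent <- function(i) {
    a <- if (i == 1L) ca[1L, ] else ca[i - 1L, ]
    b <- if (i == m) ca[m, ] else ca[i + 1L, ]
    unitv(b - a)
  }
  out <- vector("list", m)
  for (i in seq_len(m)) {
    t_i <- tangent(i)
    ref <- if (abs(t_i[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u_i <- unitv(pracma_cross(t_i, ref))
    N <- ca[i, ] - 1.46 * unitv(t_i + 0.4 * u_i)
    C <- ca[i, ] + 1.52 * unitv(t_i - 0.4 * u_i)
    out[[i]] <- rbind(N = N, CA = ca[i, ], C = C)
  }
  O <- vector("list", m)
  for (i in seq_len(m)) {
    n_next <- if (i < m) out[[i + 1L]]["N", ] else NULL
    O[[i]] <- reconstruct_carbonyl_oxygen(out[[i]]["CA", ], out[[i]]["C", ],
                                          n_next)
  }
  list(frames = out, O = O)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

random_sequence <- function(m) paste(sample(AA20, m, replace = TRUE),
                                     collapse = "")

## Build a chain record from explicit Calpha coordinates and a sequence;
## positions in `unresolved` are lowercase with no coordinates.
record_from_ca <- function(structure_id, chain_id, ca, sequence,
                           unresolved = integer(0)) {
  m <- nrow(ca)
  chars <- strsplit(sequence, "")[[1]]
  stopifnot(length(chars) == m)
  bb <- expand_backbone(ca)
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    if (i %in% unresolved) {
      rows[[i]] <- empty_residue_row(i, tolower(chars[i]))
    } else {
      r <- empty_residue_row(i, toupper(chars[i]))
      r[c("n_x", "n_y", "n_z")] <- bb$frames[[i]]["N", ]
      r[c("ca_x", "ca_y", "ca_z")] <- ca[i, ]
      r[c("c_x", "c_y", "c_z")] <- bb$frames[[i]]["C", ]
      r[c("o_x", "o_y", "o_z")] <- bb$O[[i]]
      r$resolved <- TRUE
      rows[[i]] <- r
    }
  }
  chain_record(structure_id, chain_id, do.call(rbind, rows))
}

## Draw per-member unresolved position sets, keeping every column resolved
## somewhere and every member >= 5 resolved residues.
draw_missing <- function(n, m, missing_fraction) {
  if (missing_fraction <= 0) return(rep(list(integer(0)), n))
  repeat {
    miss <- lapply(seq_len(n), function(i) {
      u <- which(stats::runif(m) < missing_fraction)
      if (length(u) > m - 5L) u <- u[seq_len(m - 5L)]
      u
    })
    covered <- rep(0L, m)
    for (u in miss) covered[setdiff(seq_len(m), u)] <-
      covered[setdiff(seq_len(m), u)] + 1L
    if (all(covered >= 1L)) return(miss)
  }
}

#' Synthetic ensemble with a single linear motion
#'
#' A base Calpha trace (self-avoiding random walk, 3.8 A steps) deformed
#' along one fixed direction, with per-conformation amplitudes regularly
#' spanning [-amplitude, +amplitude], plus isotropic Gaussian noise. The
#' direction has unit per-atom root-mean-square displacement, so the RMSD
#' between two noise-free conformations equals their amplitude difference
#' in Angstrom (the maximum pairwise RMSD is 2 amplitude). Noise-free
#' output has exactly one non-null PCA mode.
#'
#' @param m positions; `n` conformations.
#' @param n number of conformations.
#' @param amplitude half-range of the motion amplitudes (Angstrom).
#' @param noise_sd isotropic per-coordinate noise (Angstrom).
#' @param missing_fraction fraction of residues declared but unresolved.
#' @param seed RNG seed.
#' @return List: `ensemble` (a gap-filled `conf_ensemble` in a common
#'   frame), `mode` (ground-truth direction as a 3m unit vector),
#'   `amplitudes`, `base` (3m base conformation), `sequence`.
#' @export
make_linear_motion_ensemble <- function(m = 50L, n = 30L, amplitude = 2,
                                        noise_sd = 0, missing_fraction = 0,
                                        seed = 1L) {
  set.seed(seed)
  base <- random_ca_trace(m)
  D <- matrix(stats::rnorm(3L * m), m, 3L)
  D <- D / sqrt(sum(D^2) / m)  # unit per-atom RMS displacement
  amps <- seq(-amplitude, amplitude, length.out = n)
  sequence <- random_sequence(m)
  miss <- draw_missing(n, m, missing_fraction)
  records <- vector("list", n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    ca <- base + amps[i] * D +
      matrix(stats::rnorm(3L * m, sd = noise_sd), m, 3L)
    sid <- sprintf("S%03d", i)
    records[[i]] <- record_from_ca(sid, "A", ca, sequence, miss[[i]])
    seqs[i] <- records[[i]]$sequence
  }
  ids <- vapply(records, function(r) r$id, "")
  msa <- protein_msa(ids, seqs)
  ens <- conf_ensemble(records, msa, weighting = missing_fraction > 0)
  ens$reference_index <- select_reference(msa)
  ens$superimposed <- TRUE   # generated in a common frame
  ens <- fill_gaps(ens)
  list(ensemble = ens, mode = flatten_xyz(D) / vnorm(flatten_xyz(D)),
       amplitudes = amps, base = flatten_xyz(base), sequence = sequence)
}

#' Synthetic hinge ensemble: two rigid arms opening about a pivot
#'
#' Two straight pseudo-domains of m/2 residues joined at the origin open
#' symmetrically: conformation i places the arms at +/- theta_i/2 around the
#' x axis in the xy plane. The inter-domain centroid distance
#' 2 r_c sin(theta/2) is strictly monotone in the angle. Both domains move,
#' so the dominant PCA mode is collective.
#'
#' @param m positions (even).
#' @param n conformations.
#' @param angle_base central opening angle (radians).
#' @param angle_range sampled range around `angle_base` (radians).
#' @param noise_sd isotropic per-coordinate noise (Angstrom).
#' @param seed RNG seed.
#' @return List: `ensemble`, `angles`, `interdomain_distance` (per
#'   conformation), `domains` (index list).
#' @export
make_hinge_ensemble <- function(m = 40L, n = 20L, angle_base = pi / 2,
                                angle_range = pi / 4, noise_sd = 0,
                                seed = 1L) {
  set.seed(seed)
  M <- m %/% 2L
  m <- 2L * M
  thetas <- if (angle_range == 0) rep(angle_base, n)
  else angle_base + seq(-angle_range / 2, angle_range / 2, length.out = n)
  sequence <- random_sequence(m)
  arm <- function(theta_half, sign) {
    d <- c(cos(theta_half), sign * sin(theta_half), 0)
    t(vapply(seq_len(M), function(j) 3.8 * j * d, numeric(3)))
  }
  records <- vector("list", n)
  dists <- numeric(n)
  for (i in seq_len(n)) {
    a1 <- arm(thetas[i] / 2, +1)
    a2 <- arm(thetas[i] / 2, -1)
    ca <- rbind(a1[rev(seq_len(M)), , drop = FALSE], a2)
    ca <- ca + matrix(stats::rnorm(3L * m, sd = noise_sd), m, 3L)
    dists[i] <- vnorm(colMeans(a1) - colMeans(a2))
    records[[i]] <- record_from_ca(sprintf("H%03d", i), "A", ca, sequence)
  }
  ids <- vapply(records, function(r) r$id, "")
  msa <- protein_msa(ids, vapply(records, function(r) r$sequence, ""))
  ens <- conf_ensemble(records, msa, weighting = FALSE)
  ens$reference_index <- select_reference(msa)
  ens$superimposed <- TRUE
  ens <- fill_gaps(ens)
  list(ensemble = ens, angles = thetas, interdomain_distance = dists,
       domains = list(seq_len(M), M + seq_len(M)))
}

## ---------------------------------------------------------------------------
## Toy mmCIF fixture files

write_fixture_cif <- function(path, structure_id, chains,
                              duplicate_model = FALSE) {
  ## chains: named list chain_id -> chain_record
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("data_", structure_id), con)
  writeLines(c("#", "loop_", "_entity_poly_seq.entity_id",
               "_entity_poly_seq.num", "_entity_poly_seq.mon_id"), con)
  ent <- 0L
  for (ch in names(chains)) {
    ent <- ent + 1L
    res <- chains[[ch]]$residues
    for (i in seq_len(nrow(res)))
      writeLines(sprintf("%d %d %s", ent, res$seq_id[i],
                         aa_one_to_three(res$aa[i])), con)
  }
  writeLines(c("#", "loop_", "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.label_atom_id", "_atom_site.label_comp_id",
               "_atom_site.label_asym_id", "_atom_site.auth_asym_id",
               "_atom_site.label_entity_id", "_atom_site.label_seq_id",
               "_atom_site.Cartn_x", "_atom_site.Cartn_y",
               "_atom_site.Cartn_z", "_atom_site.pdbx_PDB_model_num"), con)
  aid <- 0L
  n_models <- if (duplicate_model) 2L else 1L
  for (mdl in seq_len(n_models)) {
    shift <- if (mdl == 2L) 25 else 0  # decoy model, ignored by extraction
    ent <- 0L
    for (ch in names(chains)) {
      ent <- ent + 1L
      rows <- record_atom_rows(chains[[ch]])
      for (i in seq_len(nrow(rows))) {
        aid <- aid + 1L
        writeLines(sprintf("ATOM %d %s %s %s %s %d %d %s %s %s %d",
                           aid, rows$atom[i], rows$mon[i], ch, ch, ent,
                           rows$seq_id[i], fmt_num(rows$x[i] + shift),
                           fmt_num(rows$y[i]), fmt_num(rows$z[i]), mdl), con)
      }
    }
  }
  writeLines("#", con)
  invisible(path)
}

#' Write a gapped mmCIF fixture dataset
#'
#' Generates a linear-motion ensemble and writes one toy mmCIF file per
#' conformation, each declaring the full polymer sequence in
#' `_entity_poly_seq` while a controlled fraction of residues lack atoms.
#' The first file carries a second (decoy) model, exercising the
#' first-model-only contract; optionally one file carries a short decoy
#' second chain. The ground-truth ensemble is returned for end-to-end
#' comparison after a full pipeline run.
#'
#' @inheritParams make_linear_motion_ensemble
#' @param out_dir directory for the CIF files (created if absent).
#' @param decoy_chain add an unrelated short second chain to one file?
#' @param duplicate write an extra entry duplicating the first conformation
#'   (identical sequence and coordinates), to exercise the redundancy rule?
#' @return The [make_linear_motion_ensemble()] ground-truth list, plus
#'   `files` (the written paths) and `duplicate_id` when requested.
#' @export
make_gapped_cif_fixture <- function(out_dir, m = 30L, n = 8L, amplitude = 2,
                                    noise_sd = 0, missing_fraction = 0.2,
                                    seed = 1L, decoy_chain = FALSE,
                                    duplicate = FALSE) {
  stopifnot(missing_fraction < 1)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  gt <- make_linear_motion_ensemble(m = m, n = n, amplitude = amplitude,
                                    noise_sd = noise_sd,
                                    missing_fraction = missing_fraction,
                                    seed = seed)
  ens <- gt$ensemble
  files <- character(ens$n)
  for (i in seq_len(ens$n)) {
    rec <- ens$members[[i]]
    chains <- setNames(list(rec), rec$chain_id)
    if (decoy_chain && i == 2L) {
      dec <- record_from_ca("ZZZZ", "B", random_ca_trace(8L, seed = seed + 999L),
                            random_sequence(8L))
      dec$structure_id <- rec$structure_id
      dec$chain_id <- "B"
      dec$id <- paste0(rec$structure_id, "_B")
      chains[["B"]] <- dec
    }
    files[i] <- file.path(out_dir, paste0(rec$structure_id, ".cif"))
    write_fixture_cif(files[i], rec$structure_id, chains,
                      duplicate_model = i == 1L)
  }
  if (duplicate) {
    dup <- ens$members[[1L]]
    dup$structure_id <- "SDUP"
    dup$id <- paste0("SDUP_", dup$chain_id)
    f <- file.path(out_dir, "SDUP.cif")
    write_fixture_cif(f, "SDUP", setNames(list(dup), dup$chain_id))
    files <- c(files, f)
    gt$duplicate_id <- dup$id
  }
  gt$files <- files
  gt
}
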