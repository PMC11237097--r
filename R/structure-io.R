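## Structure I/O: read mmCIF (and PDB) files into chain records with explicit
## missing-data encoding; write ensembles as multi-model files plus alignment
## and RMSD matrix.
##
## Chain records encode each polypeptide chain as an ordered residue table:
## resolved residues carry N/CA/C/O backbone coordinates and an uppercase
## one-letter code; residues declared in the entity's polymer sequence but
## lacking (complete) backbone coordinates are lowercase and carry no
## coordinates; unknown or unmappable residues are 'X'.

CARBONYL_CO_LENGTH <- 1.23  # Angstrom, canonical C=O bond length

#' Construct a chain record
#'
#' @param structure_id 4-character PDB-style entry code.
#' @param chain_id author chain label.
#' @param residues data frame with columns `seq_id`, `aa` (case-encoded
#'   one-letter code), backbone coordinate columns `n_x..o_z`, `resolved`,
#'   `o_reconstructed`.
#' @param validate drop-enforce the minimal-size invariants (>= 5 resolved
#'   residues, >= 5 non-'X' letters)?
#' @return An object of class `chain_record`, or `NULL` if `validate` is TRUE
#'   and the chain fails the size invariants.
#' @export
chain_record <- function(structure_id, chain_id, residues, validate = TRUE) {
  stopifnot(is.data.frame(residues))
  seq_chars <- residues$aa
  if (validate) {
    n_resolved <- sum(residues$resolved)
    n_known <- sum(toupper(seq_chars) != "X")
    if (n_resolved < 5L || n_known < 5L) return(NULL)
  }
  structure(list(
    structure_id = structure_id,
    chain_id = chain_id,
    id = paste0(structure_id, "_", chain_id),
    residues = residues,
    sequence = paste(seq_chars, collapse = "")
  ), class = "chain_record")
}

#' @export
print.chain_record <- function(x, ...) {
  cat(sprintf("<chain_record %s: %d residues (%d resolved)>\n",
              x$id, nrow(x$residues), sum(x$residues$resolved)))
  invisible(x)
}

empty_residue_row <- function(seq_id, aa) {
  data.frame(seq_id = seq_id, aa = aa,
             n_x = NA_real_, n_y = NA_real_, n_z = NA_real_,
             ca_x = NA_real_, ca_y = NA_real_, ca_z = NA_real_,
             c_x = NA_real_, c_y = NA_real_, c_z = NA_real_,
             o_x = NA_real_, o_y = NA_real_, o_z = NA_real_,
             resolved = FALSE, o_reconstructed = FALSE,
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Minimal mmCIF parsing: tokenises a file and returns the categories needed
## here (_atom_site, _entity_poly_seq, _pdbx_struct_assembly) as data frames.

cif_tokenize <- function(lines) {
  lines <- sub("^#.*$", "", lines)
  txt <- paste(lines, collapse = "\n")
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", txt, perl = TRUE)
  toks <- regmatches(txt, m)[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

parse_cif <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop(sprintf(
                      "cannot read structure file '%s': %s", path, conditionMessage(e))))
  toks <- cif_tokenize(lines)
  if (length(toks) == 0L || !any(startsWith(toks, "data_")))
    stop(sprintf("file '%s' is not a parseable mmCIF document", path))
  cats <- list()
  block <- NA_character_
  i <- 1L
  n <- length(toks)
  is_tag <- function(t) startsWith(t, "_")
  is_kw <- function(t) startsWith(t, "data_") || t == "loop_" || is_tag(t)
  while (i <= n) {
    t <- toks[i]
    if (startsWith(t, "data_")) {
      block <- sub("^data_", "", t)
      i <- i + 1L
    } else if (t == "loop_") {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && is_tag(toks[i])) { tags <- c(tags, toks[i]); i <- i + 1L }
      vals <- character(0)
      while (i <= n && !is_kw(toks[i])) { vals <- c(vals, toks[i]); i <- i + 1L }
      if (length(tags) > 0L && length(vals) %% length(tags) == 0L && length(vals) > 0L) {
        mat <- matrix(vals, ncol = length(tags), byrow = TRUE)
        parts <- strsplit(tags, ".", fixed = TRUE)
        cat_name <- sub("^_", "", vapply(parts, `[`, "", 1L))[1]
        item <- vapply(parts, function(p) paste(p[-1], collapse = "."), "")
        df <- as.data.frame(mat, stringsAsFactors = FALSE)
        names(df) <- item
        cats[[cat_name]] <- df
      }
    } else if (is_tag(t)) {
      if (i + 1L <= n && !is_kw(toks[i + 1L])) {
        parts <- strsplit(t, ".", fixed = TRUE)[[1]]
        cat_name <- sub("^_", "", parts[1])
        item <- paste(parts[-1], collapse = ".")
        old <- cats[[cat_name]]
        if (is.null(old)) old <- data.frame(row.names = 1L)
        old[[item]] <- toks[i + 1L]
        cats[[cat_name]] <- old
        i <- i + 2L
      } else i <- i + 1L
    } else i <- i + 1L
  }
  list(block = block, categories = cats)
}

## ---------------------------------------------------------------------------
## Chain extraction

#' Extract polypeptide chain records from a structure file
#'
#' Reads an mmCIF (or PDB) document and returns one chain record per
#' polypeptide chain of the first model. Residues declared in the entity's
#' polymer sequence (`_entity_poly_seq`) but lacking complete N/CA/C backbone
#' coordinates appear as lowercase letters and contribute no coordinates;
#' unknown or unmappable modified residues appear as 'X'. Missing carbonyl
#' oxygens are reconstructed from the backbone geometry. Chains with fewer
#' than 5 resolved residues, or fewer than 5 non-'X' letters, are dropped.
#'
#' @param path path to an mmCIF (`.cif`) or PDB (`.pdb`) file.
#' @param monomer_only if TRUE, drop all chains of entries whose selected
#'   biological assembly (first listed; in its absence, the file content
#'   itself) contains more than one polypeptide chain.
#' @return A list of `chain_record` objects (possibly empty).
#' @export
extract_chain_records <- function(path, monomer_only = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") {
    models <- read_pdb_models(path)
    if (length(models) == 0L) return(list())
    recs <- models[[1]]
  } else {
    cif <- parse_cif(path)
    recs <- cif_chain_records(cif, model = 1L)
    if (monomer_only && !cif_is_monomeric(cif)) return(list())
  }
  if (monomer_only && ext == "pdb" && length(recs) > 1L) return(list())
  Filter(Negate(is.null), recs)
}

cif_polymer_atoms <- function(cif, model = 1L) {
  at <- cif$categories[["atom_site"]]
  if (is.null(at)) return(NULL)
  need <- c("label_atom_id", "label_comp_id", "label_seq_id",
            "Cartn_x", "Cartn_y", "Cartn_z")
  if (!all(need %in% names(at)))
    stop("atom_site category lacks required items")
  at$chain <- at[["auth_asym_id"]] %||% at[["label_asym_id"]]
  if (is.null(at$chain)) at$chain <- "A"
  mdl <- at[["pdbx_PDB_model_num"]]
  if (!is.null(mdl)) {
    mnum <- suppressWarnings(as.integer(mdl))
    mnum[is.na(mnum)] <- 1L
    at <- at[mnum == sort(unique(mnum))[model], , drop = FALSE]
  }
  at <- at[at$label_seq_id != "." & at$label_seq_id != "?", , drop = FALSE]
  if (nrow(at) == 0L) return(NULL)
  at
}

cif_chain_records <- function(cif, model = 1L) {
  at <- cif_polymer_atoms(cif, model)
  if (is.null(at)) return(list())
  sid <- toupper(cif$block %||% "XXXX")
  sid <- substr(sid, 1L, 4L)
  poly <- cif$categories[["entity_poly_seq"]]
  out <- list()
  for (ch in unique(at$chain)) {
    ach <- at[at$chain == ch, , drop = FALSE]
    entity <- (ach[["label_entity_id"]] %||% rep("1", nrow(ach)))[1]
    full <- NULL
    if (!is.null(poly) && all(c("entity_id", "num", "mon_id") %in% names(poly))) {
      pe <- poly[poly$entity_id == entity, , drop = FALSE]
      if (nrow(pe) > 0L)
        full <- data.frame(seq_id = as.integer(pe$num),
                           mon = pe$mon_id, stringsAsFactors = FALSE)
    }
    out[[length(out) + 1L]] <- build_chain_record(sid, ch, ach, full)
  }
  out
}

## Assemble a chain record from observed atoms plus (optionally) the declared
## polymer sequence.
build_chain_record <- function(sid, ch, atoms, full_seq) {
  sq <- as.integer(atoms$label_seq_id)
  obs <- split(seq_len(nrow(atoms)), sq)
  get_atom <- function(rows, name) {
    k <- rows[atoms$label_atom_id[rows] == name]
    if (length(k) == 0L) return(NULL)
    as.numeric(atoms[k[1], c("Cartn_x", "Cartn_y", "Cartn_z")])
  }
  seq_ids <- if (!is.null(full_seq)) full_seq$seq_id else sort(unique(sq))
  rows <- vector("list", length(seq_ids))
  for (k in seq_along(seq_ids)) {
    sidk <- seq_ids[k]
    mon <- if (!is.null(full_seq)) full_seq$mon[k] else
      atoms$label_comp_id[obs[[as.character(sidk)]][1]]
    aa <- aa_three_to_one(mon)
    r <- empty_residue_row(sidk, tolower(aa))
    rws <- obs[[as.character(sidk)]]
    if (!is.null(rws)) {
      ## residue name of resolved residues comes from the atom records
      aa <- aa_three_to_one(atoms$label_comp_id[rws[1]])
      N <- get_atom(rws, "N"); CA <- get_atom(rws, "CA")
      C <- get_atom(rws, "C"); O <- get_atom(rws, "O")
      if (!is.null(N) && !is.null(CA) && !is.null(C)) {
        r$aa <- aa
        r[c("n_x", "n_y", "n_z")] <- N
        r[c("ca_x", "ca_y", "ca_z")] <- CA
        r[c("c_x", "c_y", "c_z")] <- C
        if (!is.null(O)) r[c("o_x", "o_y", "o_z")] <- O
        r$resolved <- TRUE
      } else {
        r$aa <- tolower(aa)  # partial backbone: disregarded, kept lowercase
      }
    }
    rows[[k]] <- r
  }
  res <- do.call(rbind, rows)
  res <- reconstruct_missing_oxygens(res)
  chain_record(sid, ch, res)
}

cif_is_monomeric <- function(cif) {
  asm <- cif$categories[["pdbx_struct_assembly"]]
  if (!is.null(asm) && "oligomeric_count" %in% names(asm)) {
    oc <- suppressWarnings(as.integer(asm$oligomeric_count[1]))
    if (!is.na(oc)) return(oc == 1L)
  }
  at <- cif_polymer_atoms(cif, 1L)
  if (is.null(at)) return(TRUE)
  length(unique(at$chain)) == 1L
}

## ---------------------------------------------------------------------------
## Carbonyl oxygen reconstruction

#' Reconstruct a missing carbonyl oxygen
#'
#' Places the backbone O atom at the canonical C=O bond length (1.23 A) from
#' the carbonyl carbon, in the peptide plane defined by CA(i), C(i) and
#' N(i+1), along the bisector of the angle opposite those two neighbours
#' (trans to the following residue). For chain-terminal residues (no
#' following N) the O is placed along the CA->C direction extended by the
#' same bond length; callers flag that case.
#'
#' @param ca,c coordinates (length-3) of the residue's CA and C atoms.
#' @param n_next coordinates of the following residue's N atom, or NULL for a
#'   terminal residue.
#' @return A length-3 numeric vector: the O position in Angstrom.
#' @export
reconstruct_carbonyl_oxygen <- function(ca, c, n_next = NULL) {
  if (is.null(n_next)) {
    return(c + CARBONYL_CO_LENGTH * unitv(c - ca))
  }
  u1 <- unitv(c - ca)
  u2 <- unitv(c - n_next)
  c + CARBONYL_CO_LENGTH * unitv(u1 + u2)
}

reconstruct_missing_oxygens <- function(res) {
  idx <- which(res$resolved & is.na(res$o_x))
  for (i in idx) {
    ca <- as.numeric(res[i, c("ca_x", "ca_y", "ca_z")])
    cc <- as.numeric(res[i, c("c_x", "c_y", "c_z")])
    n_next <- NULL
    if (i < nrow(res) && res$resolved[i + 1L] &&
        res$seq_id[i + 1L] == res$seq_id[i] + 1L)
      n_next <- as.numeric(res[i + 1L, c("n_x", "n_y", "n_z")])
    res[i, c("o_x", "o_y", "o_z")] <- reconstruct_carbonyl_oxygen(ca, cc, n_next)
    res$o_reconstructed[i] <- TRUE
  }
  res
}

## ---------------------------------------------------------------------------
## PDB reading (minimal, fixed-column) -- returns records per model

read_pdb_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sid <- toupper(sub("\\.pdb$", "", basename(path), ignore.case = TRUE))
  sid <- substr(paste0(sid, "XXXX"), 1L, 4L)
  model_no <- 1L
  models <- list()
  cur <- list()
  flush_model <- function(cur) {
    if (length(cur) == 0L) return(NULL)
    lapply(cur, function(df) {
      df <- do.call(rbind, df)
      build_pdb_chain(sid, df)
    })
  }
  for (ln in lines) {
    tag <- substr(ln, 1, 6)
    if (startsWith(tag, "MODEL")) {
      if (length(cur) > 0L) { models[[length(models) + 1L]] <- flush_model(cur); cur <- list() }
    } else if (tag == "ATOM  " || tag == "HETATM") {
      ch <- substr(ln, 22, 22)
      rec <- data.frame(
        atom = trimws(substr(ln, 13, 16)),
        mon = trimws(substr(ln, 18, 20)),
        chain = ch,
        seq_id = as.integer(trimws(substr(ln, 23, 26))),
        x = as.numeric(substr(ln, 31, 38)),
        y = as.numeric(substr(ln, 39, 46)),
        z = as.numeric(substr(ln, 47, 54)),
        stringsAsFactors = FALSE)
      if (is.null(cur[[ch]])) cur[[ch]] <- list()
      cur[[ch]][[length(cur[[ch]]) + 1L]] <- rec
    } else if (startsWith(tag, "ENDMDL")) {
      models[[length(models) + 1L]] <- flush_model(cur); cur <- list()
    }
  }
  if (length(cur) > 0L) models[[length(models) + 1L]] <- flush_model(cur)
  models
}

build_pdb_chain <- function(sid, df) {
  at <- data.frame(label_atom_id = df$atom, label_comp_id = df$mon,
                   label_seq_id = as.character(df$seq_id),
                   Cartn_x = df$x, Cartn_y = df$y, Cartn_z = df$z,
                   chain = df$chain, stringsAsFactors = FALSE)
  build_chain_record(sid, df$chain[1], at, NULL)
}

## ---------------------------------------------------------------------------
## Writers

fmt_num <- function(x) formatC(x, format = "f", digits = 3)

#' Write a conformational ensemble to disk
#'
#' Writes the ensemble as one multi-model coordinate file (models may carry
#' different sequences), the matching multiple sequence alignment in FASTA
#' format (same row order as the models), the n x n pairwise RMSD matrix as
#' TSV, and a small JSON metadata file (reference id, options).
#'
#' @param ensemble a `conf_ensemble` (see [conf_ensemble()]).
#' @param out_dir output directory (created if absent).
#' @param format `"cif"` or `"pdb"` for the coordinate file.
#' @param name basename for the output files.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_ensemble_files <- function(ensemble, out_dir, format = c("cif", "pdb"),
                                 name = "ensemble") {
  format <- match.arg(format)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stopifnot(length(ensemble$members) >= 1L)
  coord <- file.path(out_dir, paste0(name, ".", format))
  if (format == "cif") write_multimodel_cif(ensemble$members, coord)
  else write_multimodel_pdb(ensemble$members, coord)
  fasta <- file.path(out_dir, paste0(name, ".fasta"))
  write_fasta(ensemble$msa$ids, ensemble$msa$seqs, fasta)
  rmsd_path <- file.path(out_dir, paste0(name, "_rmsd.tsv"))
  M <- rmsd_matrix(ensemble)$values
  utils::write.table(round(M, 6), rmsd_path, sep = "\t", quote = FALSE,
                     col.names = NA)
  meta_path <- file.path(out_dir, paste0(name, "_meta.json"))
  meta <- list(reference_id = ensemble$member_ids[ensemble$reference_index],
               n = length(ensemble$member_ids),
               m = ensemble$m,
               weighting = isTRUE(ensemble$weighting),
               centering = ensemble$centering %||% "mean")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(coordinates = coord, msa = fasta, rmsd = rmsd_path,
              meta = meta_path))
}

write_fasta <- function(ids, seqs, path) {
  x <- Biostrings::BStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(x, path)
}

read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  list(ids = names(x), seqs = unname(as.character(x)))
}

record_atom_rows <- function(rec) {
  res <- rec$residues[rec$residues$resolved, , drop = FALSE]
  if (nrow(res) == 0L) return(NULL)
  atoms <- c("N", "CA", "C", "O")
  cols <- list(N = c("n_x", "n_y", "n_z"), CA = c("ca_x", "ca_y", "ca_z"),
               C = c("c_x", "c_y", "c_z"), O = c("o_x", "o_y", "o_z"))
  out <- list()
  for (i in seq_len(nrow(res))) {
    for (a in atoms) {
      xyz <- as.numeric(res[i, cols[[a]]])
      if (anyNA(xyz)) next
      out[[length(out) + 1L]] <- data.frame(
        atom = a, mon = aa_one_to_three(res$aa[i]), seq_id = res$seq_id[i],
        x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

write_multimodel_cif <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("data_", records[[1]]$structure_id),
               "#", "loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.label_atom_id", "_atom_site.label_comp_id",
               "_atom_site.label_asym_id", "_atom_site.auth_asym_id",
               "_atom_site.label_entity_id", "_atom_site.label_seq_id",
               "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
               "_atom_site.pdbx_PDB_model_num"), con)
  aid <- 0L
  for (mi in seq_along(records)) {
    rows <- record_atom_rows(records[[mi]])
    if (is.null(rows)) next
    ch <- records[[mi]]$chain_id
    for (i in seq_len(nrow(rows))) {
      aid <- aid + 1L
      writeLines(sprintf("ATOM %d %s %s %s %s 1 %d %s %s %s %d",
                         aid, rows$atom[i], rows$mon[i], ch, ch,
                         rows$seq_id[i], fmt_num(rows$x[i]), fmt_num(rows$y[i]),
                         fmt_num(rows$z[i]), mi), con)
    }
  }
  writeLines("#", con)
  invisible(path)
}

write_multimodel_pdb <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (mi in seq_along(records)) {
    writeLines(sprintf("MODEL     %4d", mi), con)
    rows <- record_atom_rows(records[[mi]])
    ch <- records[[mi]]$chain_id
    if (!is.null(rows)) {
      for (i in seq_len(nrow(rows))) {
        nm4 <- sprintf(" %-3s", rows$atom[i])  # name starts at column 14
        writeLines(sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                           i, nm4, rows$mon[i], substr(ch, 1, 1), rows$seq_id[i],
                           rows$x[i], rows$y[i], rows$z[i]), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read all models of a multi-model ensemble file
#'
#' Companion reader to [write_ensemble_files()]: unlike
#' [extract_chain_records()], which by contract reads only the first model,
#' this returns one chain record per model.
#'
#' @param path multi-model `.cif` or `.pdb` file.
#' @return A list of `chain_record` objects, one per model.
#' @export
read_ensemble_models <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") {
    models <- read_pdb_models(path)
    return(lapply(models, function(m) m[[1]]))
  }
  cif <- parse_cif(path)
  at <- cif$categories[["atom_site"]]
  if (is.null(at)) stop(sprintf("no atom records in '%s'", path))
  mdl <- as.integer(at[["pdbx_PDB_model_num"]] %||% rep("1", nrow(at)))
  nm <- sort(unique(mdl))
  lapply(seq_along(nm), function(k) {
    recs <- cif_chain_records(cif, model = k)
    recs[[1]]
  })
}
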