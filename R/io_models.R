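#' Particle pose tables
#'
#' TSV with documented columns `id, tomo, npc, spoke, phi, theta, psi
#' (ZYZ degrees), sx, sy, sz (Angstrom), cc`, with `#`-prefixed header
#' comments recording provenance (seed, config hash). Round-trips through
#' [read_pose_table()].
#'
#' @param poses list of [pose()]s or alignment results (with `$pose`,
#'   `$cc_score`).
#' @param path output TSV path.
#' @param id,tomo,npc,spoke identifier columns (recycled).
#' @param cc cross-correlation column; taken from alignment results when
#'   present.
#' @param comment named character vector written as `# key: value` lines.
#' @return `read_pose_table` returns `list(table, poses)`.
#' @export
write_pose_table <- function(poses, path, id = seq_along(poses), tomo = 1,
                             npc = 1, spoke = 0, cc = NA_real_,
                             comment = c()) {
  if (length(poses) && !inherits(poses[[1]], "pose")) {
    cc <- vapply(poses, function(r) r$cc_score, 0)
    poses <- lapply(poses, function(r) r$pose)
  }
  ang <- t(vapply(poses, pose_angles, numeric(3)))
  sh <- t(vapply(poses, function(p) p$shift, numeric(3)))
  df <- data.frame(id = id, tomo = tomo, npc = npc, spoke = spoke,
                   phi = ang[, 1], theta = ang[, 2], psi = ang[, 3],
                   sx = sh[, 1], sy = sh[, 2], sz = sh[, 3], cc = cc)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(comment)) writeLines(sprintf("# %s: %s", k, comment[[k]]), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pose_table
#' @export
read_pose_table <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  poses <- lapply(seq_len(nrow(df)), function(i) {
    pose(rot_zyz(df$phi[i], df$theta[i], df$psi[i]),
         c(df$sx[i], df$sy[i], df$sz[i]))
  })
  list(table = df, poses = poses)
}

#' Write a scaffold model as a Calpha-only PDB file
#'
#' Chains are assigned single-letter ids in model order (documented in
#' REMARK records when more than 62 chains are present the ids wrap).
#'
#' @param model a [scaffold_model()] or a [coord_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_ca <- function(model, path) {
  chain_letters <- c(LETTERS, letters, 0:9)
  lines <- c("REMARK   1 CALPHA-ONLY MODEL WRITTEN BY POREKIT")
  serial <- 0
  if (inherits(model, "coord_set")) {
    model <- scaffold_model(list(list(chain_id = "A", species = "X",
                                      ring = "IR", subcomplex = "X",
                                      copy_index = 1L, asym_unit = 0L,
                                      ca = model$coords)), 1)
  }
  for (i in seq_along(model$chains)) {
    ch <- model$chains[[i]]
    cid <- chain_letters[(i - 1) %% length(chain_letters) + 1]
    lines <- c(lines, sprintf("REMARK   2 CHAIN %s = %s", cid, ch$chain_id))
    for (r in seq_len(nrow(ch$ca))) {
      serial <- serial + 1
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial %% 100000, cid, r %% 10000,
        ch$ca[r, 1], ch$ca[r, 2], ch$ca[r, 3]))
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read Calpha coordinates from a PDB or mmCIF file
#'
#' Minimal readers: PDB `ATOM` records with atom name CA, or mmCIF
#' `atom_site` loops. Returns one [coord_set()] per chain.
#'
#' @param path input path; format chosen by extension (`.cif` = mmCIF).
#' @return Named list of [coord_set()]s keyed by chain id.
#' @export
read_ca_model <- function(path) {
  if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    return(read_cif_ca(path))
  }
  lines <- readLines(path)
  at <- lines[grepl("^ATOM  ", lines) &
                trimws(substr(lines, 13, 16)) == "CA"]
  if (length(at) == 0) stop("read_ca_model(): no CA ATOM records in ", path)
  chain <- substr(at, 22, 22)
  xyz <- cbind(as.numeric(substr(at, 31, 38)),
               as.numeric(substr(at, 39, 46)),
               as.numeric(substr(at, 47, 54)))
  resno <- as.integer(substr(at, 23, 26))
  out <- lapply(unique(chain), function(cid) {
    sel <- chain == cid
    coord_set(xyz[sel, , drop = FALSE], resno[sel])
  })
  names(out) <- unique(chain)
  out
}

read_cif_ca <- function(path) {
  lines <- readLines(path)
  loop_start <- which(grepl("^_atom_site\\.", lines))
  if (length(loop_start) == 0) stop("read_cif_ca(): no atom_site loop in ", path)
  fields <- sub("^_atom_site\\.", "", trimws(lines[loop_start]))
  body_start <- max(loop_start) + 1
  rows <- list()
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
        startsWith(ln, "loop_")) break
    rows[[length(rows) + 1]] <- strsplit(ln, "\\s+")[[1]]
  }
  tab <- do.call(rbind, rows)
  colnames(tab) <- fields[seq_len(ncol(tab))]
  sel <- tab[, "label_atom_id"] == "CA"
  tab <- tab[sel, , drop = FALSE]
  chain <- tab[, "label_asym_id"]
  out <- lapply(unique(chain), function(cid) {
    s <- chain == cid
    coord_set(cbind(as.numeric(tab[s, "Cartn_x"]),
                    as.numeric(tab[s, "Cartn_y"]),
                    as.numeric(tab[s, "Cartn_z"])),
              as.integer(tab[s, "label_seq_id"]))
  })
  names(out) <- unique(chain)
  out
}

#' Write a scaffold model as minimal mmCIF
#'
#' @param model a [scaffold_model()].
#' @param path output path.
#' @export
write_cif_ca <- function(model, path) {
  lines <- c("data_porekit_model", "#", "loop_",
             "_atom_site.group_PDB", "_atom_site.id",
             "_atom_site.label_atom_id", "_atom_site.label_comp_id",
             "_atom_site.label_asym_id", "_atom_site.label_seq_id",
             "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z")
  serial <- 0
  chain_letters <- c(LETTERS, letters, 0:9)
  for (i in seq_along(model$chains)) {
    ch <- model$chains[[i]]
    cid <- chain_letters[(i - 1) %% length(chain_letters) + 1]
    for (r in seq_len(nrow(ch$ca))) {
      serial <- serial + 1
      lines <- c(lines, sprintf("ATOM %d CA ALA %s %d %.3f %.3f %.3f",
                                serial, cid, r,
                                ch$ca[r, 1], ch$ca[r, 2], ch$ca[r, 3]))
    }
  }
  writeLines(c(lines, "#"), path)
  invisible(path)
}
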