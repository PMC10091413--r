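#' Residue keys
#'
#' Residues are identified throughout the package by a compact key string
#' `"chain:number"` (or `"chain:number:insert"` when a PDB insertion code
#' is present), e.g. `"A:104"`.  Keys are unique within a
#' [structure_model()] and sort by chain, then residue number, then
#' insertion code.
#'
#' @param chain chain identifier (single string).
#' @param number residue number (integer).
#' @param insert optional insertion code.
#' @return a key string.
#' @export
#' @examples
#' residue_key("A", 104)
residue_key <- function(chain, number, insert = NA) {
  ins <- ifelse(is.na(insert) | insert == "", "", paste0(":", insert))
  paste0(chain, ":", as.integer(number), ins)
}

parse_residue_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  data.frame(
    chain  = vapply(parts, `[`, "", 1),
    number = as.integer(vapply(parts, `[`, "", 2)),
    insert = vapply(parts, function(p) if (length(p) > 2) p[3] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
}

sort_residue_keys <- function(keys) {
  p <- parse_residue_key(keys)
  keys[order(p$chain, p$number, p$insert, method = "radix", na.last = FALSE)]
}

atom_res_keys <- function(atoms) {
  residue_key(atoms$chain, atoms$resnum, atoms$insert)
}

#' Receptor structure container
#'
#' A `structure_model` holds the heavy atoms of one receptor conformation
#' as a data frame (`serial`, `name`, `element`, `resname`, `chain`,
#' `resnum`, `insert`, `x`, `y`, `z`), plus an `id` tag and free-text
#' provenance.  All coordinates are in Angstrom.  Hetero groups read from
#' a PDB file are kept separately as [ligand_pose()] objects in
#' `$ligands`, never mixed into the polymer table.
#'
#' @param id model tag, e.g. `"HM"` or `"AF2"`.
#' @param atoms atom data frame as described above.
#' @param provenance free text describing where the model came from.
#' @param ligands optional list of [ligand_pose()] objects.
#' @return an object of class `structure_model`.
#' @export
structure_model <- function(id, atoms, provenance = "", ligands = list()) {
  need <- c("serial", "name", "element", "resname", "chain", "resnum",
            "insert", "x", "y", "z")
  missing <- setdiff(need, names(atoms))
  if (length(missing))
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(atoms) == 0) stop("a structure model must contain at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  atoms$insert <- as.character(atoms$insert)
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, provenance = provenance,
                 ligands = ligands),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  keys <- unique(atom_res_keys(x$atoms))
  cat("structure_model '", x$id, "': ", length(keys), " residues, ",
      nrow(x$atoms), " atoms, ", length(x$ligands), " hetero group(s)\n",
      sep = "")
  invisible(x)
}

#' Ligand pose container
#'
#' Heavy-atom coordinates of one docked (or crystallographic) ligand,
#' tied to the receptor conformation it belongs to.  Scores follow the
#' docking convention: kcal/mol, lower is better.
#'
#' @param pose_id unique pose tag.
#' @param model_id id of the receptor [structure_model()] this pose
#'   belongs to.
#' @param atoms data frame with columns `name`, `element`, `x`, `y`, `z`.
#' @param score optional docking score (finite).
#' @param round optional round label (`"IFD1"`, `"IFD2"`, `"IFD3"`,
#'   `"screen"`).
#' @param resname residue name used when writing PDB output.
#' @return an object of class `ligand_pose`.
#' @export
ligand_pose <- function(pose_id, model_id, atoms, score = NULL, round = NULL,
                        resname = "LIG") {
  if (is.matrix(atoms)) {
    if (nrow(atoms) < 1) stop("a ligand pose must contain at least one atom")
    atoms <- data.frame(name = paste0("C", seq_len(nrow(atoms))),
                        element = "C", x = atoms[, 1], y = atoms[, 2],
                        z = atoms[, 3], stringsAsFactors = FALSE)
  }
  if (nrow(atoms) < 1) stop("a ligand pose must contain at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite ligand coordinates")
  if (!is.null(score) && !is.finite(score)) stop("score must be finite")
  rownames(atoms) <- NULL
  structure(list(pose_id = pose_id, model_id = model_id, atoms = atoms,
                 score = score, round = round, resname = resname),
            class = "ligand_pose")
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat("ligand_pose '", x$pose_id, "' (model ", x$model_id, "): ",
      nrow(x$atoms), " atoms",
      if (!is.null(x$score)) sprintf(", score %.2f", x$score) else "",
      "\n", sep = "")
  invisible(x)
}

# coordinate matrix (n x 3) of a model / pose / matrix
as_xyz <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    return(unname(x))
  }
  if (is.numeric(x) && length(x) == 3) return(matrix(x, 1, 3))
  if (inherits(x, c("structure_model", "ligand_pose")))
    return(unname(as.matrix(x$atoms[, c("x", "y", "z")])))
  if (is.data.frame(x) && all(c("x", "y", "z") %in% names(x)))
    return(unname(as.matrix(x[, c("x", "y", "z")])))
  stop("cannot interpret input as 3D coordinates")
}

#' Residue keys of a model
#'
#' @param model a [structure_model()].
#' @return character vector of keys in atom-table order (unique).
#' @export
residue_keys <- function(model) {
  unique(atom_res_keys(model$atoms))
}

# rows of the atom table belonging to one residue key
residue_rows <- function(model, key) {
  which(atom_res_keys(model$atoms) == key)
}

# n x 3 matrix of one named atom per residue key, in key order
atom_coords_by_key <- function(model, keys, atom = "CA") {
  a <- model$atoms[model$atoms$name == atom, , drop = FALSE]
  idx <- match(keys, atom_res_keys(a))
  if (anyNA(idx))
    stop("residue ", keys[which(is.na(idx))[1]], " lacks atom ", atom,
         " in model ", model$id)
  unname(as.matrix(a[idx, c("x", "y", "z")]))
}

# named 3-vector of one atom of one residue, or NULL
residue_atom_xyz <- function(model, key, atom = "CA") {
  i <- residue_rows(model, key)
  i <- i[model$atoms$name[i] == atom]
  if (!length(i)) return(NULL)
  as.numeric(model$atoms[i[1], c("x", "y", "z")])
}

#' Read receptor structures (and hetero groups) from a PDB file
#'
#' Parsing is delegated to [bio3d::read.pdb()].  Each `MODEL` block
#' yields one [structure_model()]; `HETATM` groups are split off into
#' [ligand_pose()] objects attached as `$ligands`, grouped by (chain,
#' residue number, residue name).  Alternate locations other than blank
#' or `'A'` are dropped (single-conformer semantics).
#'
#' @param path PDB file path.
#' @param id base model id; defaults to the file name without extension.
#'   Multi-model files get ids `"<id>_1"`, `"<id>_2"`, ...
#' @return a single `structure_model`, or a list of them for multi-model
#'   files.
#' @export
read_structure <- function(path, id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty PDB file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  a <- pdb$atom
  a$chain[is.na(a$chain)] <- "A"
  a$elesy[is.na(a$elesy) | a$elesy == ""] <- substr(trimws(a$elety[is.na(a$elesy) | a$elesy == ""]), 1, 1)
  n_models <- nrow(pdb$xyz)
  polymer <- a$type == "ATOM"
  build_one <- function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    atoms <- data.frame(serial = a$eleno, name = a$elety, element = a$elesy,
                        resname = a$resid, chain = a$chain, resnum = a$resno,
                        insert = ifelse(is.na(a$insert), "", a$insert),
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        stringsAsFactors = FALSE)
    mid <- if (n_models > 1) paste0(id, "_", m) else id
    het <- atoms[!polymer, , drop = FALSE]
    ligs <- list()
    if (nrow(het)) {
      grp <- paste(het$resname, het$chain, het$resnum, sep = "_")
      for (g in unique(grp)) {
        hg <- het[grp == g, , drop = FALSE]
        ligs[[g]] <- ligand_pose(
          pose_id = paste0(mid, "_", g), model_id = mid,
          atoms = hg[, c("name", "element", "x", "y", "z")],
          resname = hg$resname[1])
      }
    }
    structure_model(mid, atoms[polymer, , drop = FALSE],
                    provenance = paste0("read from ", path), ligands = ligs)
  }
  models <- lapply(seq_len(n_models), build_one)
  if (n_models == 1) models[[1]] else models
}

#' Write a receptor structure (with its ligands) to a PDB file
#'
#' Inverse of [read_structure()]: coordinates survive a
#' write-then-read round trip to the PDB precision of 1e-3 Angstrom,
#' and residue identity is preserved.
#'
#' @param model a [structure_model()].
#' @param path output path.
#' @param ligands list of [ligand_pose()] to append as `HETATM` records;
#'   defaults to the model's own hetero groups.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, ligands = model$ligands) {
  at <- model$atoms
  type <- rep("ATOM", nrow(at))
  for (lig in ligands) {
    la <- lig$atoms
    n0 <- if (nrow(at)) max(at$serial) else 0
    at <- rbind(at, data.frame(
      serial = n0 + seq_len(nrow(la)), name = la$name, element = la$element,
      resname = lig$resname %||% "LIG", chain = at$chain[1] %||% "A",
      resnum = max(at$resnum) + 1, insert = "",
      x = la$x, y = la$y, z = la$z, stringsAsFactors = FALSE))
    type <- c(type, rep("HETATM", nrow(la)))
  }
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = type, resno = at$resnum, resid = at$resname,
                   eleno = at$serial, elety = at$name, chain = at$chain,
                   insert = ifelse(at$insert == "", NA, at$insert),
                   elesy = at$element)
  invisible(path)
}

#' Write an ensemble of conformations as a multi-model PDB
#'
#' All models must share the same atom identity (names, residues); only
#' coordinates may differ.
#'
#' @param models list of [structure_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(models, path) {
  stopifnot(length(models) >= 1)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (m in seq_along(models)) {
    write_structure(models[[m]], tmp)
    body <- readLines(tmp)
    body <- body[!grepl("^END", body)]
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(body, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select residues within a distance of a point set
#'
#' A residue is selected iff any of its atoms lies within `radius`
#' (closed ball, `<=`) of any point of `center`.  Returns keys sorted by
#' chain then residue number, so the selection is deterministic.
#'
#' @param model a [structure_model()].
#' @param center a 3-vector, an `n x 3` matrix, or a [ligand_pose()].
#' @param radius selection radius in Angstrom (> 0).
#' @return character vector of residue keys.
#' @export
select_within <- function(model, center, radius) {
  if (radius <= 0) stop("radius must be positive")
  if (nrow(model$atoms) == 0) stop("empty model")
  d2 <- cross_dist2(as_xyz(model), as_xyz(center))
  hit <- apply(d2, 1, min) <= radius^2 + 1e-12
  sort_residue_keys(unique(atom_res_keys(model$atoms)[hit]))
}

# ideal tetrahedral C-beta from backbone N, CA, C (bond length 1.522 A);
# the sign of the out-of-plane component gives L-amino-acid chirality
ideal_cb <- function(N, CA, C) {
  n1 <- unit3(N - CA)
  c1 <- unit3(C - CA)
  if (sqrt(sum((n1 + c1)^2)) < 1e-6)
    stop("degenerate (collinear) backbone: cannot place an ideal C-beta")
  u <- unit3(n1 + c1)
  v <- unit3(cross3(n1, c1))
  a <- (1 / 3) / sum(u * n1)      # enforce cos(N-CA-CB) = -1/3
  a <- min(max(a, -0.999), 0.999)
  b <- sqrt(1 - a^2)
  CA + 1.522 * (-a * u + b * v)
}

#' Mutate one residue to alanine
#'
#' Side-chain truncation as used for in-silico alanine scanning of
#' binding-site residues: atoms beyond C-beta are removed, the residue is
#' renamed `ALA`, and for glycine input a C-beta is constructed at ideal
#' tetrahedral geometry (1.522 Angstrom from C-alpha).  All other
#' residues are untouched.
#'
#' @param model a [structure_model()].
#' @param key residue key, e.g. `"A:104"`.
#' @return the mutated `structure_model`.  If the residue already is
#'   alanine the model is returned unchanged with a warning.
#' @export
mutate_to_alanine <- function(model, key) {
  rows <- residue_rows(model, key)
  if (!length(rows)) stop("no residue ", key, " in model ", model$id)
  res <- model$atoms[rows, ]
  bb <- c("N", "CA", "C", "O")
  if (!all(bb %in% res$name))
    stop("residue ", key, " lacks backbone atom(s): ",
         paste(setdiff(bb, res$name), collapse = ", "))
  if (res$resname[1] == "ALA") {
    warning("residue ", key, " already is alanine; model returned unchanged")
    return(model)
  }
  keep <- res$name %in% c(bb, "CB", "OXT")
  res <- res[keep, , drop = FALSE]
  if (!"CB" %in% res$name) {
    g <- function(n) as.numeric(res[res$name == n, c("x", "y", "z")][1, ])
    cb <- ideal_cb(g("N"), g("CA"), g("C"))
    new_row <- res[res$name == "CA", , drop = FALSE]
    new_row$name <- "CB"; new_row$element <- "C"
    new_row$serial <- max(model$atoms$serial) + 1
    new_row[, c("x", "y", "z")] <- as.list(cb)
    res <- rbind(res, new_row)
  }
  res$resname <- "ALA"
  before <- model$atoms[seq_len(min(rows) - 1), , drop = FALSE]
  after_idx <- setdiff(seq_len(nrow(model$atoms)), c(seq_len(min(rows) - 1), rows))
  out <- rbind(before, res, model$atoms[after_idx, , drop = FALSE])
  structure_model(model$id, out,
                  provenance = paste0(model$provenance, "; ", key, "->ALA"),
                  ligands = model$ligands)
}

#' Read a Ballesteros-Weinstein numbering map
#'
#' Generic GPCR residue labels (helix.position, e.g. `3.32`) let
#' binding-site residues be compared across receptors.  The map is
#' supplied as a 3-column CSV (`chain`, `resnum`, `bw_label`); labels are
#' validated against the `digit.point.digits` pattern and must be unique.
#'
#' @param path CSV path.
#' @return named character vector: residue key -> BW label.
#' @export
read_bw_map <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("chain", "resnum", "bw_label")
  if (!all(need %in% names(tab)))
    stop("BW map must have columns: ", paste(need, collapse = ", "))
  lab <- as.character(tab$bw_label)
  bad <- !grepl("^[0-9]+\\.[0-9]+$", lab)
  if (any(bad)) stop("malformed BW label(s): ", paste(lab[bad], collapse = ", "))
  if (anyDuplicated(lab)) stop("BW labels must be unique (injective map)")
  keys <- residue_key(tab$chain, tab$resnum)
  if (anyDuplicated(keys)) stop("duplicate residues in BW map")
  setNames(lab, keys)
}
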