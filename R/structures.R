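# Reading crystal structures and extracting labeled methyl probes.
#
# PDB handling is delegated to bio3d; this file owns the methyl-probe
# bookkeeping: which carbon of which residue type carries the label, the
# stereo tag of Leu/Val probes, multi-model ensembles, and carbon-carbon
# distance tables.

#' Default methyl labeling scheme
#'
#' Named character vector mapping 3-letter residue types to the carbon
#' atom carrying the [13C,1H3] label: Ala-beta (CB), Ile-delta1 (CD1),
#' Leu-delta2 (CD2, proS), Val-gamma2 (CG2, proS), Met-epsilon (CE),
#' Thr-gamma2 (CG2). This is the MIL(proS)V(proS)AT scheme.
#'
#' @param types optional character vector of types to retain, as either
#'   3-letter codes (`"ALA"`) or short names (`"Ala"`).
#' @return named character vector (names: residue types, values: atom names)
#' @export
#' @examples
#' default_labeling_scheme()
#' default_labeling_scheme(c("Ala", "Leu"))
default_labeling_scheme <- function(types = NULL) {
  scheme <- c(ALA = "CB", ILE = "CD1", LEU = "CD2", VAL = "CG2",
              MET = "CE", THR = "CG2")
  if (!is.null(types)) {
    types <- toupper(ifelse(types %in% names(.type2aa3), .type2aa3[types],
                            types))
    unknown <- setdiff(types, names(scheme))
    if (length(unknown))
      stop("unknown residue type(s) in scheme: ",
           paste(unknown, collapse = ", "))
    scheme <- scheme[types]
  }
  scheme
}

.methyl_code <- c(CB = "b", CG1 = "g1", CG2 = "g2", CD1 = "d1",
                  CD2 = "d2", CE = "e")

.methyl_stereo <- function(resid, atom) {
  if (resid == "LEU" && atom == "CD2") return("proS")
  if (resid == "LEU" && atom == "CD1") return("proR")
  if (resid == "VAL" && atom == "CG2") return("proS")
  if (resid == "VAL" && atom == "CG1") return("proR")
  "n/a"
}

#' Read a PDB structure into one model per MODEL record
#'
#' Wraps [bio3d::read.pdb()]. Only ATOM records are kept. Alternate
#' locations are resolved by keeping the highest-occupancy conformer;
#' true duplicate atom records (same chain, residue number, atom name and
#' altLoc) are an error naming the offending atom.
#'
#' @param path path to a PDB file
#' @param chain optional chain identifier; default: the first chain in the
#'   file (multi-chain files require explicit selection otherwise)
#' @return a list of `structure_model` objects (data frames with columns
#'   `chain`, `resno`, `resid`, `atom`, `x`, `y`, `z`; attribute
#'   `model_id`), one per MODEL in file order. Class `"structure_model_list"`.
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in '", path, "'")

  if (is.null(chain)) {
    chain <- at$chain[1]
    if (is.na(chain)) chain <- NA
  }
  keep <- if (is.na(chain)) is.na(at$chain) | at$chain == at$chain[1]
          else !is.na(at$chain) & at$chain == chain
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records for chain '", chain, "'")

  # altLoc: keep the highest-occupancy conformer of each atom
  alt <- ifelse(is.na(at$alt), "", at$alt)
  atom_key <- paste(at$chain, at$resno, at$elety, sep = "|")
  dup <- duplicated(paste(atom_key, alt, sep = "|"))
  if (any(dup)) {
    d <- at[which(dup)[1], ]
    stop("duplicate atom record: chain ", d$chain, " residue ", d$resno,
         " atom ", d$elety)
  }
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(atom_key, -occ)
  at <- at[ord, , drop = FALSE]
  sel <- !duplicated(atom_key[ord])
  row_idx <- match(rownames(at)[sel], rownames(pdb$atom))
  at <- at[sel, , drop = FALSE]

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)

  models <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    ci <- 3 * (row_idx - 1)
    df <- data.frame(
      chain = at$chain, resno = at$resno, resid = at$resid,
      atom = at$elety,
      x = xyz[m, ci + 1], y = xyz[m, ci + 2], z = xyz[m, ci + 3],
      stringsAsFactors = FALSE)
    df <- df[order(df$resno, df$atom), , drop = FALSE]
    rownames(df) <- NULL
    if (any(!is.finite(c(df$x, df$y, df$z))))
      stop("non-finite coordinates in model ", m, " of '", path, "'")
    attr(df, "model_id") <- as.character(m)
    class(df) <- c("structure_model", "data.frame")
    models[[m]] <- df
  }
  class(models) <- c("structure_model_list", "list")
  models
}

#' Build a structure model from raw coordinates
#'
#' Low-level constructor used by the synthetic-data generators and tests.
#'
#' @param resno integer residue numbers
#' @param resid 3-letter residue types
#' @param atom atom names
#' @param xyz numeric matrix (n x 3), Angstrom
#' @param chain chain identifier
#' @param model_id model label
#' @return a `structure_model` data frame
#' @export
structure_model <- function(resno, resid, atom, xyz, chain = "A",
                            model_id = "1") {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, length(resno) == nrow(xyz),
            length(resid) == nrow(xyz), length(atom) == nrow(xyz))
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  key <- paste(chain, resno, atom)
  if (anyDuplicated(key))
    stop("duplicate atom record: ", key[duplicated(key)][1])
  df <- data.frame(chain = chain, resno = as.integer(resno),
                   resid = toupper(resid), atom = atom,
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   stringsAsFactors = FALSE)
  attr(df, "model_id") <- model_id
  class(df) <- c("structure_model", "data.frame")
  df
}

#' Write a structure model to a PDB file
#'
#' @param model a `structure_model` (or a methyl table from
#'   [extract_methyls()], whose carbons are written as their labeled atoms)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_structure <- function(model, path) {
  if (inherits(model, "methyl_table")) {
    model <- structure_model(model$resno, model$resid,
                             model$atom,
                             cbind(model$x, model$y, model$z),
                             chain = attr(model, "chain") %||% "A")
  }
  xyz <- as.vector(t(as.matrix(model[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = model$resno, resid = model$resid,
                   elety = model$atom, chain = model$chain,
                   eleno = seq_len(nrow(model)))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract labeled methyl probes from a structure model
#'
#' One probe per labeled residue: the carbon named by the labeling scheme.
#' Residues of a labeled type that lack the named carbon are reported in
#' the `"missing"` attribute, never silently dropped.
#'
#' @param model a `structure_model` (from [read_structure()] or
#'   [structure_model()])
#' @param scheme labeling scheme, see [default_labeling_scheme()]
#' @return a `methyl_table` data frame with columns `key` (e.g. `"L85"`),
#'   `resno`, `resid`, `residue_type` (`"Leu"`...), `methyl_id`
#'   (e.g. `"Leu-d2"`), `stereo` (`"proS"`, `"proR"` or `"n/a"`), `atom`,
#'   `x`, `y`, `z`; attribute `missing`: data frame of skipped residues.
#' @export
extract_methyls <- function(model, scheme = default_labeling_scheme()) {
  unknown <- setdiff(names(scheme), names(.aa3totype))
  if (length(unknown))
    stop("unknown residue type(s) in scheme: ",
         paste(unknown, collapse = ", "))

  res <- unique(model[, c("chain", "resno", "resid")])
  res <- res[res$resid %in% names(scheme), , drop = FALSE]
  rows <- list(); miss <- list()
  for (i in seq_len(nrow(res))) {
    rn <- res$resno[i]; rt <- res$resid[i]
    want <- scheme[[rt]]
    hit <- which(model$resno == rn & model$resid == rt &
                   model$atom == want)
    if (length(hit) == 0) {
      miss[[length(miss) + 1]] <- data.frame(
        resno = rn, resid = rt, atom = want, stringsAsFactors = FALSE)
      next
    }
    hit <- hit[1]
    rows[[length(rows) + 1]] <- data.frame(
      key = paste0(.aa3to1[[rt]], rn),
      resno = rn, resid = rt,
      residue_type = .aa3totype[[rt]],
      methyl_id = paste0(.aa3totype[[rt]], "-", .methyl_code[[want]]),
      stereo = .methyl_stereo(rt, want),
      atom = want,
      x = model$x[hit], y = model$y[hit], z = model$z[hit],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(key = character(), resno = integer(), resid = character(),
               residue_type = character(), methyl_id = character(),
               stereo = character(), atom = character(),
               x = numeric(), y = numeric(), z = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(out$resno), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missing") <- if (length(miss)) do.call(rbind, miss) else
    data.frame(resno = integer(), resid = character(), atom = character(),
               stringsAsFactors = FALSE)
  attr(out, "chain") <- model$chain[1]
  attr(out, "model_id") <- attr(model, "model_id")
  class(out) <- c("methyl_table", "data.frame")
  out
}

#' Build a multi-model methyl ensemble
#'
#' Extracts methyl probes from each model and intersects the probe sets:
#' only methyls present in every member model are kept, in input model
#' order. Used for ensemble-averaged PCS/PRE calculations.
#'
#' @param models list of `structure_model` objects (a
#'   `structure_model_list` works directly)
#' @param scheme labeling scheme, see [default_labeling_scheme()]
#' @return a `methyl_ensemble`: list with `keys` (common probe keys),
#'   `residue_type`, `coords` (array n_common x 3 x n_models) and
#'   `tables` (per-model `methyl_table`s restricted to the common set)
#' @export
build_ensemble <- function(models, scheme = default_labeling_scheme()) {
  if (inherits(models, "structure_model")) models <- list(models)
  if (length(models) < 1) stop("need at least one model")
  tabs <- lapply(models, function(m)
    if (inherits(m, "methyl_table")) m else extract_methyls(m, scheme))
  keys <- Reduce(intersect, lapply(tabs, function(t) t$key))
  if (length(keys) == 0) stop("no methyl probes common to all models")
  keys <- tabs[[1]]$key[tabs[[1]]$key %in% keys]   # order of first model
  tabs <- lapply(tabs, function(t) {
    t2 <- t[match(keys, t$key), , drop = FALSE]
    rownames(t2) <- NULL
    class(t2) <- class(t)
    t2
  })
  coords <- array(NA_real_, dim = c(length(keys), 3, length(tabs)),
                  dimnames = list(keys, c("x", "y", "z"), NULL))
  for (m in seq_along(tabs))
    coords[, , m] <- as.matrix(tabs[[m]][, c("x", "y", "z")])
  out <- list(keys = keys,
              residue_type = tabs[[1]]$residue_type,
              coords = coords, tables = tabs)
  class(out) <- "methyl_ensemble"
  out
}

#' Inter-methyl carbon-carbon distance table
#'
#' Symmetric Euclidean distance matrix between methyl carbons of one
#' model, the geometric quantity the NOE cut-off is compared against.
#'
#' @param methyls a `methyl_table`
#' @return symmetric numeric matrix (Angstrom) with probe keys as dimnames
#' @export
methyl_distances <- function(methyls) {
  xyz <- as.matrix(methyls[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- list(methyls$key, methyls$key)
  d
}
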